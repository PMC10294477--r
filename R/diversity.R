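#' Shannon index of a clone proportion vector
#'
#' `H = -sum(p_i * ln(p_i))` over the non-zero proportions (natural
#' logarithm; the limit convention `0 * ln 0 = 0` applies). The input must
#' sum to 1 within `tol`.
#'
#' @param p Non-negative proportion vector summing to 1.
#' @param tol Tolerance on `sum(p) - 1` (default 1e-6).
#' @return Shannon index in nats.
#' @examples
#' shannon_index(rep(0.25, 4))  # log(4)
#' @export
shannon_index <- function(p, tol = 1e-6) {
  stopifnot(all(p >= 0))
  if (abs(sum(p) - 1) > tol) {
    stop("proportions must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  q <- p[p > 0]
  -sum(q * log(q))
}

#' Shannon count (effective number of clones)
#'
#' `Sh = exp(H)`: the number of equally contributing clones that would give
#' the observed diversity. For a uniform distribution over `s` clones,
#' `Sh = s`; skewed distributions give `Sh < s`, which makes the Shannon
#' count robust to many tiny noise barcodes.
#'
#' @inheritParams shannon_index
#' @return Effective clone count.
#' @examples
#' shannon_count(rep(1 / 8, 8))  # 8
#' @export
shannon_count <- function(p, tol = 1e-6) {
  exp(shannon_index(p, tol))
}

#' Per-sample diversity summary
#'
#' @inheritParams shannon_index
#' @return Tibble with `s` (number of observed barcodes), `H` (Shannon
#'   index) and `Sh` (Shannon count).
#' @export
diversity_summary <- function(p, tol = 1e-6) {
  H <- shannon_index(p, tol)
  tibble(s = sum(p > 0), H = H, Sh = exp(H))
}

#' Fraction of one sample's clones missed in another
#'
#' The asymmetric set statistic `|A \ B| / |A U B|` on presence/absence of
#' barcodes: the share of the combined clone list that is present in sample
#' A but missed in sample B. Reported also as a percentage. Note the
#' deliberate asymmetry in (A, B); [jaccard_distance()] is the symmetric
#' companion.
#'
#' @param A,B Character vectors of barcode ids (duplicates ignored).
#' @return An `overlap_result` list: `j_dist`, `missed_percent`,
#'   `n_only_A`, `n_union`.
#' @examples
#' overlap_missed_fraction(c("a", "b", "c", "d"), c("a", "b"))$j_dist  # 0.5
#' @export
overlap_missed_fraction <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  un <- union(A, B)
  if (length(un) == 0) {
    stop("both sets are empty; the overlap statistic is undefined",
         call. = FALSE)
  }
  j <- length(setdiff(A, B)) / length(un)
  structure(list(j_dist = j, missed_percent = 100 * j,
                 n_only_A = length(setdiff(A, B)), n_union = length(un)),
            class = "overlap_result")
}

#' Symmetric Jaccard distance between two barcode sets
#'
#' `|A xor B| / |A U B|`; equals the sum of the two directed
#' [overlap_missed_fraction()] statistics.
#'
#' @inheritParams overlap_missed_fraction
#' @return Numeric distance in `[0, 1]`.
#' @export
jaccard_distance <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  un <- union(A, B)
  if (length(un) == 0) {
    stop("both sets are empty; the Jaccard distance is undefined",
         call. = FALSE)
  }
  (length(setdiff(A, B)) + length(setdiff(B, A))) / length(un)
}
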