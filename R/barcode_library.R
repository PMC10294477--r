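#' Constant amplicon anchor and noninformative sequences
#'
#' The barcode amplicon is built from a forward primer whose first nine bases
#' are a sample multiplex tag followed by a 22-nt constant region that anneals
#' to the 3' end of the eGFP open reading frame, the barcode cassette itself,
#' and a 23-nt reverse primer binding site. `fwd_anchor_sequence()` returns the
#' constant forward region used as the extraction anchor, and
#' `rev_anchor_sequence()` the reverse primer site. `noninformative_sequence()`
#' returns the one library sequence known not to mark a real clone; it is
#' excluded from all counting.
#'
#' @return A DNA character string.
#' @export
fwd_anchor_sequence <- function() "CGGCATGGACGAGCTGTACAAG"

#' @rdname fwd_anchor_sequence
#' @export
rev_anchor_sequence <- function() "CGTCTGGAACAATCAACCTCTGG"

#' @rdname fwd_anchor_sequence
#' @export
noninformative_sequence <- function() {
  "AAGGGCAACCTGGTAACCGATCTATGACACGATGTGTGACGGC"
}

#' Generate a semi-random barcode reference library
#'
#' Draws `n` random sequences over A/C/G/T of a fixed length, rejecting any
#' candidate closer than `min_dist` substitutions (Hamming distance) to an
#' already accepted sequence. A minimum pairwise distance of 3 is what makes
#' single-substitution error correction unambiguous downstream
#' ([extract_and_assign()] with the `correct1` policy).
#'
#' @param n Number of barcodes to generate.
#' @param length Barcode length in bases (default 32).
#' @param min_dist Minimum pairwise Hamming distance between any two barcodes
#'   (default 3).
#' @param seed Integer seed; the same seed reproduces the same library.
#' @param include_noninformative If `TRUE`, append the known noninformative
#'   sequence as a flagged entry. Because the library must be uniform-length,
#'   this requires `length` to equal `nchar(noninformative_sequence())` (43).
#' @param max_attempts Rejection-sampling budget; an infeasible
#'   `(n, length, min_dist)` combination fails explicitly rather than
#'   silently relaxing the distance guarantee.
#'
#' @return A `bc_library` tibble with columns `barcode_id`, `sequence`,
#'   `noninformative`, carrying `barcode_length` and `min_dist` attributes.
#' @examples
#' lib <- generate_barcode_library(20, length = 16, min_dist = 3, seed = 1)
#' @export
generate_barcode_library <- function(n, length = 32L, min_dist = 3L, seed = 1L,
                                     include_noninformative = FALSE,
                                     max_attempts = 1000L * n) {
  stopifnot(n >= 1, length >= 1, min_dist >= 0, length >= min_dist)
  noninf <- noninformative_sequence()
  if (include_noninformative && length != nchar(noninf)) {
    stop("include_noninformative = TRUE requires `length` = ", nchar(noninf),
         " so that the library stays uniform-length", call. = FALSE)
  }
  set.seed(seed)
  # uniqueness is always required, even at min_dist = 0
  eff_dist <- max(1L, min_dist)
  acc <- matrix(character(0), nrow = length, ncol = 0)
  ref <- if (include_noninformative) {
    matrix(strsplit(noninf, "")[[1]], ncol = 1)
  } else {
    matrix(character(0), nrow = length, ncol = 0)
  }
  attempts <- 0L
  while (ncol(acc) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place ", n, " barcodes of length ", length,
           " at pairwise Hamming distance >= ", min_dist, " within ",
           max_attempts, " attempts", call. = FALSE)
    }
    cand <- sample(.DNA_BASES, length, replace = TRUE)
    ok <- TRUE
    if (ncol(acc) > 0) ok <- all(colSums(acc != cand) >= eff_dist)
    if (ok && ncol(ref) > 0) ok <- all(colSums(ref != cand) >= eff_dist)
    if (ok) acc <- cbind(acc, cand)
  }
  seqs <- unname(apply(acc, 2, paste, collapse = ""))
  out <- tibble(
    barcode_id = sprintf("BC%04d", seq_len(n)),
    sequence = seqs,
    noninformative = FALSE
  )
  if (include_noninformative) {
    out <- rbind(out, tibble(barcode_id = "NONINF", sequence = noninf,
                             noninformative = TRUE))
    out <- as_tibble(out)
  }
  structure(out, barcode_length = as.integer(length),
            min_dist = as.integer(min_dist),
            class = c("bc_library", class(out)))
}

# Internal: minimum pairwise Hamming distance among the non-flagged entries.
# Uses the library's recorded guarantee when available.
.library_min_dist <- function(library) {
  md <- attr(library, "min_dist")
  if (!is.null(md)) return(md)
  seqs <- library$sequence[!library$noninformative]
  if (length(seqs) < 2) return(nchar(seqs[1]))
  m <- .seq_matrix(seqs)
  best <- nchar(seqs[1])
  for (i in seq_len(length(seqs) - 1)) {
    d <- colSums(m[, -seq_len(i), drop = FALSE] != m[, i])
    best <- min(best, d)
  }
  best
}

# Internal: uniform length of the informative barcodes.
.library_length <- function(library) {
  L <- unique(nchar(library$sequence[!library$noninformative]))
  if (length(L) != 1) {
    stop("library barcodes must share a single length", call. = FALSE)
  }
  L
}
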