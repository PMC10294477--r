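#' Normalize barcode counts per 1000 and as fractions of total
#'
#' Per sample, each barcode's count is divided by the sample total and
#' expressed both per 1000 and as a fraction. Samples with a zero total
#' cannot be normalized; they are dropped with a warning rather than
#' silently producing NaNs.
#'
#' @param x A `bc_counts` object from [count_barcodes()], or a barcodes x
#'   samples numeric matrix.
#' @return A `bc_abundance` object: list with `per_1000`, `fraction`
#'   (matrices) and `totals` (named numeric).
#' @examples
#' m <- matrix(c(2, 3, 5), dimnames = list(c("a", "b", "c"), "s1"))
#' normalize_abundance(m)$per_1000
#' @export
normalize_abundance <- function(x) {
  counts <- if (inherits(x, "bc_counts")) x$counts else as.matrix(x)
  totals <- colSums(counts)
  empty <- totals == 0
  if (any(empty)) {
    warning("dropping sample(s) with zero total counts: ",
            paste(colnames(counts)[empty], collapse = ", "), call. = FALSE)
    counts <- counts[, !empty, drop = FALSE]
    totals <- totals[!empty]
  }
  fraction <- sweep(counts, 2, totals, "/")
  structure(list(per_1000 = fraction * 1000, fraction = fraction,
                 totals = totals),
            class = "bc_abundance")
}

#' Dominant barcode set: the top-ranked clones covering a cumulative
#' threshold
#'
#' Ranks barcodes by descending abundance and returns the smallest prefix
#' whose cumulative fraction of the total reaches the threshold (the "top
#' 90%" of barcodes). Ties at the boundary are broken by barcode identifier
#' so the set is deterministic. `strict = TRUE` instead requires the
#' cumulative fraction to exceed the threshold.
#'
#' @param x Named non-negative abundance vector (counts, per-1000 values or
#'   fractions; only ratios matter).
#' @param threshold Cumulative-fraction threshold (default 0.90).
#' @param strict Require cumulative fraction strictly greater than
#'   `threshold`.
#' @return A `dominant_set` list: `barcode_ids` (ordered), `k`,
#'   `cum_fraction`, `threshold`.
#' @examples
#' dominant_set(c(a = 0.5, b = 0.3, c = 0.15, d = 0.05))$k  # 3
#' @export
dominant_set <- function(x, threshold = 0.90, strict = FALSE) {
  stopifnot(all(x >= 0), sum(x) > 0, threshold > 0, threshold <= 1)
  if (is.null(names(x))) names(x) <- sprintf("bc%04d", seq_along(x))
  ord <- order(-x, names(x))
  fr <- x[ord] / sum(x)
  cum <- cumsum(fr)
  tol <- 1e-9  # guards the exact-boundary case against float round-off
  k <- if (strict) which(cum > threshold + tol)[1] else
    which(cum >= threshold - tol)[1]
  if (is.na(k)) k <- length(fr)
  structure(list(barcode_ids = names(fr)[seq_len(k)], k = as.integer(k),
                 cum_fraction = cum[k], threshold = threshold),
            class = "dominant_set")
}

#' Dominant sets per scope (mouse or sample)
#'
#' Sums fractional abundances across each scope's samples and applies
#' [dominant_set()] within the scope. The default scope pools all samples,
#' matching a per-mouse analysis in which barcodes are ranked across all
#' peripheral-blood populations of that mouse.
#'
#' @param abundance A `bc_abundance` object.
#' @param scope Named character vector mapping sample ids to scope ids;
#'   `NULL` pools all samples into one scope named `"all"`.
#' @inheritParams dominant_set
#' @return Named list of `dominant_set` objects.
#' @export
dominant_sets <- function(abundance, scope = NULL, threshold = 0.90,
                          strict = FALSE) {
  fr <- abundance$fraction
  if (is.null(scope)) scope <- setNames(rep("all", ncol(fr)), colnames(fr))
  if (!all(colnames(fr) %in% names(scope))) {
    stop("every sample needs a scope assignment", call. = FALSE)
  }
  scopes <- unique(unname(scope[colnames(fr)]))
  out <- lapply(scopes, function(sc) {
    cols <- colnames(fr)[scope[colnames(fr)] == sc]
    dominant_set(rowSums(fr[, cols, drop = FALSE]), threshold, strict)
  })
  setNames(out, scopes)
}

#' Correct clone lineage fractions for chimerism
#'
#' Clone fractions are measured within the labeled (eGFP+) compartment of a
#' lineage; multiplying by the lineage's chimerism (the eGFP+ fraction of
#' that lineage) re-expresses each clone's contribution as a share of the
#' whole lineage.
#'
#' @param fractions Data frame with at least `lineage` and `fraction`
#'   columns.
#' @param chimerism Named numeric vector in `[0, 1]`: lineage -> eGFP+
#'   fraction.
#' @return The input with a `corrected` column appended.
#' @export
chimerism_correct <- function(fractions, chimerism) {
  stopifnot(is.data.frame(fractions),
            all(c("lineage", "fraction") %in% names(fractions)))
  if (any(chimerism < 0 | chimerism > 1)) {
    stop("chimerism values must lie in [0, 1]", call. = FALSE)
  }
  missing <- setdiff(unique(fractions$lineage), names(chimerism))
  if (length(missing)) {
    stop("missing chimerism for lineage(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fractions$corrected <- fractions$fraction *
    unname(chimerism[fractions$lineage])
  fractions
}

#' Concordance (R squared) between two technical replicates
#'
#' Coefficient of determination of the least-squares regression of replicate
#' 2 on replicate 1 over the union of their barcodes (a barcode absent from
#' one replicate contributes 0). With fewer than 3 barcodes non-zero in both
#' replicates the statistic is not meaningful and `NA` is returned with a
#' warning.
#'
#' @param rep1,rep2 Named numeric abundance vectors.
#' @return List with `r_squared`, `n_points`, `n_shared_nonzero`.
#' @export
replicate_concordance <- function(rep1, rep2) {
  ids <- union(names(rep1), names(rep2))
  x <- setNames(rep(0, length(ids)), ids)
  y <- x
  x[names(rep1)] <- rep1
  y[names(rep2)] <- rep2
  shared <- sum(x > 0 & y > 0)
  if (shared < 3) {
    warning("fewer than 3 shared non-zero barcodes; concordance undefined",
            call. = FALSE)
    return(list(r_squared = NA_real_, n_points = length(ids),
                n_shared_nonzero = shared))
  }
  fit <- lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(r_squared = r2, n_points = length(ids), n_shared_nonzero = shared)
}

#' Relative measurement error (percent)
#'
#' `delta = |(v_obs - v_exp) / v_exp| * 100`, the percent deviation of an
#' observed barcode abundance from its expected (designed) value.
#'
#' @param v_obs Observed value.
#' @param v_exp Expected value (non-zero).
#' @return An `error_report` list: `delta` (percent), `v_obs`, `v_exp`.
#' @examples
#' relative_error(116, 100)$delta  # 16
#' @export
relative_error <- function(v_obs, v_exp) {
  if (any(v_exp == 0)) {
    stop("relative error is undefined for an expected value of 0",
         call. = FALSE)
  }
  structure(list(delta = abs((v_obs - v_exp) / v_exp) * 100,
                 v_obs = v_obs, v_exp = v_exp),
            class = "error_report")
}

#' Pearson correlation matrix between lineage/time clone compositions
#'
#' For every pair of (lineage, week) samples of a mouse, the Pearson
#' correlation of per-clone percentage contributions over the union of
#' clones (absent = 0). The matrix is symmetric with unit diagonal wherever
#' defined; a zero-variance composition yields `NA` for its pairs.
#'
#' @param ts Long clonal time series (`mouse`, `clone`, `lineage`, `week`,
#'   `percent`).
#' @param mouse Optional mouse filter.
#' @param time_points Optional week filter.
#' @param clones Optional clone subset (e.g. a dominant set); default all.
#' @return List with matrices `r` and `p` (columns named `lineage_wkWEEK`)
#'   and `n_clones`.
#' @export
lineage_correlation_matrix <- function(ts, mouse = NULL, time_points = NULL,
                                       clones = NULL) {
  sub <- ts
  if (!is.null(mouse)) sub <- sub[sub$mouse %in% mouse, ]
  if (!is.null(time_points)) sub <- sub[sub$week %in% time_points, ]
  if (!is.null(clones)) sub <- sub[sub$clone %in% clones, ]
  if (length(unique(sub$clone)) < 3) {
    stop("need at least 3 clones to correlate compositions", call. = FALSE)
  }
  cl <- sort(unique(sub$clone))
  key <- paste0(sub$lineage, "_wk", sub$week)
  cols <- unique(key[order(sub$week, match(sub$lineage, .LINEAGES))])
  m <- matrix(0, length(cl), length(cols), dimnames = list(cl, cols))
  m[cbind(match(sub$clone, cl), match(key, cols))] <- sub$percent
  r <- suppressWarnings(cor(m))
  sds <- apply(m, 2, sd)
  p <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(r))
  for (i in seq_len(ncol(m))) {
    for (j in seq_len(ncol(m))) {
      if (i == j || sds[i] == 0 || sds[j] == 0) next
      p[i, j] <- suppressWarnings(cor.test(m[, i], m[, j])$p.value)
    }
  }
  list(r = r, p = p, n_clones = length(cl))
}
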