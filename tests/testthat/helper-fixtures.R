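# Shared fixtures and independent oracles used across the suite.

# Small well-separated library for extraction tests.
small_library <- function(n = 10, length = 16, min_dist = 3, seed = 11) {
  generate_barcode_library(n, length = length, min_dist = min_dist,
                           seed = seed)
}

# Brute-force sliding-window Hamming oracle, independent of find_anchor():
# scans every offset, computes the distance by explicit character
# comparison, and applies the same min-distance / leftmost tie-break.
oracle_find_anchor <- function(read, anchor_seq, max_mismatch,
                               positions = NULL) {
  al <- nchar(anchor_seq)
  a <- strsplit(anchor_seq, "")[[1]]
  if (is.null(positions)) positions <- seq_len(max(0, nchar(read) - al + 1))
  best_p <- NA_integer_
  best_d <- Inf
  for (p in positions) {
    if (p < 1 || p + al - 1 > nchar(read)) next
    r <- strsplit(substr(read, p, p + al - 1), "")[[1]]
    d <- sum(r != a)
    if (d <= max_mismatch && d < best_d) {
      best_d <- d
      best_p <- p
    }
  }
  best_p
}

# Random DNA string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute one base at a position, guaranteed different from the original.
mutate_base <- function(seq, pos) {
  bases <- c("A", "C", "G", "T")
  cur <- substr(seq, pos, pos)
  substr(seq, pos, pos) <- sample(setdiff(bases, cur), 1)
  seq
}

# Build a long-format clonal time series from a lineage x week percent
# matrix for a single clone, on top of a filler clone that absorbs the
# remaining output.
ts_from_matrix <- function(m, clone = "c1", mouse = "m1",
                           filler = "filler") {
  weeks <- as.numeric(colnames(m))
  rows <- expand.grid(lineage = rownames(m), week = weeks,
                      stringsAsFactors = FALSE)
  rows$percent <- m[cbind(rows$lineage, as.character(rows$week))]
  main <- tibble::tibble(mouse = mouse, clone = clone,
                         lineage = rows$lineage, week = rows$week,
                         percent = rows$percent)
  fill <- main
  fill$clone <- filler
  fill$percent <- 100 - main$percent
  rbind(main, fill)
}

# Lineage x week matrix helper.
pct_matrix <- function(..., weeks) {
  m <- rbind(...)
  rownames(m) <- c("P", "E", "M", "B")
  colnames(m) <- weeks
  m
}
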