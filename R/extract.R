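#' Anchor specification for mismatch-tolerant anchor search
#'
#' The extraction anchor is the constant eGFP-derived region of the forward
#' primer. It is located allowing at most `max_mismatch` substitutions
#' (Hamming distance) and, when an expected position is known, a positional
#' shift of up to `window` bases either side of it.
#'
#' @param sequence Anchor DNA string.
#' @param max_mismatch Maximum Hamming distance accepted (default 1).
#' @param expected_start Expected 1-based start of the anchor in the read, or
#'   `NA` to scan the whole read.
#' @param window Allowed shift around `expected_start` (default 1).
#' @return An `anchor_spec` list.
#' @export
anchor_spec <- function(sequence, max_mismatch = 1L, expected_start = NA,
                        window = 1L) {
  stopifnot(nchar(sequence) >= 1, max_mismatch >= 0, window >= 0)
  structure(list(sequence = toupper(sequence),
                 max_mismatch = as.integer(max_mismatch),
                 expected_start = expected_start,
                 window = as.integer(window)),
            class = "anchor_spec")
}

#' Locate an anchor in a read
#'
#' Returns the start position, within the allowed positional window, whose
#' Hamming distance to the anchor is minimal and at most
#' `anchor$max_mismatch`; ties are broken towards the smaller position.
#' Returns `NA` when no position qualifies (including when the anchor is
#' longer than the read).
#'
#' @param read A single read sequence.
#' @param anchor An [anchor_spec()].
#' @return Integer position (1-based) or `NA_integer_`.
#' @examples
#' a <- anchor_spec("ACGTACGT", expected_start = 1, window = 0)
#' find_anchor("ACGTACGTTTTT", a)  # 1
#' @export
find_anchor <- function(read, anchor) {
  stopifnot(length(read) == 1, nchar(read) >= 1)
  pos <- .find_anchor_vec(read, anchor)
  pos[1]
}

# Internal: vectorized anchor search over many reads. For each read, among
# the candidate start positions, picks the smallest qualifying Hamming
# distance, breaking ties towards the smaller (leftmost) position.
.find_anchor_vec <- function(reads, anchor) {
  al <- nchar(anchor$sequence)
  n <- nchar(reads)
  if (is.na(anchor$expected_start)) {
    positions <- seq_len(max(0L, max(n) - al + 1L))
  } else {
    positions <- seq(anchor$expected_start - anchor$window,
                     anchor$expected_start + anchor$window)
    positions <- positions[positions >= 1]
  }
  best_d <- rep(Inf, length(reads))
  best_p <- rep(NA_integer_, length(reads))
  for (p in positions) {
    d <- .hamming_vec(substr(reads, p, p + al - 1L), anchor$sequence)
    d[n - p + 1L < al] <- Inf
    upd <- d <= anchor$max_mismatch & d < best_d
    best_d[upd] <- d[upd]
    best_p[upd] <- p
  }
  best_p
}

#' Extract barcodes after the anchor and assign them to the library
#'
#' The barcode is taken as the `L` bases immediately following the matched
#' forward anchor, where `L` is the library's barcode length. Under the
#' `exact` policy a read is assigned only on a perfect match to a library
#' sequence; under `correct1` a read is additionally assigned to the unique
#' library barcode within Hamming distance 1, which is unambiguous only when
#' the library's minimum pairwise distance is at least 3 (enforced at call
#' time). Reads with no anchor, a too-short barcode region, or no qualifying
#' library match are unassigned (`NA`).
#'
#' @param reads Character vector of read sequences.
#' @param fwd_anchor An [anchor_spec()] for the forward anchor.
#' @param library A [generate_barcode_library()] result (or a tibble with
#'   `barcode_id`, `sequence`, `noninformative`).
#' @param policy `"exact"` or `"correct1"`.
#' @return Character vector of `barcode_id` values, `NA` where unassigned.
#' @export
extract_and_assign <- function(reads, fwd_anchor, library,
                               policy = c("exact", "correct1")) {
  policy <- match.arg(policy)
  if (nrow(library) == 0) stop("library is empty", call. = FALSE)
  L <- .library_length(library)
  if (policy == "correct1" && .library_min_dist(library) < 3) {
    stop("the correct1 policy requires a library with minimum pairwise ",
         "Hamming distance >= 3", call. = FALSE)
  }
  pos <- .find_anchor_vec(reads, fwd_anchor)
  start <- pos + nchar(fwd_anchor$sequence)
  bc <- substr(reads, start, start + L - 1L)
  bc[is.na(pos) | nchar(bc) < L] <- NA_character_
  lookup <- .assignment_table(library, policy)
  unname(lookup[match(bc, names(lookup))])
}

# Internal: named vector mapping acceptable barcode-region sequences to
# barcode ids. Under correct1 this includes every Hamming-1 neighbor of every
# library sequence; with min pairwise distance >= 3 these neighborhoods are
# disjoint, so the map is well defined.
.assignment_table <- function(library, policy) {
  seqs <- library$sequence
  ids <- library$barcode_id
  if (policy == "correct1") {
    L <- nchar(seqs[1])
    var_seqs <- character(0)
    var_ids <- character(0)
    for (j in seq_len(L)) {
      cur <- substr(seqs, j, j)
      for (b in .DNA_BASES) {
        keep <- cur != b
        if (!any(keep)) next
        v <- seqs[keep]
        substr(v, j, j) <- b
        var_seqs <- c(var_seqs, v)
        var_ids <- c(var_ids, ids[keep])
      }
    }
    seqs <- c(seqs, var_seqs)
    ids <- c(ids, var_ids)
  }
  setNames(ids, seqs)
}

#' Demultiplex reads by their 9-nt sample tag
#'
#' Reads are routed to samples by exact match of their first nine bases
#' against the tag map; reads matching no tag go to the `undetermined` bin.
#' The partition is exhaustive and disjoint.
#'
#' @param reads A `bc_reads` tibble (or any tibble with a `sequence` column).
#' @param sample_tags Named character vector mapping 9-nt tag sequences
#'   (names) to sample identifiers (values).
#' @return Named list of read tibbles, one per sample plus `undetermined`.
#' @export
demultiplex <- function(reads, sample_tags) {
  tags <- names(sample_tags)
  if (is.null(tags) || any(tags == "")) {
    stop("sample_tags must be a named vector (tag -> sample_id)", call. = FALSE)
  }
  if (anyDuplicated(tags)) stop("duplicate multiplex tags", call. = FALSE)
  if (any(nchar(tags) != 9)) stop("multiplex tags must be 9 nt", call. = FALSE)
  obs <- substr(reads$sequence, 1, 9)
  sample <- sample_tags[match(obs, tags)]
  sample[is.na(sample)] <- "undetermined"
  out <- lapply(c(unname(sample_tags), "undetermined"),
                function(s) reads[sample == s, , drop = FALSE])
  names(out) <- c(unname(sample_tags), "undetermined")
  out
}

#' Count assigned barcodes per sample with read-count filtering
#'
#' Builds the samples x barcodes count table from per-sample assignment
#' vectors. Barcodes seen fewer than `min_count` times in a sample are zeroed
#' (reads supported by so few copies are indistinguishable from noise), the
#' noninformative library barcode is removed before any normalization, and
#' per-sample assigned/unassigned totals are ledgered.
#'
#' @param assignments Named list: sample id -> character vector of
#'   `barcode_id` per read (`NA` = unassigned), as produced by
#'   [extract_and_assign()].
#' @param library Optional library used to identify the noninformative entry.
#' @param min_count Minimum per-sample read count for a barcode to be kept
#'   (default 3: counts below 3 are ignored).
#' @param exclude_noninformative Drop the flagged noninformative barcode
#'   (default `TRUE`).
#' @return A `bc_counts` object: list with `counts` (barcodes x samples
#'   integer matrix), `unassigned` (named integer vector) and `metadata`
#'   (applied filters and totals).
#' @export
count_barcodes <- function(assignments, library = NULL, min_count = 3L,
                           exclude_noninformative = TRUE) {
  stopifnot(is.list(assignments), !is.null(names(assignments)))
  samples <- names(assignments)
  all_ids <- sort(unique(unlist(assignments)))
  all_ids <- all_ids[!is.na(all_ids)]
  counts <- matrix(0L, length(all_ids), length(samples),
                   dimnames = list(all_ids, samples))
  unassigned <- setNames(integer(length(samples)), samples)
  totals <- setNames(integer(length(samples)), samples)
  for (s in samples) {
    a <- assignments[[s]]
    totals[s] <- length(a)
    unassigned[s] <- sum(is.na(a))
    if (length(all_ids)) {
      tab <- table(factor(a[!is.na(a)], levels = all_ids))
      counts[, s] <- as.integer(tab)
    }
  }
  removed_noninf <- 0L
  if (exclude_noninformative && nrow(counts)) {
    noninf_ids <- if (!is.null(library)) {
      library$barcode_id[library$noninformative]
    } else {
      "NONINF"
    }
    drop <- rownames(counts) %in% noninf_ids
    removed_noninf <- sum(counts[drop, , drop = FALSE])
    counts <- counts[!drop, , drop = FALSE]
  }
  filtered <- sum(counts[counts < min_count])
  counts[counts < min_count] <- 0L
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  structure(list(counts = counts, unassigned = unassigned,
                 metadata = list(min_count = as.integer(min_count),
                                 exclude_noninformative = exclude_noninformative,
                                 total_reads = totals,
                                 reads_below_min_count = filtered,
                                 noninformative_reads_removed = removed_noninf)),
            class = "bc_counts")
}

#' @export
print.bc_counts <- function(x, ...) {
  cat("Barcode count table:", nrow(x$counts), "barcodes x",
      ncol(x$counts), "samples\n")
  cat("  min_count =", x$metadata$min_count,
      "| unassigned:", paste(x$unassigned, collapse = ", "), "\n")
  invisible(x)
}

#' Run demultiplexing, assignment and counting in one step
#'
#' Convenience wrapper chaining [demultiplex()], [extract_and_assign()] and
#' [count_barcodes()] for a full read set.
#'
#' @inheritParams demultiplex
#' @inheritParams extract_and_assign
#' @inheritParams count_barcodes
#' @return A `bc_counts` object (the `undetermined` bin is ledgered in
#'   `metadata$undetermined_reads`).
#' @export
extract_counts <- function(reads, sample_tags, library,
                           fwd_anchor = anchor_spec(fwd_anchor_sequence(),
                                                    expected_start = 10,
                                                    window = 1),
                           policy = c("exact", "correct1"),
                           min_count = 3L, exclude_noninformative = TRUE) {
  policy <- match.arg(policy)
  bins <- demultiplex(reads, sample_tags)
  undet <- nrow(bins$undetermined)
  bins$undetermined <- NULL
  assignments <- lapply(bins, function(b) {
    extract_and_assign(b$sequence, fwd_anchor, library, policy)
  })
  out <- count_barcodes(assignments, library, min_count,
                        exclude_noninformative)
  out$metadata$undetermined_reads <- undet
  out
}

#' Chance-collision probability of repeated barcode reads
#'
#' Probability that `n_reads` reads in one well report the same barcode
#' purely by chance, computed as `(1 / library_size) ^ n_reads`. For a
#' library of 800 barcodes and 4 reads this is 2.44e-12, which is why a
#' handful of concordant reads per cell suffices for confident assignment.
#'
#' @param library_size Number of barcodes in the library.
#' @param n_reads Number of concordant reads.
#' @return Probability.
#' @examples
#' collision_probability(800, 4)
#' @export
collision_probability <- function(library_size, n_reads) {
  stopifnot(library_size >= 1, n_reads >= 1)
  (1 / library_size)^n_reads
}
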