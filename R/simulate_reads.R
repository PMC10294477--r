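#' Simulate barcode amplicon reads from a known mixture
#'
#' Draws read identities multinomially from the mixture fractions and builds
#' each read as `tag + forward anchor + barcode + reverse anchor`, the layout
#' of the sequenced barcode amplicon. Substitution errors are then injected
#' independently per base at `sub_rate`, emulating the elevated error of
#' cDNA-derived barcode reads relative to genomic DNA. Ground-truth barcode
#' identities are retained per read, and the exact multinomial draw is stored
#' in the `truth_counts` attribute so extraction can be checked end to end.
#'
#' @param mixture A [simulate_mixture()] result.
#' @param depth Number of reads to draw (0 gives an empty read set).
#' @param sub_rate Per-base substitution probability in `[0, 1)`.
#' @param tag 9-nt sample multiplex tag prepended to every read.
#' @param seed Integer seed.
#' @param fwd_anchor,rev_anchor Constant anchor sequences flanking the barcode.
#'
#' @return A `bc_reads` tibble with columns `read_id`, `sequence`,
#'   `sample_tag`, `truth_barcode_id`.
#' @export
simulate_amplicon_reads <- function(mixture, depth, sub_rate = 0,
                                    tag = "ACGTACGTA", seed = 1L,
                                    fwd_anchor = fwd_anchor_sequence(),
                                    rev_anchor = rev_anchor_sequence()) {
  stopifnot(depth >= 0, sub_rate >= 0, sub_rate < 1)
  if (nchar(tag) != 9) stop("the multiplex tag must be 9 nt", call. = FALSE)
  set.seed(seed)
  truth_counts <- setNames(rep(0L, nrow(mixture)), mixture$barcode_id)
  if (depth == 0) {
    out <- tibble(read_id = character(0), sequence = character(0),
                  sample_tag = character(0), truth_barcode_id = character(0))
    return(structure(out, truth_counts = truth_counts,
                     class = c("bc_reads", class(out))))
  }
  draw <- as.integer(rmultinom(1, depth, mixture$fraction))
  truth_counts[] <- draw
  ids <- rep(mixture$barcode_id, draw)
  seqs <- paste0(tag, fwd_anchor, rep(mixture$sequence, draw), rev_anchor)
  seqs <- inject_substitutions(seqs, sub_rate)
  out <- tibble(
    read_id = sprintf("read%07d", seq_along(seqs)),
    sequence = seqs,
    sample_tag = tag,
    truth_barcode_id = ids
  )
  structure(out, truth_counts = truth_counts,
            class = c("bc_reads", class(out)))
}

#' Inject independent per-base substitution errors
#'
#' Every base of every sequence mutates to one of the three other bases with
#' probability `rate`, independently. Uses the current RNG state.
#'
#' @param seqs Character vector of DNA sequences (lengths may differ).
#' @param rate Per-base substitution probability in `[0, 1)`.
#' @return The mutated character vector.
#' @export
inject_substitutions <- function(seqs, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || length(seqs) == 0) return(seqs)
  len <- nchar(seqs)
  total <- sum(len)
  n_hits <- rbinom(1, total, rate)
  if (n_hits == 0) return(seqs)
  g <- sort(sample.int(total, n_hits))
  ends <- cumsum(len)
  read <- findInterval(g - 1L, ends) + 1L
  pos <- g - c(0L, ends)[read]
  # several hits can land in one read; apply them in vectorized rounds
  round_id <- stats::ave(read, read, FUN = seq_along)
  for (r in seq_len(max(round_id))) {
    sel <- round_id == r
    ri <- read[sel]
    pi <- pos[sel]
    cur <- substr(seqs[ri], pi, pi)
    shift <- sample.int(3L, length(ri), replace = TRUE)
    new <- .DNA_BASES[(match(cur, .DNA_BASES) - 1L + shift) %% 4L + 1L]
    tmp <- seqs[ri]
    substr(tmp, pi, pi) <- new
    seqs[ri] <- tmp
  }
  seqs
}
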