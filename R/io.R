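#' Read and write barcode amplicon reads as FASTQ
#'
#' Reads are written as 4-line FASTQ records with a constant Phred+33
#' quality of "I"; qualities are not used by the extraction pipeline.
#' Reading is gzip-transparent.
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path File path (`.fastq` or `.fastq.gz`).
#' @return `write_reads_fastq()` returns `path` invisibly;
#'   `read_reads_fastq()` returns a tibble with `read_id` and `sequence`.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ file: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), sequence = unname(as.character(x)))
}

#' Tab-separated table I/O
#'
#' The canonical tabular dialect of the package: tab-separated, UTF-8,
#' header row, "." decimal, no quoting, gzip-transparent on read.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @return `write_tsv_file()` returns `path` invisibly; `read_tsv_file()`
#'   returns a tibble.
#' @export
write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("no such TSV file: ", path, call. = FALSE)
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       check.names = FALSE))
}

#' Barcode count table I/O
#'
#' Count tables travel as TSV with barcodes as rows (`barcode_id` column)
#' and one column per sample.
#'
#' @param counts A `bc_counts` object or barcodes x samples matrix.
#' @param path File path.
#' @return `write_counts_tsv()` returns `path` invisibly;
#'   `read_counts_tsv()` returns a barcodes x samples integer matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  m <- if (inherits(counts, "bc_counts")) counts$counts else as.matrix(counts)
  df <- data.frame(barcode_id = rownames(m), m, check.names = FALSE)
  write_tsv_file(df, path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$barcode_id
  storage.mode(m) <- "integer"
  m
}

#' Run the simulate-extract-quantify-classify demonstration pipeline
#'
#' Generates a barcode library, the ten-clone calibration mixture, amplicon
#' reads for two replicate samples, extracts and counts barcodes, computes
#' abundances, diversity and the dominant set, simulates a perturbed clonal
#' time course and classifies its clone dynamics, writing every table to
#' `out_dir` along with a machine-readable JSON run summary. All randomness
#' derives from `seed`, so a rerun with the same arguments reproduces the
#' outputs byte for byte.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param n_barcodes Library size.
#' @param depth Reads per sample.
#' @param sub_rate Per-base substitution rate of the simulated reads.
#' @param timecourse A [timecourse_config()]; its seed is re-derived from
#'   `seed`.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_barcodes = 100L,
                         depth = 20000L, sub_rate = 0.01,
                         timecourse = timecourse_config(
                           n_clones = 100L, perturbation_time = 28)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  lib <- generate_barcode_library(n_barcodes, seed = seed)
  paths$library <- file.path(out_dir, "library.tsv")
  write_tsv_file(as.data.frame(lib), paths$library)

  mix <- simulate_mixture(lib, c(1, 10, 10, 50, 100, 100, 200, 200, 200, 250))
  paths$mixture <- file.path(out_dir, "mixture.tsv")
  write_tsv_file(as.data.frame(mix), paths$mixture)

  tags <- c(AAACCCGGG = "rep1", TTTGGGCCC = "rep2")
  reads <- rbind(
    simulate_amplicon_reads(mix, depth, sub_rate, names(tags)[1],
                            seed = seed + 1L),
    simulate_amplicon_reads(mix, depth, sub_rate, names(tags)[2],
                            seed = seed + 2L))
  paths$reads <- file.path(out_dir, "reads.fastq")
  write_reads_fastq(reads, paths$reads)

  counts <- extract_counts(reads, tags, lib, policy = "correct1")
  paths$counts <- file.path(out_dir, "counts.tsv")
  write_counts_tsv(counts, paths$counts)

  ab <- normalize_abundance(counts)
  div <- do.call(rbind, lapply(colnames(ab$fraction), function(s) {
    cbind(sample = s, diversity_summary(ab$fraction[, s]))
  }))
  paths$diversity <- file.path(out_dir, "diversity.tsv")
  write_tsv_file(div, paths$diversity)
  dom <- dominant_sets(ab)
  conc <- replicate_concordance(ab$per_1000[, "rep1"], ab$per_1000[, "rep2"])

  tc_cfg <- timecourse
  tc_cfg$seed <- seed + 3L
  sim <- simulate_clonal_timecourse(tc_cfg)
  paths$timecourse <- file.path(out_dir, "timecourse.tsv")
  write_tsv_file(sim$ts, paths$timecourse)
  pert <- tc_cfg$perturbation_time
  cls <- classify_clones(sim$ts)
  if (!is.null(pert)) {
    pre <- tc_cfg$time_points[tc_cfg$time_points < pert]
    post <- tc_cfg$time_points[tc_cfg$time_points >= pert]
    dyn <- classify_dynamics(sim$ts, pre_window = pre, post_window = post)
    cls <- merge(cls, dyn[, c("clone", "status")], by = "clone")
  }
  paths$classification <- file.path(out_dir, "classification.tsv")
  write_tsv_file(cls, paths$classification)
  summary_week <- max(tc_cfg$time_points)
  paths$class_summary <- file.path(out_dir, "class_summary.tsv")
  write_tsv_file(
    class_contribution_summary(sim$ts, classify_clones(sim$ts), summary_week),
    paths$class_summary)

  run_summary <- list(
    package = "clonetrace",
    version = as.character(utils::packageVersion("clonetrace")),
    seed = seed,
    parameters = list(n_barcodes = n_barcodes, depth = depth,
                      sub_rate = sub_rate,
                      timecourse = unclass(tc_cfg)),
    smallest_mixture_fraction_percent = 100 * min(mix$fraction),
    replicate_r_squared = conc$r_squared,
    dominant_set_size = dom$all$k,
    outputs = lapply(paths, basename)
  )
  paths$summary <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(run_summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
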