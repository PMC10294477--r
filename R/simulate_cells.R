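#' Configuration for the single-cell simulator
#'
#' Emulates plate-based full-length scRNA-seq of FACS-purified bone-marrow
#' populations (LT-HSC, MkP, CFU-E) in which each cell carries an expressed
#' barcode. Per-cell sequencing depth is log-normal (defaults centred on the
#' ~1M reads/cell typical of these libraries), the mitochondrial read
#' fraction is Beta-distributed, and the number of barcode-bearing reads per
#' cell is negative-binomial shifted by `barcode_read_min` (capture of a few
#' reads per cell is near-certain when the barcode is captured at all).
#' Gene counts are negative-binomial with log-normal gene means scaled by the
#' cell's depth.
#'
#' @param n_cells Named integer vector: cells per population.
#' @param depth_meanlog,depth_sdlog Log-normal parameters of total reads/cell.
#' @param mito_shape1,mito_shape2 Beta parameters of the mitochondrial
#'   fraction.
#' @param barcode_read_mu,barcode_read_size Negative-binomial mean/size of
#'   barcode read counts above `barcode_read_min`.
#' @param barcode_read_min Minimum barcode reads for a captured barcode.
#' @param dropout Probability that a cell's barcode is not captured at all.
#' @param n_genes Number of genes in the count matrix.
#' @param gene_dispersion Negative-binomial size parameter of gene counts.
#' @param read_sub_rate Per-base substitution rate of the emitted barcode
#'   reads.
#' @param seed Integer seed.
#' @return A `single_cell_config` list.
#' @export
single_cell_config <- function(n_cells = c("LT-HSC" = 200L, "MkP" = 150L,
                                           "CFU-E" = 150L),
                               depth_meanlog = log(1e6), depth_sdlog = 0.5,
                               mito_shape1 = 2, mito_shape2 = 38,
                               barcode_read_mu = 20, barcode_read_size = 5,
                               barcode_read_min = 3L,
                               dropout = 0.1,
                               n_genes = 2000L, gene_dispersion = 0.5,
                               read_sub_rate = 0, seed = 1L) {
  stopifnot(all(n_cells >= 1), !is.null(names(n_cells)),
            dropout >= 0, dropout <= 1, n_genes >= 1,
            barcode_read_mu >= 0, barcode_read_min >= 0,
            read_sub_rate >= 0, read_sub_rate < 1)
  structure(as.list(environment()), class = "single_cell_config")
}

#' Simulate barcoded single cells with QC attributes and gene counts
#'
#' Each cell receives a population label, a total read depth, a mitochondrial
#' fraction, a true clone barcode drawn from its population's clone frequency
#' table (or none, with probability `dropout`), a barcode read count, and a
#' negative-binomial gene expression profile. Barcode-bearing amplicon reads
#' (`forward anchor + barcode + reverse anchor`) are emitted per cell so the
#' extraction and per-cell assignment path can be exercised end to end.
#'
#' @param config A [single_cell_config()].
#' @param library A [generate_barcode_library()] result.
#' @param clone_assignment Named list, one element per population: a named
#'   numeric vector of barcode frequencies summing to 1.
#' @param mouse Mouse identifier.
#' @return A list with `cells` (tibble: `cell_id`, `population`, `mouse`,
#'   `total_reads`, `mito_fraction`, `barcode_id`, `barcode_read_count`),
#'   `counts` (genes x cells integer matrix) and `reads` (tibble: `cell_id`,
#'   `read_id`, `sequence`).
#' @export
simulate_single_cells <- function(config, library, clone_assignment,
                                  mouse = "m1") {
  stopifnot(inherits(config, "single_cell_config"))
  pops <- names(config$n_cells)
  if (!all(pops %in% names(clone_assignment))) {
    stop("clone_assignment must name every population", call. = FALSE)
  }
  for (p in pops) {
    fr <- clone_assignment[[p]]
    if (abs(sum(fr) - 1) > 1e-6) {
      stop("clone frequencies for ", p, " must sum to 1", call. = FALSE)
    }
    if (!all(names(fr) %in% library$barcode_id)) {
      stop("clone_assignment for ", p, " uses barcodes absent from the library",
           call. = FALSE)
    }
  }
  set.seed(config$seed)
  n <- sum(config$n_cells)
  population <- rep(pops, config$n_cells)
  cell_id <- sprintf("%s_c%04d", gsub("[^A-Za-z0-9]", "", population),
                     unlist(lapply(config$n_cells, seq_len)))
  total_reads <- round(rlnorm(n, config$depth_meanlog, config$depth_sdlog))
  mito_fraction <- rbeta(n, config$mito_shape1, config$mito_shape2)
  barcode_id <- character(n)
  for (p in pops) {
    sel <- population == p
    fr <- clone_assignment[[p]]
    barcode_id[sel] <- sample(names(fr), sum(sel), replace = TRUE, prob = fr)
  }
  dropped <- runif(n) < config$dropout
  barcode_id[dropped] <- NA_character_
  barcode_read_count <- ifelse(
    is.na(barcode_id), 0L,
    config$barcode_read_min + rnbinom(n, mu = config$barcode_read_mu,
                                      size = config$barcode_read_size))

  gene_means <- rlnorm(config$n_genes, log(5), 1)
  size_factor <- total_reads / exp(config$depth_meanlog)
  counts <- matrix(
    rnbinom(config$n_genes * n,
            mu = outer(gene_means, size_factor),
            size = config$gene_dispersion),
    nrow = config$n_genes,
    dimnames = list(sprintf("gene%04d", seq_len(config$n_genes)), cell_id))

  with_bc <- which(!is.na(barcode_id))
  bc_seq <- library$sequence[match(barcode_id[with_bc], library$barcode_id)]
  read_cell <- rep(cell_id[with_bc], barcode_read_count[with_bc])
  read_seq <- paste0(fwd_anchor_sequence(),
                     rep(bc_seq, barcode_read_count[with_bc]),
                     rev_anchor_sequence())
  read_seq <- inject_substitutions(read_seq, config$read_sub_rate)
  reads <- tibble(cell_id = read_cell,
                  read_id = sprintf("scread%07d", seq_along(read_seq)),
                  sequence = read_seq)
  cells <- tibble(cell_id = cell_id, population = population, mouse = mouse,
                  total_reads = total_reads, mito_fraction = mito_fraction,
                  barcode_id = barcode_id,
                  barcode_read_count = as.integer(barcode_read_count))
  list(cells = cells, counts = counts, reads = reads)
}
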