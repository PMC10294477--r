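# Generators: barcode library, mixtures, reads, time courses, single cells.

test_that("barcode libraries respect the pairwise Hamming-distance floor", {
  lib <- generate_barcode_library(200, length = 20, min_dist = 3, seed = 7)
  expect_equal(nrow(lib), 200)
  expect_true(all(nchar(lib$sequence) == 20))
  expect_false(anyDuplicated(lib$sequence) > 0)
  # exhaustive pairwise scan, independent of the generator's incremental check
  chars <- do.call(cbind, strsplit(lib$sequence, ""))
  min_d <- Inf
  for (i in seq_len(ncol(chars) - 1)) {
    d <- colSums(chars[, (i + 1):ncol(chars), drop = FALSE] != chars[, i])
    min_d <- min(min_d, d)
  }
  expect_gte(min_d, 3)
})

test_that("library generation is deterministic and validates inputs", {
  a <- generate_barcode_library(50, length = 12, min_dist = 2, seed = 42)
  b <- generate_barcode_library(50, length = 12, min_dist = 2, seed = 42)
  expect_identical(a$sequence, b$sequence)
  one <- generate_barcode_library(1, length = 10, min_dist = 0, seed = 1)
  expect_equal(nchar(one$sequence), 10)
  expect_true(grepl("^[ACGT]+$", one$sequence))
  # at length 2 and distance 2 only 4 sequences can coexist
  expect_error(
    generate_barcode_library(5, length = 2, min_dist = 2, seed = 1,
                             max_attempts = 2000),
    "could not place")
})

test_that("the noninformative entry is appended flagged, at its own length", {
  lib <- generate_barcode_library(5, length = 43, min_dist = 3, seed = 3,
                                  include_noninformative = TRUE)
  expect_equal(sum(lib$noninformative), 1)
  expect_equal(lib$sequence[lib$noninformative], noninformative_sequence())
  expect_error(
    generate_barcode_library(5, length = 20, include_noninformative = TRUE),
    "uniform-length")
})

test_that("mixture fractions renormalize ratios; the ten-clone design bottoms at 0.089%", {
  lib <- small_library()
  mix <- simulate_mixture(lib, c(1, 10, 10, 50, 100, 100, 200, 200, 200, 250))
  expect_equal(sum(mix$fraction), 1)
  expect_equal(round(100 * min(mix$fraction), 3), 0.089)
  even <- simulate_mixture(lib, c(1, 1), lib$barcode_id[1:2])
  expect_equal(even$fraction, c(0.5, 0.5))
  spike <- simulate_mixture(lib, c(0.1, 1, 5, 10, 20, 50),
                            lib$barcode_id[1:6])
  expect_equal(spike$fraction, c(0.1, 1, 5, 10, 20, 50) / 86.1)
  expect_error(simulate_mixture(lib, c(1, 0)), "positive")
  expect_error(simulate_mixture(lib, c(1, 1), c("BC0001", "nope")), "absent")
})

test_that("amplicon reads carry the tag-anchor-barcode-anchor layout and truth", {
  lib <- small_library()
  mix <- simulate_mixture(lib, c(3, 7), lib$barcode_id[1:2])
  reads <- simulate_amplicon_reads(mix, 500, sub_rate = 0,
                                   tag = "AAACCCGGG", seed = 5)
  expect_equal(nrow(reads), 500)
  expect_true(all(substr(reads$sequence, 1, 9) == "AAACCCGGG"))
  expect_true(all(substr(reads$sequence, 10, 31) == fwd_anchor_sequence()))
  truth <- attr(reads, "truth_counts")
  expect_equal(sum(truth), 500)
  expect_equal(as.vector(table(reads$truth_barcode_id)[names(truth)]),
               unname(truth))
  # the error-free barcode region equals the true barcode sequence
  bc <- substr(reads$sequence, 32, 32 + 15)
  expect_identical(bc, mix$sequence[match(reads$truth_barcode_id,
                                          mix$barcode_id)])
  expect_equal(nrow(simulate_amplicon_reads(mix, 0, seed = 1)), 0)
  again <- simulate_amplicon_reads(mix, 500, sub_rate = 0,
                                   tag = "AAACCCGGG", seed = 5)
  expect_identical(reads$sequence, again$sequence)
  expect_error(simulate_amplicon_reads(mix, 10, tag = "TOOSHORT"), "9 nt")
})

test_that("substitution injection hits bases at the requested rate", {
  set.seed(101)
  seqs <- replicate(300, random_dna(60))
  mut <- inject_substitutions(seqs, 0.05)
  n_diff <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, seqs, mut)
  total <- 300 * 60
  p_hat <- sum(n_diff) / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(p_hat - 0.05), 3 * se)
  expect_identical(inject_substitutions(seqs, 0), seqs)
})

test_that("noiseless symmetric time course gives exactly equal shares", {
  cfg <- timecourse_config(n_clones = 4,
                           class_proportions = c(PEMB = 1),
                           n_silent = 0, noise_cv = 0,
                           size_range = c(1, 1), seed = 1)
  sim <- simulate_clonal_timecourse(cfg)
  expect_true(all(sim$ts$percent == 25))
})

test_that("lineage columns sum to 100% at every time point", {
  sim <- simulate_clonal_timecourse(
    timecourse_config(n_clones = 60, noise_cv = 0.3,
                      perturbation_time = 28, seed = 9))
  tot <- aggregate(percent ~ lineage + week, data = sim$ts, FUN = sum)
  expect_equal(tot$percent, rep(100, nrow(tot)), tolerance = 1e-9)
})

test_that("repurposed clones lose myeloid output after the perturbation only", {
  cfg <- timecourse_config(n_clones = 30, noise_cv = 0,
                           perturbation_time = 28,
                           repurpose_fraction = 1, seed = 13)
  sim <- simulate_clonal_timecourse(cfg)
  rep_clones <- sim$truth$clone[sim$truth$status == "repurposed"]
  expect_gt(length(rep_clones), 0)
  m <- sim$ts[sim$ts$lineage == "M" & sim$ts$clone %in% rep_clones, ]
  expect_true(all(m$percent[m$week >= 28] == 0))
  expect_true(all(m$percent[m$week < 28] > 0.089))
  other <- sim$ts[sim$ts$lineage %in% c("P", "E", "B") &
                    sim$ts$clone %in% rep_clones & sim$ts$week >= 28, ]
  expect_true(all(other$percent > 0.089))
})

test_that("sampled class counts follow the configured proportions", {
  props <- default_class_proportions()
  sim <- simulate_clonal_timecourse(
    timecourse_config(n_clones = 400, n_silent = 0, noise_cv = 0, seed = 21))
  counts <- table(factor(sim$truth$class,
                         levels = unique(sim$truth$class)))
  # compare the dominant class against its multinomial sampling error
  p <- props[["PEMB"]]
  se <- sqrt(p * (1 - p) * 400)
  expect_lt(abs(sum(sim$truth$class == "PEMB") - 400 * p), 3 * se)
  expect_equal(sum(counts), 400)
})

test_that("perturbation week must be a sampling week", {
  expect_error(timecourse_config(perturbation_time = 25), "time_points")
})

test_that("single-cell simulation honours dropout and determinism", {
  lib <- small_library()
  freq <- setNames(rep(0.2, 5), lib$barcode_id[1:5])
  assign <- list("LT-HSC" = freq, "MkP" = freq, "CFU-E" = freq)
  cfg <- single_cell_config(n_cells = c("LT-HSC" = 30, "MkP" = 20,
                                        "CFU-E" = 20),
                            n_genes = 50, dropout = 1, seed = 2)
  sim <- simulate_single_cells(cfg, lib, assign)
  expect_true(all(is.na(sim$cells$barcode_id)))
  expect_true(all(sim$cells$barcode_read_count == 0))
  expect_equal(nrow(sim$reads), 0)

  cfg0 <- single_cell_config(n_cells = c("LT-HSC" = 30, "MkP" = 20,
                                         "CFU-E" = 20),
                             n_genes = 50, dropout = 0, seed = 2)
  sim0 <- simulate_single_cells(cfg0, lib, assign)
  expect_true(all(!is.na(sim0$cells$barcode_id)))
  expect_true(all(sim0$cells$barcode_read_count >= 3))
  expect_equal(dim(sim0$counts), c(50, 70))
  sim0b <- simulate_single_cells(cfg0, lib, assign)
  expect_identical(sim0$cells, sim0b$cells)
  expect_identical(sim0$counts, sim0b$counts)
})

test_that("QC pass rate tracks the depth distribution's tail mass", {
  lib <- small_library()
  freq <- setNames(1, lib$barcode_id[1])
  cfg <- single_cell_config(n_cells = c("LT-HSC" = 600, "MkP" = 1,
                                        "CFU-E" = 1),
                            depth_meanlog = log(5e4), depth_sdlog = 0.4,
                            mito_shape1 = 1e-3, mito_shape2 = 10,
                            n_genes = 5, seed = 8)
  sim <- simulate_single_cells(cfg, lib, list("LT-HSC" = freq, "MkP" = freq,
                                              "CFU-E" = freq))
  qc <- qc_filter_cells(sim$cells)
  # mito is essentially 0 here, so the pass rate is the lognormal upper tail
  p_pass <- stats::plnorm(5e4, log(5e4), 0.4, lower.tail = FALSE)
  n <- nrow(sim$cells)
  se <- sqrt(p_pass * (1 - p_pass) / n)
  expect_lt(abs(nrow(qc$kept) / n - p_pass), 3 * se)
})
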