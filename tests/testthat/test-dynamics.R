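# Clone lineage-output classification, repurposing and activation detection.

test_that("classification credits lineages above threshold at consecutive times", {
  m <- pct_matrix(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1),
                  weeks = c(12, 20, 28))
  ts <- ts_from_matrix(m / 4)  # filler keeps columns sensible
  expect_equal(classify_clone(ts, "c1"), "PEMB")
  m2 <- pct_matrix(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(0.01, 0.01, 0.01),
                   weeks = c(12, 20, 28))
  expect_equal(classify_clone(ts_from_matrix(m2 / 4), "c1"), "PEM")
  m3 <- pct_matrix(c(0.05, 0.05, 0.05), c(0.05, 0.05, 0.05),
                   c(0.05, 0.05, 0.05), c(0.05, 0.05, 0.05),
                   weeks = c(12, 20, 28))
  expect_equal(classify_clone(ts_from_matrix(m3), "c1"), "unclassified")
  expect_error(classify_clone(ts, "ghost"), "absent")
})

test_that("a contribution exactly at the threshold qualifies for neither side", {
  m <- pct_matrix(c(0.089, 0.089), c(1, 1), c(1, 1), c(1, 1),
                  weeks = c(12, 20))
  expect_equal(classify_clone(ts_from_matrix(m)[1:8, ], "c1"), "EMB")
})

test_that("the consecutive requirement is relaxable to any two time points", {
  # P is above threshold at weeks 12 and 28 but not 20
  m <- pct_matrix(c(1, 0.01, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1),
                  weeks = c(12, 20, 28))
  ts <- ts_from_matrix(m)
  expect_equal(classify_clone(ts, "c1"), "EMB")
  any2 <- classification_rule(require_consecutive = FALSE)
  expect_equal(classify_clone(ts, "c1", any2), "PEMB")
})

test_that("repurposing requires multipotency before and myeloid silence after", {
  pre_post <- function(P, E, M, B) {
    ts_from_matrix(pct_matrix(P, E, M, B, weeks = c(12, 20, 28, 30)))
  }
  rule <- classification_rule()
  # PEMB pre; M silenced post, others persist -> repurposed
  ts <- pre_post(c(1, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, 0.01, 0.01),
                 c(1, 1, 1, 1))
  expect_true(detect_repurposed(ts, "c1", rule, c(12, 20), c(28, 30)))
  # PEMB throughout -> not repurposed
  ts2 <- pre_post(c(1, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_false(detect_repurposed(ts2, "c1", rule, c(12, 20), c(28, 30)))
  # PEM pre (B silent) is not multipotent, so an M drop is not repurposing
  ts3 <- pre_post(c(1, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, 0.01, 0.01),
                  c(0.01, 0.01, 0.01, 0.01))
  expect_false(detect_repurposed(ts3, "c1", rule, c(12, 20), c(28, 30)))
  # M must stay silent at every post time point
  ts4 <- pre_post(c(1, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, 0.01, 1),
                  c(1, 1, 1, 1))
  expect_false(detect_repurposed(ts4, "c1", rule, c(12, 20), c(28, 30)))
  expect_error(detect_repurposed(ts, "c1", rule, c(28, 30), c(12, 20)),
               "strictly before")
})

test_that("activation requires pre-silence and post output above threshold", {
  rule <- classification_rule()
  mk <- function(M) {
    ts_from_matrix(pct_matrix(c(1, 1, 1, 1), c(1, 1, 1, 1), M,
                              c(1, 1, 1, 1), weeks = c(12, 20, 28, 30)))
  }
  expect_true(detect_activated(mk(c(0, 0, 5, 5)), "c1", rule,
                               c(12, 20), c(28, 30), "M"))
  # output at one pre time point breaks pre-silence
  expect_false(detect_activated(mk(c(1, 0, 5, 5)), "c1", rule,
                                c(12, 20), c(28, 30), "M"))
  # exactly at the boundary pre: not strictly below threshold -> false
  expect_false(detect_activated(mk(c(0.089, 0, 5, 5)), "c1", rule,
                                c(12, 20), c(28, 30), "M"))
  # only one post time point above threshold is not stable output
  expect_false(detect_activated(mk(c(0, 0, 5, 0.01)), "c1", rule,
                                c(12, 20), c(28, 30), "M"))
})

test_that("repurposed and activated are mutually exclusive for any clone", {
  set.seed(91)
  rule <- classification_rule()
  for (i in 1:40) {
    m <- matrix(sample(c(0, 0.01, 0.089, 0.2, 5), 16, replace = TRUE), 4, 4)
    ts <- ts_from_matrix(pct_matrix(m[1, ], m[2, ], m[3, ], m[4, ],
                                    weeks = c(12, 20, 28, 30)))
    rep_ <- detect_repurposed(ts, "c1", rule, c(12, 20), c(28, 30))
    act <- any(vapply(c("P", "E", "M", "B"), function(l) {
      detect_activated(ts, "c1", rule, c(12, 20), c(28, 30), l)
    }, logical(1)))
    expect_false(rep_ && act)
  }
})

test_that("the classifier recovers generated truth exactly without noise", {
  sim <- simulate_clonal_timecourse(
    timecourse_config(n_clones = 60, noise_cv = 0,
                      perturbation_time = 28, seed = 23))
  labels <- classify_clones(sim$ts, window = c(12, 20))
  merged <- merge(labels, sim$truth, by = "clone")
  expect_equal(merged$label, merged$class)
  dyn <- classify_dynamics(sim$ts, pre_window = c(12, 20),
                           post_window = c(28, 30))
  md <- merge(dyn, sim$truth, by = "clone")
  expect_equal(md$status.x == "repurposed", md$status.y == "repurposed")
  expect_equal(md$status.x == "activated", md$status.y == "activated")
  # activated clones are detected in the lineage the generator gave them
  act <- md[md$status.y == "activated", ]
  expect_equal(act$activated_lineage.x, act$activated_lineage.y)
})

test_that("class contribution summaries conserve lineage totals", {
  sim <- simulate_clonal_timecourse(
    timecourse_config(n_clones = 50, noise_cv = 0.2, seed = 29))
  cls <- classify_clones(sim$ts)
  summ <- class_contribution_summary(sim$ts, cls, week = 20)
  tot <- tapply(summ$percent, summ$lineage, sum)
  expect_equal(as.vector(tot), rep(100, 4), tolerance = 1e-9)
  # independent group-by-sum oracle on the long table
  sub <- sim$ts[sim$ts$week == 20, ]
  lab <- cls$label[match(sub$clone, cls$clone)]
  oracle <- tapply(sub$percent, list(sub$lineage, lab), sum)
  for (r in seq_len(nrow(summ))) {
    expect_equal(summ$percent[r], unname(oracle[summ$lineage[r],
                                                summ$label[r]]))
  }
})

test_that("single-class cohorts concentrate all output in that class", {
  sim <- simulate_clonal_timecourse(
    timecourse_config(n_clones = 10, class_proportions = c(PEMB = 1),
                      n_silent = 0, noise_cv = 0, seed = 3))
  cls <- classify_clones(sim$ts)
  summ <- class_contribution_summary(sim$ts, cls, week = 12)
  expect_true(all(summ$label == "PEMB"))
  expect_equal(summ$percent, rep(100, 4))
})

test_that("PB/BM overlap reports shared and missed percentages", {
  pb <- sprintf("c%02d", 1:10)
  # |PB| = 10, |BM| = 8, 6 shared -> shared-of-union 6/12
  res <- pb_bm_overlap(pb, list(MkP = c(pb[1:6], "x", "y")))
  row <- res[res$population == "MkP", ]
  expect_equal(row$shared_percent, 100 * 6 / 12)
  ident <- pb_bm_overlap(pb, list(MkP = pb))
  expect_equal(ident$shared_percent, c(100, 100))
  disj <- pb_bm_overlap(pb, list(MkP = c("z1", "z2")))
  expect_equal(disj$shared_percent[1], 0)
  expect_equal(disj$missed_from_pb_percent[1], 100 * 10 / 12)
})
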