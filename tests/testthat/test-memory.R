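# Recognition and source memory: rating collapse, hit/FA counting, t-tests,
# effect sizes, repeated-measures ANOVAs.

test_that("confidence ratings collapse to binary old/new", {
  expect_equal(collapse_ratings(c("ProbOld", "DefOld", "ProbNew", "DefNew", NA)),
               c("old", "old", "new", "new", NA))
  expect_error(collapse_ratings("Maybe"), "unknown")
})

test_that("hit and false-alarm rates count collapsed responses", {
  rec <- data.frame(
    status = c(rep("old", 3), rep("new", 3)),
    rating = c("DefOld", "ProbOld", "ProbNew", "DefNew", "ProbNew", "DefOld"),
    lp_bin = c(1L, 2L, 3L, NA, NA, NA),
    category = "a.x", stringsAsFactors = FALSE
  )
  rs <- recognition_summary(rec)
  expect_equal(rs$hit_rate, 2 / 3)
  expect_equal(rs$fa_rate, 1 / 3)
  expect_true(rs$defined)

  perfect <- rec
  perfect$rating <- c("DefOld", "DefOld", "ProbOld", "DefNew", "ProbNew",
                      "ProbNew")
  rs2 <- recognition_summary(perfect)
  expect_equal(rs2$hit_rate, 1.0)
  expect_equal(rs2$fa_rate, 0.0)

  # conservation: per-bin counts sum to responded old trials
  expect_equal(sum(rs$n_by_bin), 3L)

  no_new <- rec[rec$status == "old", ]
  expect_false(recognition_summary(no_new)$defined)
})

test_that("baseline categories are the ones sharing keys across learner groups", {
  des <- experiment_design(1, clustered = TRUE, biased_dimension = "color")
  bc <- baseline_categories(des)
  # keys 1 and 3 coincide between the two layouts
  expect_equal(bc, c("red.square", "blue.square"))
})

test_that("the chance-memory test handles the null and degenerate cases", {
  hit <- c(0.6, 0.7, 0.55, 0.65)
  et <- chance_memory_test(hit, hit)
  expect_equal(et$t, 0); expect_equal(et$d, 0); expect_equal(et$cl, 0.5)
  expect_error(chance_memory_test(hit, hit - 0.2), "degenerate")
  et2 <- chance_memory_test(hit, c(0.3, 0.35, 0.2, 0.4))
  expect_gt(et2$t, 0)
  expect_equal(et2$d, et2$t / sqrt(4))
})

test_that("effect sizes follow the paired and independent conventions", {
  es <- paired_effect_size(5, 25)
  expect_equal(es$d, 1.0)
  expect_equal(es$cl, pnorm(1))
  expect_equal(paired_effect_size(0, 10)$cl, 0.5)
  expect_equal(paired_effect_size(-5, 25)$cl, 1 - paired_effect_size(5, 25)$cl)

  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  es2 <- independent_effect_size(x, y)
  expect_equal(es2$d, (mean(x) - mean(y)) / sqrt(var(x)))  # equal vars pool to var(x)
  expect_equal(es2$cl, pnorm(es2$d / sqrt(2)))
})

test_that("the repeated-measures ANOVA agrees with the aov reference on a fixed toy table", {
  wide <- matrix(c(
    0.62, 0.55, 0.50, 0.47,
    0.58, 0.60, 0.52, 0.44,
    0.70, 0.61, 0.55, 0.52,
    0.66, 0.68, 0.58, 0.60,
    0.72, 0.65, 0.66, 0.58,
    0.64, 0.70, 0.61, 0.57), nrow = 6, byrow = TRUE)
  group <- rep(c("clustered", "nonclustered"), each = 3)
  an <- binned_hit_anova(wide, group)
  ref <- oracle_aov_f(wide, group)
  expect_equal(an$F[an$effect == "group"], unname(ref["group"]),
               tolerance = 1e-6)
  expect_equal(an$F[an$effect == "bin"], unname(ref["bin"]), tolerance = 1e-6)
  expect_equal(an$F[an$effect == "group:bin"], unname(ref["group:bin"]),
               tolerance = 1e-6)
  expect_true(all(an$pes >= 0 & an$pes <= 1))
  expect_true(all(!is.na(an$gg_eps[an$effect %in% c("bin", "group:bin")])))
})

test_that("identical group bin profiles give a zero group effect", {
  set.seed(8)
  half <- matrix(runif(20, 0.4, 0.8), nrow = 5)
  wide <- rbind(half, half)  # mirror the same participants into both groups
  group <- rep(c("clustered", "nonclustered"), each = 5)
  an <- binned_hit_anova(wide, group)
  expect_lt(an$F[an$effect == "group"], 1e-10)
  expect_lt(an$F[an$effect == "group:bin"], 1e-10)
})

test_that("spherical data yield a Greenhouse-Geisser epsilon near 1", {
  set.seed(12)
  wide <- matrix(rnorm(4 * 60), ncol = 4) + rnorm(60)  # compound symmetry
  an <- binned_hit_anova(wide, rep(c("a", "b"), each = 30))
  expect_gt(an$gg_eps[an$effect == "bin"], 0.85)
})

test_that("covariate ANOVAs center and include the switch costs", {
  set.seed(13)
  wide <- matrix(runif(80, 0.3, 0.9), ncol = 4)
  group <- rep(c("clustered", "nonclustered"), each = 10)
  cov <- data.frame(rt_cost = rnorm(20, 40, 20), acc_cost = rnorm(20, 0, 0.05))
  an <- binned_hit_anova(wide, group, covariates = cov)
  expect_true(all(c("rt_cost", "acc_cost", "rt_cost:bin") %in% an$effect))
  expect_error(binned_hit_anova(wide[1:3, ], c("a", "a", "b")), "at least 2")
})

test_that("the early-bin comparison pools experiments and tests bin-1 hits", {
  set.seed(14)
  n <- 30
  b1 <- c(runif(n, 0.50, 0.64), runif(n, 0.60, 0.74))  # nonclustered higher
  b2 <- runif(2 * n, 0.5, 0.6)
  group <- rep(c("clustered", "nonclustered"), each = n)
  expe <- rep(c(2, 3), n)
  res <- early_bins_comparison(b1, b2, group, expe)
  expect_true(all(c("group", "experiment", "bin") %in% res$anova$effect))
  expect_gt(res$bin1_test$t, 0)  # non-clustered minus clustered
  expect_warning(early_bins_comparison(b1, b2, group, rep(2, 2 * n)),
                 "dropped")
})

test_that("source-memory analysis tests accuracy against chance and refuses non-source data", {
  co <- simulate_cohort(1, n_per_group = 8, seed = 17,
                        hier_fraction = c(clustered = 0, nonclustered = 0))
  mm <- filter_memory_responses(co$memory)
  res <- source_memory_analysis(mm, group = co$participants[, c("participant",
                                                                "group")])
  # chance source responding: pooled accuracy near 0.5, t-tests null-ish
  acc <- colMeans(res$cells[, c("acc_d1_old", "acc_d2_old")], na.rm = TRUE)
  expect_true(all(abs(acc - 0.5) < 0.08))
  expect_true(all(c("type", "rating", "group") %in%
                    sub(":.*", "", res$anova$effect)))

  co2 <- simulate_cohort(2, n_per_group = 3, seed = 18)
  expect_error(source_memory_analysis(filter_memory_responses(co2$memory),
                                      co2$participants),
               "source")
})

test_that("the transfer analysis detects the negative-transfer learning reset", {
  co <- simulate_cohort(3, n_per_group = 10, seed = 19,
                        hier_fraction = c(clustered = 1, nonclustered = 0))
  res <- transfer_analysis(co)
  m <- colMeans(res$cells[, c("pos1", "pos2", "neg1", "neg2")])
  # negative-transfer categories restart learning: early deficit that shrinks
  expect_lt(m["neg1"], m["pos1"])
  expect_gt(m["neg2"] - m["neg1"], m["pos2"] - m["pos1"])
  expect_true("transfer:bin" %in% res$anova$effect)

  expect_error(transfer_analysis(simulate_cohort(2, 3, seed = 20)),
               "Experiment 3")
})
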