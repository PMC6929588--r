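# Switch-cost statistics, permutation nulls, dimension inference.

test_that("the normalized switch cost evaluates its printed formula", {
  vS <- 690 + 20 * as.numeric(scale(1:4))  # mean 690, sd 20 exactly
  vN <- 610 + 20 * as.numeric(scale(1:4))
  values <- c(vS, vN)
  labels <- rep(c("supra_switch", "supra_repeat"), each = 4)
  sc <- switch_cost(values, labels, "rt")
  expect_equal(sc$signed, 80)
  expect_equal(sc$abs, 80)
  expect_equal(sc$z_individual, 4.0)
  expect_equal(sc$z_group, 80 / sqrt(0.5 * 2 * (20 / sqrt(4))^2))

  # identical conditions: zero cost
  sc0 <- switch_cost(c(vS, vS), labels, "rt")
  expect_equal(sc0$signed, 0)
  expect_equal(sc0$z_individual, 0)

  # swapping condition labels negates the signed cost, abs unchanged
  sc_sw <- switch_cost(values, rev(labels), "rt")
  expect_equal(sc_sw$signed, -80)
  expect_equal(sc_sw$abs, 80)
})

test_that("the accuracy cost is repeat minus switch, so positive reads as structure evidence", {
  values <- c(1, 1, 1, 1, 0, 1, 0, 1)
  labels <- rep(c("supra_repeat", "supra_switch"), each = 4)
  sc <- switch_cost(values, labels, "accuracy")
  expect_equal(sc$signed, 0.5)
  expect_gt(sc$z_individual, 0)
})

test_that("the normalized cost is invariant to RT rescaling", {
  set.seed(3)
  values <- rlnorm(60, log(600), 0.2)
  labels <- sample(rep(c("supra_switch", "supra_repeat"), each = 30))
  z1 <- switch_cost(values, labels, "rt")$z_individual
  z2 <- switch_cost(values * 3.7, labels, "rt")$z_individual
  expect_equal(z1, z2)
})

test_that("undefined costs are flagged rather than silently computed", {
  sc <- switch_cost(c(600, 610, 620), c("supra_switch", "supra_repeat",
                                        "supra_repeat"), "rt")
  expect_false(sc$defined)
  expect_true(is.na(sc$z_individual))
  expect_error(permute_switch_cost(c(600, 610, 620),
                                   c("supra_switch", "supra_repeat",
                                     "supra_repeat"), "rt", n_perm = 200),
               "undefined")
})

test_that("permutation percentiles hit their boundary cases", {
  set.seed(1)
  # huge observed effect: every null draw below the observed statistic
  values <- c(rnorm(20, 1000, 5), rnorm(20, 500, 5))
  labels <- rep(c("supra_switch", "supra_repeat"), each = 20)
  pt <- permute_switch_cost(values, labels, "rt", n_perm = 500, seed = 4)
  expect_equal(pt$percentile, 1.0)
  expect_true(pt$significant)

  # constant data: observed 0 equals every null value -> percentile 0
  values0 <- rep(600, 40)
  pt0 <- permute_switch_cost(values0, labels, "rt", n_perm = 200, seed = 4)
  expect_equal(pt0$observed, 0)
  expect_equal(pt0$percentile, 0)
  expect_false(pt0$significant)

  expect_warning(permute_switch_cost(values, labels, "rt", n_perm = 50,
                                     seed = 1), "100 permutations")
})

test_that("the Monte-Carlo null matches full enumeration on small inputs", {
  set.seed(7)
  x <- round(rnorm(8, 600, 50))
  n_S <- 3L
  exact <- oracle_exact_null(x, n_S)
  labels <- c(rep("supra_switch", n_S), rep("supra_repeat", 8 - n_S))
  pt <- permute_switch_cost(x, labels, "rt", n_perm = 20000, seed = 9)
  # mean and variance agree within Monte-Carlo sampling error (3 SE)
  se_mean <- sd(exact) / sqrt(pt$n_perm)
  expect_lt(abs(mean(pt$null) - mean(exact)), 3 * se_mean)
  expect_lt(abs(var(pt$null) - var(exact)) / var(exact), 0.05)
  # observed statistic agrees with the plain-formula oracle
  expect_equal(pt$observed, oracle_abs_z(x, labels == "supra_switch"))
})

test_that("permutation percentiles are uniform on exchangeable data", {
  set.seed(11)
  pct <- vapply(1:400, function(i) {
    values <- rlnorm(80, log(600), 0.25)
    labels <- sample(rep(c("supra_switch", "supra_repeat"), c(30, 50)))
    permute_switch_cost(values, labels, "rt", n_perm = 500,
                        seed = 1000 + i)$percentile
  }, numeric(1))
  # percentiles live on a 1/n_perm lattice, so test uniformity over bins
  counts <- table(cut(pct, seq(0, 1, by = 0.1), include.lowest = TRUE))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("individual flag rate grows monotonically with the injected cost", {
  # common random numbers across cost levels: identical simulation and
  # permutation seeds per agent index isolate the effect of the injected cost
  des <- experiment_design(2, clustered = TRUE, biased_dimension = "age")
  rate_at <- function(delta, n = 150) {
    strat <- if (delta == 0) "flat" else "hierarchical"
    ag <- agent_config(strat, supra_dim = if (delta == 0) NULL else "age",
                       switch_cost_ms = delta)
    sig <- vapply(seq_len(n), function(i) {
      trials <- simulate_learning_phase(ag, des, derive_seed(1, i))
      md <- tasksetmem:::.measure_data(trials, 1L, "rt")
      pt <- permute_switch_cost(md$values, md$labels, "rt", n_perm = 500,
                                seed = derive_seed(2, i))
      pt$significant
    }, logical(1))
    mean(sig)
  }
  rates <- vapply(c(0, 20, 40, 80), rate_at, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.10)
  expect_gt(rates[4], rates[1])
})

test_that("the group permutation test aggregates SEM-normalized costs", {
  set.seed(21)
  mk <- function(delta) {
    values <- rlnorm(80, log(600), 0.25)
    labels <- sample(rep(c("supra_switch", "supra_repeat"), c(30, 50)))
    values[labels == "supra_switch"] <- values[labels == "supra_switch"] + delta
    list(values = values, labels = labels)
  }
  strong <- lapply(1:8, function(i) mk(120))
  gt <- permute_group_cost(lapply(strong, `[[`, "values"),
                           lapply(strong, `[[`, "labels"), "rt",
                           n_perm = 500, seed = 3)
  expect_true(gt$significant)
  expect_equal(gt$n_participants, 8L)

  nulls <- lapply(1:8, function(i) mk(0))
  gt0 <- permute_group_cost(lapply(nulls, `[[`, "values"),
                            lapply(nulls, `[[`, "labels"), "rt",
                            n_perm = 500, seed = 3)
  expect_true(gt0$percentile >= 0 && gt0$percentile <= 1)
  expect_length(gt0$null, 500L)
})

test_that("supraordinate-dimension inference recovers the generative dimension", {
  des <- experiment_design(2, clustered = TRUE, biased_dimension = "age")
  ag <- agent_config("hierarchical", supra_dim = "age", switch_cost_ms = 80)
  hits <- vapply(1:60, function(i) {
    trials <- simulate_learning_phase(ag, des, derive_seed(31, i))
    infer_supra_dim(trials, des$mapping)$dimension == "age"
  }, logical(1))
  expect_gt(mean(hits), 0.85)

  # flat agents: inferred dimension near-uniform over the two candidates
  fl <- agent_config("flat")
  dims <- vapply(1:100, function(i) {
    trials <- simulate_learning_phase(fl, des, derive_seed(32, i))
    infer_supra_dim(trials, des$mapping)$dimension
  }, character(1))
  expect_gt(binom.test(sum(dims == "age"), length(dims), 0.5)$p.value, 0.01)
})

test_that("union flag combines the two measures", {
  mkpt <- function(sig) structure(list(significant = sig), class = "perm_test")
  expect_true(union_flag(mkpt(TRUE), mkpt(FALSE)))
  expect_true(union_flag(mkpt(FALSE), mkpt(TRUE)))
  expect_false(union_flag(mkpt(FALSE), mkpt(FALSE)))
})

test_that("pre/post rule-switch costs recover a hand-built cost change", {
  des <- experiment_design(3, clustered = TRUE, biased_dimension = "age")
  lp <- generate_learning_trials(des, 13)
  sw_ind <- c(FALSE, lp$dim1[-1] != lp$dim1[-nrow(lp)])
  set.seed(14)
  delta <- ifelse(lp$trial <= 60, 80, 30)
  trials <- make_trials(lp$dim1, lp$dim2,
                        rt = 600 + delta * sw_ind + rnorm(120, 0, 10))
  pp <- pre_post_switch_costs(trials, des, "rt", supra = 1)
  expect_true(pp$pre$defined && pp$post$defined)
  expect_gt(pp$pre$abs, pp$post$abs)
  expect_lt(abs(pp$pre$abs - 80), 15)
  expect_lt(abs(pp$post$abs - 30), 15)

  # identical halves: difference centered near zero
  trials2 <- make_trials(lp$dim1, lp$dim2, rt = 600 + rnorm(120, 0, 10))
  pp2 <- pre_post_switch_costs(trials2, des, "rt", supra = 1)
  expect_lt(abs(pp2$pre$abs - pp2$post$abs), 20)

  expect_error(pre_post_switch_costs(trials, experiment_design(2), "rt"),
               "rule switch")

  # a half without 2 trials per condition is undefined, not an error
  few <- trials[c(1:3, 61:120), ]
  pp3 <- pre_post_switch_costs(few, des, "rt", supra = 1)
  expect_false(pp3$pre$defined)
})
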