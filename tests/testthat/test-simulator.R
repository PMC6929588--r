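# Agent simulator: learning curves, switch costs, timeouts, signal-detection
# memory, cohort bookkeeping.

test_that("agent configuration enforces its invariants", {
  expect_error(agent_config("flat", switch_cost_ms = 50), "flat")
  expect_error(agent_config("hierarchical"), "supraordinate")
  expect_error(agent_config("hierarchical", supra_dim = "age",
                            memory_criteria = c(1, 0.5, 2)))
  a <- agent_config("flat")
  expect_equal(a$switch_cost_ms, 0)
})

test_that("flat agents show no systematic RT switch cost; hierarchical agents carry the injected cost", {
  des <- experiment_design(2, clustered = TRUE, biased_dimension = "age")
  flat <- agent_config("flat", timeout_rate = 0)
  hier <- agent_config("hierarchical", supra_dim = "age", switch_cost_ms = 80,
                       timeout_rate = 0)
  diff_of <- function(agent, seeds) {
    d <- vapply(seeds, function(s) {
      lp <- simulate_learning_phase(agent, des, s)
      sw <- c(FALSE, lp$dim1[-1] != lp$dim1[-nrow(lp)])
      ok <- !lp$timeout
      mean(lp$rt_ms[sw & ok]) - mean(lp$rt_ms[!sw & ok][-1])
    }, numeric(1))
    mean(d)
  }
  expect_lt(abs(diff_of(flat, 1:100)), 5)
  expect_lt(abs(diff_of(hier, 1:100) - 80), 5)
})

test_that("the learning curve starts at chance and collapses to asymptote as tau -> 0", {
  des <- experiment_design(2)
  inst <- agent_config("flat", learn_tau = 0, p_asym = 0.95, lapse_rate = 0,
                       timeout_rate = 0)
  acc <- vapply(1:60, function(s) {
    lp <- simulate_learning_phase(inst, des, s)
    c(early = mean(lp$correct[1:10], na.rm = TRUE),
      late = mean(lp$correct[111:120], na.rm = TRUE))
  }, numeric(2))
  expect_lt(abs(mean(acc["early", ]) - 0.95), 0.03)
  expect_lt(abs(mean(acc["late", ]) - 0.95), 0.03)

  slow <- agent_config("flat", learn_tau = 10, p_asym = 0.95, lapse_rate = 0,
                       timeout_rate = 0)
  acc2 <- vapply(1:60, function(s) {
    lp <- simulate_learning_phase(slow, des, s)
    mean(lp$correct[1:5], na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(acc2), 0.7)  # early accuracy well below asymptote
})

test_that("timeouts null out the response fields and occur at about the configured rate", {
  des <- experiment_design(2)
  ag <- agent_config("flat", timeout_rate = 0.03)
  lp <- do.call(rbind, lapply(1:50, function(s)
    simulate_learning_phase(ag, des, s)))
  to <- lp[lp$timeout, ]
  expect_true(all(is.na(to$response_key)))
  expect_true(all(is.na(to$rt_ms)))
  expect_true(all(is.na(to$correct)))
  expect_true(all(lp$rt_ms[!lp$timeout] > 0))
  expect_true(all(lp$rt_ms[!lp$timeout] <= 1250))
  rate <- mean(lp$timeout)
  expect_gt(rate, 0.02); expect_lt(rate, 0.06)
})

test_that("memory simulator matches its Gaussian closed forms", {
  des <- experiment_design(2)
  mk <- function(agent, seeds) {
    do.call(rbind, lapply(seeds, function(s) {
      lp <- generate_learning_trials(des, s)
      mt <- generate_memory_trials(des, lp, s + 1000)
      simulate_memory_phase(agent, mt, s)
    }))
  }
  # zero signal: hit rate equals false-alarm rate
  null_ag <- agent_config("flat", encoding_strength_by_bin = rep(0, 4),
                          timeout_rate = 0)
  mp <- mk(null_ag, 1:40)
  resp <- collapse_ratings(mp$rating)
  hit <- mean(resp[mp$status == "old"] == "old")
  fa <- mean(resp[mp$status == "new"] == "old")
  expect_lt(abs(hit - fa), 0.02)

  # strength 1.5, middle criterion 0.75: hit rate ~ Phi(0.75)
  sig_ag <- agent_config("flat", encoding_strength_by_bin = rep(1.5, 4),
                         memory_criteria = c(0, 0.75, 1.5), timeout_rate = 0)
  mp2 <- mk(sig_ag, 1:40)
  resp2 <- collapse_ratings(mp2$rating)
  hit2 <- mean(resp2[mp2$status == "old"] == "old")
  expect_lt(abs(hit2 - pnorm(0.75)), 0.02)

  # declining strengths: pooled hit rates non-increasing across bins
  dec_ag <- agent_config("flat", encoding_strength_by_bin = c(1.2, 0.9, 0.6, 0.3),
                         timeout_rate = 0)
  mp3 <- mk(dec_ag, 1:60)
  resp3 <- collapse_ratings(mp3$rating)
  old3 <- mp3$status == "old"
  byb <- vapply(1:4, function(b)
    mean(resp3[old3 & mp3$lp_bin == b] == "old"), numeric(1))
  expect_true(all(diff(byb) < 0))
})

test_that("source responses are correct at the configured probability", {
  des <- experiment_design(1)
  ag <- agent_config("flat", source_accuracy = 0.7, timeout_rate = 0)
  lp <- generate_learning_trials(des, 3)
  mt <- generate_memory_trials(des, lp, 4)
  mp <- do.call(rbind, lapply(1:30, function(s)
    simulate_memory_phase(ag, mt, s, source_memory = TRUE)))
  expect_lt(abs(mean(mp$source_dim1 == mp$dim1) - 0.7), 0.02)
  expect_lt(abs(mean(mp$source_dim2 == mp$dim2) - 0.7), 0.02)
})

test_that("cohorts are balanced, reproducible, and mix strategies at the requested fraction", {
  co <- simulate_cohort(2, n_per_group = 12, seed = 9)
  expect_equal(nrow(co$participants), 24L)
  expect_equal(as.integer(table(co$participants$group)), c(12L, 12L))
  vcl <- co$participants$version[co$participants$group == "clustered"]
  expect_true(max(table(vcl)) - min(table(vcl)) <= 1)

  co2 <- simulate_cohort(2, n_per_group = 12, seed = 9)
  expect_identical(co$learning, co2$learning)
  expect_identical(co$memory, co2$memory)
  expect_false(identical(
    co$learning$rt_ms,
    simulate_cohort(2, n_per_group = 12, seed = 10)$learning$rt_ms))

  big <- simulate_cohort(2, n_per_group = 150, seed = 11,
                         hier_fraction = c(clustered = 0.5, nonclustered = 0.5))
  frac <- mean(big$participants$strategy == "hierarchical")
  ci <- binom.test(round(frac * 300), 300, p = 0.5)$conf.int
  expect_true(0.5 >= ci[1] && 0.5 <= ci[2])

  expect_error(simulate_cohort(2, n_per_group = 0), "at least 1")
})

test_that("cohorts round-trip through CSV serialization", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(1, n_per_group = 3, seed = 2)
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_equal(co2$experiment, 1L)
  expect_equal(nrow(co2$learning), nrow(co$learning))
  expect_equal(co2$participants$seed, co$participants$seed)
  expect_equal(co2$memory$rating, co$memory$rating)
})
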