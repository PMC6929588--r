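# Simulation studies of the permutation machinery: type-I calibration on
# flat agents and recovery of injected switch costs in hierarchical agents.

# One agent's learning phase on a fixed design, analysed for both measures.
.agent_tests <- function(agent, design, seed, n_perm, perm_seed) {
  trials <- simulate_learning_phase(agent, design, seed)
  dn <- vapply(design$dims, `[[`, "", "name")
  supra <- match(design$biased_dimension, dn)
  out <- list()
  for (measure in c("rt", "accuracy")) {
    pp <- .participant_perm(trials, supra, measure, n_perm,
                            derive_seed(perm_seed, measure))
    sig <- NA
    pct <- NA_real_
    if (!is.null(pp$null)) {
      pct <- mean(pp$null$sd < abs(pp$cost$z_individual))
      sig <- pct >= 0.975
    }
    out[[measure]] <- list(cost = pp$cost, percentile = pct, significant = sig)
  }
  out$trials <- trials
  out
}

#' Type-I-error calibration of the individual permutation test
#'
#' Simulates flat agents (no switch cost by construction), runs the
#' individual label-permutation test on both measures, and reports the
#' flagged fraction per measure and for the union flag. On exchangeable data
#' the per-measure rate should sit near the nominal 2.5% upper tail and the
#' union rate near 1 - 0.975^2.
#'
#' @param n_agents Number of simulated flat agents.
#' @param n_perm Permutations per test.
#' @param seed Master seed.
#' @param experiment Design to simulate on (default 2: 120 learning trials).
#' @param agent_args Extra [agent_config()] arguments.
#' @return data.frame with one row per agent: `rt_sig`, `acc_sig`, `union`,
#'   `rt_percentile`, `acc_percentile`, `rt_signed`.
#' @export
flat_agent_calibration <- function(n_agents, n_perm = 2000L, seed = 1L,
                                   experiment = 2L, agent_args = list()) {
  design <- experiment_design(experiment, clustered = TRUE)
  agent <- do.call(agent_config,
                   c(list(strategy = "flat", switch_cost_ms = 0), agent_args))
  rows <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    at <- .agent_tests(agent, design, derive_seed(seed, paste0("sim", i)),
                       n_perm, derive_seed(seed, paste0("perm", i)))
    rows[[i]] <- data.frame(
      rt_sig = isTRUE(at$rt$significant),
      acc_sig = isTRUE(at$accuracy$significant),
      union = isTRUE(at$rt$significant) || isTRUE(at$accuracy$significant),
      rt_percentile = at$rt$percentile,
      acc_percentile = at$accuracy$percentile,
      rt_signed = at$rt$cost$signed
    )
  }
  do.call(rbind, rows)
}

#' Recovery of an injected RT switch cost
#'
#' Simulates hierarchical agents with a known switch cost and supraordinate
#' dimension, recomputes the signed RT switch cost through the full filtering
#' and labelling path, and infers the supraordinate dimension from the data.
#' Used to verify that the analysis recovers the generative parameters
#' (small negative bias is expected from the 1250 ms response-window
#' truncation).
#'
#' @param n_agents Number of simulated hierarchical agents.
#' @param switch_cost_ms Injected RT cost in ms.
#' @param seed Master seed.
#' @param experiment Design to simulate on (default 2).
#' @param agent_args Extra [agent_config()] arguments.
#' @return data.frame per agent: `recovered` (signed RT cost, ms),
#'   `inferred_dim`, `true_dim`.
#' @export
switch_cost_recovery <- function(n_agents, switch_cost_ms = 80, seed = 1L,
                                 experiment = 2L, agent_args = list()) {
  design <- experiment_design(experiment, clustered = TRUE)
  true_dim <- design$biased_dimension
  agent <- do.call(agent_config,
                   c(list(strategy = "hierarchical", supra_dim = true_dim,
                          switch_cost_ms = switch_cost_ms), agent_args))
  dn <- vapply(design$dims, `[[`, "", "name")
  supra <- match(design$biased_dimension, dn)
  rows <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    trials <- simulate_learning_phase(agent, design,
                                      derive_seed(seed, paste0("sim", i)))
    md <- .measure_data(trials, supra, "rt")
    sc <- switch_cost(md$values, md$labels, "rt")
    inf <- infer_supra_dim(trials, design$mapping)
    rows[[i]] <- data.frame(recovered = sc$signed,
                            inferred_dim = inf$dimension,
                            true_dim = true_dim, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
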