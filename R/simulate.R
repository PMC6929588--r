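# Synthetic behavioral data: flat and hierarchical learner agents producing
# learning-phase and memory-phase records with the statistical structure the
# analyses assume.

#' Configure a simulated learner agent
#'
#' A `flat` agent memorizes all four category-key associations directly and
#' carries no switch cost; a `hierarchical` agent organizes responses under a
#' supraordinate dimension and pays an RT penalty (`switch_cost_ms`) whenever
#' that dimension's level changes between trials. Accuracy follows an
#' exponential approach from chance (0.25) to `p_asym` with time constant
#' `learn_tau` trials; RTs are lognormal with median `base_rt_ms` and log-sd
#' `rt_sd_log`, truncated by the 1250 ms response window (slower responses
#' become timeouts). Recognition memory is signal-detection: old items draw
#' strength from N(`encoding_strength_by_bin[bin]`, 1), new from N(0, 1), and
#' strength is mapped onto 4 confidence ratings via three ascending criteria.
#'
#' @param strategy `"hierarchical"` or `"flat"`.
#' @param supra_dim Supraordinate dimension name (hierarchical agents only).
#' @param switch_cost_ms RT penalty in ms on supraordinate-switch trials;
#'   must be 0 for flat agents.
#' @param base_rt_ms Median baseline RT in ms.
#' @param rt_sd_log Lognormal sd on the log scale.
#' @param learn_tau Learning-curve time constant in trials.
#' @param p_asym Asymptotic accuracy in (0.25, 1].
#' @param lapse_rate Probability of an attentional lapse (random response).
#' @param timeout_rate Probability of a missed response per trial.
#' @param encoding_strength_by_bin Old-item memory strength (d') per
#'   learning-phase bin (length 4).
#' @param memory_criteria Three strictly ascending decision criteria mapping
#'   strength onto DefNew/ProbNew/ProbOld/DefOld.
#' @param source_accuracy Probability of a correct source response
#'   (Experiment 1 probes; 0.5 = chance).
#' @return Object of class `agent_config`.
#' @export
agent_config <- function(strategy = c("hierarchical", "flat"),
                         supra_dim = NULL,
                         switch_cost_ms = if (strategy[1] == "flat") 0 else 80,
                         base_rt_ms = 650, rt_sd_log = 0.25,
                         learn_tau = 5, p_asym = 0.9, lapse_rate = 0.02,
                         timeout_rate = 0.03,
                         encoding_strength_by_bin = c(1.1, 0.95, 0.8, 0.7),
                         memory_criteria = c(-0.5, 0.75, 1.5),
                         source_accuracy = 0.5) {
  strategy <- match.arg(strategy)
  if (strategy == "flat" && switch_cost_ms != 0)
    .stopf("flat agents have no task-set to reconfigure: switch_cost_ms must be 0")
  if (strategy == "hierarchical" && is.null(supra_dim))
    .stopf("hierarchical agents need a supraordinate dimension")
  stopifnot(switch_cost_ms >= 0, base_rt_ms > 0, rt_sd_log > 0, learn_tau >= 0,
            p_asym > 0.25, p_asym <= 1, lapse_rate >= 0, lapse_rate < 1,
            timeout_rate >= 0, timeout_rate < 1,
            length(encoding_strength_by_bin) == 4L,
            all(is.finite(encoding_strength_by_bin)),
            length(memory_criteria) == 3L, all(diff(memory_criteria) > 0),
            source_accuracy >= 0, source_accuracy <= 1)
  structure(list(strategy = strategy, supra_dim = supra_dim,
                 switch_cost_ms = switch_cost_ms, base_rt_ms = base_rt_ms,
                 rt_sd_log = rt_sd_log, learn_tau = learn_tau,
                 p_asym = p_asym, lapse_rate = lapse_rate,
                 timeout_rate = timeout_rate,
                 encoding_strength_by_bin = encoding_strength_by_bin,
                 memory_criteria = memory_criteria,
                 source_accuracy = source_accuracy),
            class = "agent_config")
}

#' @export
print.agent_config <- function(x, ...) {
  cat(sprintf("%s agent", x$strategy))
  if (x$strategy == "hierarchical")
    cat(sprintf(" (supra: %s, switch cost %g ms)", x$supra_dim,
                x$switch_cost_ms))
  cat(sprintf("\n  RT ~ lognormal(median %g ms, sdlog %g); p_asym %g, tau %g trials\n",
              x$base_rt_ms, x$rt_sd_log, x$p_asym, x$learn_tau))
  cat(sprintf("  lapse %g, timeout %g; encoding d' by bin: %s\n",
              x$lapse_rate, x$timeout_rate,
              paste(x$encoding_strength_by_bin, collapse = ", ")))
  invisible(x)
}

# learning-curve accuracy at (effective) trial t
.p_correct <- function(agent, t_eff) {
  p <- if (agent$learn_tau == 0) rep(agent$p_asym, length(t_eff))
       else agent$p_asym - (agent$p_asym - 0.25) * exp(-t_eff / agent$learn_tau)
  (1 - agent$lapse_rate) * p + agent$lapse_rate * 0.25
}

#' Simulate a learning phase
#'
#' Generates the design's seeded trial list and the agent's responses. For
#' instructed designs (Experiment 4) the learning curve starts at asymptote.
#' Across the Experiment-3 rule switch, negative-transfer categories restart
#' their learning curve while positive-transfer categories continue.
#'
#' @param agent An `agent_config`.
#' @param design An `experiment_design`.
#' @param seed Integer seed.
#' @return data.frame of trial records: `trial`, `category`, `dim1`, `dim2`,
#'   `image_id`, `correct_key`, `response_key`, `correct`, `rt_ms`,
#'   `timeout`. Timeouts have `NA` response, correctness and RT.
#' @export
simulate_learning_phase <- function(agent, design, seed) {
  stopifnot(inherits(agent, "agent_config"), inherits(design, "experiment_design"))
  dn <- vapply(design$dims, `[[`, "", "name")
  if (agent$strategy == "hierarchical" && !(agent$supra_dim %in% dn))
    .stopf("agent supraordinate dimension '%s' is not a design dimension (%s)",
           agent$supra_dim, paste(dn, collapse = ", "))
  lp <- generate_learning_trials(design, seed)
  n <- nrow(lp)
  set.seed(derive_seed(seed, "lp-behavior"))

  t_eff <- lp$trial
  if (!is.null(design$rule_switch_at)) {
    neg <- names(transfer_classes(design))[transfer_classes(design) == "negative"]
    reset <- lp$trial > design$rule_switch_at & lp$category %in% neg
    t_eff[reset] <- lp$trial[reset] - design$rule_switch_at
  }
  p <- if (design$instructed) .p_correct(agent, rep(Inf, n))
       else .p_correct(agent, t_eff)
  correct <- stats::runif(n) < p
  resp <- lp$correct_key
  wrong <- which(!correct)
  if (length(wrong))
    resp[wrong] <- vapply(lp$correct_key[wrong],
                          function(k) sample(setdiff(1:4, k), 1L), integer(1))

  rt <- exp(stats::rnorm(n, log(agent$base_rt_ms), agent$rt_sd_log))
  if (agent$strategy == "hierarchical") {
    s <- if (agent$supra_dim == dn[1]) lp$dim1 else lp$dim2
    sw <- c(FALSE, s[-1] != s[-n])
    rt <- rt + agent$switch_cost_ms * sw
  }
  timeout <- stats::runif(n) < agent$timeout_rate | rt > 1250
  resp[timeout] <- NA_integer_
  correct[timeout] <- NA
  rt[timeout] <- NA_real_

  lp$response_key <- resp
  lp$correct <- correct
  lp$rt_ms <- rt
  lp$timeout <- timeout
  lp
}

#' Simulate a memory phase
#'
#' Signal-detection responding on the memory trial list: strength is compared
#' against the agent's three criteria to produce a 4-level confidence rating;
#' responses are omitted with probability `timeout_rate`. For source-memory
#' designs (Experiment 1) level judgments for each dimension are correct with
#' probability `source_accuracy`.
#'
#' @param agent An `agent_config`.
#' @param memory_trials Trial list from [generate_memory_trials()].
#' @param seed Integer seed.
#' @param source_memory Logical: generate source responses?
#' @return data.frame of memory records: `position`, `image_id`, `status`,
#'   `category`, `dim1`, `dim2`, `lp_trial`, `lp_bin`, `rating`
#'   (DefNew/ProbNew/ProbOld/DefOld or NA), `rt_ms`, and for source designs
#'   `source_dim1`, `source_dim2`.
#' @export
simulate_memory_phase <- function(agent, memory_trials, seed,
                                  source_memory = FALSE) {
  stopifnot(inherits(agent, "agent_config"))
  mt <- memory_trials
  n <- nrow(mt)
  set.seed(derive_seed(seed, "mp-behavior"))
  mu <- ifelse(mt$status == "old",
               agent$encoding_strength_by_bin[mt$lp_bin], 0)
  strength <- stats::rnorm(n, mu, 1)
  rating <- cut(strength, c(-Inf, agent$memory_criteria, Inf),
                labels = c("DefNew", "ProbNew", "ProbOld", "DefOld"))
  rating <- as.character(rating)
  rt <- exp(stats::rnorm(n, log(agent$base_rt_ms), agent$rt_sd_log))
  missed <- stats::runif(n) < agent$timeout_rate
  rating[missed] <- NA_character_
  rt[missed] <- NA_real_
  mt$rating <- rating
  mt$rt_ms <- rt
  if (source_memory) {
    hit1 <- stats::runif(n) < agent$source_accuracy
    hit2 <- stats::runif(n) < agent$source_accuracy
    flip <- function(lv, ok) {
      # swap to the other level of the same dimension when wrong
      pair <- unique(lv)
      alt <- if (length(pair) == 2L) pair[3L - match(lv, pair)]
             else rep(NA_character_, length(lv))
      ifelse(ok, lv, alt)
    }
    mt$source_dim1 <- flip(mt$dim1, hit1)
    mt$source_dim2 <- flip(mt$dim2, hit2)
    mt$source_dim1[missed] <- NA_character_
    mt$source_dim2[missed] <- NA_character_
  }
  mt
}

#' Simulate a cohort of participants for one experiment
#'
#' Participants are split evenly into clustered and non-clustered learner
#' groups and assigned round-robin to that group's counterbalanced task
#' versions. Within each group a fraction of agents is hierarchical (the rest
#' flat); clustered hierarchical agents adopt the biased dimension of their
#' mapping as supraordinate, non-clustered hierarchical agents pick a
#' dimension at random. The group-level encoding defaults reproduce the study
#' conditions the analyses target: the clustered group carries a first-bin
#' encoding deficit (early structure learning diverting attention from
#' stimulus encoding).
#'
#' @param experiment Integer 1-4.
#' @param n_per_group Participants per learner group.
#' @param seed Master integer seed; all per-participant streams derive from it.
#' @param hier_fraction Named fractions of hierarchical agents,
#'   `c(clustered = ..., nonclustered = ...)`.
#' @param switch_cost_ms Injected RT switch cost for hierarchical agents (ms).
#' @param encoding_clustered,encoding_nonclustered Per-bin encoding strengths
#'   for the two groups.
#' @param agent_args Extra arguments passed to [agent_config()] for every
#'   agent (e.g. `list(learn_tau = 8)`).
#' @return Object of class `cohort`: list with `experiment`, `participants`
#'   (one row per participant: id, group, version, strategy, true supra
#'   dimension, seed), `learning` and `memory` (long data.frames keyed by
#'   `participant`), and `designs` (version-indexed list).
#' @export
simulate_cohort <- function(experiment, n_per_group = 30L, seed = 1L,
                            hier_fraction = c(clustered = 0.6,
                                              nonclustered = 0.15),
                            switch_cost_ms = 80,
                            encoding_clustered = c(0.9, 0.95, 0.8, 0.7),
                            encoding_nonclustered = c(1.1, 0.95, 0.8, 0.7),
                            agent_args = list()) {
  experiment <- .check_experiment(experiment)
  if (n_per_group < 1L) .stopf("n_per_group must be at least 1")
  versions <- enumerate_versions(experiment)
  is_cl <- vapply(versions, `[[`, TRUE, "clustered")
  v_cl <- which(is_cl); v_nc <- which(!is_cl)
  set.seed(seed)
  p_seeds <- sample.int(2147483646L, 2L * n_per_group)

  participants <- data.frame(
    participant = seq_len(2L * n_per_group),
    group = rep(c("clustered", "nonclustered"), each = n_per_group),
    stringsAsFactors = FALSE
  )
  participants$version <- c(v_cl[(seq_len(n_per_group) - 1L) %% length(v_cl) + 1L],
                            v_nc[(seq_len(n_per_group) - 1L) %% length(v_nc) + 1L])
  hier <- stats::runif(2L * n_per_group) <
    ifelse(participants$group == "clustered",
           hier_fraction[["clustered"]], hier_fraction[["nonclustered"]])
  participants$strategy <- ifelse(hier, "hierarchical", "flat")
  participants$seed <- p_seeds

  dn <- vapply(experiment_dimensions(experiment), `[[`, "", "name")
  lp_list <- vector("list", nrow(participants))
  mp_list <- vector("list", nrow(participants))
  supra_true <- character(nrow(participants))
  for (i in seq_len(nrow(participants))) {
    des <- versions[[participants$version[i]]]
    s_i <- participants$seed[i]
    supra <- NA_character_
    if (participants$strategy[i] == "hierarchical") {
      supra <- if (des$clustered) des$biased_dimension
               else dn[1L + (derive_seed(s_i, "supra") %% 2L)]
    }
    supra_true[i] <- supra
    enc <- if (des$clustered) encoding_clustered else encoding_nonclustered
    ag <- do.call(agent_config, c(list(
      strategy = participants$strategy[i],
      supra_dim = if (is.na(supra)) NULL else supra,
      switch_cost_ms = if (participants$strategy[i] == "flat") 0 else switch_cost_ms,
      encoding_strength_by_bin = enc), agent_args))
    lp <- simulate_learning_phase(ag, des, s_i)
    mt <- generate_memory_trials(des, lp, derive_seed(s_i, "mp-order"))
    mp <- simulate_memory_phase(ag, mt, s_i, source_memory = des$source_memory)
    lp$participant <- participants$participant[i]
    mp$participant <- participants$participant[i]
    lp_list[[i]] <- lp
    mp_list[[i]] <- mp
  }
  participants$supra_dim_true <- supra_true
  structure(list(experiment = experiment,
                 participants = participants,
                 learning = do.call(rbind, lp_list),
                 memory = do.call(rbind, mp_list),
                 designs = versions),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated Experiment %d cohort: %d participants (%d clustered, %d non-clustered)\n",
              x$experiment, nrow(x$participants),
              sum(x$participants$group == "clustered"),
              sum(x$participants$group == "nonclustered")))
  cat(sprintf("  %d learning-phase and %d memory-phase trial records\n",
              nrow(x$learning), nrow(x$memory)))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' @param cohort A `cohort`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    learning = file.path(dir, "learning.csv"),
    memory = file.path(dir, "memory.csv"),
    participants = file.path(dir, "participants.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  utils::write.csv(cohort$learning, paths["learning"], row.names = FALSE)
  utils::write.csv(cohort$memory, paths["memory"], row.names = FALSE)
  utils::write.csv(cohort$participants, paths["participants"], row.names = FALSE)
  jsonlite::write_json(list(experiment = cohort$experiment,
                            n_participants = nrow(cohort$participants)),
                       paths["manifest"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `learning.csv`, `memory.csv`,
#'   `participants.csv` and `manifest.json`.
#' @return A `cohort` object (designs re-enumerated from the experiment id).
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(list(
    experiment = as.integer(man$experiment),
    participants = utils::read.csv(file.path(dir, "participants.csv"),
                                   stringsAsFactors = FALSE),
    learning = utils::read.csv(file.path(dir, "learning.csv"),
                               stringsAsFactors = FALSE),
    memory = utils::read.csv(file.path(dir, "memory.csv"),
                             stringsAsFactors = FALSE),
    designs = enumerate_versions(as.integer(man$experiment))
  ), class = "cohort")
}
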