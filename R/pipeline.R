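# End-to-end orchestration: configuration, the simulate -> preprocess ->
# infer -> memory-report pipeline, and its serialized outputs.

#' Required sample size for a one-sample t-test
#'
#' Thin wrapper around [stats::power.t.test()] used for the design's a priori
#' power analysis (e.g. d = 0.88, power 0.90, two-sided alpha 0.05 gives 16).
#'
#' @param d Standardized effect size (Cohen's d_z).
#' @param power Target power.
#' @param sig.level Two-sided alpha.
#' @return Integer sample size (rounded up).
#' @export
required_sample_size <- function(d, power = 0.90, sig.level = 0.05) {
  ceiling(stats::power.t.test(delta = d, sd = 1, power = power,
                              sig.level = sig.level, type = "one.sample",
                              alternative = "two.sided")$n)
}

#' Build a pipeline run configuration
#'
#' @param experiment Integer 1-4.
#' @param n_per_group Participants per learner group.
#' @param n_perm Permutations for the switch-cost tests.
#' @param seed Master seed (all stage seeds derive from it).
#' @param hier_fraction,switch_cost_ms,encoding_clustered,encoding_nonclustered,agent_args
#'   Passed to [simulate_cohort()].
#' @param covariates Add individual switch costs as ANOVA covariates?
#' @return List of class `run_config`; serializable with [save_config()].
#' @export
run_config <- function(experiment, n_per_group = 30L, n_perm = 10000L,
                       seed = 1L,
                       hier_fraction = c(clustered = 0.6, nonclustered = 0.15),
                       switch_cost_ms = 80,
                       encoding_clustered = c(0.9, 0.95, 0.8, 0.7),
                       encoding_nonclustered = c(1.1, 0.95, 0.8, 0.7),
                       agent_args = list(), covariates = FALSE) {
  hier_fraction <- unlist(hier_fraction)
  stopifnot(all(c("clustered", "nonclustered") %in% names(hier_fraction)))
  cfg <- list(experiment = .check_experiment(experiment),
              n_per_group = as.integer(n_per_group),
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              hier_fraction = hier_fraction,
              switch_cost_ms = switch_cost_ms,
              encoding_clustered = encoding_clustered,
              encoding_nonclustered = encoding_nonclustered,
              agent_args = agent_args, covariates = isTRUE(covariates))
  class(cfg) <- "run_config"
  cfg
}

#' Save / load a run configuration as JSON
#'
#' `load_config(save_config(cfg, f))` round-trips the configuration.
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `save_config` returns the path invisibly; `load_config` the
#'   `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  cfg <- unclass(config)
  cfg$hier_fraction <- as.list(cfg$hier_fraction)  # keep names in JSON
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, applies the participant gates, fits the
#' structure-formation analysis, and runs the memory analyses appropriate to
#' the experiment (chance tests, baseline-category comparison, binned hit
#' ANOVA with optional switch-cost covariates; source memory for Experiment
#' 1; pre/post switch-cost and transfer analyses for Experiment 3). With an
#' output directory, writes the cohort CSVs, an exclusions report, the
#' per-participant results, and a JSON run manifest. Identical configurations
#' produce identical outputs.
#'
#' @param config A `run_config`.
#' @param out_dir Optional output directory; refuses to overwrite a non-empty
#'   directory unless `force = TRUE`.
#' @param force Overwrite existing outputs?
#' @return Object of class `pipeline_result`: `config`, `cohort`,
#'   `structure` (a `structure_analysis`), `memory` (summaries and tests),
#'   plus experiment-specific components.
#' @export
run_pipeline <- function(config, out_dir = NULL, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && dir.exists(out_dir) &&
      length(dir(out_dir)) && !force)
    .stopf("output directory '%s' is not empty; use force = TRUE to overwrite",
           out_dir)
  cohort <- simulate_cohort(config$experiment, config$n_per_group,
                            seed = config$seed,
                            hier_fraction = config$hier_fraction,
                            switch_cost_ms = config$switch_cost_ms,
                            encoding_clustered = config$encoding_clustered,
                            encoding_nonclustered = config$encoding_nonclustered,
                            agent_args = config$agent_args)
  struct <- structure_analysis(cohort, n_perm = config$n_perm,
                               seed = derive_seed(config$seed, "perm"))
  memory <- .memory_report(cohort, struct, covariates = config$covariates)
  out <- list(config = config, cohort = cohort, structure = struct,
              memory = memory)
  if (cohort$experiment == 3L) {
    out$transfer <- transfer_analysis(cohort)
    out$pre_post <- pre_post_report(cohort)
  }
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) .write_pipeline(out, out_dir)
  out
}

# Recognition-memory stage shared by all experiments.
.memory_report <- function(cohort, struct, covariates = FALSE) {
  pt <- struct$participants
  included <- pt$participant[which(pt$include)]
  recs <- lapply(included, function(id) {
    des <- cohort$designs[[pt$version[pt$participant == id]]]
    m <- cohort$memory[cohort$memory$participant == id, , drop = FALSE]
    recognition_summary(filter_memory_responses(m),
                        baseline_category = baseline_categories(des)[1])
  })
  tab <- data.frame(
    participant = included,
    group = pt$group[match(included, pt$participant)],
    hit = vapply(recs, `[[`, 0, "hit_rate"),
    fa = vapply(recs, `[[`, 0, "fa_rate"),
    baseline_hit = vapply(recs, `[[`, 0, "baseline_hit"),
    bin_gate_ok = vapply(recs, `[[`, TRUE, "bin_gate_ok"),
    stringsAsFactors = FALSE
  )
  bins <- t(vapply(recs, `[[`, numeric(4), "hits_by_bin"))
  colnames(bins) <- paste0("hit_bin", 1:4)
  tab <- cbind(tab, bins)

  chance <- lapply(split(tab, tab$group),
                   function(g) chance_memory_test(g$hit, g$fa))
  bl <- independent_memory_test(tab$baseline_hit[tab$group == "nonclustered"],
                                tab$baseline_hit[tab$group == "clustered"])
  ok <- tab$bin_gate_ok & stats::complete.cases(bins)
  cov <- NULL
  if (covariates) {
    cov <- data.frame(
      rt_cost = pt$rt_signed[match(tab$participant, pt$participant)],
      acc_cost = pt$acc_signed[match(tab$participant, pt$participant)]
    )
    ok <- ok & stats::complete.cases(cov)
    cov <- cov[ok, , drop = FALSE]
  }
  anova <- binned_hit_anova(bins[ok, , drop = FALSE], tab$group[ok],
                            covariates = cov)
  mem <- list(table = tab, chance_tests = chance, baseline_test = bl,
              binned_anova = anova, n_in_anova = sum(ok))
  if (cohort$experiment == 1L) {
    mm <- cohort$memory[cohort$memory$participant %in% included, , drop = FALSE]
    mem$source <- source_memory_analysis(
      filter_memory_responses(mm),
      group = pt[, c("participant", "group")])
  }
  mem
}

#' Pre/post rule-switch switch-cost comparison (Experiment 3)
#'
#' Computes each participant's absolute switch cost before and after the
#' implicit rule switch (per measure) and tests the time (pre/post) x group
#' repeated-measures ANOVA.
#'
#' @param cohort An Experiment-3 `cohort`.
#' @return List per measure with `cells` and `anova`; participants with an
#'   undefined half are dropped.
#' @export
pre_post_report <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"), cohort$experiment == 3L)
  pt <- cohort$participants
  out <- list()
  for (measure in c("rt", "accuracy")) {
    rows <- list()
    for (i in seq_len(nrow(pt))) {
      des <- cohort$designs[[pt$version[i]]]
      dn <- vapply(des$dims, `[[`, "", "name")
      trials <- cohort$learning[cohort$learning$participant ==
                                  pt$participant[i], , drop = FALSE]
      pp <- pre_post_switch_costs(trials, des, measure,
                                  supra = match(des$biased_dimension, dn))
      if (!pp$pre$defined || !pp$post$defined) next
      rows[[length(rows) + 1L]] <-
        data.frame(participant = pt$participant[i], group = pt$group[i],
                   pre = pp$pre$abs, post = pp$post$abs,
                   stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, rows)
    an <- .rm_anova(as.matrix(cells[, c("pre", "post")]),
                    data.frame(group = factor(cells$group)),
                    data.frame(time = factor(c("pre", "post"),
                                             c("pre", "post"))),
                    ~time)
    out[[measure]] <- list(cells = cells, anova = an)
  }
  out
}

.write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(result$cohort, file.path(out_dir, "cohort"))
  pt <- result$structure$participants
  utils::write.csv(pt, file.path(out_dir, "switch_costs.csv"),
                   row.names = FALSE)
  excl <- pt[!vapply(pt$include, isTRUE, TRUE),
             c("participant", "group", "reason")]
  utils::write.csv(excl, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(result$structure$groups,
                   file.path(out_dir, "group_permutation.csv"),
                   row.names = FALSE)
  utils::write.csv(result$memory$table, file.path(out_dir, "memory.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(result$config),
         package_version = as.character(utils::packageVersion("tasksetmem")),
         groups = result$structure$groups,
         binned_anova = as.data.frame(result$memory$binned_anova)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== Structure-formation pipeline ==\n\n")
  print(x$structure)
  cat("\n== Recognition memory ==\n")
  for (g in names(x$memory$chance_tests)) {
    cat(sprintf("  %s hit vs FA: ", g)); print(x$memory$chance_tests[[g]])
  }
  cat("  baseline-category group test: "); print(x$memory$baseline_test)
  cat(sprintf("\nBinned hit-rate ANOVA (n = %d):\n", x$memory$n_in_anova))
  print(x$memory$binned_anova)
  invisible(x)
}

#' Human-readable pipeline report
#'
#' Prints the group permutation percentiles, flagged-individual counts,
#' inferred-dimension counts and hit rates by bin and group, in the reporting
#' style of the learning/memory analyses.
#'
#' @param result A `pipeline_result`.
#' @return Invisibly, a list of the printed tables.
#' @export
report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  print(result)
  tab <- result$memory$table
  bybin <- stats::aggregate(
    cbind(hit_bin1, hit_bin2, hit_bin3, hit_bin4) ~ group, data = tab,
    FUN = mean, na.action = stats::na.omit)
  cat("\nMean hit rates by learning-phase bin:\n")
  print(bybin, row.names = FALSE)
  invisible(list(groups = result$structure$groups, hit_by_bin = bybin))
}
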