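# Cohort-level structure-formation inference: per-participant switch costs,
# permutation tests, union flags and inferred supraordinate dimensions, plus
# the group-level permutation tests.

# Extract a participant's analysis-ready values and labels for one measure.
.measure_data <- function(trials, supra, measure, full_repeat = "repeat") {
  lab <- classify_transitions(trials$dim1, trials$dim2, supra = supra,
                              full_repeat = full_repeat)
  flt <- if (measure == "rt") filter_learning_rt(trials)
         else filter_learning_accuracy(trials)
  lab_flt <- lab[match(flt$trial, trials$trial)]
  keep <- lab_flt %in% c("supra_switch", "supra_repeat")
  values <- if (measure == "rt") flt$rt_ms else as.numeric(flt$correct)
  list(values = values[keep], labels = lab_flt[keep])
}

# Per-participant permutation machinery for one measure; returns the observed
# switch_cost plus the sd- and sem-form null vectors (or NULL when undefined).
.participant_perm <- function(trials, supra, measure, n_perm, seed,
                              full_repeat = "repeat") {
  md <- .measure_data(trials, supra, measure, full_repeat)
  sc <- switch_cost(md$values, md$labels, measure)
  if (!sc$defined) return(list(cost = sc, null = NULL))
  is_S <- md$labels == "supra_switch"
  null <- .perm_null_abs_z(as.numeric(md$values), sum(is_S), n_perm, seed)
  list(cost = sc, null = null)
}

#' Fit the structure-formation analysis to a cohort
#'
#' The central estimator of the package: applies the trial and participant
#' filters, computes RT and accuracy switch costs under each participant's
#' candidate supraordinate dimension (the mapping's layout dimension), runs
#' the individual-level label-permutation tests (SD-normalized statistic,
#' upper-tail 97.5% criterion on both measures, combined with a union flag),
#' infers each participant's supraordinate dimension from the sign of the raw
#' RT costs, and runs the group-level permutation test on the mean absolute
#' SEM-normalized costs within each learner group.
#'
#' @param cohort A `cohort` from [simulate_cohort()] or [read_cohort()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Master seed for the permutation streams.
#' @param full_repeat Handling of exact category repetitions (see
#'   [classify_transitions()]).
#' @return Object of class `structure_analysis`: `participants` (one row per
#'   participant with costs, percentiles, flags, inferred dimension and
#'   exclusion bookkeeping), `groups` (group x measure permutation results),
#'   `n_perm`, `seed`, `experiment`.
#' @seealso [permute_switch_cost()], [permute_group_cost()],
#'   [infer_supra_dim()]
#' @export
structure_analysis <- function(cohort, n_perm = 10000L, seed = 1L,
                               full_repeat = "repeat") {
  stopifnot(inherits(cohort, "cohort"))
  pt <- cohort$participants
  P <- nrow(pt)
  res <- data.frame(
    participant = pt$participant, group = pt$group, version = pt$version,
    include = NA, reason = NA_character_, accuracy = NA_real_,
    rt_signed = NA_real_, rt_abs = NA_real_, rt_z = NA_real_,
    rt_percentile = NA_real_, rt_significant = NA,
    acc_signed = NA_real_, acc_abs = NA_real_, acc_z = NA_real_,
    acc_percentile = NA_real_, acc_significant = NA,
    structure_former = NA, inferred_dim = NA_character_,
    stringsAsFactors = FALSE
  )
  null_sem <- list(rt = vector("list", P), accuracy = vector("list", P))
  obs_sem <- list(rt = rep(NA_real_, P), accuracy = rep(NA_real_, P))

  for (i in seq_len(P)) {
    des <- cohort$designs[[pt$version[i]]]
    trials <- cohort$learning[cohort$learning$participant == pt$participant[i], ,
                              drop = FALSE]
    responded <- trials[!trials$timeout & !is.na(trials$correct), , drop = FALSE]
    acc <- if (nrow(responded)) mean(responded$correct) else 0
    gate <- participant_gate(acc)
    res$include[i] <- gate$include
    res$reason[i] <- gate$reason
    res$accuracy[i] <- acc
    if (!gate$include) next

    dn <- vapply(des$dims, `[[`, "", "name")
    supra <- match(des$biased_dimension, dn)
    for (measure in c("rt", "accuracy")) {
      pp <- .participant_perm(trials, supra, measure, n_perm,
                              derive_seed(seed, paste0(pt$participant[i], measure)),
                              full_repeat)
      sc <- pp$cost
      pre <- if (measure == "rt") "rt" else "acc"
      res[[paste0(pre, "_signed")]][i] <- sc$signed
      res[[paste0(pre, "_abs")]][i] <- sc$abs
      res[[paste0(pre, "_z")]][i] <- sc$z_individual
      if (!is.null(pp$null)) {
        obs <- abs(sc$z_individual)
        pct <- mean(pp$null$sd < obs)
        res[[paste0(pre, "_percentile")]][i] <- pct
        res[[paste0(pre, "_significant")]][i] <- pct >= 0.975
        null_sem[[measure]][[i]] <- pp$null$sem
        obs_sem[[measure]][i] <- abs(sc$z_group)
      }
    }
    res$structure_former[i] <- isTRUE(res$rt_significant[i]) ||
      isTRUE(res$acc_significant[i])
    inf <- infer_supra_dim(trials, des$mapping)
    res$inferred_dim[i] <- inf$dimension
  }

  groups <- do.call(rbind, lapply(unique(res$group), function(g) {
    do.call(rbind, lapply(c("rt", "accuracy"), function(m) {
      idx <- which(res$group == g & !is.na(obs_sem[[m]]))
      if (length(idx) < 2L)
        return(data.frame(group = g, measure = m, n = length(idx),
                          observed = NA_real_, percentile = NA_real_,
                          significant = NA, stringsAsFactors = FALSE))
      null <- rowMeans(do.call(cbind, null_sem[[m]][idx]))
      observed <- mean(obs_sem[[m]][idx])
      pct <- mean(null < observed)
      data.frame(group = g, measure = m, n = length(idx), observed = observed,
                 percentile = pct, significant = pct >= 0.975,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(groups) <- NULL

  structure(list(participants = res, groups = groups, n_perm = n_perm,
                 seed = seed, experiment = cohort$experiment),
            class = "structure_analysis")
}

#' @export
print.structure_analysis <- function(x, ...) {
  cat(sprintf("Structure-formation analysis (Experiment %d, %d permutations)\n",
              x$experiment, x$n_perm))
  inc <- x$participants[which(x$participants$include), , drop = FALSE]
  cat(sprintf("  %d of %d participants included\n", nrow(inc),
              nrow(x$participants)))
  cat("\nGroup-level permutation percentiles (mean |z|, SEM form):\n")
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-13s %-9s %6.2f%%%s (n=%d)\n", g$group[i], g$measure[i],
                100 * g$percentile[i],
                ifelse(isTRUE(g$significant[i]), " *", ""), g$n[i]))
  cat("\nIndividual structure formers (union of RT/accuracy flags):\n")
  for (gr in unique(inc$group))
    cat(sprintf("  %-13s %d of %d\n", gr,
                sum(inc$structure_former[inc$group == gr], na.rm = TRUE),
                sum(inc$group == gr)))
  tab <- table(inc$group, inc$inferred_dim)
  if (length(tab)) {
    cat("\nInferred supraordinate dimension counts:\n")
    print(tab)
  }
  invisible(x)
}

#' @export
summary.structure_analysis <- function(object, ...) {
  inc <- object$participants[which(object$participants$include), , drop = FALSE]
  out <- list(
    groups = object$groups,
    flagged = stats::aggregate(structure_former ~ group, data = inc,
                               FUN = function(z) sum(z, na.rm = TRUE)),
    inferred = as.data.frame(table(group = inc$group, dim = inc$inferred_dim)),
    mean_costs = stats::aggregate(cbind(rt_signed, rt_abs, acc_signed, acc_abs)
                                  ~ group, data = inc, FUN = mean,
                                  na.action = stats::na.omit),
    exclusions = object$participants[!vapply(object$participants$include,
                                             isTRUE, TRUE),
                                     c("participant", "group", "reason")]
  )
  class(out) <- "summary.structure_analysis"
  out
}

#' @export
print.summary.structure_analysis <- function(x, ...) {
  cat("Group-level permutation results:\n"); print(x$groups)
  cat("\nFlagged structure formers by group:\n"); print(x$flagged)
  cat("\nMean switch costs by group:\n"); print(x$mean_costs)
  if (nrow(x$exclusions)) {
    cat("\nExcluded participants:\n"); print(x$exclusions)
  }
  invisible(x)
}
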