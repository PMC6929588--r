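# Switch-cost computation, supraordinate-dimension inference, and the
# within-participant label-permutation tests at the individual and group
# level.

#' Compute switch-cost statistics for one participant and measure
#'
#' Condition means, SDs and SEMs on supraordinate-switch (S) and
#' supraordinate-repeat (N) trials, together with the signed cost, its
#' absolute value, and two d-prime-style normalized forms:
#' `z_individual = (mu_S - mu_N) / sqrt((sigma_S^2 + sigma_N^2) / 2)` and
#' `z_group = (mu_S - mu_N) / sqrt((sem_S^2 + sem_N^2) / 2)` (the SEM-based
#' form used for group-level averaging). For accuracy the signed cost is
#' repeat minus switch, so a positive value always reads "structure
#' evidence"; the normalized forms carry that sign. The normalized cost is
#' scale invariant and does not index the strength of structure formation.
#'
#' @param values RT in ms (filtered correct trials) or 0/1 correctness
#'   (responded trials), already restricted to labelled trials.
#' @param labels Transition labels parallel to `values`; only `supra_switch`
#'   and `supra_repeat` entries are used.
#' @param measure `"rt"` or `"accuracy"` (fixes the sign convention).
#' @param supra_dim Dimension name assumed supraordinate (metadata).
#' @return Object of class `switch_cost`; `defined` is `FALSE` when either
#'   condition has fewer than 2 trials.
#' @export
switch_cost <- function(values, labels, measure = c("rt", "accuracy"),
                        supra_dim = NA_character_) {
  measure <- match.arg(measure)
  stopifnot(length(values) == length(labels))
  vS <- values[labels == "supra_switch"]
  vN <- values[labels == "supra_repeat"]
  n_S <- length(vS); n_N <- length(vN)
  out <- list(measure = measure, supra_dim = supra_dim,
              mu_S = .safe_mean(vS), mu_N = .safe_mean(vN),
              sd_S = .safe_sd(vS), sd_N = .safe_sd(vN),
              n_S = n_S, n_N = n_N,
              defined = n_S >= 2L && n_N >= 2L)
  out$sem_S <- out$sd_S / sqrt(n_S)
  out$sem_N <- out$sd_N / sqrt(n_N)
  diffSN <- out$mu_S - out$mu_N
  out$signed <- if (measure == "rt") diffSN else -diffSN
  out$abs <- abs(out$signed)
  pooled_sd <- sqrt(0.5 * (out$sd_S^2 + out$sd_N^2))
  pooled_sem <- sqrt(0.5 * (out$sem_S^2 + out$sem_N^2))
  out$z_individual <- if (isTRUE(pooled_sd > 0)) out$signed / pooled_sd else 0
  out$z_group <- if (isTRUE(pooled_sem > 0)) out$signed / pooled_sem else 0
  if (!out$defined) out$z_individual <- out$z_group <- NA_real_
  structure(out, class = "switch_cost")
}

#' @export
print.switch_cost <- function(x, ...) {
  unit <- if (x$measure == "rt") "ms" else "prop."
  cat(sprintf("Switch cost (%s%s)\n", x$measure,
              if (is.na(x$supra_dim)) "" else paste0(", supra: ", x$supra_dim)))
  cat(sprintf("  switch: mean %.3f, sd %.3f (n=%d); repeat: mean %.3f, sd %.3f (n=%d)\n",
              x$mu_S, x$sd_S, x$n_S, x$mu_N, x$sd_N, x$n_N))
  cat(sprintf("  signed %.3f %s | abs %.3f | z (SD) %.3f | z (SEM) %.3f\n",
              x$signed, unit, x$abs, x$z_individual, x$z_group))
  invisible(x)
}

# Null distribution of the absolute normalized cost under label shuffles.
# One sampling pass yields both the SD-based (individual) and SEM-based
# (group) forms; condition counts are preserved in every draw; degenerate
# draws (zero pooled spread) score 0.
.perm_null_abs_z <- function(x, n_S, n_perm, seed) {
  n <- length(x); n_N <- n - n_S
  stopifnot(n_S >= 2L, n_N >= 2L, n_perm >= 1L)
  set.seed(seed)
  sel <- vapply(seq_len(n_perm), function(i) sample.int(n, n_S),
                integer(n_S))
  xs <- matrix(x[sel], nrow = n_S)
  sum_S <- .colSums(xs, n_S, n_perm)
  ssq_S <- .colSums(xs * xs, n_S, n_perm)
  tot <- sum(x); totsq <- sum(x * x)
  mu_S <- sum_S / n_S
  mu_N <- (tot - sum_S) / n_N
  var_S <- pmax((ssq_S - n_S * mu_S^2) / (n_S - 1), 0)
  var_N <- pmax(((totsq - ssq_S) - n_N * mu_N^2) / (n_N - 1), 0)
  d <- abs(mu_S - mu_N)
  z_sd <- d / sqrt(0.5 * (var_S + var_N))
  z_sem <- d / sqrt(0.5 * (var_S / n_S + var_N / n_N))
  z_sd[!is.finite(z_sd)] <- 0
  z_sem[!is.finite(z_sem)] <- 0
  list(sd = z_sd, sem = z_sem)
}

#' Individual-level permutation test of a switch cost
#'
#' Shuffles the supraordinate-repeat/switch labels over the participant's
#' included trials (condition counts fixed), recomputing the absolute
#' normalized (SD-based) switch cost for each of `n_perm` draws. The observed
#' statistic is flagged significant when its percentile — the fraction of
#' null draws strictly below it — reaches 0.975 (upper tail of a two-sided
#' 2.5% criterion).
#'
#' @inheritParams switch_cost
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param statistic `"sd"` for the individual (SD-normalized) statistic or
#'   `"sem"` for the group-form statistic.
#' @return Object of class `perm_test`: `observed`, `null` (length `n_perm`),
#'   `percentile`, `significant`, `n_perm`, `seed`.
#' @export
permute_switch_cost <- function(values, labels, measure = c("rt", "accuracy"),
                                n_perm = 10000L, seed = 1L,
                                statistic = c("sd", "sem")) {
  measure <- match.arg(measure)
  statistic <- match.arg(statistic)
  if (n_perm < 100L)
    warning("fewer than 100 permutations gives a low-resolution null",
            call. = FALSE)
  sc <- switch_cost(values, labels, measure)
  if (!sc$defined)
    .stopf("switch cost undefined: need at least 2 trials per condition (have %d switch, %d repeat)",
           sc$n_S, sc$n_N)
  keep <- labels %in% c("supra_switch", "supra_repeat")
  x <- as.numeric(values[keep])
  is_S <- labels[keep] == "supra_switch"
  null <- .perm_null_abs_z(x, sum(is_S), n_perm, seed)[[statistic]]
  observed <- abs(if (statistic == "sd") sc$z_individual else sc$z_group)
  percentile <- mean(null < observed)
  structure(list(observed = observed, null = null, percentile = percentile,
                 significant = percentile >= 0.975, n_perm = n_perm,
                 seed = seed, measure = measure, statistic = statistic),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s-normalized, %d draws)\n",
              x$measure, x$statistic, x$n_perm))
  cat(sprintf("  observed |z| = %.3f, percentile = %.2f%%, %s\n",
              x$observed, 100 * x$percentile,
              if (x$significant) "significant (>= 97.5%)" else "not significant"))
  invisible(x)
}

#' Group-level permutation test of mean normalized switch costs
#'
#' The observed statistic is the mean over participants of the absolute
#' SEM-normalized switch cost. Each participant's labels are shuffled
#' independently (seeded per participant) and the k-th null value is the mean
#' of the participants' k-th permuted statistics. Significance is read from
#' the upper tail at 97.5% as in the individual test.
#'
#' @param value_list List (one element per participant) of value vectors.
#' @param label_list Parallel list of label vectors.
#' @param measure `"rt"` or `"accuracy"`.
#' @param n_perm Number of permutations.
#' @param seed Master seed; per-participant streams are derived from it.
#' @return A `perm_test` with an extra element `n_participants`; participants
#'   with an undefined cost are dropped (recorded in `dropped`).
#' @export
permute_group_cost <- function(value_list, label_list,
                               measure = c("rt", "accuracy"),
                               n_perm = 10000L, seed = 1L) {
  measure <- match.arg(measure)
  stopifnot(length(value_list) == length(label_list))
  P <- length(value_list)
  obs <- rep(NA_real_, P)
  nulls <- vector("list", P)
  for (i in seq_len(P)) {
    labels <- label_list[[i]]
    sc <- switch_cost(value_list[[i]], labels, measure)
    if (!sc$defined) next
    keep <- labels %in% c("supra_switch", "supra_repeat")
    x <- as.numeric(value_list[[i]][keep])
    is_S <- labels[keep] == "supra_switch"
    nulls[[i]] <- .perm_null_abs_z(x, sum(is_S), n_perm,
                                   derive_seed(seed, i))$sem
    obs[i] <- abs(sc$z_group)
  }
  ok <- !is.na(obs)
  if (sum(ok) < 2L)
    .stopf("group permutation test needs at least 2 participants with defined costs")
  null <- rowMeans(do.call(cbind, nulls[ok]))
  observed <- mean(obs[ok])
  percentile <- mean(null < observed)
  structure(list(observed = observed, null = null, percentile = percentile,
                 significant = percentile >= 0.975, n_perm = n_perm,
                 seed = seed, measure = measure, statistic = "sem",
                 n_participants = sum(ok), dropped = which(!ok)),
            class = "perm_test")
}

#' Infer a participant's supraordinate dimension
#'
#' Computes the signed RT switch cost assuming each dimension in turn is
#' supraordinate and reports the dimension yielding the larger signed cost
#' (a hierarchical learner is slowed when their true supraordinate level
#' changes, so the true dimension produces the more positive cost). Exact
#' ties fall back to a tie-break: the mapping's biased dimension for
#' clustered mappings, the first dimension otherwise.
#'
#' Exact category repetitions are excluded by default here (unlike the cost
#' estimate itself): they are labelled "repeat" under both candidate
#' dimensions, so they carry no information about which dimension is
#' supraordinate and only dilute the contrast between the two candidate
#' costs.
#'
#' @param trials A participant's learning trial records (with `dim1`, `dim2`,
#'   `trial`, `correct`, `rt_ms`, `timeout`).
#' @param mapping The participant's `response_mapping` (used for the
#'   tie-break).
#' @param full_repeat Passed to [classify_transitions()].
#' @return List with `dimension` (name or `NA` if undetermined), `tie`
#'   (logical), and `signed_costs` (named vector, one per candidate).
#' @export
infer_supra_dim <- function(trials, mapping, full_repeat = "exclude") {
  dn <- vapply(mapping$dims, `[[`, "", "name")
  costs <- stats::setNames(rep(NA_real_, 2L), dn)
  for (k in 1:2) {
    lab <- classify_transitions(trials$dim1, trials$dim2, supra = k,
                                full_repeat = full_repeat)
    flt <- filter_learning_rt(trials)
    lab_flt <- lab[match(flt$trial, trials$trial)]
    sc <- switch_cost(flt$rt_ms, lab_flt, "rt", supra_dim = dn[k])
    if (sc$defined) costs[k] <- sc$signed
  }
  if (all(is.na(costs)))
    return(list(dimension = NA_character_, tie = FALSE, signed_costs = costs))
  tie <- !anyNA(costs) && costs[1] == costs[2]
  dimension <- if (tie) {
    if (mapping$clustered) mapping$biased_dimension else dn[1]
  } else names(costs)[which.max(costs)]
  list(dimension = dimension, tie = tie, signed_costs = costs)
}

#' Union structure-former flag
#'
#' A participant counts as a structure former when either the RT or the
#' accuracy permutation test is significant.
#'
#' @param rt_test,acc_test `perm_test` objects for the two measures.
#' @return Logical flag.
#' @export
union_flag <- function(rt_test, acc_test) {
  stopifnot(inherits(rt_test, "perm_test"), inherits(acc_test, "perm_test"))
  isTRUE(rt_test$significant) || isTRUE(acc_test$significant)
}

#' Absolute switch costs before and after the Experiment-3 rule switch
#'
#' Splits the learning phase at the rule switch and computes the absolute
#' switch cost separately in each half. Transition labels are re-derived
#' within each half, so each half's opening trial is excluded as `first`.
#'
#' @param trials A participant's learning trial records.
#' @param design The Experiment-3 `experiment_design`.
#' @param measure `"rt"` or `"accuracy"`.
#' @param supra Candidate supraordinate dimension index (1 or 2).
#' @return List with `pre` and `post` `switch_cost` objects (either may be
#'   undefined when a half lacks 2 trials per condition).
#' @export
pre_post_switch_costs <- function(trials, design, measure = c("rt", "accuracy"),
                                  supra = 1L) {
  measure <- match.arg(measure)
  if (is.null(design$rule_switch_at))
    .stopf("design has no rule switch; pre/post comparison applies to Experiment 3")
  half <- function(rows) {
    lab <- classify_transitions(rows$dim1, rows$dim2, supra = supra)
    flt <- if (measure == "rt") {
      keep <- !is.na(rows$correct) & rows$correct & !rows$timeout &
        !is.na(rows$rt_ms) & rows$rt_ms >= 200 & rows$rt_ms <= 1250
      rows[keep, , drop = FALSE]
    } else {
      rows[!rows$timeout & !is.na(rows$correct), , drop = FALSE]
    }
    keep_lab <- lab[match(flt$trial, rows$trial)]
    drop_first <- keep_lab != "first"
    vals <- if (measure == "rt") flt$rt_ms else as.numeric(flt$correct)
    switch_cost(vals[drop_first], keep_lab[drop_first], measure)
  }
  pre <- half(trials[trials$trial <= design$rule_switch_at, , drop = FALSE])
  post <- half(trials[trials$trial > design$rule_switch_at, , drop = FALSE])
  list(pre = pre, post = post)
}
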