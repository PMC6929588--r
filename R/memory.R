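# Recognition- and source-memory analyses: hit/false-alarm rates, chance
# tests, binned repeated-measures ANOVAs (Greenhouse-Geisser corrected) with
# optional switch-cost covariates, and effect sizes.

#' Collapse 4-level confidence ratings to binary old/new
#'
#' @param rating Character vector of `DefOld`/`ProbOld`/`ProbNew`/`DefNew`.
#' @return Character vector of `"old"`/`"new"` (`NA` passes through).
#' @export
collapse_ratings <- function(rating) {
  out <- rep(NA_character_, length(rating))
  out[rating %in% c("DefOld", "ProbOld")] <- "old"
  out[rating %in% c("DefNew", "ProbNew")] <- "new"
  if (any(!is.na(rating) & is.na(out)))
    .stopf("unknown rating values: %s",
           paste(unique(rating[!is.na(rating) & is.na(out)]), collapse = ", "))
  out
}

#' Category with identical key across learner groups
#'
#' The clustered and non-clustered layouts for a given biased dimension agree
#' on two category-key pairs; the canonical first of these serves as the
#' baseline category for the between-group memory-capacity check.
#'
#' @param design An `experiment_design`.
#' @return Character vector of the invariant categories (baseline first).
#' @export
baseline_categories <- function(design) {
  cl <- response_mapping(TRUE, design$biased_dimension, design$dims)$assignment
  nc <- response_mapping(FALSE, design$biased_dimension, design$dims)$assignment
  names(cl)[cl == nc[names(cl)]]
}

#' Per-participant recognition-memory summary
#'
#' Hits are old items rated old after collapsing confidence; false alarms are
#' new items rated old. Per-bin hit rates are computed over responded old
#' items by learning-phase bin; the baseline hit rate is restricted to the
#' category whose key mapping is shared across learner groups.
#'
#' @param records One participant's filtered memory records (see
#'   [filter_memory_responses()]), with `status`, `rating`, `lp_bin`,
#'   `category`.
#' @param baseline_category Category label for the baseline hit rate
#'   (optional).
#' @return Object of class `recognition_summary`: `hit_rate`, `fa_rate`,
#'   `hits_by_bin`, `n_by_bin`, `baseline_hit`, `defined` (`FALSE` when there
#'   are no responded old or no responded new trials), `bin_gate_ok`.
#' @export
recognition_summary <- function(records, baseline_category = NULL) {
  resp <- collapse_ratings(records$rating)
  old <- records$status == "old" & !is.na(resp)
  new <- records$status == "new" & !is.na(resp)
  defined <- sum(old) > 0 && sum(new) > 0
  hit_rate <- if (sum(old)) mean(resp[old] == "old") else NA_real_
  fa_rate <- if (sum(new)) mean(resp[new] == "old") else NA_real_
  hits_by_bin <- rep(NA_real_, 4L)
  n_by_bin <- integer(4L)
  for (b in 1:4) {
    sel <- old & records$lp_bin == b
    n_by_bin[b] <- sum(sel, na.rm = TRUE)
    if (n_by_bin[b]) hits_by_bin[b] <- mean(resp[which(sel)] == "old")
  }
  baseline_hit <- NA_real_
  if (!is.null(baseline_category)) {
    sel <- old & records$category == baseline_category
    if (sum(sel)) baseline_hit <- mean(resp[which(sel)] == "old")
  }
  structure(list(hit_rate = hit_rate, fa_rate = fa_rate,
                 hits_by_bin = hits_by_bin, n_by_bin = n_by_bin,
                 baseline_hit = baseline_hit, defined = defined,
                 bin_gate_ok = bin_occupancy_ok(records$lp_bin[old])),
            class = "recognition_summary")
}

#' @export
print.recognition_summary <- function(x, ...) {
  cat(sprintf("Recognition: hit %.3f, FA %.3f; hits by bin: %s\n",
              x$hit_rate, x$fa_rate,
              paste(sprintf("%.3f", x$hits_by_bin), collapse = ", ")))
  invisible(x)
}

# --- effect sizes ----------------------------------------------------------

#' Effect sizes for a paired comparison
#'
#' Cohen's d_z = t / sqrt(n); common-language effect size CL = Phi(d_z), the
#' probability that a random pair shows a difference in the observed
#' direction.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs.
#' @return List with `d` and `cl`.
#' @export
paired_effect_size <- function(t, n) {
  d <- t / sqrt(n)
  list(d = d, cl = stats::pnorm(d))
}

#' Effect sizes for an independent two-group comparison
#'
#' Cohen's d_s from the pooled SD; CL = Phi(d_s / sqrt(2)).
#'
#' @param x,y Group value vectors.
#' @return List with `d` and `cl`.
#' @export
independent_effect_size <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  d <- (mean(x) - mean(y)) / sp
  list(d = d, cl = stats::pnorm(d / sqrt(2)))
}

#' Paired t-test of hit against false-alarm rates
#'
#' Tests whether incidental encoding is above chance within a group. Constant
#' zero differences give t = 0 (null case); a nonzero constant difference has
#' no defined t and raises an error.
#'
#' @param hit,fa Per-participant hit and false-alarm rates (paired).
#' @return Object of class `effect_test`: `t`, `df`, `p`, `d` (d_z), `cl`,
#'   `mean_diff`, `n`.
#' @export
chance_memory_test <- function(hit, fa) {
  stopifnot(length(hit) == length(fa), length(hit) >= 2)
  d <- hit - fa
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(structure(list(t = 0, df = length(d) - 1L, p = 1, d = 0,
                            cl = 0.5, mean_diff = 0, n = length(d)),
                       class = "effect_test"))
    .stopf("degenerate variance: constant nonzero hit-FA difference has no defined t")
  }
  tt <- stats::t.test(hit, fa, paired = TRUE)
  es <- paired_effect_size(unname(tt$statistic), length(d))
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = es$d, cl = es$cl, mean_diff = mean(d),
                 n = length(d)),
            class = "effect_test")
}

#' Independent-samples t-test with effect sizes
#'
#' Used for the baseline-category and early-bin group comparisons.
#'
#' @param x,y Group value vectors.
#' @return An `effect_test` (d is Cohen's d_s; CL uses the independent form).
#' @export
independent_memory_test <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = TRUE)
  es <- independent_effect_size(x, y)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = es$d, cl = es$cl,
                 mean_diff = mean(x) - mean(y), n = length(x) + length(y)),
            class = "effect_test")
}

#' @export
print.effect_test <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4f, Cohen's d = %.3f, CL = %.1f%% (mean diff %.3f)\n",
              x$df, x$t, x$p, x$d, 100 * x$cl, x$mean_diff))
  invisible(x)
}

# --- repeated-measures ANOVA machinery -------------------------------------

# Fit a multivariate lm and extract the univariate repeated-measures table
# with Greenhouse-Geisser corrections via car::Anova (type III, sum
# contrasts). `within` is a P x K response matrix, `between` a data.frame of
# factors (and optionally centered numeric covariates), `idata`/`idesign`
# describe the within design.
.rm_anova <- function(within, between, idata, idesign) {
  within <- as.matrix(within)
  stopifnot(nrow(within) == nrow(between))
  dat <- cbind(as.data.frame(between), as.data.frame(within))
  resp_cols <- colnames(within)
  fac <- names(between)[vapply(between, is.factor, TRUE)]
  num <- setdiff(names(between), fac)
  for (v in num) dat[[v]] <- dat[[v]] - mean(dat[[v]])  # center covariates
  rhs_terms <- c(if (length(fac)) paste(fac, collapse = "*"), num)
  rhs <- if (length(rhs_terms)) paste(rhs_terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste0(
    "cbind(", paste(resp_cols, collapse = ","), ") ~ ", rhs))
  contr <- stats::setNames(rep(list("contr.sum"), length(fac)), fac)
  mod <- stats::lm(form, data = dat,
                   contrasts = if (length(fac)) contr else NULL)
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  # car warns when the Huynh-Feldt estimate exceeds 1; HF is not reported here
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  uni <- s$univariate.tests
  eff <- rownames(uni)
  out <- data.frame(
    effect = eff,
    df1 = uni[, "num Df"], df2 = uni[, "den Df"],
    ss = uni[, "Sum Sq"], error_ss = uni[, "Error SS"],
    F = uni[, "F value"], p = uni[, "Pr(>F)"],
    pes = uni[, "Sum Sq"] / (uni[, "Sum Sq"] + uni[, "Error SS"]),
    gg_eps = NA_real_, df1_gg = NA_real_, df2_gg = NA_real_, p_gg = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  adj <- s$pval.adjustments
  for (i in seq_len(nrow(out))) {
    e <- out$effect[i]
    if (!is.null(adj) && e %in% rownames(adj) && !is.na(adj[e, "GG eps"])) {
      out$gg_eps[i] <- adj[e, "GG eps"]
    } else if (grepl(.within_names_pattern(idata), e)) {
      out$gg_eps[i] <- 1  # 2-level within factor: sphericity trivially holds
    }
    if (!is.na(out$gg_eps[i])) {
      out$df1_gg[i] <- out$df1[i] * out$gg_eps[i]
      out$df2_gg[i] <- out$df2[i] * out$gg_eps[i]
      out$p_gg[i] <- stats::pf(out$F[i], out$df1_gg[i], out$df2_gg[i],
                               lower.tail = FALSE)
    }
  }
  out <- out[out$effect != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

.within_names_pattern <- function(idata) {
  paste(names(idata), collapse = "|")
}

#' @export
print.rm_anova <- function(x, ...) {
  y <- as.data.frame(x)
  y$F <- round(y$F, 3); y$p <- signif(y$p, 4); y$pes <- round(y$pes, 3)
  y$gg_eps <- round(y$gg_eps, 3); y$p_gg <- signif(y$p_gg, 4)
  print(y[, c("effect", "df1", "df2", "F", "p", "pes", "gg_eps", "p_gg")],
        row.names = FALSE)
  invisible(x)
}

#' Binned hit-rate repeated-measures ANOVA
#'
#' Learning-phase bin (4 levels) as the within-participant factor, learner
#' group between, with optional centered continuous covariates (individual
#' RT/accuracy switch costs). Greenhouse-Geisser correction is reported for
#' the within effects.
#'
#' @param hits_by_bin Numeric matrix, participants x 4 bins.
#' @param group Factor or character of learner-group labels.
#' @param covariates Optional data.frame of numeric covariates (centered
#'   internally).
#' @return An `rm_anova` table (F, df, p, partial eta squared, GG epsilon and
#'   corrected p per effect).
#' @export
binned_hit_anova <- function(hits_by_bin, group, covariates = NULL) {
  hits_by_bin <- as.matrix(hits_by_bin)
  stopifnot(ncol(hits_by_bin) == 4L)
  group <- factor(group)
  if (any(table(group) < 2L))
    .stopf("each learner group needs at least 2 participants")
  colnames(hits_by_bin) <- paste0("bin", 1:4)
  between <- data.frame(group = group)
  if (!is.null(covariates)) between <- cbind(between, covariates)
  idata <- data.frame(bin = factor(1:4))
  .rm_anova(hits_by_bin, between, idata, ~bin)
}

#' Early-bin hit-rate comparison across experiments
#'
#' Pools cohorts whose first 60 learning trials share a design: bin (first vs
#' second 30 trials) within, experiment and learner group between, plus an
#' independent t-test on first-bin hits (non-clustered vs clustered).
#'
#' @param hit_bin1,hit_bin2 Per-participant hit rates for learning-phase bins
#'   1 and 2.
#' @param group Learner-group labels.
#' @param experiment Experiment labels; with a single level the factor is
#'   dropped with a warning.
#' @return List with `anova` (an `rm_anova`) and `bin1_test` (an
#'   `effect_test`, non-clustered minus clustered).
#' @export
early_bins_comparison <- function(hit_bin1, hit_bin2, group, experiment) {
  group <- factor(group)
  experiment <- factor(experiment)
  between <- data.frame(group = group)
  if (nlevels(experiment) > 1L) between$experiment <- experiment
  else warning("single experiment supplied; experiment factor dropped",
               call. = FALSE)
  within <- cbind(bin1 = hit_bin1, bin2 = hit_bin2)
  idata <- data.frame(bin = factor(1:2))
  an <- .rm_anova(within, between, idata, ~bin)
  nc <- hit_bin1[group == "nonclustered"]
  cl <- hit_bin1[group == "clustered"]
  list(anova = an, bin1_test = independent_memory_test(nc, cl))
}

#' Source-memory analysis (Experiment 1)
#'
#' Restricted to old images: per participant, source accuracy for each
#' question type (dimension 1 / dimension 2) split by the collapsed
#' recognition rating (old / new). Tests accuracy against chance (0.5) per
#' rating class within each group, compares rated-old against rated-new
#' accuracy with a paired t-test per group, and runs the trial type x rating
#' x group repeated-measures ANOVA.
#'
#' @param records Filtered memory records with `participant`, `status`,
#'   `rating`, `dim1`, `dim2`, `source_dim1`, `source_dim2`.
#' @param group Named vector or data.frame mapping participant to learner
#'   group, or a vector parallel to unique participants.
#' @return List with `cells` (per-participant 4-cell accuracies), `anova`,
#'   `chance_tests` (one-sample t vs 0.5 per group x rating), and
#'   `old_vs_new` (paired t per group).
#' @export
source_memory_analysis <- function(records, group) {
  if (is.null(records$source_dim1) || all(is.na(records$source_dim1)))
    .stopf("no source-memory responses present (source probes are Experiment 1 only)")
  old <- records[records$status == "old" & !is.na(records$rating) &
                   !is.na(records$source_dim1), , drop = FALSE]
  old$rated <- collapse_ratings(old$rating)
  ids <- sort(unique(old$participant))
  cells <- do.call(rbind, lapply(ids, function(id) {
    r <- old[old$participant == id, ]
    cell <- function(rated) {
      sel <- r$rated == rated
      c(d1 = if (any(sel)) mean(r$source_dim1[sel] == r$dim1[sel]) else NA_real_,
        d2 = if (any(sel)) mean(r$source_dim2[sel] == r$dim2[sel]) else NA_real_)
    }
    co <- cell("old"); cn <- cell("new")
    data.frame(participant = id, acc_d1_old = co["d1"], acc_d2_old = co["d2"],
               acc_d1_new = cn["d1"], acc_d2_new = cn["d2"],
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  grp <- if (is.data.frame(group)) {
    group$group[match(ids, group$participant)]
  } else if (!is.null(names(group))) unname(group[as.character(ids)])
  else group
  cells$group <- factor(grp)
  cc <- cells[stats::complete.cases(cells), , drop = FALSE]
  within <- as.matrix(cc[, c("acc_d1_old", "acc_d2_old", "acc_d1_new",
                             "acc_d2_new")])
  idata <- data.frame(type = factor(c("d1", "d2", "d1", "d2")),
                      rating = factor(c("old", "old", "new", "new")))
  an <- .rm_anova(within, data.frame(group = cc$group), idata, ~type * rating)
  chance_tests <- list()
  old_vs_new <- list()
  for (g in levels(cc$group)) {
    sub <- cc[cc$group == g, ]
    acc_old <- rowMeans(sub[, c("acc_d1_old", "acc_d2_old")])
    acc_new <- rowMeans(sub[, c("acc_d1_new", "acc_d2_new")])
    for (cl in c("old", "new")) {
      a <- if (cl == "old") acc_old else acc_new
      tt <- stats::t.test(a, mu = 0.5)
      es <- paired_effect_size(unname(tt$statistic), length(a))
      chance_tests[[paste(g, cl, sep = ".")]] <-
        structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value, d = es$d, cl = es$cl,
                       mean_diff = mean(a) - 0.5, n = length(a)),
                  class = "effect_test")
    }
    old_vs_new[[g]] <- chance_memory_test(acc_old, acc_new)
  }
  list(cells = cells, anova = an, chance_tests = chance_tests,
       old_vs_new = old_vs_new)
}

#' Post-switch transfer analysis (Experiment 3)
#'
#' Accuracy on post-switch trials by transfer class (positive: category kept
#' its key across the rule switch; negative: it changed) and post-switch time
#' bin (trials 61-90 vs 91-120), analysed with a transfer x bin x group
#' repeated-measures ANOVA.
#'
#' @param cohort An Experiment-3 `cohort`.
#' @return List with `cells` (per-participant accuracies) and `anova`;
#'   participants with an empty cell are dropped (ids in `dropped`).
#' @export
transfer_analysis <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (cohort$experiment != 3L)
    .stopf("transfer analysis applies to Experiment 3 cohorts")
  pt <- cohort$participants
  rows <- list(); dropped <- integer(0)
  for (i in seq_len(nrow(pt))) {
    des <- cohort$designs[[pt$version[i]]]
    tc <- transfer_classes(des)
    sw <- des$rule_switch_at
    tr <- cohort$learning[cohort$learning$participant == pt$participant[i] &
                            cohort$learning$trial > sw, , drop = FALSE]
    tr <- tr[!tr$timeout & !is.na(tr$correct), , drop = FALSE]
    tr$transfer <- unname(tc[tr$category])
    tr$bin <- ifelse(tr$trial <= sw + 30L, 1L, 2L)
    cell <- function(tf, b) {
      sel <- tr$transfer == tf & tr$bin == b
      if (!any(sel)) NA_real_ else mean(tr$correct[sel])
    }
    v <- c(pos1 = cell("positive", 1), pos2 = cell("positive", 2),
           neg1 = cell("negative", 1), neg2 = cell("negative", 2))
    if (anyNA(v)) { dropped <- c(dropped, pt$participant[i]); next }
    rows[[length(rows) + 1L]] <-
      data.frame(participant = pt$participant[i], group = pt$group[i],
                 t(v), stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, rows)
  within <- as.matrix(cells[, c("pos1", "pos2", "neg1", "neg2")])
  idata <- data.frame(transfer = factor(c("pos", "pos", "neg", "neg")),
                      bin = factor(c(1, 2, 1, 2)))
  an <- .rm_anova(within, data.frame(group = factor(cells$group)), idata,
                  ~transfer * bin)
  list(cells = cells, anova = an, dropped = dropped)
}
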