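# Trial- and participant-level filtering, transition classification, and
# learning-phase bin assignment.

#' Classify trial-to-trial transitions under a candidate supraordinate
#' dimension
#'
#' The first trial is labelled `first`; trials where both feature dimensions
#' change are `double_switch_excluded` (they cannot be attributed to either
#' rule); trials where the candidate supraordinate level repeats are
#' `supra_repeat`; trials where it changes while the sub-level repeats are
#' `supra_switch`. Exact category repetitions count as `supra_repeat` by
#' default (the supraordinate rule persists); set `full_repeat = "exclude"`
#' to drop them for sensitivity analyses.
#'
#' @param dim1,dim2 Level labels per trial, in presentation order.
#' @param supra Which dimension is the candidate supraordinate: `1` or `2`.
#' @param full_repeat `"repeat"` (default) or `"exclude"`.
#' @return Character vector of labels, one per trial.
#' @export
classify_transitions <- function(dim1, dim2, supra = 1L,
                                 full_repeat = c("repeat", "exclude")) {
  full_repeat <- match.arg(full_repeat)
  stopifnot(length(dim1) == length(dim2), supra %in% 1:2)
  n <- length(dim1)
  if (n == 0L) return(character(0))
  s <- if (supra == 1L) dim1 else dim2
  u <- if (supra == 1L) dim2 else dim1
  s_rep <- c(NA, s[-1] == s[-n])
  u_rep <- c(NA, u[-1] == u[-n])
  lab <- rep("first", n)
  lab[which(!s_rep & !u_rep)] <- "double_switch_excluded"
  lab[which(s_rep)] <- "supra_repeat"
  lab[which(!s_rep & u_rep)] <- "supra_switch"
  if (full_repeat == "exclude")
    lab[which(s_rep & u_rep)] <- "full_repeat_excluded"
  lab
}

#' Filter learning-phase trials for RT analysis
#'
#' Retains correct, responded trials with 200 <= RT <= 1250 ms, excluding the
#' first trial. Boundary values are retained (the exclusions are strictly
#' below 200 and strictly above the 1250 ms response window).
#'
#' @param trials data.frame with columns `trial`, `correct`, `rt_ms`,
#'   `timeout`.
#' @return The retained rows.
#' @export
filter_learning_rt <- function(trials) {
  keep <- !is.na(trials$correct) & trials$correct & !trials$timeout &
    !is.na(trials$rt_ms) & trials$rt_ms >= 200 & trials$rt_ms <= 1250 &
    trials$trial > 1L
  trials[keep, , drop = FALSE]
}

#' Filter learning-phase trials for accuracy analysis
#'
#' Accuracy analyses keep error trials (correctness is the outcome) but drop
#' timeouts (no registered response) and the first trial.
#'
#' @inheritParams filter_learning_rt
#' @return The retained rows.
#' @export
filter_learning_accuracy <- function(trials) {
  keep <- !trials$timeout & !is.na(trials$correct) & trials$trial > 1L
  trials[keep, , drop = FALSE]
}

#' Filter memory-phase trials
#'
#' Retains trials with a registered response that was not excessively fast
#' (RT >= 200 ms; the exclusion is strictly below 200, so 200 is kept).
#'
#' @param records data.frame with columns `rating` (NA = no response) and
#'   `rt_ms`.
#' @return The retained rows.
#' @export
filter_memory_responses <- function(records) {
  keep <- !is.na(records$rating) & !is.na(records$rt_ms) & records$rt_ms >= 200
  records[keep, , drop = FALSE]
}

#' Participant-level inclusion gate
#'
#' Excludes participants with learning-phase accuracy below 65% (65.0% is
#' included: the criterion is a strict inequality), a failed post-test of the
#' category-response associations, or — where the age policy applies — age
#' above 60. Also reports bonus eligibility (accuracy above 90%).
#'
#' @param accuracy Learning-phase proportion correct in `[0, 1]`.
#' @param post_test_pass Logical, post-test passed.
#' @param age Age in years or `NA`.
#' @param max_age Age cutoff (default `Inf`; 60 for the Experiment-2 policy).
#' @return List with `include` (logical), `reason` (`NA` when included) and
#'   `bonus` (logical).
#' @export
participant_gate <- function(accuracy, post_test_pass = TRUE, age = NA,
                             max_age = Inf) {
  stopifnot(is.numeric(accuracy), accuracy >= 0, accuracy <= 1)
  reason <- NA_character_
  if (!is.na(age) && age > max_age) reason <- "age"
  if (!isTRUE(post_test_pass)) reason <- "post_test"
  if (accuracy < 0.65) reason <- "accuracy"
  list(include = is.na(reason), reason = reason, bonus = accuracy > 0.90)
}

#' Learning-phase bin sizes
#'
#' 128 learning trials are split into three bins of 30 and a fourth of 38;
#' 120 trials into four bins of 30. Any other trial count is an error (no
#' silent rebinning).
#'
#' @param n_learning_trials 120 or 128.
#' @return Integer vector of 4 bin sizes summing to `n_learning_trials`.
#' @export
assign_bins <- function(n_learning_trials) {
  if (n_learning_trials == 128L) c(30L, 30L, 30L, 38L)
  else if (n_learning_trials == 120L) rep(30L, 4L)
  else .stopf("unsupported learning-phase length %s (expected 120 or 128)",
              n_learning_trials)
}

#' Bin of origin for a learning-phase trial index
#'
#' @param trial Trial indices (1-based).
#' @param n_learning_trials 120 or 128.
#' @return Integer bin 1-4 per trial.
#' @export
lp_bin_of_trial <- function(trial, n_learning_trials) {
  sizes <- assign_bins(n_learning_trials)
  findInterval(trial, cumsum(c(1L, sizes)), rightmost.closed = FALSE)
}

#' Bin-occupancy gate for memory ANOVAs
#'
#' Participants with fewer than `min_per_bin` responded old trials in any
#' learning-phase bin are excluded from binned analyses.
#'
#' @param lp_bin Bin indices of a participant's responded old memory trials.
#' @param min_per_bin Minimum responded trials per bin (default 10).
#' @return Logical: passes the gate?
#' @export
bin_occupancy_ok <- function(lp_bin, min_per_bin = 10L) {
  counts <- tabulate(lp_bin[!is.na(lp_bin)], nbins = 4L)
  all(counts >= min_per_bin)
}
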