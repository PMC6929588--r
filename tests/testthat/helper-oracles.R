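# Independent oracles used by the tests. These deliberately re-derive the
# statistics from their definitions (plain formulas, full enumeration, aov)
# rather than calling the package's computational path.

# Absolute SD-normalized switch cost from its definition.
oracle_abs_z <- function(x, is_switch) {
  mu_s <- mean(x[is_switch]); mu_n <- mean(x[!is_switch])
  v_s <- var(x[is_switch]); v_n <- var(x[!is_switch])
  den <- sqrt(0.5 * (v_s + v_n))
  if (den == 0) return(0)
  abs(mu_s - mu_n) / den
}

# Exact permutation null of the absolute normalized cost by full enumeration
# of all label assignments (condition counts fixed). Feasible for <= ~10
# trials.
oracle_exact_null <- function(x, n_switch) {
  combos <- combn(length(x), n_switch)
  apply(combos, 2, function(idx) {
    is_s <- seq_along(x) %in% idx
    oracle_abs_z(x, is_s)
  })
}

# Reference repeated-measures ANOVA via aov with an Error stratum, on a
# balanced table in long format. Returns named F statistics.
oracle_aov_f <- function(wide, group) {
  long <- data.frame(
    y = as.vector(t(wide)),
    bin = factor(rep(seq_len(ncol(wide)), nrow(wide))),
    group = factor(rep(group, each = ncol(wide))),
    id = factor(rep(seq_len(nrow(wide)), each = ncol(wide)))
  )
  fit <- summary(aov(y ~ group * bin + Error(id / bin), data = long))
  between <- fit[["Error: id"]][[1]]
  within <- fit[["Error: id:bin"]][[1]]
  c(group = between["group", "F value"],
    bin = within["bin", "F value"],
    `group:bin` = within["group:bin", "F value"])
}

# A tiny simulated participant data frame with hand-controlled RT structure.
make_trials <- function(dim1, dim2, rt, correct = TRUE, timeout = FALSE) {
  n <- length(dim1)
  data.frame(trial = seq_len(n), category = paste(dim1, dim2, sep = "."),
             dim1 = dim1, dim2 = dim2, image_id = seq_len(n),
             correct_key = 1L, response_key = 1L,
             correct = rep_len(correct, n), rt_ms = rep_len(rt, n),
             timeout = rep_len(timeout, n), stringsAsFactors = FALSE)
}
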