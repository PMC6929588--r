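# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a key
#'
#' Deterministic seed streams let per-participant simulations and permutation
#' runs be reproduced individually while everything hangs off one master seed.
#' The result is always a positive integer below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param key Character or integer key identifying the stream (e.g. a
#'   participant id or stage name).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, key) {
  chars <- utf8ToInt(as.character(key))
  m <- 2147483647
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% m
  s <- (as.numeric(master) %% m)
  out <- (s * 48271 + h + 1) %% m
  as.integer(if (out == 0) 1 else out)
}

# mean/sd that return NA rather than warnings on empty input
.safe_mean <- function(x) if (length(x)) mean(x) else NA_real_
.safe_sd <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_

.is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
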