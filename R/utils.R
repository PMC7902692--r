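# Small internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-stream seed from a global seed
#'
#' Independent analysis layers (covariates, noise, censoring, subsampling,
#' bootstrap) each get their own seed derived deterministically from one
#' global integer seed, so any layer can be reproduced in isolation.
#'
#' @param seed integer global seed.
#' @param k integer stream index (>= 0).
#' @return an integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  m <- 2147483647
  s <- (abs(seed) %% m) * 48271 %% m
  as.integer((s + k * 1000003) %% (m - 1) + 1)
}

# canonical key for an unordered label pair (lexicographic, locale-free)
edge_key <- function(from, to) {
  swap <- to < from
  a <- ifelse(swap, to, from)
  b <- ifelse(swap, from, to)
  paste(a, b, sep = "\r")
}

#' Mean of a normal distribution truncated from above
#'
#' `E[X | X < upper]` for `X ~ Normal(mu, sigma^2)` — the conditional
#' expectation imputed for below-LOD values. Evaluated on the log scale so
#' that means far above the truncation point stay finite.
#'
#' @param mu,sigma normal mean and standard deviation (vectorized over
#'   `mu` and `upper`).
#' @param upper truncation point.
#' @return the truncated mean, always strictly below `upper`.
#' @export
truncated_normal_mean <- function(mu, sigma, upper) {
  alpha <- (upper - mu) / sigma
  ratio <- exp(stats::dnorm(alpha, log = TRUE) - stats::pnorm(alpha, log.p = TRUE))
  mu - sigma * ratio
}

truncnorm_upper_mean <- truncated_normal_mean

is_binary <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2L && all(u %in% c(0, 1))
}
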