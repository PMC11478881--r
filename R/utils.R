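# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

## configuration error naming the offending field
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## truncated normal via inverse-CDF; exact under a fixed RNG stream
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## most frequent level; ties broken by factor-level order (stable)
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  tab <- table(x)
  names(tab)[which.max(tab)]
}

## E[round(clip(X, 0, k))] for X ~ N(mu, sd): exact bin-probability sum,
## used for analytic ground-truth means of bounded integer scores
expected_rounded_normal <- function(mu, sd, k_max) {
  ks <- 0:k_max
  lo <- c(-Inf, ks[-1] - 0.5)
  hi <- c(ks[-(k_max + 1)] + 0.5, Inf)
  p <- stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd)
  sum(ks * p)
}

## sample one categorical level per row from a matrix of row-wise probabilities
sample_categorical <- function(prob, levels) {
  prob <- prob / rowSums(prob)
  u <- stats::runif(nrow(prob))
  cum <- t(apply(prob, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  levels[pmin(idx, length(levels))]
}

## two-sided bootstrap p-value for a null of zero, with add-one smoothing
boot_p_value <- function(draws) {
  draws <- draws[is.finite(draws)]
  b <- length(draws)
  if (!b) return(NA_real_)
  p_lo <- (sum(draws <= 0) + 1) / (b + 1)
  p_hi <- (sum(draws >= 0) + 1) / (b + 1)
  min(1, 2 * min(p_lo, p_hi))
}

percentile_ci <- function(draws, level = 0.95) {
  draws <- draws[is.finite(draws)]
  a <- (1 - level) / 2
  unname(stats::quantile(draws, c(a, 1 - a), names = FALSE))
}
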