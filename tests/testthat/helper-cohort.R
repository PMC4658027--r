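# shared fixtures and small independent oracles, built in code at test time

quiet_cohort <- function(...) {
  suppressWarnings(generate_cohort(...))
}

small_spec <- function(n = 60, ...) {
  cohort_spec(n_heifers = ceiling(n / 2), n_steers = floor(n / 2), ...)
}

# closed-form mean and sd of a Normal(mean, sd) truncated to [lo, hi]
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                 ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# exhaustive best-subset search by BIC: the independent oracle for stepwise
best_subset_bic <- function(data, response, candidates) {
  best <- NULL
  best_bic <- Inf
  for (k in 0:length(candidates)) {
    combs <- utils::combn(candidates, k, simplify = FALSE)
    for (s in combs) {
      rhs <- if (length(s)) paste(s, collapse = " + ") else "1"
      fit <- lm(stats::as.formula(paste(response, "~", rhs)), data = data)
      b <- stats::BIC(fit)
      if (b < best_bic) {
        best_bic <- b
        best <- s
      }
    }
  }
  sort(best)
}
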