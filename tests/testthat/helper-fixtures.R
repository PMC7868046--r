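# Small fixtures and independent oracles, built in code.

# closed-form OLS via the normal equations (independent of lm.fit)
ols_oracle <- function(x, y) {
  d <- cbind(1, x)
  as.numeric(solve(crossprod(d), crossprod(d, y)))
}

# two-pattern bivariate fixture: X1 missing in the second half, outcome with a
# pattern-specific intercept/slope shift (delta1 = delta3 = 1)
two_pattern_data <- function(n = 20, seed = 1, delta = c(1, 1), noise_sd = 1) {
  set.seed(seed)
  x2 <- rnorm(n, 3)
  x1 <- 3 + 0.5 * (x2 - 3) + rnorm(n, sd = 0.8)
  m1 <- rep(c(0L, 1L), each = n / 2)
  y <- 1 + 3 * x1 + x2 + m1 * (delta[1] + delta[2] * x1) +
    rnorm(n, sd = noise_sd)
  list(data = ps_data(y, cbind(X1 = ifelse(m1 == 1, NA, x1), X2 = x2)),
       truth = cbind(X1 = x1, X2 = x2), m1 = m1)
}

headline_pspec <- function(n = 1000) {
  predictor_spec(n, mu = c(3, 3), sigma = matrix(c(1, .5, .5, 1), 2))
}
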