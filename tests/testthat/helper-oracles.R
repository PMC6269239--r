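# Independent brute-force oracles and fixture generators used across the
# test files. The oracle solves weighted least squares via the explicit
# normal equations, a different route from the package's QR/weighted-mean
# implementations.

# WLS through the normal equations: b = (X'WX)^{-1} X'W y.
wls_oracle <- function(X, y, w) {
  X <- as.matrix(X)
  XtW <- t(X * w)
  b <- solve(XtW %*% X, XtW %*% y)
  res <- y - X %*% b
  list(coef = as.vector(b), wrss = sum(w * res^2))
}

# IVW via the oracle: no-intercept WLS of beta_out on beta_exp with
# weights 1/se_out^2 (the association-scale formulation).
ivw_oracle <- function(d) {
  wls_oracle(matrix(d$beta_exp, ncol = 1), d$beta_out, 1 / d$se_out^2)
}

# Egger via the oracle, applying the same positive-alpha orientation the
# method defines.
egger_oracle <- function(d) {
  flip <- d$beta_exp < 0
  a <- ifelse(flip, -d$beta_exp, d$beta_exp)
  y <- ifelse(flip, -d$beta_out, d$beta_out)
  wls_oracle(cbind(1, a), y, 1 / d$se_out^2)
}

# Random valid summary dataset; exposure associations bounded away from
# zero, random signs.
random_dataset <- function(m) {
  mr_summary(paste0("rs", seq_len(m)),
             beta_exp = sample(c(-1, 1), m, replace = TRUE) *
               runif(m, 0.1, 1),
             beta_out = rnorm(m, 0, 0.5),
             se_out = runif(m, 0.05, 0.5))
}
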