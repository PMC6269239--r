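test_that("Wald ratios and inverse-variance weights follow their definitions", {
  d <- suppressWarnings(mr_summary(
    c("a", "b", "c"),
    beta_exp = c(0.1, -0.1, 1),
    beta_out = c(0.2, 0.2, 0.7),
    se_out = c(0.05, 0.05, 1)))
  r <- ratio_estimates(d)
  expect_equal(r$beta_ratio, c(2, -2, 0.7))
  expect_equal(r$weight, c(4, 4, 1))
})

test_that("IVW is the weighted mean of the ratio estimates", {
  # equal weights: plain average
  d <- mr_summary(c("a", "b"), beta_exp = c(1, 1), beta_out = c(1, 3),
                  se_out = c(1, 1))
  fit <- mr_ivw(d)
  expect_equal(fit$beta, 2)
  expect_equal(fit$se, 1 / sqrt(2))
  # weights 1 and 3 on ratios 0 and 4 -> 3
  d2 <- mr_summary(c("a", "b"), beta_exp = c(1, sqrt(3)),
                   beta_out = c(0, 4 * sqrt(3)), se_out = c(1, 1))
  expect_equal(mr_ivw(d2)$beta, 3)
  # single element degenerates to the ratio itself
  core <- pleioq:::ivw_core(0.1, 0.2, 0.05)
  expect_equal(core$beta, 2)
  expect_null(core$q)
})

test_that("weighted residuals about the IVW estimate sum to zero", {
  set.seed(21)
  for (i in 1:20) {
    d <- random_dataset(sample(3:12, 1))
    r <- ratio_estimates(d)
    fit <- mr_ivw(d)
    expect_equal(sum(r$weight * (r$beta_ratio - fit$beta)), 0,
                 tolerance = 1e-10)
  }
})

test_that("Egger regression interpolates exact linear data", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  d <- mr_summary(paste0("rs", 1:4), beta_exp = a,
                  beta_out = 0.1 + 0.5 * a, se_out = rep(0.05, 4))
  fit <- mr_egger(d)
  expect_equal(fit$intercept, 0.1)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$q_prime, 0, tolerance = 1e-20)
  expect_false(fit$orientation_applied)
})

test_that("Egger coefficients match the normal-equations oracle on generic points", {
  set.seed(22)
  for (i in 1:20) {
    d <- random_dataset(3)
    fit <- mr_egger(d)
    or <- egger_oracle(d)
    expect_equal(fit$intercept, or$coef[1], tolerance = 1e-10)
    expect_equal(fit$slope, or$coef[2], tolerance = 1e-10)
    expect_equal(fit$q_prime, or$wrss, tolerance = 1e-10)
  }
})

test_that("Egger rejects too few instruments and constant instrument strength", {
  d <- mr_summary(c("a", "b"), beta_exp = c(0.1, 0.2),
                  beta_out = c(0.1, 0.1), se_out = c(0.1, 0.1))
  expect_error(mr_egger(d), "at least 3")
  dc <- mr_summary(c("a", "b", "c"), beta_exp = rep(0.3, 3),
                   beta_out = c(0.1, 0.2, 0.3), se_out = rep(0.1, 3))
  expect_error(mr_egger(dc), "singular")
})

test_that("jointly flipping a variant's effect-allele signs changes nothing", {
  set.seed(23)
  for (i in 1:10) {
    d <- random_dataset(8)
    flip <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    d2 <- mr_summary(d$snp,
                     beta_exp = ifelse(flip, -d$beta_exp, d$beta_exp),
                     beta_out = ifelse(flip, -d$beta_out, d$beta_out),
                     se_out = d$se_out)
    r1 <- ratio_estimates(d); r2 <- ratio_estimates(d2)
    expect_equal(r2$beta_ratio, r1$beta_ratio)
    expect_equal(r2$weight, r1$weight)
    f1 <- mr_ivw(d); f2 <- mr_ivw(d2)
    expect_equal(f2$beta, f1$beta)
    expect_equal(f2$q, f1$q)
    e1 <- mr_egger(d); e2 <- mr_egger(d2)
    expect_equal(e2$intercept, e1$intercept)
    expect_equal(e2$slope, e1$slope)
    expect_equal(e2$q_prime, e1$q_prime)
  }
})

test_that("random-effects scaling inflates Egger SEs only under overdispersion", {
  set.seed(24)
  d <- random_dataset(10)
  fe <- mr_egger(d, random_effects = FALSE)
  re <- mr_egger(d, random_effects = TRUE)
  expect_equal(re$overdispersion,
               max(1, sqrt(fe$q_prime / fe$q_prime_df)))
  expect_gte(re$slope_se, fe$slope_se)
  expect_equal(re$slope, fe$slope)
})

test_that("2SLS recovers a deterministic causal chain and rejects collinear instruments", {
  G <- matrix(rep(c(0, 1), each = 10), ncol = 1)
  x <- as.vector(G)
  y <- 2 * x
  fit <- two_stage_least_squares(G, x, y)
  expect_equal(fit$estimate, 2)
  Gdup <- cbind(G, G)
  expect_error(two_stage_least_squares(Gdup, x, y), "singular")
})

test_that("summary-data IVW agrees with 2SLS on the same individual-level sample", {
  cfg <- sim_config(pleiotropy_mode = "none", beta1 = 0.3)
  sim <- simulate_individual_data(cfg, n = 5000, seed = 25)
  c1 <- sim$cohort1
  tsls <- two_stage_least_squares(c1$G, c1$exposure, c1$outcome)
  within <- summary_from_individual(c1$G, c1$exposure, c1$outcome)
  ivw <- mr_ivw(within)
  expect_lt(abs(ivw$beta - tsls$estimate),
            2 * sqrt(ivw$se^2 + tsls$se^2))
})

test_that("marginal-regression summaries match per-SNP lm fits", {
  set.seed(26)
  n <- 200
  G <- matrix(rbinom(n * 3, 2, 0.3), ncol = 3)
  x <- rnorm(n); y <- rnorm(n)
  s <- summary_from_individual(G, x, y)
  for (j in 1:3) {
    ref <- summary(lm(y ~ G[, j]))$coefficients
    expect_equal(s$beta_out[j], ref[2, 1], tolerance = 1e-10)
    expect_equal(s$se_out[j], ref[2, 2], tolerance = 1e-10)
  }
})
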