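test_that("Cochran's Q matches the hand-computed definition", {
  # equal unit weights, ratios 1 and 3: IVW = 2, Q = 1 + 1 = 2
  d <- mr_summary(c("a", "b"), beta_exp = c(1, 1), beta_out = c(1, 3),
                  se_out = c(1, 1))
  q <- cochran_q(d)
  expect_equal(q$q, 2)
  expect_equal(unname(q$contributions), c(1, 1))
  expect_equal(q$df, 1)
  expect_equal(q$pvalue, pchisq(2, 1, lower.tail = FALSE))
})

test_that("perfectly proportional associations give zero heterogeneity", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  d <- mr_summary(paste0("rs", 1:4), beta_exp = a, beta_out = 0.5 * a,
                  se_out = rep(0.1, 4))
  q <- cochran_q(d)
  expect_equal(q$q, 0, tolerance = 1e-25)
  expect_equal(q$pvalue, 1)
})

test_that("a common intercept leaves Q positive but Q' at zero", {
  a <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  d <- mr_summary(paste0("rs", 1:5), beta_exp = a,
                  beta_out = 0.1 + 0.5 * a, se_out = rep(0.05, 5))
  q <- cochran_q(d)
  qp <- rucker_q(d)
  expect_gt(q$q, 0)
  expect_equal(qp$q_prime, 0, tolerance = 1e-18)
  expect_equal(qp$df, 3)
})

test_that("decomposition sums and the nesting inequality hold on random data", {
  set.seed(31)
  for (i in 1:50) {
    d <- random_dataset(sample(3:15, 1))
    q <- cochran_q(d)
    eg <- mr_egger(d)
    qp <- rucker_q(d, eg)
    expect_equal(sum(q$contributions), q$q,
                 tolerance = 1e-10 * max(1, q$q))
    expect_equal(sum(qp$contributions), qp$q_prime,
                 tolerance = 1e-10 * max(1, qp$q_prime))
    expect_lte(qp$q_prime, q$q * (1 + 1e-12))
    # Q' equals the weighted RSS from the independent oracle
    expect_equal(qp$q_prime, egger_oracle(d)$wrss, tolerance = 1e-10)
  }
})

test_that("rucker_q refuses a fit of a different dataset", {
  set.seed(32)
  d1 <- random_dataset(5)
  d2 <- random_dataset(6)
  expect_error(rucker_q(d1, mr_egger(d2)), "does not match")
})

test_that("outlier thresholds are the chi-squared(1) quantiles at 1-fwer and 1-fwer/m", {
  th <- pleiotropy_thresholds(25, 0.05)
  expect_equal(th$percentiles, c(uncorrected = 95, bonferroni = 99.8))
  expect_equal(th$uncorrected, qchisq(0.95, 1))
  expect_equal(th$bonferroni, qchisq(0.998, 1))
  th10 <- pleiotropy_thresholds(10, 0.1)
  expect_equal(th10$bonferroni, qchisq(1 - 0.01, 1))
})

test_that("per-SNP flagging separates the uncorrected and Bonferroni thresholds", {
  # all-zero contributions: nothing flagged
  z <- setNames(rep(0, 25), paste0("rs", 1:25))
  fz <- individual_pleiotropy_test(z, fwer = 0.05)
  expect_false(any(fz$flag_uncorrected))
  expect_length(attr(fz, "outliers"), 0)
  # a contribution at the 99.7th percentile: uncorrected yes, Bonferroni no
  x <- z
  x["rs07"] <- qchisq(0.997, 1)
  fx <- individual_pleiotropy_test(x, fwer = 0.05)
  expect_true(fx$flag_uncorrected[fx$snp == "rs07"])
  expect_false(fx$flag_bonferroni[fx$snp == "rs07"])
  # one clearly beyond both
  x["rs08"] <- qchisq(1 - 1e-6, 1)
  fx2 <- individual_pleiotropy_test(x, fwer = 0.05)
  expect_identical(attr(fx2, "outliers"), "rs08")
})

test_that("every Bonferroni flag is also an uncorrected flag", {
  set.seed(33)
  for (i in 1:20) {
    contrib <- rchisq(25, 1) * runif(1, 0.5, 4)
    f <- individual_pleiotropy_test(contrib, fwer = 0.05)
    expect_true(all(!f$flag_bonferroni | f$flag_uncorrected))
  }
})

test_that("the model hint flags Egger as the better fit only when Q outliers vanish under Q'", {
  # data on a line with a substantial intercept: Qj huge, Q'j = 0
  a <- seq(0.1, 0.5, length.out = 6)
  d <- mr_summary(paste0("rs", 1:6), beta_exp = a,
                  beta_out = 0.1 + 0.05 * a, se_out = rep(0.01, 6))
  q <- cochran_q(d)
  qp <- rucker_q(d)
  hint <- model_hint(q, qp, fwer = 0.05)
  expect_identical(hint$hint, "egger-better")
  expect_equal(hint$q_minus_q_prime, q$q - qp$q_prime)
  # proportional data: Q = Q' = 0, neutral
  d0 <- mr_summary(paste0("rs", 1:4), beta_exp = a[1:4],
                   beta_out = 0.5 * a[1:4], se_out = rep(0.05, 4))
  h0 <- model_hint(cochran_q(d0), rucker_q(d0))
  expect_identical(h0$hint, "neutral")
  expect_equal(h0$q_minus_q_prime, 0, tolerance = 1e-12)
})

test_that("the full report is internally consistent", {
  set.seed(34)
  sim <- simulate_summary_data(sim_config(pleiotropy_mode = "directional"))
  rep <- pleiotropy_report(sim$data)
  expect_s3_class(rep, "pleiotropy_report")
  expect_equal(sum(rep$snp_table$q_contrib), rep$ivw$q, tolerance = 1e-10)
  expect_equal(sum(rep$snp_table$q_prime_contrib), rep$egger$q_prime,
               tolerance = 1e-10)
  expect_setequal(rep$outlier_ids,
                  rep$snp_table$snp[rep$snp_table$flag_bonf])
  expect_true(all(!rep$snp_table$flag_bonf | rep$snp_table$flag_95))
  # serialization round trip
  jpath <- withr::local_tempfile(fileext = ".json")
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_report_json(rep, jpath)
  write_report_table(rep, tpath)
  parsed <- jsonlite::read_json(jpath)
  expect_equal(parsed$ivw$estimate, rep$ivw$beta)
  expect_equal(parsed$egger$q, rep$egger$q_prime)
  tab <- read.delim(tpath)
  expect_equal(nrow(tab), 25)
})

test_that("outlier removal is a fixed point without outliers and recovers a planted outlier", {
  # clean null dataset: nothing removed, identical fit
  sim <- simulate_summary_data(sim_config(pleiotropy_mode = "none"),
                               seed = 35)
  res <- remove_outliers_and_refit(sim$data)
  expect_length(res$removed, 0)
  expect_equal(res$ivw$beta, mr_ivw(sim$data)$beta)
  expect_equal(nrow(res$data), 25)

  # plant a single huge pleiotropic effect
  d <- sim$data
  d$beta_out[7] <- d$beta_out[7] + 1.5
  planted <- mr_summary(d$snp, d$beta_exp, d$beta_out, d$se_out)
  before <- mr_ivw(planted)
  res2 <- remove_outliers_and_refit(planted)
  expect_true("snp07" %in% res2$removed)
  expect_lt(abs(res2$ivw$beta - sim$truth$beta1),
            abs(before$beta - sim$truth$beta1))
})

test_that("removal refuses to reduce the dataset below two variants", {
  # mutually inconsistent precise variants: all flagged as outliers
  d <- mr_summary(c("a", "b", "c"), beta_exp = c(1, 1.5, 2),
                  beta_out = c(0, 2, -2), se_out = rep(0.01, 3))
  expect_error(remove_outliers_and_refit(d), "fewer than 2")
})

test_that("iterative removal warns about repeated testing", {
  sim <- simulate_summary_data(sim_config(pleiotropy_mode = "none"),
                               seed = 36)
  expect_warning(remove_outliers_and_refit(sim$data, policy = "iterate"),
                 "familywise")
})

test_that("all statistics are invariant to variant ordering", {
  set.seed(37)
  d <- random_dataset(12)
  perm <- sample(12)
  dp <- mr_summary(d$snp[perm], d$beta_exp[perm], d$beta_out[perm],
                   d$se_out[perm])
  expect_equal(mr_ivw(dp)$beta, mr_ivw(d)$beta)
  expect_equal(cochran_q(dp)$q, cochran_q(d)$q)
  expect_equal(sort(cochran_q(dp)$contributions),
               sort(cochran_q(d)$contributions))
  expect_equal(mr_egger(dp)$slope, mr_egger(d)$slope)
  expect_equal(rucker_q(dp)$q_prime, rucker_q(d)$q_prime)
})
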