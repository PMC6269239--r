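# Causal-effect estimators: per-SNP Wald ratios, IVW pooling, MR-Egger
# weighted regression, and a 2SLS estimator used as an individual-level
# reference point.

#' Per-SNP Wald ratio estimates and inverse-variance weights
#'
#' For each variant the causal effect is estimated by the Wald ratio
#' \eqn{\hat\beta_j = \hat\beta_{YGj} / \alpha_j}. Under the NOME
#' assumption its variance is \eqn{\sigma_{Yj}^2/\alpha_j^2}, whose
#' reciprocal \eqn{w_j = \alpha_j^2/\sigma_{Yj}^2} is the weight used by
#' the IVW estimate and by Cochran's Q.
#'
#' @param data an `mr_summary` dataset (all `beta_exp != 0`).
#' @return Data frame with columns `snp`, `beta_ratio`, `weight`.
#' @export
ratio_estimates <- function(data) {
  stopifnot(inherits(data, "mr_summary"))
  data.frame(snp = data$snp,
             beta_ratio = data$beta_out / data$beta_exp,
             weight = data$beta_exp^2 / data$se_out^2,
             stringsAsFactors = FALSE)
}

# Core IVW + Q computation on bare vectors; shared by the public
# estimators and the Monte-Carlo drivers.
ivw_core <- function(beta_exp, beta_out, se_out) {
  w <- beta_exp^2 / se_out^2
  br <- beta_out / beta_exp
  sw <- sum(w)
  beta <- sum(w * br) / sw
  m <- length(w)
  out <- list(beta = beta, se = 1 / sqrt(sw), m = m)
  if (m >= 2) {
    qc <- w * (br - beta)^2
    out$q <- sum(qc)
    out$q_contributions <- qc
    out$q_df <- m - 1
    out$q_pvalue <- stats::pchisq(out$q, df = m - 1, lower.tail = FALSE)
  }
  out
}

# Core MR-Egger fit on bare vectors. Orients variants to positive
# exposure association, fits WLS of beta_out on beta_exp with weights
# 1/se_out^2 by QR (lm.wfit), and computes Rucker's Q' as the weighted
# residual sum of squares.
egger_core <- function(beta_exp, beta_out, se_out,
                       random_effects = FALSE, t_dist = FALSE) {
  m <- length(beta_exp)
  if (m < 3) {
    stop("MR-Egger regression requires at least 3 variants", call. = FALSE)
  }
  flip <- beta_exp < 0
  a <- ifelse(flip, -beta_exp, beta_exp)
  y <- ifelse(flip, -beta_out, beta_out)
  if (max(a) - min(a) < .Machine$double.eps^0.5 * max(a)) {
    stop("singular design: no variability in instrument strengths",
         call. = FALSE)
  }
  w <- 1 / se_out^2
  X <- cbind(`(Intercept)` = 1, beta_exp = a)
  fit <- stats::lm.wfit(X, y, w)
  co <- fit$coefficients
  res <- y - X %*% co
  q_prime_contributions <- as.vector(w * res^2)
  q_prime <- sum(q_prime_contributions)
  df <- m - 2
  # known-variance WLS covariance; no residual rescaling under the
  # fixed-effect model
  V <- chol2inv(chol(crossprod(X * sqrt(w))))
  ses <- sqrt(diag(V))
  scale <- 1
  if (random_effects) {
    scale <- max(1, sqrt(q_prime / df))
    ses <- ses * scale
  }
  z <- co / ses
  pvals <- if (t_dist) {
    2 * stats::pt(abs(z), df = df, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  list(intercept = unname(co[1]), slope = unname(co[2]),
       intercept_se = ses[1], slope_se = ses[2],
       intercept_pvalue = unname(pvals[1]),
       slope_pvalue = unname(pvals[2]),
       q_prime = q_prime,
       q_prime_contributions = q_prime_contributions,
       q_prime_df = df,
       q_prime_pvalue = stats::pchisq(q_prime, df = df,
                                      lower.tail = FALSE),
       overdispersion = scale,
       orientation_applied = any(flip),
       m = m)
}

#' Inverse-variance-weighted causal estimate with Cochran's Q
#'
#' Pools the per-SNP Wald ratios by their inverse-variance weights,
#' \eqn{\hat\beta_{IVW} = \sum_j w_j \hat\beta_j / \sum_j w_j}, with
#' fixed-effect standard error \eqn{1/\sqrt{\sum_j w_j}}. With two or more
#' variants the global heterogeneity statistic
#' \eqn{Q = \sum_j w_j(\hat\beta_j - \hat\beta_{IVW})^2} and its per-SNP
#' contributions are attached; under the null of no horizontal pleiotropy
#' Q follows a chi-squared distribution with m-1 degrees of freedom.
#'
#' @param data an `mr_summary` dataset with at least one variant.
#' @param level two-sided confidence level for the reported interval.
#' @return An object of class `mr_ivw`: a list with elements `beta`, `se`,
#'   `ci_low`, `ci_high`, and (for m >= 2) `q`, `q_df`, `q_pvalue`,
#'   `q_contributions` (named by variant).
#' @examples
#' sim <- simulate_summary_data(sim_config(pleiotropy_mode = "none"),
#'                              seed = 1)
#' mr_ivw(sim$data)
#' @export
mr_ivw <- function(data, level = 0.95) {
  stopifnot(inherits(data, "mr_summary"))
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  core <- ivw_core(data$beta_exp, data$beta_out, data$se_out)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  core$ci_low <- core$beta - zq * core$se
  core$ci_high <- core$beta + zq * core$se
  core$level <- level
  core$snp <- data$snp
  if (!is.null(core$q_contributions)) {
    names(core$q_contributions) <- data$snp
  }
  structure(core, class = "mr_ivw")
}

#' MR-Egger regression with Rucker's Q'
#'
#' Fits the weighted regression \eqn{E[\hat\beta_{YGj}] = \beta_{0E} +
#' \beta_{1E}\alpha_j} with weights \eqn{\sigma_{Yj}^{-2}}, after orienting
#' every variant so its exposure association is positive (the intercept is
#' not identified under arbitrary allele recoding). The intercept estimates
#' the mean pleiotropic effect; the slope is the pleiotropy-adjusted causal
#' estimate under the InSIDE assumption. Residual heterogeneity after the
#' adjustment is summarized by Rucker's
#' \eqn{Q' = \sum_j (\hat\beta_{YGj} - \beta_{0E} - \beta_{1E}\alpha_j)^2 /
#' \sigma_{Yj}^2}, chi-squared with m-2 df under the equal-direct-effect
#' null, with per-SNP contributions \eqn{Q'_j}.
#'
#' Standard errors are the known-variance WLS ones by default
#' (fixed-effect); `random_effects = TRUE` inflates them by
#' \eqn{\max(1, \sqrt{Q'/(m-2)})}. Intercept/slope p-values use a
#' two-sided z-test, or a t(m-2) reference with `t_dist = TRUE`.
#'
#' @param data an `mr_summary` dataset with at least 3 variants.
#' @param random_effects logical; multiplicative overdispersion scaling of
#'   the standard errors.
#' @param t_dist logical; use a t(m-2) instead of a normal reference.
#' @param level confidence level for the slope interval.
#' @return An object of class `mr_egger`: intercept and slope with standard
#'   errors and p-values, `q_prime`, `q_prime_df`, `q_prime_pvalue`,
#'   per-SNP `q_prime_contributions`, and `orientation_applied`.
#' @examples
#' sim <- simulate_summary_data(sim_config(pleiotropy_mode = "directional"),
#'                              seed = 1)
#' mr_egger(sim$data)
#' @export
mr_egger <- function(data, random_effects = FALSE, t_dist = FALSE,
                     level = 0.95) {
  stopifnot(inherits(data, "mr_summary"))
  core <- egger_core(data$beta_exp, data$beta_out, data$se_out,
                     random_effects = random_effects, t_dist = t_dist)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  core$ci_low <- core$slope - zq * core$slope_se
  core$ci_high <- core$slope + zq * core$slope_se
  core$level <- level
  core$snp <- data$snp
  names(core$q_prime_contributions) <- data$snp
  structure(core, class = "mr_egger")
}

#' Two-stage least squares on individual-level data
#'
#' Classical instrumental-variable estimator: the exposure is regressed on
#' the instruments, then the outcome on the fitted exposure. With
#' uncorrelated instruments and both stages estimated in the same (or a
#' homogeneous) population the summary-data IVW estimate is asymptotically
#' equivalent to this estimate; the package uses 2SLS as an independent
#' reference in its tests.
#'
#' @param G numeric matrix of instrument dosages (n x m).
#' @param exposure numeric vector of length n.
#' @param outcome numeric vector of length n.
#' @return List with `estimate` and `se` (homoscedastic 2SLS standard
#'   error using residuals from the observed, not fitted, exposure).
#' @export
two_stage_least_squares <- function(G, exposure, outcome) {
  G <- as.matrix(G)
  n <- nrow(G)
  stopifnot(length(exposure) == n, length(outcome) == n)
  X1 <- cbind(1, G)
  if (qr(X1)$rank < ncol(X1)) {
    stop("singular first stage: instruments are collinear", call. = FALSE)
  }
  first <- stats::lm.fit(X1, exposure)
  xhat <- exposure - first$residuals
  X2 <- cbind(1, xhat)
  second <- stats::lm.fit(X2, outcome)
  b <- second$coefficients
  # 2SLS residuals use the observed exposure
  res <- outcome - b[1] - b[2] * exposure
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sum((xhat - mean(xhat))^2))
  list(estimate = unname(b[2]), se = se)
}

#' Derive per-SNP summary statistics from individual-level data
#'
#' Runs the m marginal simple regressions of exposure and outcome on each
#' instrument and packages the coefficients and standard errors as an
#' `mr_summary` dataset. Used to connect the individual-level simulator to
#' the summary-data estimators.
#'
#' @param G numeric matrix of instrument dosages (n x m).
#' @param exposure numeric vector; SNP-exposure associations are estimated
#'   from these data.
#' @param outcome numeric vector; SNP-outcome associations and their
#'   standard errors are estimated from these data.
#' @param snp optional variant identifiers.
#' @return An `mr_summary` dataset with `se_exp` filled in.
#' @export
summary_from_individual <- function(G, exposure, outcome, snp = NULL) {
  G <- as.matrix(G)
  n <- nrow(G)
  if (is.null(snp)) snp <- paste0("snp", seq_len(ncol(G)))
  gc <- scale(G, center = TRUE, scale = FALSE)
  sxx <- colSums(gc^2)
  xc <- exposure - mean(exposure)
  yc <- outcome - mean(outcome)
  a <- colSums(gc * xc) / sxx
  b <- colSums(gc * yc) / sxx
  # residual variance of each marginal regression via the closed form
  se_a <- sqrt(pmax(sum(xc^2) - a^2 * sxx, 0) / (n - 2) / sxx)
  se_b <- sqrt(pmax(sum(yc^2) - b^2 * sxx, 0) / (n - 2) / sxx)
  mr_summary(snp, beta_exp = a, beta_out = b, se_out = se_b, se_exp = se_a)
}

#' @export
print.mr_ivw <- function(x, ...) {
  cat("IVW causal estimate\n")
  cat(sprintf("  beta = %.6g (se %.4g), %d%% CI [%.6g, %.6g]\n",
              x$beta, x$se, round(100 * x$level), x$ci_low, x$ci_high))
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran's Q = %.4f on %d df, p = %.4g\n",
                x$q, x$q_df, x$q_pvalue))
  }
  invisible(x)
}

#' @export
print.mr_egger <- function(x, ...) {
  cat("MR-Egger regression\n")
  cat(sprintf("  intercept = %.6g (se %.4g), p = %.4g\n",
              x$intercept, x$intercept_se, x$intercept_pvalue))
  cat(sprintf("  slope     = %.6g (se %.4g), %d%% CI [%.6g, %.6g]\n",
              x$slope, x$slope_se, round(100 * x$level),
              x$ci_low, x$ci_high))
  cat(sprintf("  Rucker's Q' = %.4f on %d df, p = %.4g\n",
              x$q_prime, x$q_prime_df, x$q_prime_pvalue))
  if (x$orientation_applied) {
    cat("  (variants re-oriented to positive exposure association)\n")
  }
  invisible(x)
}
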