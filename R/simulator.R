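# Seeded data-generating processes for summary-level and individual-level
# two-sample MR datasets with balanced or directional pleiotropy under the
# InSIDE assumption.

#' Simulation configuration
#'
#' Parameters of the summary-level data-generating process. Defaults
#' describe a 25-variant analysis with instrument strengths
#' \eqn{\alpha_j \sim U(0.05, 0.5)}, outcome-association standard errors
#' \eqn{\sigma_{Yj} \sim U(0.05, 0.15)}, a true causal effect of 0.05, and
#' pleiotropic effects drawn independently of the instrument strengths
#' (InSIDE holds by construction):
#' \itemize{
#'   \item `"none"`: all \eqn{\beta_{2j} = 0};
#'   \item `"balanced"`: \eqn{\beta_{2j} \sim U(-c, c)} with
#'     `c = pleio_max`, mean zero;
#'   \item `"directional"`: \eqn{\beta_{2j} \sim U(2\mu - c, c)} with
#'     `mu = pleio_mean`, so mean `pleio_mean` and maximum `pleio_max`
#'     (defaults: U(0, 0.2), mean 0.1).
#' }
#' With `alpha_se > 0` the reported exposure associations carry additive
#' Gaussian measurement error, violating the no-measurement-error (NOME)
#' assumption; the default 0 keeps NOME intact.
#'
#' @param m number of variants.
#' @param beta1 true causal effect of the exposure on the outcome.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleio_max maximum pleiotropy magnitude `c` (>= 0).
#' @param pleio_mean mean of directional pleiotropy.
#' @param alpha_low,alpha_high bounds of the instrument-strength
#'   distribution; `alpha_low` must be positive.
#' @param sigma_low,sigma_high bounds of the outcome-SE distribution.
#' @param alpha_se standard deviation of the exposure-association
#'   measurement error (0 = NOME holds).
#' @param n_sim default Monte-Carlo replicate count for experiments.
#' @param level significance level used by the experiment drivers.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m = 25, beta1 = 0.05,
                       pleiotropy_mode = c("balanced", "directional",
                                           "none"),
                       pleio_max = 0.2, pleio_mean = 0.1,
                       alpha_low = 0.05, alpha_high = 0.5,
                       sigma_low = 0.05, sigma_high = 0.15,
                       alpha_se = 0, n_sim = 1000, level = 0.05) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (m < 2) stop("m must be at least 2", call. = FALSE)
  if (pleio_max < 0) stop("pleio_max must be >= 0", call. = FALSE)
  if (alpha_low <= 0) stop("alpha_low must be positive", call. = FALSE)
  if (alpha_high < alpha_low) {
    stop("alpha_high must be >= alpha_low", call. = FALSE)
  }
  if (sigma_low <= 0 || sigma_high < sigma_low) {
    stop("invalid outcome-SE bounds", call. = FALSE)
  }
  if (alpha_se < 0) stop("alpha_se must be >= 0", call. = FALSE)
  if (n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  if (pleiotropy_mode == "directional" &&
      (pleio_mean < 0 || 2 * pleio_mean - pleio_max > pleio_max)) {
    stop("directional mode needs 0 <= pleio_mean <= pleio_max",
         call. = FALSE)
  }
  structure(list(m = m, beta1 = beta1, pleiotropy_mode = pleiotropy_mode,
                 pleio_max = pleio_max, pleio_mean = pleio_mean,
                 alpha_low = alpha_low, alpha_high = alpha_high,
                 sigma_low = sigma_low, sigma_high = sigma_high,
                 alpha_se = alpha_se, n_sim = n_sim, level = level),
            class = "sim_config")
}

# Draw the per-variant pleiotropic effects for one replicate.
draw_beta2 <- function(config) {
  switch(config$pleiotropy_mode,
         none = rep(0, config$m),
         balanced = stats::runif(config$m, -config$pleio_max,
                                 config$pleio_max),
         directional = stats::runif(config$m,
                                    2 * config$pleio_mean - config$pleio_max,
                                    config$pleio_max))
}

# Core summary-level draw on bare vectors; uses the current RNG stream.
sim_core <- function(config) {
  m <- config$m
  alpha_true <- stats::runif(m, config$alpha_low, config$alpha_high)
  sigma <- stats::runif(m, config$sigma_low, config$sigma_high)
  beta2 <- draw_beta2(config)
  beta_out <- config$beta1 * alpha_true + beta2 +
    stats::rnorm(m, 0, sigma)
  alpha_rep <- alpha_true
  se_exp <- rep(NA_real_, m)
  if (config$alpha_se > 0) {
    alpha_rep <- alpha_true + stats::rnorm(m, 0, config$alpha_se)
    se_exp <- rep(config$alpha_se, m)
  }
  list(alpha = alpha_rep, beta_out = beta_out, se_out = sigma,
       se_exp = se_exp, alpha_true = alpha_true, beta2 = beta2)
}

#' Simulate a summary-level two-sample MR dataset
#'
#' Draws one dataset from the configured generating process:
#' \eqn{\hat\beta_{YGj} = \beta_1\alpha_j + \beta_{2j} + \epsilon_j} with
#' \eqn{\epsilon_j \sim N(0, \sigma_{Yj}^2)}, pleiotropic effects
#' \eqn{\beta_{2j}} drawn independently of \eqn{\alpha_j} (InSIDE). With
#' `alpha_se > 0` the reported exposure associations are
#' \eqn{\hat\alpha_j = \alpha_j + N(0, \alpha_{se}^2)} while `se_out`
#' remains the outcome SE — the weak-instrument (NOME-violation) mode.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; when supplied the RNG is seeded so
#'   identical (config, seed) pairs give bitwise-identical datasets.
#'   When `NULL` the current RNG stream is used (so experiment drivers can
#'   manage their own stream).
#' @return List with `data` (an `mr_summary`) and `truth` (list with
#'   `beta1`, `beta2`, `alpha_true`, and a `config` echo).
#' @examples
#' sim <- simulate_summary_data(sim_config(pleiotropy_mode = "none"),
#'                              seed = 7)
#' mr_ivw(sim$data)
#' @export
simulate_summary_data <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  draw <- sim_core(config)
  data <- new_mr_summary(sprintf("snp%02d", seq_len(config$m)),
                         draw$alpha, draw$beta_out, draw$se_out,
                         draw$se_exp)
  list(data = data,
       truth = list(beta1 = config$beta1, beta2 = draw$beta2,
                    alpha_true = draw$alpha_true,
                    config = unclass(config), seed = seed))
}

#' Simulate individual-level two-cohort MR data
#'
#' Generates two disjoint cohorts from the same population: biallelic
#' genotypes \eqn{G_{ij} \sim Binomial(2, maf)}, exposure
#' \eqn{X = \sum_j \alpha_j G_j + U + e_X}, outcome
#' \eqn{Y = \beta_1 X + \sum_j \beta_{2j} G_j + U + e_Y}, with a shared
#' standard-normal confounder U and unit-variance noise. A two-sample
#' summary dataset is derived by regressing the exposure on each variant
#' in cohort 2 and the outcome on each variant in cohort 1.
#'
#' @param config a [sim_config()] (continuous-trait mode).
#' @param n individuals per cohort (>= 100).
#' @param maf minor-allele frequency shared by all variants.
#' @param seed optional integer seed.
#' @return List with `cohort1` and `cohort2` (each `G`, `exposure`,
#'   `outcome`), the derived two-sample `summary` (`mr_summary`), and
#'   `truth`.
#' @export
simulate_individual_data <- function(config = sim_config(), n = 10000,
                                     maf = 0.3, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n >= 100,
            maf > 0, maf < 1)
  if (!is.null(seed)) set.seed(seed)
  m <- config$m
  alpha_true <- stats::runif(m, config$alpha_low, config$alpha_high)
  beta2 <- draw_beta2(config)
  cohort <- function() {
    G <- matrix(stats::rbinom(n * m, 2, maf), nrow = n, ncol = m)
    U <- stats::rnorm(n)
    exposure <- as.vector(G %*% alpha_true) + U + stats::rnorm(n)
    outcome <- config$beta1 * exposure + as.vector(G %*% beta2) + U +
      stats::rnorm(n)
    list(G = G, exposure = exposure, outcome = outcome)
  }
  c1 <- cohort()
  c2 <- cohort()
  snp <- sprintf("snp%02d", seq_len(m))
  exp_part <- summary_from_individual(c2$G, c2$exposure, c2$outcome,
                                      snp = snp)
  out_part <- summary_from_individual(c1$G, c1$exposure, c1$outcome,
                                      snp = snp)
  summary <- mr_summary(snp,
                        beta_exp = exp_part$beta_exp,
                        beta_out = out_part$beta_out,
                        se_out = out_part$se_out,
                        se_exp = exp_part$se_exp)
  list(cohort1 = c1, cohort2 = c2, summary = summary,
       truth = list(beta1 = config$beta1, beta2 = beta2,
                    alpha_true = alpha_true, maf = maf, n = n,
                    config = unclass(config), seed = seed))
}

#' Write the simulation truth sidecar as JSON
#'
#' @param truth the `truth` element of a simulated dataset.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
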