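# Monte-Carlo experiment drivers: global-test power across pleiotropy
# magnitudes, per-variant contribution profiles, and type-I-error
# behaviour under weak instruments.

# One replicate's three global p-values (Q, Q', Egger intercept) from the
# shared estimator cores; operates on bare vectors for speed.
global_test_pvalues <- function(config, egger_random_effects = FALSE) {
  draw <- sim_core(config)
  ivw <- ivw_core(draw$alpha, draw$beta_out, draw$se_out)
  eg <- egger_core(draw$alpha, draw$beta_out, draw$se_out,
                   random_effects = egger_random_effects)
  c(q = ivw$q_pvalue, q_prime = eg$q_prime_pvalue,
    egger_intercept = eg$intercept_pvalue)
}

#' Power of the global pleiotropy tests across pleiotropy magnitudes
#'
#' For each maximum pleiotropy magnitude `c` in `c_grid`, simulates
#' `n_sim` balanced-pleiotropy datasets and records the fraction of
#' replicates in which Cochran's Q, Rucker's Q' and the MR-Egger intercept
#' test reject at the configured significance level. At `c = 0` the data
#' satisfy the global null, so the rejection rates estimate the tests'
#' type-I error.
#'
#' @param config a [sim_config()]; its `pleio_max` is overridden by each
#'   grid value and its mode forced to `"balanced"` (`"none"` at c = 0).
#' @param c_grid numeric vector of maximum pleiotropy magnitudes.
#' @param n_sim replicates per grid point (defaults to `config$n_sim`).
#' @param seed integer seed for the whole study.
#' @param egger_se `"fixed"` or `"random"`: which standard-error variant
#'   the Egger intercept test uses; recorded in the output.
#' @return A data frame of class `power_curve` with columns `c`, `test`,
#'   `power`, `mc_se` (binomial Monte-Carlo standard error
#'   \eqn{\sqrt{p(1-p)/n_{sim}}}), `n_sim`, `seed`; the configuration echo
#'   is attached as attribute `config`.
#' @examples
#' \donttest{
#' pc <- run_power_study(c_grid = c(0, 0.2), n_sim = 200, seed = 1)
#' pc
#' }
#' @export
run_power_study <- function(config = sim_config(),
                            c_grid = seq(0, 0.2, by = 0.05),
                            n_sim = config$n_sim, seed = 1,
                            egger_se = c("fixed", "random")) {
  stopifnot(inherits(config, "sim_config"), length(c_grid) >= 1,
            all(c_grid >= 0), n_sim >= 1)
  egger_se <- match.arg(egger_se)
  set.seed(seed)
  level <- config$level
  rows <- vector("list", length(c_grid))
  for (i in seq_along(c_grid)) {
    cc <- c_grid[i]
    cfg <- config
    cfg$pleio_max <- cc
    cfg$pleiotropy_mode <- if (cc == 0) "none" else "balanced"
    rej <- matrix(0, nrow = n_sim, ncol = 3)
    for (r in seq_len(n_sim)) {
      p <- global_test_pvalues(cfg, egger_random_effects =
                                 (egger_se == "random"))
      rej[r, ] <- p < level
    }
    pw <- colMeans(rej)
    rows[[i]] <- data.frame(
      c = cc,
      test = c("cochran_q", "rucker_q_prime", "egger_intercept"),
      power = pw,
      mc_se = sqrt(pw * (1 - pw) / n_sim),
      n_sim = n_sim, seed = seed,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- c(unclass(config),
                           list(egger_se = egger_se, seed = seed,
                                n_sim = n_sim))
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Per-variant contribution profile for a single dataset
#'
#' Simulates one dataset (directional pleiotropy by default, to induce a
#' difference between the Q and Q' decompositions), computes the per-SNP
#' contributions Qj and Q'j, and annotates them with the uncorrected and
#' Bonferroni chi-squared(1) thresholds.
#'
#' @param config a [sim_config()]; defaults to the directional setting.
#' @param seed integer seed.
#' @param fwer familywise error rate for the thresholds.
#' @return List with `table` (the per-SNP table of the underlying
#'   [pleiotropy_report()]), `thresholds`, `report`, `data`, `truth`.
#' @export
run_contribution_profile <- function(config = sim_config(
                                       pleiotropy_mode = "directional"),
                                     seed = 1, fwer = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_summary_data(config, seed = seed)
  report <- pleiotropy_report(sim$data, fwer = fwer)
  list(table = report$snp_table,
       thresholds = report$thresholds,
       report = report, data = sim$data, truth = sim$truth)
}

#' Type-I error of the Q test under weak instruments
#'
#' With pleiotropy switched off, sweeps the exposure-association
#' measurement-error standard deviation `alpha_se` over a grid (including
#' 0, where NOME holds and the test is calibrated) and records the
#' empirical rejection rate of Cochran's Q at the configured level. With
#' weak instruments the inverse-variance weights ignore the error in
#' \eqn{\hat\alpha_j}, and the type-I error inflates.
#'
#' The variance understatement — and hence the inflation — scales with
#' the product of the causal effect and the measurement error, so the
#' default study configuration uses a substantial causal effect
#' (`beta1 = 0.5`); with a near-zero causal effect the naive weights are
#' nearly correct and no inflation exists to detect.
#'
#' @param config a [sim_config()]; pleiotropy mode forced to `"none"`.
#' @param alpha_se_grid grid of measurement-error SDs; must include 0.
#' @param n_sim replicates per grid point.
#' @param seed integer seed.
#' @return Data frame with columns `alpha_se`, `rejection_rate`, `mc_se`,
#'   `n_sim`, `seed`; configuration echo attached as attribute `config`.
#' @export
run_weak_instrument_study <- function(config = sim_config(beta1 = 0.5),
                                      alpha_se_grid = c(0, 0.02, 0.05,
                                                        0.1),
                                      n_sim = config$n_sim, seed = 1) {
  stopifnot(inherits(config, "sim_config"), 0 %in% alpha_se_grid,
            all(alpha_se_grid >= 0), n_sim >= 1)
  set.seed(seed)
  level <- config$level
  rate <- numeric(length(alpha_se_grid))
  for (i in seq_along(alpha_se_grid)) {
    cfg <- config
    cfg$pleiotropy_mode <- "none"
    cfg$alpha_se <- alpha_se_grid[i]
    rej <- 0L
    for (r in seq_len(n_sim)) {
      draw <- sim_core(cfg)
      ivw <- ivw_core(draw$alpha, draw$beta_out, draw$se_out)
      rej <- rej + (ivw$q_pvalue < level)
    }
    rate[i] <- rej / n_sim
  }
  out <- data.frame(alpha_se = alpha_se_grid,
                    rejection_rate = rate,
                    mc_se = sqrt(rate * (1 - rate) / n_sim),
                    n_sim = n_sim, seed = seed)
  attr(out, "config") <- c(unclass(config),
                           list(seed = seed, n_sim = n_sim))
  out
}

#' Write an experiment table with its JSON run manifest
#'
#' The table goes to `path` as comma-separated text; the exact
#' configuration echo (attribute `config`) goes to `<path>.manifest.json`.
#'
#' @param x a result of [run_power_study()] or
#'   [run_weak_instrument_study()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(cfg, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Plot a power curve in the style of a power-versus-pleiotropy figure
#'
#' Base-graphics helper: one line per test, rejection rate against the
#' maximum pleiotropy magnitude.
#'
#' @param x a `power_curve` data frame.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.power_curve <- function(x, ...) {
  tests <- unique(x$test)
  cs <- sort(unique(x$c))
  mat <- sapply(tests, function(t) {
    x$power[x$test == t][order(x$c[x$test == t])]
  })
  graphics::matplot(cs, mat, type = "b", pch = 19, lty = 1,
                    xlab = "maximum pleiotropy magnitude",
                    ylab = "rejection rate", ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = tests, col = seq_along(tests),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
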