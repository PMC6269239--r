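# Global and per-variant pleiotropy tests built on Cochran's Q and
# Rucker's Q', outlier flagging, and outlier removal with refitting.

#' Cochran's Q statistic with per-SNP decomposition
#'
#' Computes \eqn{Q_j = w_j(\hat\beta_j - \hat\beta_{IVW})^2} and
#' \eqn{Q = \sum_j Q_j}. Under the global null of no horizontal pleiotropy
#' (and NOME) Q is chi-squared with m-1 df; each \eqn{Q_j} is approximately
#' chi-squared with 1 df when m is large, and tests the corresponding
#' variant for individual pleiotropy.
#'
#' @param data an `mr_summary` dataset with at least 2 variants.
#' @return List with `q`, `contributions` (named per SNP), `df` = m-1, and
#'   `pvalue` (upper chi-squared tail).
#' @examples
#' d <- mr_summary(c("a", "b"), beta_exp = c(1, 1),
#'                 beta_out = c(1, 3), se_out = c(1, 1))
#' cochran_q(d)$q  # 2
#' @export
cochran_q <- function(data) {
  stopifnot(inherits(data, "mr_summary"))
  if (nrow(data) < 2) {
    stop("Cochran's Q requires at least 2 variants", call. = FALSE)
  }
  core <- ivw_core(data$beta_exp, data$beta_out, data$se_out)
  contrib <- core$q_contributions
  names(contrib) <- data$snp
  list(q = core$q, contributions = contrib, df = core$q_df,
       pvalue = core$q_pvalue)
}

#' Rucker's Q' statistic with per-SNP decomposition
#'
#' Residual heterogeneity after the MR-Egger adjustment:
#' \eqn{Q'_j = (\hat\beta_{YGj} - \beta_{0E} - \beta_{1E}\alpha_j)^2 /
#' \sigma_{Yj}^2} on the (orientation-consistent) association scale, and
#' \eqn{Q' = \sum_j Q'_j}, chi-squared with m-2 df under the null that all
#' variants share the same direct effect. Because the Egger fit adds a free
#' intercept to the same weighted regression that defines the IVW estimate,
#' \eqn{Q' \le Q} for every dataset.
#'
#' @param data an `mr_summary` dataset with at least 3 variants.
#' @param egger optionally, an [mr_egger()] fit of the same data; refitted
#'   when missing. Supplying a fit of a different dataset is an error.
#' @return List with `q_prime`, `contributions`, `df` = m-2, `pvalue`.
#' @export
rucker_q <- function(data, egger = NULL) {
  stopifnot(inherits(data, "mr_summary"))
  if (is.null(egger)) {
    egger <- mr_egger(data)
  } else {
    stopifnot(inherits(egger, "mr_egger"))
    if (egger$m != nrow(data) || !identical(egger$snp, data$snp)) {
      stop("the supplied MR-Egger fit does not match the dataset",
           call. = FALSE)
    }
  }
  list(q_prime = egger$q_prime,
       contributions = egger$q_prime_contributions,
       df = egger$q_prime_df,
       pvalue = egger$q_prime_pvalue)
}

#' Chi-squared(1) outlier thresholds for per-SNP contributions
#'
#' The uncorrected per-test threshold is the chi-squared(1) quantile at
#' `1 - fwer`; the Bonferroni familywise threshold is the quantile at
#' `1 - fwer/m`. For the canonical 25-variant analysis at FWER 0.05 these
#' are the 95th and 99.8th percentiles.
#'
#' @param m number of variants in the family.
#' @param fwer familywise error rate to control, in (0, 1).
#' @return List with `uncorrected`, `bonferroni` (chi-squared(1) critical
#'   values) and the corresponding `percentiles`.
#' @export
pleiotropy_thresholds <- function(m, fwer = 0.05) {
  stopifnot(m >= 1, fwer > 0, fwer < 1)
  list(uncorrected = stats::qchisq(1 - fwer, df = 1),
       bonferroni = stats::qchisq(1 - fwer / m, df = 1),
       percentiles = c(uncorrected = 100 * (1 - fwer),
                       bonferroni = 100 * (1 - fwer / m)))
}

#' Flag individual variants by their heterogeneity contributions
#'
#' Compares per-SNP contributions (Qj or Q'j, approximately chi-squared on
#' 1 df under no individual pleiotropy) against the uncorrected and
#' Bonferroni chi-squared(1) thresholds. Variants above the Bonferroni
#' threshold form the outlier list.
#'
#' @param contributions named numeric vector of per-SNP Qj or Q'j values.
#' @param m family size for the Bonferroni correction; defaults to
#'   `length(contributions)`.
#' @param fwer familywise error rate.
#' @return Data frame with columns `snp`, `contribution`,
#'   `flag_uncorrected`, `flag_bonferroni`; attribute `outliers` holds the
#'   Bonferroni-flagged identifiers and attribute `thresholds` the critical
#'   values.
#' @export
individual_pleiotropy_test <- function(contributions,
                                       m = length(contributions),
                                       fwer = 0.05) {
  th <- pleiotropy_thresholds(m, fwer)
  snp <- names(contributions)
  if (is.null(snp)) snp <- paste0("snp", seq_along(contributions))
  out <- data.frame(snp = snp,
                    contribution = as.numeric(contributions),
                    flag_uncorrected = contributions > th$uncorrected,
                    flag_bonferroni = contributions > th$bonferroni,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "outliers") <- out$snp[out$flag_bonferroni]
  attr(out, "thresholds") <- th
  out
}

#' Compare the IVW and MR-Egger fits of the same data
#'
#' Reports the drop in heterogeneity Q - Q' (a 1-df heuristic for
#' directional pleiotropy) and a purely advisory hint: `"egger-better"`
#' when some Qj exceed the Bonferroni threshold while no Q'j does —
#' i.e. outliers under the IVW model vanish once the mean pleiotropic
#' effect is absorbed by the Egger intercept — and `"neutral"` otherwise.
#' The hint never auto-selects a model.
#'
#' @param q result of [cochran_q()].
#' @param q_prime result of [rucker_q()].
#' @param fwer familywise error rate used for the flags.
#' @return List with `q_minus_q_prime` and `hint`.
#' @export
model_hint <- function(q, q_prime, fwer = 0.05) {
  m <- q$df + 1
  fq <- individual_pleiotropy_test(q$contributions, m = m, fwer = fwer)
  fqp <- individual_pleiotropy_test(q_prime$contributions, m = m,
                                    fwer = fwer)
  hint <- if (any(fq$flag_bonferroni) && !any(fqp$flag_bonferroni)) {
    "egger-better"
  } else {
    "neutral"
  }
  list(q_minus_q_prime = q$q - q_prime$q_prime, hint = hint)
}

#' Full pleiotropy report: global tests, per-SNP flags, outliers
#'
#' Runs the whole detection pipeline on a validated dataset: IVW with
#' Cochran's Q, MR-Egger with Rucker's Q' (when m >= 3), per-SNP flags at
#' the uncorrected and Bonferroni chi-squared(1) thresholds for both
#' decompositions, the Bonferroni outlier list (based on Qj), and the
#' advisory model hint.
#'
#' @param data an `mr_summary` dataset.
#' @param fwer familywise error rate for per-SNP flags.
#' @param level confidence level passed to the estimators.
#' @param random_effects,t_dist passed to [mr_egger()].
#' @return An object of class `pleiotropy_report`: list with `ivw`,
#'   `egger` (`NULL` when m < 3), `global_q_pvalue`,
#'   `global_q_prime_pvalue`, `snp_table`, `outlier_ids`, `thresholds`,
#'   `model_hint`, `m`, `fwer`.
#' @export
pleiotropy_report <- function(data, fwer = 0.05, level = 0.95,
                              random_effects = FALSE, t_dist = FALSE) {
  stopifnot(inherits(data, "mr_summary"), fwer > 0, fwer < 1)
  m <- nrow(data)
  ivw <- mr_ivw(data, level = level)
  q <- list(q = ivw$q, contributions = ivw$q_contributions,
            df = ivw$q_df, pvalue = ivw$q_pvalue)
  fq <- individual_pleiotropy_test(q$contributions, m = m, fwer = fwer)
  egger <- NULL
  qp <- NULL
  if (m >= 3) {
    egger <- mr_egger(data, random_effects = random_effects,
                      t_dist = t_dist, level = level)
    qp <- rucker_q(data, egger)
    fqp <- individual_pleiotropy_test(qp$contributions, m = m, fwer = fwer)
  }
  snp_table <- data.frame(snp = data$snp,
                          q_contrib = unname(q$contributions),
                          q_prime_contrib = if (is.null(qp)) NA_real_
                                            else unname(qp$contributions),
                          flag_95 = fq$flag_uncorrected,
                          flag_bonf = fq$flag_bonferroni,
                          q_prime_flag_95 = if (is.null(qp)) NA
                                            else fqp$flag_uncorrected,
                          q_prime_flag_bonf = if (is.null(qp)) NA
                                              else fqp$flag_bonferroni,
                          stringsAsFactors = FALSE)
  hint <- if (is.null(qp)) {
    list(q_minus_q_prime = NA_real_, hint = "unavailable")
  } else {
    model_hint(q, qp, fwer = fwer)
  }
  structure(list(ivw = ivw, egger = egger,
                 global_q_pvalue = q$pvalue,
                 global_q_prime_pvalue = if (is.null(qp)) NA_real_
                                         else qp$pvalue,
                 snp_table = snp_table,
                 outlier_ids = snp_table$snp[snp_table$flag_bonf],
                 thresholds = pleiotropy_thresholds(m, fwer),
                 model_hint = hint, m = m, fwer = fwer),
            class = "pleiotropy_report")
}

#' Remove Bonferroni outliers and refit
#'
#' Drops the variants whose Qj exceed the Bonferroni chi-squared(1)
#' threshold and refits IVW and (when possible) MR-Egger. Under
#' `policy = "iterate"` the flag-and-remove cycle repeats until no outliers
#' remain or removal would leave fewer than 3 variants; iterative removal
#' re-tests on refitted statistics and therefore no longer controls the
#' nominal familywise error rate, so enabling it emits a warning.
#'
#' @param data an `mr_summary` dataset.
#' @param report optionally a precomputed [pleiotropy_report()] of `data`.
#' @param policy `"single-pass"` (default) or `"iterate"`.
#' @param fwer familywise error rate for the flags.
#' @return List with `data` (filtered), `removed` (identifiers in removal
#'   order), `ivw`, `egger` (refitted; `NULL` when m < 3), and `report`
#'   (recomputed on the filtered data).
#' @export
remove_outliers_and_refit <- function(data, report = NULL,
                                      policy = c("single-pass", "iterate"),
                                      fwer = 0.05) {
  stopifnot(inherits(data, "mr_summary"))
  policy <- match.arg(policy)
  if (policy == "iterate") {
    warning("iterative outlier removal re-tests refitted statistics; ",
            "the familywise error rate is no longer controlled at fwer",
            call. = FALSE)
  }
  if (is.null(report)) report <- pleiotropy_report(data, fwer = fwer)
  removed <- character(0)
  current <- data
  repeat {
    out_ids <- report$outlier_ids
    if (length(out_ids) == 0) break
    if (nrow(current) - length(out_ids) < 2) {
      stop("refusing to remove ", length(out_ids), " outlier(s): fewer ",
           "than 2 variants would remain", call. = FALSE)
    }
    keep <- !(current$snp %in% out_ids)
    current <- new_mr_summary(current$snp[keep], current$beta_exp[keep],
                              current$beta_out[keep], current$se_out[keep],
                              current$se_exp[keep])
    removed <- c(removed, out_ids)
    report <- pleiotropy_report(current, fwer = fwer)
    if (policy == "single-pass" || nrow(current) < 3) break
  }
  list(data = current, removed = removed,
       ivw = report$ivw, egger = report$egger, report = report)
}

#' Serialize a pleiotropy report to flat JSON
#'
#' @param report a [pleiotropy_report()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pleiotropy_report"))
  ivw <- report$ivw
  out <- list(
    m = report$m,
    fwer = report$fwer,
    ivw = list(estimate = ivw$beta, se = ivw$se,
               ci_low = ivw$ci_low, ci_high = ivw$ci_high,
               q = ivw$q, df = ivw$q_df, p = ivw$q_pvalue,
               contributions = unname(ivw$q_contributions)),
    thresholds = list(uncorrected = report$thresholds$uncorrected,
                      bonferroni = report$thresholds$bonferroni),
    outliers = as.list(report$outlier_ids),
    model_hint = report$model_hint)
  if (!is.null(report$egger)) {
    eg <- report$egger
    out$egger <- list(estimate = eg$slope, se = eg$slope_se,
                      ci_low = eg$ci_low, ci_high = eg$ci_high,
                      intercept = eg$intercept,
                      intercept_se = eg$intercept_se,
                      intercept_p = eg$intercept_pvalue,
                      q = eg$q_prime, df = eg$q_prime_df,
                      p = eg$q_prime_pvalue,
                      contributions = unname(eg$q_prime_contributions),
                      orientation_applied = eg$orientation_applied)
  } else {
    out$egger <- "unavailable: fewer than 3 variants"
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the per-SNP contribution table as tab-delimited text
#'
#' @param report a [pleiotropy_report()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(report, path) {
  stopifnot(inherits(report, "pleiotropy_report"))
  utils::write.table(report$snp_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.pleiotropy_report <- function(x, ...) {
  ivw <- x$ivw
  cat(sprintf("Pleiotropy report (%d variants, FWER %.3g)\n", x$m, x$fwer))
  cat(sprintf("  IVW beta = %.6g (se %.4g)\n", ivw$beta, ivw$se))
  cat(sprintf("  Q  = %.4f on %d df, p = %.4g\n",
              ivw$q, ivw$q_df, ivw$q_pvalue))
  if (!is.null(x$egger)) {
    eg <- x$egger
    cat(sprintf("  Egger slope = %.6g (se %.4g), intercept = %.6g (p = %.4g)\n",
                eg$slope, eg$slope_se, eg$intercept, eg$intercept_pvalue))
    cat(sprintf("  Q' = %.4f on %d df, p = %.4g\n",
                eg$q_prime, eg$q_prime_df, eg$q_prime_pvalue))
    cat(sprintf("  Q - Q' = %.4f; model hint: %s\n",
                x$model_hint$q_minus_q_prime, x$model_hint$hint))
  } else {
    cat("  MR-Egger unavailable (fewer than 3 variants)\n")
  }
  n_out <- length(x$outlier_ids)
  if (n_out > 0) {
    cat(sprintf("  %d Bonferroni outlier(s): %s\n", n_out,
                paste(x$outlier_ids, collapse = ", ")))
  } else {
    cat("  no Bonferroni outliers\n")
  }
  invisible(x)
}
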