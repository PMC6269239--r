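# Summary-data container and validation for two-sample MR.

#' Construct a validated two-sample MR summary dataset
#'
#' Builds the per-SNP summary-statistic container used throughout the
#' package. Each row holds the association of one genetic variant with the
#' exposure (`beta_exp`, the instrument strength \eqn{\alpha_j}) and with the
#' outcome (`beta_out`, \eqn{\hat\beta_{YGj}}, with standard error `se_out`,
#' \eqn{\sigma_{Yj}}), pre-harmonized to a common effect allele. The
#' exposure-association standard error `se_exp` is optional and is only used
#' by weak-instrument diagnostics; when missing it is treated as exactly
#' zero measurement error (the no-measurement-error, NOME, assumption).
#'
#' Variants with `beta_exp == 0` (undefined Wald ratio) or `se_out <= 0`
#' are dropped with a warning, unless `strict = TRUE` in which case they
#' raise an error. At least 2 variants must survive validation; MR-Egger
#' and Rucker's Q' additionally require 3.
#'
#' @param snp character vector of unique variant identifiers.
#' @param beta_exp numeric, SNP-exposure associations (per-allele).
#' @param beta_out numeric, SNP-outcome associations (per-allele).
#' @param se_out numeric, standard errors of `beta_out`; must be positive.
#' @param se_exp optional numeric, standard errors of `beta_exp`; `NA`
#'   permitted (interpreted as negligible error).
#' @param strict logical; if `TRUE`, invalid rows raise instead of being
#'   dropped.
#' @return A data frame of class `mr_summary` with columns `snp`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @examples
#' d <- mr_summary(paste0("rs", 1:3),
#'                 beta_exp = c(0.1, 0.2, 0.3),
#'                 beta_out = c(0.02, 0.03, 0.05),
#'                 se_out   = c(0.05, 0.05, 0.05))
#' nrow(d)
#' @export
mr_summary <- function(snp, beta_exp, beta_out, se_out, se_exp = NULL,
                       strict = FALSE) {
  snp <- as.character(snp)
  m0 <- length(snp)
  if (is.null(se_exp)) se_exp <- rep(NA_real_, m0)
  beta_exp <- as.numeric(beta_exp)
  beta_out <- as.numeric(beta_out)
  se_out <- as.numeric(se_out)
  se_exp <- as.numeric(se_exp)
  lens <- c(length(beta_exp), length(beta_out), length(se_out),
            length(se_exp))
  if (any(lens != m0)) {
    stop("all columns must have the same length", call. = FALSE)
  }
  if (anyDuplicated(snp)) {
    stop("duplicate snp identifiers: ",
         paste(unique(snp[duplicated(snp)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(snp) || anyNA(beta_exp) || anyNA(beta_out) || anyNA(se_out)) {
    stop("NA values are only permitted in se_exp", call. = FALSE)
  }
  bad_alpha <- beta_exp == 0
  bad_sigma <- se_out <= 0
  bad <- bad_alpha | bad_sigma
  if (any(bad)) {
    msg <- sprintf(
      "dropping %d variant(s) with zero exposure association or non-positive outcome SE: %s",
      sum(bad), paste(snp[bad], collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  keep <- !bad
  if (sum(keep) < 2) {
    stop("fewer than 2 valid variants remain after validation",
         call. = FALSE)
  }
  new_mr_summary(snp[keep], beta_exp[keep], beta_out[keep], se_out[keep],
                 se_exp[keep])
}

# Internal fast constructor: assumes inputs already valid.
new_mr_summary <- function(snp, beta_exp, beta_out, se_out,
                           se_exp = rep(NA_real_, length(snp))) {
  structure(
    data.frame(snp = snp, beta_exp = beta_exp, se_exp = se_exp,
               beta_out = beta_out, se_out = se_out,
               stringsAsFactors = FALSE),
    class = c("mr_summary", "data.frame"))
}

#' Read a two-sample MR summary dataset from a tab-delimited file
#'
#' Expects a header row with columns `snp`, `beta_exp`, `beta_out`,
#' `se_out` and optionally `se_exp`; `NA` is permitted only in `se_exp`.
#' Rows are validated by [mr_summary()].
#'
#' @param path path to a tab-delimited text file.
#' @param strict passed to [mr_summary()].
#' @return An `mr_summary` data frame.
#' @export
read_mr_summary <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("snp", "beta_exp", "beta_out", "se_out")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  se_exp <- if ("se_exp" %in% names(raw)) raw$se_exp else NULL
  mr_summary(raw$snp, raw$beta_exp, raw$beta_out, raw$se_out,
             se_exp = se_exp, strict = strict)
}

#' Write a summary dataset in the tab-delimited interchange dialect
#'
#' Numbers are written with 17 significant digits so that re-reading the
#' file reproduces every double bit-exactly.
#'
#' @param x an `mr_summary` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mr_summary <- function(x, path) {
  stopifnot(inherits(x, "mr_summary"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  out <- data.frame(snp = x$snp,
                    beta_exp = fmt(x$beta_exp),
                    se_exp = fmt(x$se_exp),
                    beta_out = fmt(x$beta_out),
                    se_out = fmt(x$se_out),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.mr_summary <- function(x, ...) {
  cat(sprintf("Two-sample MR summary data: %d variants\n", nrow(x)))
  nome <- all(is.na(x$se_exp)) || all(x$se_exp == 0, na.rm = TRUE)
  cat(sprintf("Exposure-association error: %s\n",
              if (nome) "assumed negligible (NOME)" else "reported"))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}
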