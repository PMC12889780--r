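# z-quantile used throughout for 95% intervals, matching printed-CI precision
Z95 <- 1.959964

#' Reconstruct a study estimate from a printed OR and 95% CI
#'
#' When per-study standard errors are not published, the canonical
#' reconstruction from a printed odds ratio and symmetric-on-log-scale 95\%
#' CI is \code{log_or = ln(or)} and
#' \code{se = (ln ci_high - ln ci_low) / (2 x 1.959964)}.
#'
#' @param or_point Printed odds ratio (> 0).
#' @param ci_low,ci_high Printed 95\% CI bounds; need
#'   \code{0 < ci_low <= or_point <= ci_high} and \code{ci_low < ci_high}
#'   (a degenerate CI would give se = 0).
#' @param label Study label.
#' @return One-row \code{data.frame}: \code{label}, \code{log_or},
#'   \code{se}, \code{source = "FROM_CI"}.
#' @examples
#' estimateFromCI(0.98, 0.54, 1.75, "UKB")  # log_or -0.0202, se 0.300
#' @export
estimateFromCI <- function(or_point, ci_low, ci_high, label = "study") {
  if (!(ci_low > 0 && ci_low <= or_point && or_point <= ci_high))
    azfcError("azfc_config_error",
              "need 0 < ci_low <= or_point <= ci_high")
  if (ci_low == ci_high)
    azfcError("azfc_config_error", "degenerate CI: se would be 0")
  data.frame(label = label, log_or = log(or_point),
             se = (log(ci_high) - log(ci_low)) / (2 * Z95),
             source = "FROM_CI", stringsAsFactors = FALSE)
}

#' Study estimate from a fitted model
#'
#' @param log_or Log odds ratio.
#' @param se Its standard error (> 0).
#' @param label Study label.
#' @return One-row studies \code{data.frame} with \code{source = "FITTED"}.
#' @export
studyEstimate <- function(log_or, se, label = "study") {
  if (!is.finite(se) || se <= 0)
    azfcError("azfc_config_error", "se must be finite and > 0")
  data.frame(label = label, log_or = log_or, se = se, source = "FITTED",
             stringsAsFactors = FALSE)
}

checkStudies <- function(studies, min_k = 1L) {
  if (!all(c("log_or", "se") %in% colnames(studies)))
    azfcError("azfc_config_error", "studies need columns log_or, se")
  if (nrow(studies) < min_k)
    azfcError("azfc_config_error",
              sprintf("need at least %d studies", min_k))
  if (any(studies$se <= 0))
    azfcError("azfc_config_error", "all study se must be > 0")
  invisible(studies)
}

metaResult <- function(method, theta, se, studies, q = NA_real_,
                       q_p = NA_real_, tau2 = 0, i2 = NA_real_,
                       i2_ci = c(NA_real_, NA_real_)) {
  z <- theta / se
  structure(list(method = method, combined_log_or = theta, se = se,
                 or_point = exp(theta),
                 ci95 = exp(theta + c(-1, 1) * Z95 * se),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 q_stat = q, q_p = q_p, tau2 = tau2, i2_percent = i2,
                 i2_ci = i2_ci, k = nrow(studies), studies = studies),
            class = "azfc_meta")
}

#' @export
print.azfc_meta <- function(x, ...) {
  cat(sprintf("%s-effect%s meta-analysis of %d studies\n",
              if (x$method == "FIXED") "fixed" else "random (DerSimonian-Laird)",
              if (x$method == "FIXED") "" else "s", x$k))
  cat(sprintf("  combined OR %.2f (95%% CI %.2f-%.2f), z = %.3f, p = %.2g\n",
              x$or_point, x$ci95[1], x$ci95[2], x$z, x$p))
  if (!is.na(x$q_stat))
    cat(sprintf("  Q = %.2f (p = %.2f), tau2 = %.4f, I2 = %.1f%%\n",
                x$q_stat, x$q_p, x$tau2, x$i2_percent))
  invisible(x)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Weights \code{w_i = 1/se_i^2}; combined log-OR is the weighted mean with
#' \code{se = 1/sqrt(sum(w))}; two-sided normal z test. A single study is
#' returned unchanged. With >= 2 studies the heterogeneity block
#' (\code{\link{heterogeneity}}) is filled in for reference (fixed-effect
#' inference itself ignores it).
#'
#' @param studies Studies \code{data.frame} (see
#'   \code{\link{estimateFromCI}} / \code{\link{studyEstimate}}).
#' @return List of class \code{"azfc_meta"} with \code{method = "FIXED"},
#'   \code{tau2 = 0}.
#' @export
fixedEffect <- function(studies) {
  checkStudies(studies, 1L)
  w <- 1 / studies$se^2
  theta <- sum(w * studies$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- if (nrow(studies) >= 2L) heterogeneity(studies) else
    list(q_stat = NA_real_, q_p = NA_real_, tau2 = NA_real_,
         i2_percent = NA_real_, i2_ci = c(NA_real_, NA_real_))
  metaResult("FIXED", theta, se, studies, q = het$q_stat, q_p = het$q_p,
             tau2 = 0, i2 = het$i2_percent, i2_ci = het$i2_ci)
}

#' Cochran's Q, DerSimonian-Laird tau^2 and I^2
#'
#' \code{Q = sum(w_i (theta_i - theta_fixed)^2)} with fixed-effect weights;
#' p from chi-square with k-1 df;
#' \code{tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))}
#' (moment estimator); \code{I2 = max(0, (Q - (k-1))/Q) x 100}. The I^2 CI
#' uses the test-based log-H method and is reported for orientation only:
#' it is method-sensitive, and for k = 2 with Q <= k it is undefined
#' (\code{NA}).
#'
#' @param studies Studies \code{data.frame}, >= 2 rows.
#' @return List: \code{q_stat}, \code{q_p}, \code{tau2}, \code{i2_percent},
#'   \code{i2_ci} (percent scale, truncated to [0, 100]).
#' @export
heterogeneity <- function(studies) {
  checkStudies(studies, 2L)
  k <- nrow(studies)
  w <- 1 / studies$se^2
  theta_f <- sum(w * studies$log_or) / sum(w)
  q <- sum(w * (studies$log_or - theta_f)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  i2 <- max(0, (q - (k - 1)) / q) * 100
  if (!is.finite(i2)) i2 <- 0

  # test-based CI for ln H (Higgins & Thompson); percent I2 scale
  se_lnH <- if (q > k) {
    0.5 * (log(q) - log(k - 1)) / (sqrt(2 * q) - sqrt(2 * k - 3))
  } else if (k > 2) {
    sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else NA_real_
  i2_ci <- c(NA_real_, NA_real_)
  if (is.finite(se_lnH)) {
    lnH <- 0.5 * max(0, log(q) - log(k - 1))
    H_ci <- exp(lnH + c(-1, 1) * Z95 * se_lnH)
    i2_ci <- pmin(100, pmax(0, (H_ci^2 - 1) / H_ci^2 * 100))
  }
  list(q_stat = q, q_p = q_p, tau2 = tau2, i2_percent = i2, i2_ci = i2_ci)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Inverse-variance weighting with the between-study variance added:
#' \code{w*_i = 1/(se_i^2 + tau2)}, tau2 from \code{\link{heterogeneity}}.
#' When \code{Q <= k - 1} the moment estimator truncates to tau2 = 0 and
#' the result equals \code{\link{fixedEffect}} exactly.
#'
#' @param studies Studies \code{data.frame}, >= 2 rows.
#' @return List of class \code{"azfc_meta"} with \code{method =
#'   "RANDOM_DL"}.
#' @export
randomEffects <- function(studies) {
  checkStudies(studies, 2L)
  het <- heterogeneity(studies)
  w <- 1 / (studies$se^2 + het$tau2)
  theta <- sum(w * studies$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  metaResult("RANDOM_DL", theta, se, studies, q = het$q_stat, q_p = het$q_p,
             tau2 = het$tau2, i2 = het$i2_percent, i2_ci = het$i2_ci)
}

#' Read a studies TSV (columns label, or, ci_low, ci_high)
#'
#' Each row is reconstructed via \code{\link{estimateFromCI}}.
#'
#' @param path File path.
#' @return Studies \code{data.frame}.
#' @export
readStudies <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "or", "ci_low", "ci_high")
  if (!all(need %in% colnames(raw)))
    azfcError("azfc_config_error",
              sprintf("studies TSV needs columns: %s",
                      paste(need, collapse = ", ")))
  do.call(rbind, lapply(seq_len(nrow(raw)), function(i)
    estimateFromCI(raw$or[i], raw$ci_low[i], raw$ci_high[i], raw$label[i])))
}

#' Serialize meta-analysis results as JSON
#'
#' @param results An \code{"azfc_meta"} or named list of them (e.g. one per
#'   histology stratum).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeMetaJSON <- function(results, path) {
  if (inherits(results, "azfc_meta")) results <- list(meta = results)
  out <- lapply(results, function(x) {
    x <- unclass(x)
    x$studies <- NULL
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Forest-plot-ready table of study and combined estimates
#'
#' @param studies Studies \code{data.frame}.
#' @param ... Named \code{"azfc_meta"} results to append as summary rows.
#' @return \code{data.frame}: \code{label}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{kind} (study/summary).
#' @export
forestTable <- function(studies, ...) {
  metas <- list(...)
  rows <- data.frame(label = studies$label, or = exp(studies$log_or),
                     ci_low = exp(studies$log_or - Z95 * studies$se),
                     ci_high = exp(studies$log_or + Z95 * studies$se),
                     kind = "study", stringsAsFactors = FALSE)
  for (nm in names(metas)) {
    m <- metas[[nm]]
    rows <- rbind(rows, data.frame(label = nm, or = m$or_point,
                                   ci_low = m$ci95[1], ci_high = m$ci95[2],
                                   kind = "summary", stringsAsFactors = FALSE))
  }
  rows
}
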