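#' Cross-tabulate calls against truth labels
#'
#' Positives are \code{GRGR_POSITIVE} calls / truth architecture
#' \code{GRGR_DEL}. \code{CALL_FAILED} samples are excluded from the matrix
#' and counted separately, mirroring pipeline-failure exclusions. The
#' result is order-invariant: samples are joined by \code{sample_id}.
#'
#' @param truth \code{data.frame} with \code{sample_id} and either a logical
#'   \code{positive} column or an \code{architecture} column (positive iff
#'   \code{"GRGR_DEL"}).
#' @param calls Calls \code{data.frame} from \code{\link{callCohort}}.
#' @return List of class \code{"azfc_confusion"}: \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}, \code{n_failed}.
#' @export
confusionCounts <- function(truth, calls) {
  if (!"positive" %in% colnames(truth)) {
    if (!"architecture" %in% colnames(truth))
      azfcError("azfc_config_error",
                "truth needs a 'positive' or 'architecture' column")
    truth$positive <- truth$architecture == "GRGR_DEL"
  }
  if (!setequal(truth$sample_id, calls$sample_id) ||
      anyDuplicated(truth$sample_id) || anyDuplicated(calls$sample_id))
    azfcError("azfc_manifest_mismatch",
              "truth and calls must cover exactly the same sample_ids")
  m <- merge(truth[, c("sample_id", "positive")],
             calls[, c("sample_id", "status")], by = "sample_id")
  failed <- m$status == "CALL_FAILED"
  m <- m[!failed, , drop = FALSE]
  called_pos <- m$status == "GRGR_POSITIVE"
  structure(list(tp = sum(m$positive & called_pos),
                 fp = sum(!m$positive & called_pos),
                 tn = sum(!m$positive & !called_pos),
                 fn = sum(m$positive & !called_pos),
                 n_failed = sum(failed)),
            class = "azfc_confusion")
}

#' Benchmark metrics from a confusion matrix
#'
#' Computes sensitivity \code{tp/(tp+fn)}, specificity \code{tn/(tn+fp)},
#' and two "false positive rate" variants: the standard
#' \code{fpr_standard = fp/(fp+tn)} (= 1 - specificity), and
#' \code{fpr_reported = fp/(fp+tp)}, i.e. the fraction of positive calls that
#' are wrong (a false discovery rate). Benchmarks of this caller family
#' have reported the latter under the name "false positive rate" (e.g.
#' 1 FP among 48 positive calls reported as 0.021), so both are exposed and
#' clearly labeled; use \code{fpr_reported} when reproducing such tables.
#' Metrics with zero denominators are \code{NA}.
#'
#' @param cm An \code{"azfc_confusion"} list (see
#'   \code{\link{confusionCounts}}) or a list with \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}.
#' @return List of class \code{"azfc_metrics"}: \code{sensitivity},
#'   \code{specificity}, \code{fpr_standard}, \code{fpr_reported}, plus the
#'   input cells. Values are full precision; \code{print} displays 3
#'   decimals.
#' @export
performanceMetrics <- function(cm) {
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
    n_failed = if (!is.null(cm$n_failed)) cm$n_failed else 0L,
    sensitivity = rate(cm$tp, cm$tp + cm$fn),
    specificity = rate(cm$tn, cm$tn + cm$fp),
    fpr_standard = rate(cm$fp, cm$fp + cm$tn),
    fpr_reported = rate(cm$fp, cm$fp + cm$tp)),
    class = "azfc_metrics")
}

#' @export
print.azfc_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d (failed: %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_failed))
  for (m in c("sensitivity", "specificity", "fpr_standard", "fpr_reported"))
    cat(sprintf("  %-13s %s\n", m,
                if (is.na(x[[m]])) "NA" else sprintf("%.3f", x[[m]])))
  invisible(x)
}

#' Benchmark report across coverage levels
#'
#' Assembles a benchmark-table-shaped \code{data.frame} (one column set per
#' condition) from named metrics objects, for writing as TSV.
#'
#' @param metrics_list Named list of \code{"azfc_metrics"} objects, one per
#'   condition (e.g. coverage level).
#' @return \code{data.frame} with one row per condition: confusion cells and
#'   all four metrics.
#' @export
metricsTable <- function(metrics_list) {
  out <- do.call(rbind, lapply(names(metrics_list), function(nm) {
    m <- metrics_list[[nm]]
    data.frame(condition = nm, tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
               n_failed = m$n_failed, sensitivity = m$sensitivity,
               specificity = m$specificity, fpr_standard = m$fpr_standard,
               fpr_reported = m$fpr_reported, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write metrics as JSON
#'
#' @param metrics An \code{"azfc_metrics"} object or named list of them.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeMetricsJSON <- function(metrics, path) {
  if (inherits(metrics, "azfc_metrics")) metrics <- list(metrics = metrics)
  jsonlite::write_json(lapply(metrics, unclass), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
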