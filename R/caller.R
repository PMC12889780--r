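#' Round a copy-number profile to an integer vector
#'
#' Nearest integer per class; exact halves round away from zero (so 2.5 -> 3,
#' not banker's rounding); negative noise floors at 0. Uses the centered
#' copy numbers when present, else the raw ones (single-sample mode must be
#' made explicit via \code{\link{skipCentering}}).
#'
#' @param profile A \linkS4class{CopyNumberProfile} with \code{centeredCN}
#'   present (or explicitly uncentered).
#' @return Named integer vector, class_id -> rounded copies.
#' @export
roundProfile <- function(profile) {
  cn <- if (length(centeredCN(profile))) centeredCN(profile) else {
    if (!"UNCENTERED" %in% profileFlags(profile))
      azfcError("azfc_uncentered",
                paste0("profile has no centered copy numbers; run ",
                       "medianCenter() or skipCentering() first"))
    rawCN(profile)
  }
  stats::setNames(roundHalfAway(cn), names(cn))
}

#' Call one sample against a signature catalog
#'
#' The rounded copy-number vector is looked up in the catalog by exact
#' match. The matched signature's category determines the status:
#' \code{REFERENCE -> GRGR_NEGATIVE}, \code{GRGR_DEL -> GRGR_POSITIVE},
#' \code{OTHER_CNV -> OTHER_AZFC_CNV}; a vector matching no signature is
#' also \code{OTHER_AZFC_CNV} (conservative: such samples are excluded from
#' association anyway). Profiles flagged \code{CALL_FAILED} (normalization
#' or coverage failure) yield a \code{CALL_FAILED} record, never an
#' exception.
#'
#' @param profile A \linkS4class{CopyNumberProfile}.
#' @param catalog A \linkS4class{SignatureCatalog} bound to the same
#'   definition set.
#' @return One-row \code{data.frame}: \code{sample_id}, \code{status},
#'   \code{matched_signature} (\code{NA} if none), \code{mode},
#'   \code{flags}, then one \code{cn_<class>} column per rounded class and
#'   one \code{raw_<class>} per raw estimate.
#' @export
callSample <- function(profile, catalog) {
  keys <- sort(names(signatures(catalog)[[1]]@copyVector))
  if ("CALL_FAILED" %in% profileFlags(profile)) {
    rounded <- stats::setNames(rep(NA_integer_, length(keys)), keys)
    raw <- stats::setNames(rep(NA_real_, length(keys)), keys)
    status <- "CALL_FAILED"
    matched <- NA_character_
  } else {
    rounded <- roundProfile(profile)[keys]
    raw <- rawCN(profile)[keys]
    sig <- lookupSignature(catalog, rounded)
    if (is.null(sig)) {
      status <- "OTHER_AZFC_CNV"
      matched <- NA_character_
    } else {
      status <- switch(sig@category,
                       REFERENCE = "GRGR_NEGATIVE",
                       GRGR_DEL = "GRGR_POSITIVE",
                       OTHER_CNV = "OTHER_AZFC_CNV")
      matched <- sig@name
    }
  }
  out <- data.frame(sample_id = sampleId(profile), status = status,
                    matched_signature = matched, mode = profile@mode,
                    flags = paste(profileFlags(profile), collapse = ";"),
                    stringsAsFactors = FALSE)
  out[paste0("cn_", keys)] <- as.list(rounded)
  out[paste0("raw_", keys)] <- as.list(raw)
  out
}

#' Call a median-centered cohort of profiles
#'
#' One call per input profile, order preserved; failures are encoded in the
#' \code{status} column, never raised. A per-status summary is emitted as a
#' message.
#'
#' @param profiles List of \linkS4class{CopyNumberProfile}, median-centered
#'   as a batch (see \code{\link{medianCenter}}).
#' @param catalog A \linkS4class{SignatureCatalog}.
#' @param verbose Emit the summary message; default TRUE.
#' @return \code{data.frame} of calls, one row per profile (zero rows for
#'   empty input); columns as in \code{\link{callSample}}.
#' @export
callCohort <- function(profiles, catalog, verbose = TRUE) {
  if (length(profiles) == 0L) {
    return(data.frame(sample_id = character(0), status = character(0),
                      matched_signature = character(0), mode = character(0),
                      flags = character(0), stringsAsFactors = FALSE))
  }
  calls <- do.call(rbind, lapply(profiles, callSample, catalog = catalog))
  rownames(calls) <- NULL
  if (verbose) {
    counts <- table(factor(calls$status,
                           levels = c("GRGR_POSITIVE", "GRGR_NEGATIVE",
                                      "OTHER_AZFC_CNV", "CALL_FAILED")))
    message(paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                  collapse = " "))
  }
  calls
}

#' Run the full cohort calling chain on bin-depth tables
#'
#' Convenience driver for the per-batch pipeline: summarize class depths,
#' estimate copy numbers, median-center across the batch, match signatures.
#' Samples whose control depth is zero (unnormalizable) become
#' \code{CALL_FAILED} records; the rest of the cohort is unaffected.
#'
#' @param tables List of bin-depth tables (one per sample).
#' @param architecture,catalog The bound definition set.
#' @param mode Copy-number mode, see \code{\link{estimateCopyNumbers}}.
#' @param center Median-center across the batch (default TRUE; FALSE uses
#'   \code{\link{skipCentering}}).
#' @param verbose Passed to \code{\link{callCohort}}.
#' @return \code{list(calls = data.frame, profiles = list)}.
#' @export
callDepthTables <- function(tables, architecture, catalog,
                            mode = "auto", center = TRUE, verbose = TRUE) {
  profiles <- lapply(tables, function(tab) {
    sid <- if (nrow(tab)) tab$sample_id[1] else "unknown"
    tryCatch(
      estimateCopyNumbers(summarizeClassDepths(tab), architecture,
                          sample_id = sid, mode = mode),
      azfc_normalization_error = function(e)
        methods::new("CopyNumberProfile", sampleId = sid, rawCN = numeric(0),
                     centeredCN = numeric(0), controlDepth = NA_real_,
                     mode = if (identical(mode, "auto")) "AGGREGATE" else mode,
                     flags = "CALL_FAILED"))
  })
  profiles <- if (center) medianCenter(profiles, architecture)
              else skipCentering(profiles)
  list(calls = callCohort(profiles, catalog, verbose = verbose),
       profiles = profiles)
}

#' Build the association-ready table from calls and a sample manifest
#'
#' Retains \code{GRGR_POSITIVE} (carrier = 1) and \code{GRGR_NEGATIVE}
#' (carrier = 0) samples only; samples carrying other AZFc copy-number
#' states and failed samples are dropped, with counts reported (excluding
#' rarer CNV carriers avoids confounding if those CNVs associate with the
#' phenotype themselves). Samples whose histology equals
#' \code{histology_exclude} are retained overall but marked non-stratifiable
#' (column \code{histology_stratifiable}), so they drop out of
#' histology-stratified analyses only.
#'
#' @param calls Calls \code{data.frame} from \code{\link{callCohort}}.
#' @param manifest \code{data.frame} with \code{sample_id},
#'   \code{phenotype} (0/1), optional \code{histology} and covariate
#'   columns; must cover every called sample.
#' @param histology_exclude Histology label excluded from stratified
#'   outputs; default \code{"spermatocytic seminoma"}.
#' @return \code{list(table = data.frame(sample_id, carrier, phenotype,
#'   histology, histology_stratifiable, covariates...),
#'   excluded = c(OTHER_AZFC_CNV = n, CALL_FAILED = n))}.
#' @export
filterForAssociation <- function(calls, manifest,
                                 histology_exclude = "spermatocytic seminoma") {
  missing <- setdiff(calls$sample_id, manifest$sample_id)
  if (length(missing))
    azfcError("azfc_manifest_mismatch",
              sprintf("manifest lacks sample(s): %s",
                      paste(missing, collapse = ", ")))
  excluded <- c(OTHER_AZFC_CNV = sum(calls$status == "OTHER_AZFC_CNV"),
                CALL_FAILED = sum(calls$status == "CALL_FAILED"))
  keep <- calls[calls$status %in% c("GRGR_POSITIVE", "GRGR_NEGATIVE"),
                c("sample_id", "status")]
  keep$carrier <- as.integer(keep$status == "GRGR_POSITIVE")
  keep$status <- NULL
  tab <- merge(keep, manifest, by = "sample_id", sort = FALSE)
  if (!"histology" %in% colnames(tab)) tab$histology <- NA_character_
  tab$histology_stratifiable <- is.na(tab$histology) |
    tab$histology != histology_exclude
  front <- c("sample_id", "carrier", "phenotype", "histology",
             "histology_stratifiable")
  tab <- tab[, c(front, setdiff(colnames(tab), front)), drop = FALSE]
  list(table = tab, excluded = excluded)
}

#' Read / write call tables
#'
#' TSV with a provenance header, mirroring the \code{data.frame} returned
#' by \code{\link{callCohort}}.
#'
#' @param calls Calls \code{data.frame}.
#' @param path File path.
#' @param seed Seed recorded in the header (provenance only).
#' @return \code{readCalls}: the calls table; \code{writeCalls}: invisibly,
#'   \code{path}.
#' @export
writeCalls <- function(calls, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outputHeader(seed = seed), con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
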