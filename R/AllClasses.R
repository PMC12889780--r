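#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

#' AzfcArchitecture: amplicon-class definitions for a repeat region
#'
#' Describes the genomic architecture used for copy-number calling: a set of
#' amplicon classes (plus inverted-repeat classes treated identically), each
#' with a reference copy number and a set of non-overlapping genomic
#' intervals, and at least one single-copy control class used for depth
#' normalization. Intervals are stored as a \code{GRanges}; on disk the BED
#' convention (0-based half-open) is used.
#'
#' @slot intervals \code{GRanges} with a \code{class_id} metadata column.
#' @slot classes \code{data.frame} with columns \code{class_id},
#'   \code{reference_copies}, \code{is_control}.
#' @slot checksum Identifier binding signature catalogs to this definition
#'   set.
#' @export
setClass("AzfcArchitecture",
  slots = c(intervals = "GRanges", classes = "data.frame",
            checksum = "character"))

setValidity("AzfcArchitecture", function(object) {
  cls <- object@classes
  need <- c("class_id", "reference_copies", "is_control")
  if (!all(need %in% colnames(cls)))
    return(sprintf("classes must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(cls$class_id)) return("duplicate class_id in classes")
  if (any(cls$reference_copies < 1) ||
      any(cls$reference_copies != round(cls$reference_copies)))
    return("reference_copies must be positive integers")
  if (!any(cls$is_control)) return("no control class (is_control = TRUE)")
  iv <- object@intervals
  if (!"class_id" %in% colnames(S4Vectors::mcols(iv)))
    return("intervals must carry a class_id metadata column")
  if (any(GenomicRanges::width(iv) < 1)) return("interval with end <= start")
  if (!all(S4Vectors::mcols(iv)$class_id %in% cls$class_id))
    return("interval class_id absent from classes table")
  for (cid in unique(S4Vectors::mcols(iv)$class_id)) {
    sub <- iv[S4Vectors::mcols(iv)$class_id == cid]
    if (length(IRanges::findOverlaps(sub, drop.self = TRUE)) > 0)
      return(sprintf("overlapping intervals within class '%s'", cid))
  }
  TRUE
})

#' ArchitectureSignature: one expected integer copy-number state
#'
#' A named integer copy-number vector over the non-control classes of an
#' architecture, together with its biological category: \code{REFERENCE}
#' (the wild-type architecture), \code{GRGR_DEL} (the gr/gr deletion
#' signature), or \code{OTHER_CNV} (any other copy-number state worth
#' recognizing, e.g. large deletions or duplications).
#'
#' @slot name Signature label.
#' @slot category One of \code{"REFERENCE"}, \code{"GRGR_DEL"},
#'   \code{"OTHER_CNV"}.
#' @slot copyVector Named integer vector, class_id -> expected copies (>= 0).
#' @export
setClass("ArchitectureSignature",
  slots = c(name = "character", category = "character",
            copyVector = "integer"))

setValidity("ArchitectureSignature", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (!object@category %in% c("REFERENCE", "GRGR_DEL", "OTHER_CNV"))
    return("category must be REFERENCE, GRGR_DEL or OTHER_CNV")
  if (is.null(names(object@copyVector)) || anyDuplicated(names(object@copyVector)))
    return("copyVector must have unique names")
  if (any(object@copyVector < 0)) return("copy numbers must be >= 0")
  TRUE
})

#' SignatureCatalog: the set of recognizable copy-number states
#'
#' Holds the signatures matched against rounded copy-number profiles.
#' A valid catalog has exactly one \code{REFERENCE} signature, pairwise
#' distinct copy vectors (matching is unambiguous), and identical key sets
#' across all signatures. The checksum binds the catalog to the
#' \linkS4class{AzfcArchitecture} it was validated against.
#'
#' @slot signatures Named list of \linkS4class{ArchitectureSignature}.
#' @slot checksum Checksum of the bound definition set.
#' @export
setClass("SignatureCatalog",
  slots = c(signatures = "list", checksum = "character"))

setValidity("SignatureCatalog", function(object) {
  sigs <- object@signatures
  if (length(sigs) == 0L) return("catalog has no signatures")
  if (!all(vapply(sigs, is, logical(1), "ArchitectureSignature")))
    return("signatures must be ArchitectureSignature objects")
  cats <- vapply(sigs, slot, character(1), "category")
  if (sum(cats == "REFERENCE") != 1L)
    return("catalog must contain exactly one REFERENCE signature")
  keysets <- lapply(sigs, function(s) sort(names(s@copyVector)))
  if (length(unique(keysets)) != 1L)
    return("all signatures must cover the same class_ids")
  keys <- keysets[[1L]]
  vecs <- vapply(sigs, function(s) paste(s@copyVector[keys], collapse = ","),
                 character(1))
  if (anyDuplicated(vecs))
    return("duplicate copy vectors: signature matching would be ambiguous")
  TRUE
})

#' CopyNumberProfile: per-sample class-level copy-number estimates
#'
#' Raw copy numbers are reference_copies * depth ratio against the control
#' class; centered copy numbers appear after cohort median centering (or
#' after an explicit single-sample passthrough) and are what the caller
#' rounds and matches.
#'
#' @slot sampleId Sample identifier.
#' @slot rawCN Named numeric, class_id -> raw copy-number estimate.
#' @slot centeredCN Named numeric; length 0 until centering.
#' @slot controlDepth Depth of the control class used for normalization.
#' @slot mode \code{"MEDIAN_BIN"} or \code{"AGGREGATE"}.
#' @slot flags Character vector of processing flags (e.g. \code{"UNCENTERED"},
#'   \code{"CALL_FAILED"}).
#' @export
setClass("CopyNumberProfile",
  slots = c(sampleId = "character", rawCN = "numeric", centeredCN = "numeric",
            controlDepth = "numeric", mode = "character", flags = "character"))

setValidity("CopyNumberProfile", function(object) {
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  failed <- "CALL_FAILED" %in% object@flags
  if (!failed) {
    if (is.null(names(object@rawCN)) || length(object@rawCN) == 0L)
      return("rawCN must be a non-empty named vector")
    if (any(!is.finite(object@rawCN)) || any(object@rawCN < 0))
      return("rawCN must be finite and non-negative")
    if (!is.finite(object@controlDepth) || object@controlDepth <= 0)
      return("controlDepth must be > 0")
  }
  if (!object@mode %in% c("MEDIAN_BIN", "AGGREGATE"))
    return("mode must be MEDIAN_BIN or AGGREGATE")
  if (length(object@centeredCN) &&
      !identical(names(object@centeredCN), names(object@rawCN)))
    return("centeredCN names must match rawCN names")
  TRUE
})

setMethod("show", "AzfcArchitecture", function(object) {
  cls <- object@classes
  cat(sprintf("AzfcArchitecture: %d classes (%d control), %d intervals, checksum %s\n",
              nrow(cls), sum(cls$is_control), length(object@intervals),
              object@checksum))
  for (i in seq_len(nrow(cls))) {
    sub <- object@intervals[
      S4Vectors::mcols(object@intervals)$class_id == cls$class_id[i]]
    cat(sprintf("  %-8s x%d %s| %d interval(s), %s bp\n", cls$class_id[i],
                cls$reference_copies[i],
                if (cls$is_control[i]) "(control) " else "",
                length(sub), format(sum(GenomicRanges::width(sub)),
                                    big.mark = ",")))
  }
})

setMethod("show", "SignatureCatalog", function(object) {
  cat(sprintf("SignatureCatalog: %d signatures (checksum %s)\n",
              length(object@signatures), object@checksum))
  for (s in object@signatures) {
    cat(sprintf("  %-12s [%s] %s\n", s@name, s@category,
                paste(sprintf("%s=%d", names(s@copyVector), s@copyVector),
                      collapse = " ")))
  }
})

setMethod("show", "CopyNumberProfile", function(object) {
  cat(sprintf("CopyNumberProfile for %s (mode %s, control depth %.3g)\n",
              object@sampleId, object@mode, object@controlDepth))
  fmt <- function(v) paste(sprintf("%s=%.2f", names(v), v), collapse = " ")
  cat("  raw:      ", fmt(object@rawCN), "\n")
  if (length(object@centeredCN)) cat("  centered: ", fmt(object@centeredCN), "\n")
  if (length(object@flags)) cat("  flags:    ", paste(object@flags, collapse = ","), "\n")
})
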