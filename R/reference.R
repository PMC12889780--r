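#' Construct an amplicon-class architecture
#'
#' Builds and validates an \linkS4class{AzfcArchitecture} from an interval
#' table and a class table. This is the programmatic route; use
#' \code{\link{loadDefinitions}} to read the on-disk BED + JSON pair.
#'
#' @param intervals Either a \code{GRanges} with a \code{class_id} metadata
#'   column, or a \code{data.frame} with columns \code{contig}, \code{start},
#'   \code{end} (0-based half-open, BED convention) and \code{class_id}.
#' @param classes \code{data.frame} with columns \code{class_id},
#'   \code{reference_copies}, \code{is_control}.
#' @return A validated \linkS4class{AzfcArchitecture}.
#' @examples
#' arch <- azfcArchitecture(
#'   data.frame(contig = "chrT", start = c(0, 5000, 9000),
#'              end = c(3500, 8000, 12000),
#'              class_id = c("ctrl", "green", "red")),
#'   data.frame(class_id = c("ctrl", "green", "red"),
#'              reference_copies = c(1L, 3L, 4L),
#'              is_control = c(TRUE, FALSE, FALSE)))
#' classIds(arch, control = FALSE)
#' @export
azfcArchitecture <- function(intervals, classes) {
  if (is.data.frame(intervals)) {
    intervals <- GenomicRanges::GRanges(
      seqnames = intervals$contig,
      ranges = IRanges::IRanges(start = intervals$start + 1L,
                                end = intervals$end),
      class_id = intervals$class_id)
  }
  classes <- as.data.frame(classes, stringsAsFactors = FALSE)
  classes$reference_copies <- as.integer(classes$reference_copies)
  classes$is_control <- as.logical(classes$is_control)

  # raise named conditions for the failure modes callers branch on;
  # everything else is caught by the validity method
  if (!any(classes$is_control))
    azfcError("azfc_missing_control",
              "definition set has no control class (is_control = TRUE)")
  bad <- setdiff(unique(S4Vectors::mcols(intervals)$class_id), classes$class_id)
  if (length(bad))
    azfcError("azfc_unknown_class",
              sprintf("interval class_id not declared in config: %s",
                      paste(bad, collapse = ", ")))
  for (cid in unique(S4Vectors::mcols(intervals)$class_id)) {
    sub <- intervals[S4Vectors::mcols(intervals)$class_id == cid]
    if (length(IRanges::findOverlaps(sub, drop.self = TRUE)) > 0)
      azfcError("azfc_interval_overlap",
                sprintf("overlapping intervals within class '%s'", cid))
  }

  obj <- new("AzfcArchitecture", intervals = intervals, classes = classes,
             checksum = "")
  obj@checksum <- contentChecksum(list(
    as.data.frame(intervals), classes))
  methods::validObject(obj)
  obj
}

#' Construct one architecture signature
#'
#' @param name Signature label.
#' @param category \code{"REFERENCE"}, \code{"GRGR_DEL"} or
#'   \code{"OTHER_CNV"}.
#' @param copy_vector Named vector of expected integer copy numbers over the
#'   non-control classes.
#' @return An \linkS4class{ArchitectureSignature}.
#' @export
architectureSignature <- function(name, category, copy_vector) {
  stopifnotNamed(copy_vector, "copy_vector")
  cv <- as.integer(copy_vector)
  names(cv) <- names(copy_vector)
  methods::new("ArchitectureSignature", name = name, category = category,
               copyVector = cv)
}

#' Assemble and validate a signature catalog against an architecture
#'
#' Enforces the catalog contract: exactly one \code{REFERENCE} signature
#' whose copy vector equals the architecture's reference copies; all
#' signatures keyed by exactly the non-control class ids; pairwise distinct
#' copy vectors so matching is unambiguous.
#'
#' @param sigs List of \linkS4class{ArchitectureSignature}.
#' @param architecture The \linkS4class{AzfcArchitecture} the catalog binds
#'   to.
#' @return A \linkS4class{SignatureCatalog} stamped with the architecture's
#'   checksum.
#' @export
signatureCatalog <- function(sigs, architecture) {
  expected <- sort(classIds(architecture, control = FALSE))
  for (s in sigs) {
    if (!identical(sort(names(s@copyVector)), expected))
      azfcError("azfc_key_mismatch",
                sprintf("signature '%s' keys do not match non-control classes (%s)",
                        s@name, paste(expected, collapse = ", ")))
  }
  vecs <- vapply(sigs, function(s) paste(s@copyVector[expected], collapse = ","),
                 character(1))
  if (anyDuplicated(vecs))
    azfcError("azfc_duplicate_signature",
              sprintf("signatures share a copy vector: %s",
                      paste(vapply(sigs, slot, character(1), "name")[
                        duplicated(vecs) | duplicated(vecs, fromLast = TRUE)],
                        collapse = ", ")))
  cats <- vapply(sigs, slot, character(1), "category")
  if (sum(cats == "REFERENCE") != 1L)
    azfcError("azfc_missing_reference",
              "catalog must contain exactly one REFERENCE signature")
  refsig <- sigs[[which(cats == "REFERENCE")]]
  refcp <- referenceCopies(architecture, control = FALSE)
  if (!all(refsig@copyVector[names(refcp)] == refcp))
    azfcError("azfc_reference_mismatch",
              "REFERENCE signature copy vector must equal reference_copies")
  names(sigs) <- vapply(sigs, slot, character(1), "name")
  obj <- methods::new("SignatureCatalog", signatures = sigs,
                      checksum = definitionChecksum(architecture))
  methods::validObject(obj)
  obj
}

#' Load an architecture and signature catalog from BED + JSON
#'
#' The BED file (tab-separated, 0-based half-open; column 4 = class_id)
#' supplies the intervals; the JSON config declares per-class reference
#' copies and control status, and the signature catalog. All structural
#' invariants are enforced on load; violations raise distinct named
#' conditions (\code{azfc_missing_control}, \code{azfc_unknown_class},
#' \code{azfc_interval_overlap}, \code{azfc_duplicate_signature},
#' \code{azfc_key_mismatch}).
#'
#' @param bed_path Path to the interval BED file.
#' @param config_path Path to the JSON config.
#' @return \code{list(architecture = AzfcArchitecture,
#'   catalog = SignatureCatalog)}.
#' @seealso \code{\link{writeDefinitions}} for the inverse,
#'   \code{\link{loadDefaultDefinitions}} for the packaged AZFc files.
#' @export
loadDefinitions <- function(bed_path, config_path) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (!"name" %in% colnames(S4Vectors::mcols(gr)) ||
      any(is.na(S4Vectors::mcols(gr)$name)))
    azfcError("azfc_unknown_class",
              "BED file must carry the class label in column 4")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    class_id = S4Vectors::mcols(gr)$name)

  cfg <- jsonlite::fromJSON(config_path, simplifyVector = FALSE)
  if (is.null(cfg$classes) || is.null(cfg$signatures))
    azfcError("azfc_config_error", "config must declare 'classes' and 'signatures'")
  classes <- data.frame(
    class_id = names(cfg$classes),
    reference_copies = vapply(cfg$classes, function(x)
      as.integer(x$reference_copies), integer(1)),
    is_control = vapply(cfg$classes, function(x)
      isTRUE(x$is_control), logical(1)),
    stringsAsFactors = FALSE)
  arch <- azfcArchitecture(gr, classes)

  sigs <- lapply(cfg$signatures, function(s)
    architectureSignature(s$name, s$category, unlist(s$copy_vector)))
  catalog <- signatureCatalog(sigs, arch)
  list(architecture = arch, catalog = catalog)
}

#' Write an architecture and catalog back to BED + JSON
#'
#' Inverse of \code{\link{loadDefinitions}}; a written pair reloads to
#' identical structures (round-trip property).
#'
#' @param architecture An \linkS4class{AzfcArchitecture}.
#' @param catalog The bound \linkS4class{SignatureCatalog}.
#' @param bed_path,config_path Output paths.
#' @return Invisibly, the two paths.
#' @export
writeDefinitions <- function(architecture, catalog, bed_path, config_path) {
  gr <- classIntervals(architecture)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(gr)$class_id)
  rtracklayer::export(gr, bed_path, format = "BED")

  cls <- architecture@classes
  cfg <- list(
    classes = stats::setNames(lapply(seq_len(nrow(cls)), function(i)
      list(reference_copies = cls$reference_copies[i],
           is_control = cls$is_control[i])), cls$class_id),
    signatures = lapply(signatures(catalog), function(s)
      list(name = s@name, category = s@category,
           copy_vector = as.list(s@copyVector))))
  jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(bed = bed_path, config = config_path))
}

#' Paths to the packaged AZFc definition files
#'
#' The shipped files describe the human Y-chromosome AZFc region: six
#' amplicon classes named by colors, two inverted-repeat classes quantified
#' identically, and a single-copy X-degenerate control region, with a
#' catalog containing the wild-type reference, the gr/gr deletion signature
#' and further recognized copy-number states. Coordinates are an approximate
#' transcription of the published architecture onto GRCh38 chrY and are
#' configuration (editable data), not code.
#'
#' @return Named character vector with elements \code{bed} and \code{config}.
#' @export
defaultDefinitionFiles <- function() {
  c(bed = system.file("extdata", "azfc_grch38.bed", package = "azfcCaller",
                      mustWork = TRUE),
    config = system.file("extdata", "azfc_catalog.json", package = "azfcCaller",
                         mustWork = TRUE))
}

#' Load the packaged AZFc definition set
#'
#' @return \code{list(architecture, catalog)}; see
#'   \code{\link{defaultDefinitionFiles}}.
#' @export
loadDefaultDefinitions <- function() {
  p <- defaultDefinitionFiles()
  loadDefinitions(p[["bed"]], p[["config"]])
}

#' Look up a copy-number vector in a signature catalog
#'
#' Exact-match lookup: returns the unique signature whose copy vector equals
#' \code{vector} in every class, or \code{NULL} when no signature matches.
#' There is no distance threshold; near-misses are deliberately unmatched
#' (the caller maps them to \code{OTHER_AZFC_CNV}).
#'
#' @param catalog A \linkS4class{SignatureCatalog}.
#' @param vector Named integer vector, class_id -> copies; keys must match
#'   the catalog's classes exactly.
#' @return An \linkS4class{ArchitectureSignature} or \code{NULL}.
#' @export
lookupSignature <- function(catalog, vector) {
  stopifnotNamed(vector, "vector")
  keys <- sort(names(signatures(catalog)[[1]]@copyVector))
  if (!identical(sort(names(vector)), keys))
    azfcError("azfc_key_mismatch",
              sprintf("vector keys must be exactly: %s",
                      paste(keys, collapse = ", ")))
  for (s in signatures(catalog)) {
    if (all(s@copyVector[keys] == vector[keys])) return(s)
  }
  NULL
}
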