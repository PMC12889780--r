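#' @rdname accessors
#' @export
setGeneric("classIds", function(x, ...) standardGeneric("classIds"))

#' @rdname accessors
#' @export
setGeneric("referenceCopies", function(x, ...) standardGeneric("referenceCopies"))

#' @rdname accessors
#' @export
setGeneric("controlClasses", function(x) standardGeneric("controlClasses"))

#' @rdname accessors
#' @export
setGeneric("classIntervals", function(x, ...) standardGeneric("classIntervals"))

#' @rdname accessors
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' @rdname accessors
#' @export
setGeneric("definitionChecksum", function(x) standardGeneric("definitionChecksum"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("rawCN", function(x) standardGeneric("rawCN"))

#' @rdname accessors
#' @export
setGeneric("centeredCN", function(x) standardGeneric("centeredCN"))

#' @rdname accessors
#' @export
setGeneric("profileFlags", function(x) standardGeneric("profileFlags"))

#' Accessors for azfcCaller S4 classes
#'
#' Small read-only accessors for \linkS4class{AzfcArchitecture},
#' \linkS4class{SignatureCatalog} and \linkS4class{CopyNumberProfile}
#' objects; user code should use these rather than reaching into slots.
#'
#' @param x An azfcCaller S4 object.
#' @param ... For \code{classIds}: \code{control} (\code{NA} = all classes,
#'   \code{TRUE}/\code{FALSE} to restrict); for \code{classIntervals}: a
#'   \code{class_id} to subset to.
#' @return \code{classIds}, \code{controlClasses}: character vectors.
#'   \code{referenceCopies}: named integer vector. \code{classIntervals}: a
#'   \code{GRanges}. \code{signatures}: named list of
#'   \linkS4class{ArchitectureSignature}. \code{rawCN}, \code{centeredCN}:
#'   named numerics. \code{sampleId}, \code{definitionChecksum}: strings.
#'   \code{profileFlags}: character vector.
#' @name accessors
#' @aliases classIds referenceCopies controlClasses classIntervals signatures
#'   definitionChecksum sampleId rawCN centeredCN profileFlags
NULL

#' @rdname accessors
setMethod("classIds", "AzfcArchitecture", function(x, control = NA) {
  cls <- x@classes
  if (is.na(control)) return(cls$class_id)
  cls$class_id[cls$is_control == control]
})

#' @rdname accessors
setMethod("referenceCopies", "AzfcArchitecture", function(x, control = NA) {
  ids <- classIds(x, control = control)
  out <- as.integer(x@classes$reference_copies)
  names(out) <- x@classes$class_id
  out[ids]
})

#' @rdname accessors
setMethod("controlClasses", "AzfcArchitecture",
          function(x) classIds(x, control = TRUE))

#' @rdname accessors
setMethod("classIntervals", "AzfcArchitecture", function(x, class_id = NULL) {
  iv <- x@intervals
  if (is.null(class_id)) return(iv)
  iv[S4Vectors::mcols(iv)$class_id %in% class_id]
})

#' @rdname accessors
setMethod("signatures", "SignatureCatalog", function(x) x@signatures)

#' @rdname accessors
setMethod("definitionChecksum", "AzfcArchitecture", function(x) x@checksum)

#' @rdname accessors
setMethod("definitionChecksum", "SignatureCatalog", function(x) x@checksum)

#' @rdname accessors
setMethod("sampleId", "CopyNumberProfile", function(x) x@sampleId)

#' @rdname accessors
setMethod("rawCN", "CopyNumberProfile", function(x) x@rawCN)

#' @rdname accessors
setMethod("centeredCN", "CopyNumberProfile", function(x) x@centeredCN)

#' @rdname accessors
setMethod("profileFlags", "CopyNumberProfile", function(x) x@flags)
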