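#' Tile architecture intervals with fixed-size bins
#'
#' Each interval is tiled left-to-right with bins of exactly
#' \code{bin_size} bases; a trailing partial bin is kept iff its length is
#' at least \code{bin_size / 2}, otherwise dropped. A class whose intervals
#' yield zero bins is a validation error (it could never be quantified).
#'
#' @param architecture An \linkS4class{AzfcArchitecture}.
#' @param bin_size Bin width in bases, >= 100. Default 1000: at ultra-low
#'   (~0.7X) aggregate coverage this still leaves several expected reads per
#'   bin while giving tens of bins per class.
#' @return A \code{GRanges} of bins with a \code{class_id} metadata column.
#' @examples
#' arch <- azfcArchitecture(
#'   data.frame(contig = "chrT", start = 0, end = 3500, class_id = "ctrl"),
#'   data.frame(class_id = "ctrl", reference_copies = 1L, is_control = TRUE))
#' width(makeBins(arch, 1000))  # 1000 1000 1000 500: partial bin kept
#' @export
makeBins <- function(architecture, bin_size = 1000L) {
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 100L)
    azfcError("azfc_config_error", "bin_size must be an integer >= 100")
  iv <- classIntervals(architecture)
  pieces <- lapply(seq_along(iv), function(i) {
    s <- GenomicRanges::start(iv)[i]   # 1-based inclusive
    e <- GenomicRanges::end(iv)[i]
    len <- e - s + 1L
    n_full <- len %/% bin_size
    rem <- len - n_full * bin_size
    keep_partial <- rem >= bin_size / 2
    n <- n_full + keep_partial
    if (n == 0L) return(NULL)
    starts <- s + bin_size * (seq_len(n) - 1L)
    ends <- pmin(starts + bin_size - 1L, e)
    if (!keep_partial && rem > 0L) ends[n] <- starts[n] + bin_size - 1L
    GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(iv))[i],
      ranges = IRanges::IRanges(start = starts, end = ends),
      class_id = S4Vectors::mcols(iv)$class_id[i])
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  bins <- do.call(c, pieces)
  empty <- setdiff(classIds(architecture),
                   unique(S4Vectors::mcols(bins)$class_id))
  if (length(empty))
    azfcError("azfc_empty_class",
              sprintf("class(es) with zero bins at bin_size %d: %s",
                      bin_size, paste(empty, collapse = ", ")))
  bins
}

#' Mean per-base depth per bin from a per-base depth table
#'
#' Positions absent from the source count as depth 0, so
#' \code{mean_depth = sum(depth over covered positions in bin) / bin width}.
#'
#' @param depth_source \code{data.frame} with columns \code{contig},
#'   \code{pos} (0-based) and \code{depth}; sparse (zero-depth positions may
#'   be omitted).
#' @param bins \code{GRanges} from \code{\link{makeBins}}.
#' @param sample_id Sample identifier recorded in the output.
#' @return A bin-depth table: \code{data.frame} with columns \code{contig},
#'   \code{start}, \code{end} (0-based half-open), \code{class_id},
#'   \code{mean_depth}, \code{sample_id}.
#' @export
computeBinDepths <- function(depth_source, bins, sample_id = "sample") {
  need <- c("contig", "pos", "depth")
  if (!all(need %in% colnames(depth_source)))
    azfcError("azfc_config_error",
              "depth_source needs columns contig, pos, depth")
  missing_ctg <- setdiff(
    unique(as.character(GenomicRanges::seqnames(bins))),
    unique(as.character(depth_source$contig)))
  if (length(missing_ctg))
    azfcError("azfc_missing_contig",
              sprintf("depth source lacks contig(s): %s",
                      paste(missing_ctg, collapse = ", ")))
  pos <- GenomicRanges::GRanges(
    seqnames = depth_source$contig,
    ranges = IRanges::IRanges(start = depth_source$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(pos, bins)
  total <- rep(0, length(bins))
  agg <- rowsum(depth_source$depth[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits))
  total[as.integer(rownames(agg))] <- agg[, 1]
  binDepthTable(bins, total / GenomicRanges::width(bins), sample_id)
}

# assemble the canonical bin-depth data.frame from bins + per-bin means
binDepthTable <- function(bins, mean_depth, sample_id) {
  data.frame(
    contig = as.character(GenomicRanges::seqnames(bins)),
    start = GenomicRanges::start(bins) - 1L,
    end = GenomicRanges::end(bins),
    class_id = S4Vectors::mcols(bins)$class_id,
    mean_depth = as.numeric(mean_depth),
    sample_id = sample_id,
    stringsAsFactors = FALSE)
}

#' Summarize bin depths per class
#'
#' Computes, for every class present, the median of bin mean depths
#' (\code{MEDIAN_BIN} statistic), the aggregate depth (total read-bases over
#' total bin length, \code{AGGREGATE} statistic) and the bin count. Both
#' statistics are always computed; mode selection happens downstream in
#' \code{\link{estimateCopyNumbers}}.
#'
#' @param table A bin-depth table (see \code{\link{computeBinDepths}}).
#' @return \code{data.frame} with columns \code{class_id}, \code{n_bins},
#'   \code{median_bin_depth}, \code{aggregate_depth}.
#' @export
summarizeClassDepths <- function(table) {
  if (nrow(table) == 0L)
    azfcError("azfc_config_error", "empty bin-depth table")
  if (any(!is.finite(table$mean_depth)) || any(table$mean_depth < 0))
    azfcError("azfc_config_error", "depths must be finite and non-negative")
  len <- table$end - table$start
  split_idx <- split(seq_len(nrow(table)), table$class_id)
  out <- do.call(rbind, lapply(names(split_idx), function(cid) {
    i <- split_idx[[cid]]
    data.frame(class_id = cid,
               n_bins = length(i),
               total_length = sum(len[i]),
               median_bin_depth = stats::median(table$mean_depth[i]),
               aggregate_depth = sum(table$mean_depth[i] * len[i]) / sum(len[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Estimate per-class copy numbers from class depth summaries
#'
#' For each non-control class \code{c},
#' \code{raw_cn[c] = reference_copies[c] * depth[c] / depth[control]}, where
#' \code{depth} is the statistic of the active mode. With \code{mode =
#' "auto"}, \code{AGGREGATE} is selected when the control aggregate depth is
#' below \code{aggregate_threshold} (per-bin medians are dominated by zeros
#' at ultra-low coverage), else \code{MEDIAN_BIN}; the choice is recorded in
#' the profile and overridable.
#'
#' @param class_summary Output of \code{\link{summarizeClassDepths}}.
#' @param architecture The \linkS4class{AzfcArchitecture}.
#' @param sample_id Sample identifier.
#' @param mode \code{"auto"}, \code{"MEDIAN_BIN"} or \code{"AGGREGATE"}.
#' @param aggregate_threshold Control aggregate depth below which auto mode
#'   selects \code{AGGREGATE}; default 2.0.
#' @return A \linkS4class{CopyNumberProfile} (uncentered). A control depth
#'   of zero raises condition \code{azfc_normalization_error}; cohort-level
#'   drivers catch it and emit a \code{CALL_FAILED} record instead.
#' @export
estimateCopyNumbers <- function(class_summary, architecture,
                                sample_id = "sample",
                                mode = c("auto", "MEDIAN_BIN", "AGGREGATE"),
                                aggregate_threshold = 2.0) {
  mode <- match.arg(mode)
  ctrl <- controlClasses(architecture)
  ctrl_rows <- class_summary[class_summary$class_id %in% ctrl, , drop = FALSE]
  if (nrow(ctrl_rows) == 0L)
    azfcError("azfc_missing_control", "no control class in depth summary")
  ctrl_agg <- sum(ctrl_rows$aggregate_depth * ctrl_rows$total_length) /
    sum(ctrl_rows$total_length)
  if (mode == "auto")
    mode <- if (ctrl_agg < aggregate_threshold) "AGGREGATE" else "MEDIAN_BIN"
  stat_col <- if (mode == "AGGREGATE") "aggregate_depth" else "median_bin_depth"
  ctrl_depth <- sum(ctrl_rows[[stat_col]] * ctrl_rows$total_length) /
    sum(ctrl_rows$total_length)
  if (!is.finite(ctrl_depth) || ctrl_depth <= 0)
    azfcError("azfc_normalization_error",
              sprintf("control depth is %s for sample %s: cannot normalize",
                      format(ctrl_depth), sample_id))
  refcp <- referenceCopies(architecture, control = FALSE)
  depths <- stats::setNames(class_summary[[stat_col]], class_summary$class_id)
  missing <- setdiff(names(refcp), names(depths))
  if (length(missing))
    azfcError("azfc_empty_class",
              sprintf("no depth for class(es): %s", paste(missing, collapse = ", ")))
  raw <- refcp * depths[names(refcp)] / ctrl_depth
  methods::new("CopyNumberProfile", sampleId = sample_id, rawCN = raw,
               centeredCN = numeric(0), controlDepth = ctrl_depth,
               mode = mode, flags = character(0))
}

#' Cohort median centering of copy-number profiles
#'
#' Removes marker-specific multiplicative biases and batch effects: for each
#' class \code{c} and sample \code{s},
#' \code{centered_cn[c, s] = raw_cn[c, s] * reference_copies[c] /
#' median_s(raw_cn[c, .])}. This assumes carriers are a minority per class
#' (< 50\%) so the cohort median tracks the wild-type; a warning is issued
#' when any class's rounded cohort median differs from its reference copy
#' number. Classes whose cohort median is 0 are left uncentered and flagged.
#'
#' Fewer than \code{min_cohort} profiles is an error directing the caller to
#' \code{\link{skipCentering}} (single-sample mode): a median over one or
#' two samples would center each sample on itself.
#'
#' @param profiles List of \linkS4class{CopyNumberProfile}.
#' @param architecture The bound \linkS4class{AzfcArchitecture}.
#' @param min_cohort Minimum cohort size for centering; default 3.
#' @return The profiles with \code{centeredCN} filled in, order preserved;
#'   \code{CALL_FAILED} profiles pass through untouched and do not
#'   contribute to the medians.
#' @export
medianCenter <- function(profiles, architecture, min_cohort = 3L) {
  ok <- !vapply(profiles, function(p) "CALL_FAILED" %in% profileFlags(p),
                logical(1))
  if (sum(ok) < min_cohort)
    azfcError("azfc_small_cohort",
              sprintf(paste0("median centering needs >= %d profiles (got %d); ",
                             "use skipCentering() for single-sample mode"),
                      min_cohort, sum(ok)))
  refcp <- referenceCopies(architecture, control = FALSE)
  raw <- do.call(rbind, lapply(profiles[ok], function(p)
    rawCN(p)[names(refcp)]))
  med <- apply(raw, 2, stats::median)
  if (any(roundHalfAway(med) != refcp))
    warning(sprintf(paste0("rounded cohort median differs from reference for ",
                           "class(es) %s: carrier-minority assumption may be ",
                           "violated"),
                    paste(names(refcp)[roundHalfAway(med) != refcp],
                          collapse = ", ")),
            call. = FALSE)
  uncenterable <- med == 0
  for (i in which(ok)) {
    p <- profiles[[i]]
    cc <- rawCN(p)[names(refcp)] * refcp / med
    cc[uncenterable] <- rawCN(p)[names(refcp)][uncenterable]
    p@centeredCN <- cc
    if (any(uncenterable))
      p@flags <- union(p@flags, paste0("CENTERING_SKIPPED:",
                                       names(refcp)[uncenterable]))
    profiles[[i]] <- p
  }
  profiles
}

#' Single-sample passthrough in place of median centering
#'
#' Sets \code{centeredCN = rawCN} and records an \code{UNCENTERED} flag, for
#' cohorts too small to center (see \code{\link{medianCenter}}).
#'
#' @param profiles List of \linkS4class{CopyNumberProfile} (or one profile).
#' @return Profiles with \code{centeredCN} set and flagged.
#' @export
skipCentering <- function(profiles) {
  single <- methods::is(profiles, "CopyNumberProfile")
  if (single) profiles <- list(profiles)
  profiles <- lapply(profiles, function(p) {
    if (!"CALL_FAILED" %in% p@flags) {
      p@centeredCN <- p@rawCN
      p@flags <- union(p@flags, "UNCENTERED")
    }
    p
  })
  if (single) profiles[[1]] else profiles
}

#' Read / write bin-depth tables
#'
#' TSV dialect: columns \code{contig}, \code{start}, \code{end},
#' \code{class_id}, \code{mean_depth}, \code{sample_id}; 0-based half-open
#' coordinates; leading \code{#} comment lines carry provenance (tool
#' version, seed) and are ignored on read.
#'
#' @param table A bin-depth table.
#' @param path File path.
#' @param seed Seed recorded in the header (provenance only).
#' @return \code{readBinDepths}: the table; \code{writeBinDepths}:
#'   invisibly, \code{path}.
#' @export
writeBinDepths <- function(table, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outputHeader(seed = seed), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeBinDepths
#' @export
readBinDepths <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read a per-base depth TSV (columns contig, pos, depth; pos 0-based)
#'
#' @param path File path.
#' @return \code{data.frame} suitable for \code{\link{computeBinDepths}}.
#' @export
readPerBaseDepth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
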