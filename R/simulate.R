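#' A miniature AZFc-style architecture for simulation and testing
#'
#' Builds a scaled-down synthetic stand-in for the AZFc region on contig
#' \code{"chrY_mini"}: six amplicon classes named by colors (blue x4,
#' teal x2, green x3, red x4, gray x2, yellow x2), two inverted-repeat
#' classes (ir1 x2, ir2 x2) quantified identically, and a single-copy
#' control class. Each amplicon copy is one interval of \code{unit} bases,
#' laid out with gaps. The catalog holds the wild-type REFERENCE signature,
#' the gr/gr deletion signature (six amplicon copies lost: blue -1,
#' green -1, red -2, gray -1, yellow -1; IR dosage unchanged), and two
#' OTHER_CNV states (a gr/gr-region duplication and a full b2/b4-style
#' deletion).
#'
#' @param unit Length in bases of one amplicon copy interval; default
#'   30000 (about one tenth of real amplicon scale, keeping tens of 1-kb
#'   bins per class).
#' @param control_length Length of the single-copy control interval;
#'   default 1e5.
#' @return \code{list(architecture = AzfcArchitecture,
#'   catalog = SignatureCatalog)}.
#' @export
miniatureAzfcArchitecture <- function(unit = 30000L, control_length = 100000L) {
  copies <- c(blue = 4L, teal = 2L, green = 3L, red = 4L, gray = 2L,
              yellow = 2L, ir1 = 2L, ir2 = 2L)
  gap <- 5000L
  rows <- list(data.frame(contig = "chrY_mini", start = 0L,
                          end = control_length, class_id = "ctrl"))
  cursor <- control_length + gap
  for (cid in names(copies)) {
    for (k in seq_len(copies[[cid]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = "chrY_mini", start = cursor, end = cursor + unit,
        class_id = cid)
      cursor <- cursor + unit + gap
    }
  }
  intervals <- do.call(rbind, rows)
  classes <- data.frame(
    class_id = c("ctrl", names(copies)),
    reference_copies = c(1L, unname(copies)),
    is_control = c(TRUE, rep(FALSE, length(copies))))
  arch <- azfcArchitecture(intervals, classes)

  ref <- copies
  grgr <- ref + c(blue = -1L, teal = 0L, green = -1L, red = -2L, gray = -1L,
                  yellow = -1L, ir1 = 0L, ir2 = 0L)[names(ref)]
  dup <- ref + c(blue = 1L, teal = 0L, green = 1L, red = 2L, gray = 1L,
                 yellow = 1L, ir1 = 0L, ir2 = 0L)[names(ref)]
  b2b4 <- c(blue = 2L, teal = 2L, green = 0L, red = 0L, gray = 0L,
            yellow = 0L, ir1 = 1L, ir2 = 1L)[names(ref)]
  catalog <- signatureCatalog(list(
    architectureSignature("REFERENCE", "REFERENCE", ref),
    architectureSignature("GRGR_DEL", "GRGR_DEL", grgr),
    architectureSignature("GRGR_DUP", "OTHER_CNV", dup),
    architectureSignature("B2B4_DEL", "OTHER_CNV", b2b4)), arch)
  list(architecture = arch, catalog = catalog)
}

# expected copy ratio per bin for a given architecture state
copyRatioForBins <- function(bins, architecture, catalog, architecture_name) {
  sigs <- signatures(catalog)
  if (!architecture_name %in% names(sigs))
    azfcError("azfc_unknown_signature",
              sprintf("architecture '%s' not in catalog (have: %s)",
                      architecture_name, paste(names(sigs), collapse = ", ")))
  cv <- sigs[[architecture_name]]@copyVector
  refcp <- referenceCopies(architecture)
  cid <- S4Vectors::mcols(bins)$class_id
  ratio <- rep(1, length(bins))  # control classes stay at 1
  idx <- cid %in% names(cv)
  ratio[idx] <- cv[cid[idx]] / refcp[cid[idx]]
  ratio
}

#' Simulate a truth-labeled bin-depth table
#'
#' Per-bin read counts are Poisson with mean
#' \code{coverage * bin_length / read_length * (copies_c / reference_copies_c)
#' * class_bias_c}; \code{mean_depth = count * read_length / bin_length}.
#' \code{coverage} is the mean haploid depth, so a single-copy control bin
#' at coverage 30 has expected depth 30. Read placement is not simulated:
#' dosage enters only through the mean, consistent with depth-only calling.
#'
#' @param bins \code{GRanges} from \code{\link{makeBins}}.
#' @param architecture,catalog The definition set.
#' @param architecture_name Name of the signature whose copy state the
#'   sample carries (e.g. \code{"REFERENCE"}, \code{"GRGR_DEL"}).
#' @param coverage Mean haploid depth (X); > 0.
#' @param read_length Read length in bases; default 150.
#' @param class_bias Named multiplicative bias per class (marker-specific
#'   bias); classes absent default to 1. May include control classes.
#' @param sample_id Sample identifier.
#' @param seed Integer seed; \code{NULL} draws from the current RNG stream
#'   (used by \code{\link{simulateCohort}}, which seeds once).
#' @return A bin-depth table (see \code{\link{computeBinDepths}}), with
#'   attribute \code{read_length}.
#' @export
simulateDepths <- function(bins, architecture, catalog, architecture_name,
                           coverage, read_length = 150L, class_bias = NULL,
                           sample_id = "sim", seed = NULL) {
  if (coverage <= 0) azfcError("azfc_config_error", "coverage must be > 0")
  if (!is.null(class_bias)) {
    stopifnotNamed(class_bias, "class_bias")
    if (any(class_bias <= 0))
      azfcError("azfc_config_error", "class_bias must be positive")
  }
  ratio <- copyRatioForBins(bins, architecture, catalog, architecture_name)
  cid <- S4Vectors::mcols(bins)$class_id
  bias <- rep(1, length(bins))
  if (!is.null(class_bias)) {
    idx <- cid %in% names(class_bias)
    bias[idx] <- class_bias[cid[idx]]
  }
  w <- GenomicRanges::width(bins)
  lambda <- coverage * w / read_length * ratio * bias
  draw <- function() stats::rpois(length(lambda), lambda)
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tab <- binDepthTable(bins, counts * read_length / w, sample_id)
  attr(tab, "read_length") <- read_length
  tab
}

#' Binomial read thinning (downsampling) of a bin-depth table
#'
#' Emulates samtools-style read subsampling: each bin's read count is
#' thinned binomially with retention probability \code{p}, independently
#' across bins, and depths rescaled. Thinning a Poisson(lambda) count gives
#' Poisson(p * lambda), so a 7.4X simulation thinned at p = 0.1 has the
#' statistics of a direct 0.74X simulation.
#'
#' @param table A bin-depth table.
#' @param p Retention probability in [0, 1]; \code{p = 1} is the identity.
#' @param seed Integer seed; \code{NULL} uses the current RNG stream.
#' @param read_length Read length used to recover integer counts from
#'   depths; defaults to the table's \code{read_length} attribute, else 150.
#' @return The thinned bin-depth table.
#' @export
downsampleDepths <- function(table, p, seed = NULL, read_length = NULL) {
  if (p < 0 || p > 1)
    azfcError("azfc_config_error", "retention probability p must be in [0, 1]")
  if (is.null(read_length))
    read_length <- if (!is.null(attr(table, "read_length")))
      attr(table, "read_length") else 150L
  if (p == 1) return(table)
  w <- table$end - table$start
  counts <- as.integer(round(table$mean_depth * w / read_length))
  draw <- function() stats::rbinom(length(counts), counts, p)
  thinned <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  table$mean_depth <- thinned * read_length / w
  attr(table, "read_length") <- read_length
  table
}

#' Carrier frequency in cases implied by an odds ratio
#'
#' \code{p1 = OR * q / (1 - q + OR * q)} where \code{q} is the carrier
#' frequency in controls.
#'
#' @param q Carrier frequency among controls, in [0, 1].
#' @param odds_ratio Odds ratio; positive.
#' @return Carrier frequency among cases.
#' @examples
#' caseCarrierFreq(0.015, 2.1)  # 0.0310
#' @export
caseCarrierFreq <- function(q, odds_ratio) {
  if (q < 0 || q > 1 || odds_ratio <= 0)
    azfcError("azfc_config_error", "need 0 <= q <= 1 and odds_ratio > 0")
  p1 <- odds_ratio * q / (1 - q + odds_ratio * q)
  if (p1 > 1) azfcError("azfc_config_error", "infeasible carrier frequency > 1")
  p1
}

#' Simulate a truth-labeled case-control cohort
#'
#' Carrier labels are drawn per arm: controls carry the gr/gr state with
#' probability \code{carrier_freq_controls}, cases with the frequency
#' implied by \code{odds_ratio} (see \code{\link{caseCarrierFreq}}).
#' Non-carriers harbor an \code{OTHER_CNV} architecture (uniform over the
#' catalog's OTHER_CNV signatures) with probability \code{other_cnv_freq},
#' else the wild-type reference. One depth table per sample is generated
#' unless \code{depths = FALSE} (label-only mode, for large statistical
#' simulations where the depth layer is not under study).
#'
#' @param n_cases,n_controls Arm sizes.
#' @param carrier_freq_controls Carrier frequency among controls.
#' @param odds_ratio Target gr/gr-phenotype odds ratio.
#' @param other_cnv_freq Frequency of other AZFc CNVs among non-carriers;
#'   default 0.
#' @param coverage Mean haploid depth for the depth tables.
#' @param bins,architecture,catalog Definition set (required when
#'   \code{depths = TRUE}).
#' @param read_length,class_bias Passed to \code{\link{simulateDepths}}.
#' @param seed Mandatory integer seed; echoed into the manifest.
#' @param depths Generate depth tables (default TRUE).
#' @return \code{list(manifest = data.frame(sample_id, phenotype,
#'   architecture, arm, seed), tables = list of bin-depth tables or NULL)}.
#' @export
simulateCohort <- function(n_cases, n_controls, carrier_freq_controls,
                           odds_ratio, other_cnv_freq = 0, coverage = 30,
                           bins = NULL, architecture = NULL, catalog = NULL,
                           read_length = 150L, class_bias = NULL,
                           seed, depths = TRUE) {
  if (missing(seed)) azfcError("azfc_config_error", "seed is mandatory")
  if (other_cnv_freq < 0 || other_cnv_freq > 1)
    azfcError("azfc_config_error", "other_cnv_freq must be in [0, 1]")
  p1 <- caseCarrierFreq(carrier_freq_controls, odds_ratio)
  other_sigs <- character(0)
  if (!is.null(catalog)) {
    cats <- vapply(signatures(catalog), slot, character(1), "category")
    other_sigs <- names(signatures(catalog))[cats == "OTHER_CNV"]
  }
  if (other_cnv_freq > 0 && length(other_sigs) == 0L)
    azfcError("azfc_config_error",
              "other_cnv_freq > 0 needs a catalog with OTHER_CNV signatures")

  withr::with_seed(seed, {
    pheno <- c(rep(1L, n_cases), rep(0L, n_controls))
    freq <- ifelse(pheno == 1L, p1, carrier_freq_controls)
    carrier <- stats::rbinom(length(pheno), 1L, freq) == 1L
    archname <- ifelse(carrier, "GRGR_DEL", "REFERENCE")
    if (other_cnv_freq > 0) {
      oth <- !carrier & stats::rbinom(length(pheno), 1L, other_cnv_freq) == 1L
      archname[oth] <- sample(other_sigs, sum(oth), replace = TRUE)
    }
    manifest <- data.frame(
      sample_id = sprintf("S%05d", seq_along(pheno)),
      phenotype = pheno,
      architecture = archname,
      arm = ifelse(pheno == 1L, "case", "control"),
      seed = seed,
      stringsAsFactors = FALSE)
    tables <- NULL
    if (depths) {
      if (is.null(bins) || is.null(architecture) || is.null(catalog))
        azfcError("azfc_config_error",
                  "depths = TRUE needs bins, architecture and catalog")
      tables <- lapply(seq_len(nrow(manifest)), function(i)
        simulateDepths(bins, architecture, catalog,
                       architecture_name = manifest$architecture[i],
                       coverage = coverage, read_length = read_length,
                       class_bias = class_bias,
                       sample_id = manifest$sample_id[i], seed = NULL))
    }
    list(manifest = manifest, tables = tables)
  })
}

#' Write / read a cohort truth manifest
#'
#' TSV with provenance header: columns \code{sample_id}, \code{phenotype},
#' \code{architecture}, \code{arm}, \code{seed}.
#'
#' @param manifest Manifest \code{data.frame}.
#' @param path File path.
#' @return \code{readManifest}: the manifest; \code{writeManifest}:
#'   invisibly, \code{path}.
#' @export
writeManifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outputHeader(seed = manifest$seed[1]), con)
  utils::write.table(manifest, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
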