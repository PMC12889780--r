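#' Run one pipeline subcommand
#'
#' Orchestrates the analysis stages as composable subcommands communicating
#' through documented TSV/JSON files, so each stage is independently
#' testable and scriptable. A thin shell wrapper is installed at
#' \code{system.file("cli", "azfc-cnv.R", package = "azfcCaller")}.
#'
#' Subcommands and their flags (all file outputs carry a provenance
#' header):
#' \describe{
#'   \item{bins}{\code{--bed --config [--bin-size 1000] --out bins.tsv}:
#'     write the bin tiling.}
#'   \item{depth}{\code{--bed --config --per-base depth.tsv [--bin-size]
#'     [--sample id] --out bins_depth.tsv}: per-base depth to binned
#'     depth.}
#'   \item{call}{\code{--bed --config --depths f1.tsv,f2.tsv,...
#'     [--mode auto|MEDIAN_BIN|AGGREGATE] [--no-center] --out calls.tsv}:
#'     summarize, normalize, median-center as one batch, match signatures.}
#'   \item{simulate}{\code{--miniature --n-cases --n-controls --carrier-freq
#'     --odds-ratio [--other-cnv-freq 0] --coverage --seed --out-dir dir}:
#'     truth manifest plus one depth table per sample.}
#'   \item{downsample}{\code{--in t.tsv --p 0.1 --seed s --out t2.tsv}:
#'     binomial read thinning.}
#'   \item{evaluate}{\code{--truth manifest.tsv --calls calls.tsv --out
#'     metrics.json [--tsv report.tsv]}: confusion matrix and metrics.}
#'   \item{assoc}{\code{--counts a,b,c,d --out res.json} or \code{--table
#'     assoc.tsv [--covariates N] [--wald] --out res.json}: unadjusted 2x2
#'     and/or Firth-adjusted association.}
#'   \item{meta}{\code{--studies studies.tsv --out res.json}: fixed- and
#'     random-effects meta-analysis of a label/or/ci_low/ci_high table.}
#' }
#'
#' @param command Subcommand name.
#' @param args Character vector of \code{--flag value} arguments.
#' @return Invisibly, a list of the primary in-memory results; errors raise
#'   conditions (the shell wrapper converts them to exit status 1 and a
#'   \code{.FAILED} sentinel next to the requested output).
#' @export
runPipelineCommand <- function(command, args = character()) {
  opts <- parseArgv(args)
  get <- function(key, default = NULL) {
    if (!is.null(opts[[key]])) opts[[key]] else default
  }
  need <- function(key) {
    v <- opts[[key]]
    if (is.null(v)) azfcError("azfc_cli_error",
                              sprintf("%s: missing required --%s", command, key))
    v
  }
  loadDefs <- function() {
    if (isTRUE(get("miniature"))) miniatureAzfcArchitecture()
    else loadDefinitions(need("bed"), need("config"))
  }
  seed <- if (!is.null(get("seed"))) as.integer(get("seed")) else NA_integer_

  switch(command,
    bins = {
      defs <- loadDefs()
      bins <- makeBins(defs$architecture,
                       as.integer(get("bin-size", 1000L)))
      tab <- binDepthTable(bins, NA_real_, NA_character_)
      tab$mean_depth <- NULL
      tab$sample_id <- NULL
      out <- need("out")
      con <- file(out, "w"); on.exit(close(con))
      writeLines(outputHeader(), con)
      utils::write.table(tab, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      invisible(list(bins = bins))
    },
    depth = {
      defs <- loadDefs()
      bins <- makeBins(defs$architecture, as.integer(get("bin-size", 1000L)))
      tab <- computeBinDepths(readPerBaseDepth(need("per-base")), bins,
                              sample_id = get("sample", "sample"))
      writeBinDepths(tab, need("out"))
      invisible(list(table = tab))
    },
    call = {
      defs <- loadDefs()
      files <- strsplit(need("depths"), ",", fixed = TRUE)[[1]]
      tables <- lapply(files, readBinDepths)
      res <- callDepthTables(tables, defs$architecture, defs$catalog,
                             mode = get("mode", "auto"),
                             center = !isTRUE(get("no-center")),
                             verbose = FALSE)
      writeCalls(res$calls, need("out"))
      invisible(res)
    },
    simulate = {
      defs <- loadDefs()
      bins <- makeBins(defs$architecture, as.integer(get("bin-size", 1000L)))
      if (is.na(seed)) azfcError("azfc_cli_error", "simulate: --seed is mandatory")
      sim <- simulateCohort(
        n_cases = as.integer(need("n-cases")),
        n_controls = as.integer(need("n-controls")),
        carrier_freq_controls = as.numeric(need("carrier-freq")),
        odds_ratio = as.numeric(need("odds-ratio")),
        other_cnv_freq = as.numeric(get("other-cnv-freq", 0)),
        coverage = as.numeric(need("coverage")),
        bins = bins, architecture = defs$architecture,
        catalog = defs$catalog, seed = seed)
      dir <- need("out-dir")
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      writeManifest(sim$manifest, file.path(dir, "manifest.tsv"))
      for (i in seq_along(sim$tables))
        writeBinDepths(sim$tables[[i]],
                       file.path(dir, paste0(sim$manifest$sample_id[i],
                                             ".depth.tsv")), seed = seed)
      invisible(sim)
    },
    downsample = {
      if (is.na(seed)) azfcError("azfc_cli_error",
                                 "downsample: --seed is mandatory")
      tab <- downsampleDepths(readBinDepths(need("in")),
                              p = as.numeric(need("p")), seed = seed)
      writeBinDepths(tab, need("out"), seed = seed)
      invisible(list(table = tab))
    },
    evaluate = {
      truth <- readManifest(need("truth"))
      calls <- readCalls(need("calls"))
      met <- performanceMetrics(confusionCounts(truth, calls))
      writeMetricsJSON(met, need("out"))
      if (!is.null(get("tsv")))
        utils::write.table(metricsTable(list(run = met)), get("tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(list(metrics = met))
    },
    assoc = {
      out <- list()
      if (!is.null(get("counts"))) {
        cells <- as.numeric(strsplit(get("counts"), ",", fixed = TRUE)[[1]])
        if (length(cells) != 4L)
          azfcError("azfc_cli_error", "--counts needs a,b,c,d")
        out$unadjusted <- unclass(unadjustedOR(cells[1], cells[2], cells[3],
                                               cells[4]))
      }
      if (!is.null(get("table"))) {
        tab <- utils::read.table(get("table"), header = TRUE, sep = "\t",
                                 comment.char = "#", stringsAsFactors = FALSE)
        a <- sum(tab$carrier == 1 & tab$phenotype == 1)
        b <- sum(tab$carrier == 0 & tab$phenotype == 1)
        cc <- sum(tab$carrier == 1 & tab$phenotype == 0)
        d <- sum(tab$carrier == 0 & tab$phenotype == 0)
        out$unadjusted <- unclass(unadjustedOR(a, b, cc, d))
        fit <- assocWithCovariates(tab,
                                   n_covariates = as.integer(get("covariates", 0)),
                                   ci = if (isTRUE(get("wald"))) "wald"
                                        else "profile")
        out$adjusted <- list(or = fit$or_adjusted, ci95 = fit$or_ci95,
                             p = fit$or_p, ci_method = fit$ci_method,
                             coefficients = as.list(fit$coefficients),
                             converged = fit$converged, n_iter = fit$n_iter)
      }
      if (length(out) == 0L)
        azfcError("azfc_cli_error", "assoc: need --counts and/or --table")
      jsonlite::write_json(out, need("out"), auto_unbox = TRUE, digits = NA,
                           na = "null")
      invisible(out)
    },
    meta = {
      studies <- readStudies(need("studies"))
      res <- list(fixed = fixedEffect(studies),
                  random = randomEffects(studies))
      writeMetaJSON(res, need("out"))
      invisible(res)
    },
    azfcError("azfc_cli_error",
              sprintf(paste0("unknown subcommand '%s' (have: bins, depth, ",
                             "call, simulate, downsample, evaluate, assoc, ",
                             "meta)"), command))
  )
}
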