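test_that("makeBins tiles intervals with the half-bin partial rule", {
  arch1 <- azfcArchitecture(
    data.frame(contig = "chrT", start = 0L, end = 3500L, class_id = "ctrl"),
    data.frame(class_id = "ctrl", reference_copies = 1L, is_control = TRUE))
  b <- makeBins(arch1, 1000)
  expect_identical(GenomicRanges::width(b), c(1000L, 1000L, 1000L, 500L))

  arch2 <- azfcArchitecture(
    data.frame(contig = "chrT", start = 0L, end = 1400L, class_id = "ctrl"),
    data.frame(class_id = "ctrl", reference_copies = 1L, is_control = TRUE))
  b2 <- makeBins(arch2, 1000)
  expect_identical(GenomicRanges::width(b2), 1000L)  # trailing 400 dropped

  # a class whose intervals are all shorter than bin_size/2 has zero bins
  arch3 <- azfcArchitecture(
    data.frame(contig = "chrT", start = c(0L, 5000L), end = c(3500L, 5300L),
               class_id = c("ctrl", "green")),
    data.frame(class_id = c("ctrl", "green"), reference_copies = c(1L, 3L),
               is_control = c(TRUE, FALSE)))
  expect_error(makeBins(arch3, 1000), class = "azfc_empty_class")
  expect_error(makeBins(toyArchitecture(), 50), class = "azfc_config_error")
})

test_that("total tiled length matches a brute-force tiling oracle", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      lens <- sample(600:9000, 6)
      starts <- cumsum(c(0, head(lens, -1) + 500))
      arch <- azfcArchitecture(
        data.frame(contig = "chrT", start = starts, end = starts + lens,
                   class_id = "ctrl"),
        data.frame(class_id = "ctrl", reference_copies = 1L,
                   is_control = TRUE))
      b <- makeBins(arch, 1000)
      expect_identical(sum(GenomicRanges::width(b)),
                       as.integer(sum(vapply(lens, oracleTiledLength,
                                             numeric(1), bs = 1000))))
    }
  })
})

test_that("computeBinDepths averages per-base depth with absent bases as 0", {
  arch <- azfcArchitecture(
    data.frame(contig = "chrT", start = 0L, end = 2000L, class_id = "ctrl"),
    data.frame(class_id = "ctrl", reference_copies = 1L, is_control = TRUE))
  bins <- makeBins(arch, 1000)
  # uniform 10x everywhere
  uni <- data.frame(contig = "chrT", pos = 0:1999, depth = 10)
  expect_equal(computeBinDepths(uni, bins)$mean_depth, c(10, 10))
  # 10x over the first half of bin 1 only
  half <- data.frame(contig = "chrT", pos = 0:499, depth = 10)
  expect_equal(computeBinDepths(half, bins)$mean_depth, c(5, 0))
  # random depths vs direct summation oracle
  withr::with_seed(5, {
    d <- data.frame(contig = "chrT", pos = sample(0:1999, 900),
                    depth = rpois(900, 8))
  })
  got <- computeBinDepths(d, bins)$mean_depth
  want <- c(sum(d$depth[d$pos < 1000]) / 1000,
            sum(d$depth[d$pos >= 1000]) / 1000)
  expect_equal(got, want)
  expect_error(
    computeBinDepths(data.frame(contig = "chrZ", pos = 1, depth = 1), bins),
    class = "azfc_missing_contig")
})

test_that("class depth summaries: median, aggregate, and their agreement", {
  tab <- data.frame(contig = "chrT", start = c(0, 1000, 2000),
                    end = c(1000, 2000, 3000), class_id = "ctrl",
                    mean_depth = c(1, 2, 100), sample_id = "s")
  s <- summarizeClassDepths(tab)
  expect_equal(s$median_bin_depth, 2)  # robust to the outlier bin
  expect_equal(s$aggregate_depth, mean(c(1, 2, 100)))  # equal-length bins
  # both statistics agree on constant depth
  tab$mean_depth <- 7.5
  s2 <- summarizeClassDepths(tab)
  expect_equal(s2$median_bin_depth, s2$aggregate_depth)
})

test_that("copy numbers scale reference copies by the control depth ratio", {
  arch <- toyArchitecture()
  mk <- function(dg, dr, dc) data.frame(
    class_id = c("ctrl", "green", "red"), n_bins = c(10L, 10L, 10L),
    total_length = c(1e4, 1e4, 1e4), median_bin_depth = c(dc, dg, dr),
    aggregate_depth = c(dc, dg, dr))
  p <- estimateCopyNumbers(mk(10, 10, 10), arch, mode = "MEDIAN_BIN")
  expect_equal(unname(rawCN(p)["red"]), 4)     # depth ratio 1.0
  p2 <- estimateCopyNumbers(mk(10, 5, 10), arch, mode = "MEDIAN_BIN")
  expect_equal(unname(rawCN(p2)["red"]), 2)    # depth ratio 0.5
  expect_error(estimateCopyNumbers(mk(10, 10, 0), arch, mode = "MEDIAN_BIN"),
               class = "azfc_normalization_error")
  # auto mode: AGGREGATE at ultra-low control depth, MEDIAN_BIN otherwise
  expect_identical(estimateCopyNumbers(mk(1, 1, 0.7), arch)@mode, "AGGREGATE")
  expect_identical(estimateCopyNumbers(mk(10, 10, 10), arch)@mode,
                   "MEDIAN_BIN")
})

test_that("raw copy numbers recover generative values at 30X", {
  defs <- miniatureAzfcArchitecture()
  bins <- makeBins(defs$architecture, 1000)
  grgr <- signatures(defs$catalog)[["GRGR_DEL"]]@copyVector
  tab <- simulateDepths(bins, defs$architecture, defs$catalog, "GRGR_DEL",
                        coverage = 30, seed = 303)
  p <- estimateCopyNumbers(summarizeClassDepths(tab), defs$architecture)
  expect_lt(max(abs(rawCN(p)[names(grgr)] - grgr)), 0.2)
})

test_that("raw copy numbers are invariant to depth rescaling", {
  defs <- miniatureAzfcArchitecture()
  bins <- makeBins(defs$architecture, 1000)
  tab <- simulateDepths(bins, defs$architecture, defs$catalog, "REFERENCE",
                        coverage = 10, seed = 7)
  p1 <- estimateCopyNumbers(summarizeClassDepths(tab), defs$architecture,
                            mode = "AGGREGATE")
  tab$mean_depth <- tab$mean_depth * 3.7
  p2 <- estimateCopyNumbers(summarizeClassDepths(tab), defs$architecture,
                            mode = "AGGREGATE")
  expect_equal(rawCN(p1), rawCN(p2))
})

test_that("median centering removes per-class multiplicative bias", {
  arch <- toyArchitecture()
  # cohort of mostly wild-type samples; class red globally inflated x1.2
  withr::with_seed(21, {
    profs <- lapply(1:21, function(i) {
      cn <- c(green = 3, red = 4 * 1.2) * exp(rnorm(2, 0, 0.02))
      if (i <= 2) cn <- c(green = 2, red = 2 * 1.2)  # a couple of carriers
      makeProfile(cn, sprintf("s%02d", i), centered = FALSE, flags = NULL)
    })
  })
  profs <- lapply(profs, function(p) { p@flags <- character(0); p })
  cent <- suppressWarnings(medianCenter(profs, arch))  # x1.2 bias trips the
  # carrier-minority warning by design; centering is exactly what fixes it
  allred <- vapply(cent, function(p) centeredCN(p)[["red"]], numeric(1))
  # by construction of the formula the cohort median lands on the reference
  expect_equal(median(allred), 4, tolerance = 1e-9)
  # and wild-type samples sit near the reference despite the x1.2 bias
  wt <- allred[3:21]
  expect_lt(max(abs(wt - 4)), 0.3)
  # all-identical profiles center to the reference copies exactly
  same <- lapply(1:5, function(i)
    makeProfile(c(green = 3.3, red = 4.4), paste0("t", i), centered = FALSE,
                flags = character(0)))
  same <- lapply(same, function(p) { p@flags <- character(0); p })
  cent2 <- medianCenter(same, arch)
  expect_equal(unname(centeredCN(cent2[[1]])), c(3, 4))
})

test_that("centering warns when the carrier-minority assumption is violated", {
  arch <- toyArchitecture()
  # carriers in the majority: the cohort median tracks the deleted dosage
  profs <- lapply(1:9, function(i)
    makeProfile(if (i <= 6) c(green = 2, red = 2) else c(green = 3, red = 4),
                paste0("s", i), centered = FALSE))
  expect_warning(medianCenter(profs, arch), "carrier-minority")
})

test_that("median centering is idempotent and demands a cohort", {
  arch <- toyArchitecture()
  withr::with_seed(33, {
    profs <- lapply(1:9, function(i)
      makeProfile(c(green = 3, red = 4) * exp(rnorm(2, 0, 0.05)),
                  paste0("s", i), centered = FALSE, flags = character(0)))
  })
  profs <- lapply(profs, function(p) { p@flags <- character(0); p })
  once <- medianCenter(profs, arch)
  # feed the centered values back in as raw: a second pass must not move them
  again <- medianCenter(lapply(once, function(p) {
    p@rawCN <- centeredCN(p); p@centeredCN <- numeric(0); p
  }), arch)
  for (i in seq_along(once))
    expect_equal(centeredCN(again[[i]]), centeredCN(once[[i]]),
                 tolerance = 1e-12)
  expect_error(medianCenter(profs[1:2], arch), class = "azfc_small_cohort")
  solo <- skipCentering(profs[[1]])
  expect_equal(centeredCN(solo), rawCN(solo))
  expect_true("UNCENTERED" %in% profileFlags(solo))
})

test_that("centering is equivariant under per-class multiplicative bias", {
  arch <- toyArchitecture()
  withr::with_seed(44, {
    base <- lapply(1:11, function(i)
      makeProfile(c(green = 3, red = 4) * exp(rnorm(2, 0, 0.04)),
                  paste0("s", i), centered = FALSE, flags = character(0)))
  })
  base <- lapply(base, function(p) { p@flags <- character(0); p })
  biased <- lapply(base, function(p) {
    p@rawCN <- p@rawCN * c(green = 1.0, red = 1.3); p
  })
  c1 <- medianCenter(base, arch)
  c2 <- suppressWarnings(medianCenter(biased, arch))
  for (i in seq_along(c1))
    expect_equal(centeredCN(c2[[i]]), centeredCN(c1[[i]]), tolerance = 1e-9)
})
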