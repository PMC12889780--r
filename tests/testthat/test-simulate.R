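bigControlArch <- function(len = 1.2e7) {
  # one long single-copy interval: >= 1e4 bins of 1 kb for law-of-large-
  # numbers checks
  azfcArchitecture(
    data.frame(contig = "chrT", start = 0L, end = as.integer(len),
               class_id = "ctrl"),
    data.frame(class_id = "ctrl", reference_copies = 1L, is_control = TRUE))
}

test_that("simulated depths have the requested mean and dosage ratios", {
  defs <- miniatureAzfcArchitecture()
  bins <- makeBins(defs$architecture, 1000)
  ref <- simulateDepths(bins, defs$architecture, defs$catalog, "REFERENCE",
                        coverage = 30, seed = 1)
  ctrl <- ref$mean_depth[ref$class_id == "ctrl"]
  expect_equal(mean(ctrl), 30, tolerance = 0.05)
  # control at coverage 30 over many bins: within 1% of 30
  big <- bigControlArch()
  bigbins <- makeBins(big, 1000)
  bigtab <- simulateDepths(bigbins, big, defs$catalog, "REFERENCE",
                           coverage = 30, seed = 2)
  expect_equal(mean(bigtab$mean_depth[bigtab$class_id == "ctrl"]), 30,
               tolerance = 0.01)
  # gr/gr halves the red class dosage relative to the reference simulation
  grgr <- simulateDepths(bins, defs$architecture, defs$catalog, "GRGR_DEL",
                         coverage = 30, seed = 3)
  ratio <- mean(grgr$mean_depth[grgr$class_id == "red"]) /
    mean(ref$mean_depth[ref$class_id == "red"])
  expect_equal(ratio, 0.5, tolerance = 0.05)
  expect_error(simulateDepths(bins, defs$architecture, defs$catalog,
                              "NOPE", coverage = 30, seed = 1),
               class = "azfc_unknown_signature")
})

test_that("per-bin counts follow the exact Poisson law", {
  big <- bigControlArch()
  bins <- makeBins(big, 1000)
  defs <- miniatureAzfcArchitecture()
  tab <- simulateDepths(bins, big, defs$catalog, "REFERENCE", coverage = 3,
                        read_length = 150, seed = 99)
  counts <- round(tab$mean_depth * 1000 / 150)
  lambda <- 3 * 1000 / 150  # 20 expected reads per bin
  # chi-square GOF against exact Poisson probabilities, pooled tails
  ks <- 0:40
  p <- dpois(ks, lambda)
  p[length(p)] <- p[length(p)] + ppois(max(ks), lambda, lower.tail = FALSE)
  obs <- tabulate(pmin(counts, max(ks)) + 1L, nbins = length(ks))
  keep <- p * length(counts) >= 5
  chi <- sum((obs[keep] - length(counts) * p[keep])^2 /
               (length(counts) * p[keep]))
  expect_gt(pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE), 0.001)
  # mean/variance moment match (Poisson: equal)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.05)
})

test_that("identical specs and seeds reproduce byte-identical tables", {
  defs <- miniatureAzfcArchitecture()
  bins <- makeBins(defs$architecture, 1000)
  a <- simulateDepths(bins, defs$architecture, defs$catalog, "GRGR_DEL",
                      coverage = 7.4, seed = 12345)
  b <- simulateDepths(bins, defs$architecture, defs$catalog, "GRGR_DEL",
                      coverage = 7.4, seed = 12345)
  expect_identical(a, b)
  s1 <- simulateCohort(5, 5, 0.2, 2, coverage = 5, bins = bins,
                       architecture = defs$architecture,
                       catalog = defs$catalog, seed = 77)
  s2 <- simulateCohort(5, 5, 0.2, 2, coverage = 5, bins = bins,
                       architecture = defs$architecture,
                       catalog = defs$catalog, seed = 77)
  expect_identical(s1, s2)
})

test_that("binomial thinning: identity at p=1, zero at p=0, 0.74X from 7.4X at p=0.1", {
  big <- bigControlArch()
  bins <- makeBins(big, 1000)
  defs <- miniatureAzfcArchitecture()
  tab <- simulateDepths(bins, big, defs$catalog, "REFERENCE", coverage = 7.4,
                        seed = 8)
  expect_identical(downsampleDepths(tab, 1, seed = 1), tab)
  expect_true(all(downsampleDepths(tab, 0, seed = 1)$mean_depth == 0))
  thin <- downsampleDepths(tab, 0.1, seed = 9)
  # the 90% downsampling of a 7.4X dataset has ~0.74X mean control depth
  expect_equal(mean(thin$mean_depth), 0.74, tolerance = 0.05 * 0.74)
  # thinned Poisson is Poisson with mean p*lambda: moment match
  cnt <- round(thin$mean_depth * 1000 / 150)
  expect_equal(var(cnt) / mean(cnt), 1, tolerance = 0.06)
})

test_that("case carrier frequency follows the odds-ratio identity", {
  expect_equal(caseCarrierFreq(0.3, 1.0), 0.3)  # OR 1: arms equal
  expect_equal(round(caseCarrierFreq(0.015, 2.1), 4), 0.0310)
  expect_equal(caseCarrierFreq(0.015, 2.1),
               2.1 * 0.015 / (1 - 0.015 + 2.1 * 0.015))
  expect_error(caseCarrierFreq(1.5, 2), class = "azfc_config_error")
})

test_that("cohort truth labels realize the target odds ratio", {
  sim <- simulateCohort(5e4, 5e4, 0.015, 2.0, seed = 314, depths = FALSE)
  m <- sim$manifest
  a <- sum(m$arm == "case" & m$architecture == "GRGR_DEL")
  b <- sum(m$arm == "case") - a
  cc <- sum(m$arm == "control" & m$architecture == "GRGR_DEL")
  d <- sum(m$arm == "control") - cc
  or_hat <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  # inside the 95% Monte-Carlo band around the generative OR 2.0
  expect_lt(abs(log(or_hat) - log(2)), 1.96 * se)
  # other-CNV architectures appear at the requested frequency
  defs <- miniatureAzfcArchitecture()
  sim2 <- simulateCohort(0, 2e4, 0.0, 1.0, other_cnv_freq = 0.05,
                         catalog = defs$catalog, seed = 315, depths = FALSE)
  frac <- mean(sim2$manifest$architecture %in% c("GRGR_DUP", "B2B4_DEL"))
  expect_equal(frac, 0.05, tolerance = 0.15)
})

test_that("caller sensitivity is monotone non-decreasing in coverage", {
  defs <- miniatureAzfcArchitecture()
  bins <- makeBins(defs$architecture, 1000)
  sens <- vapply(c(0.7, 7.4, 30), function(cov)
    simulateAndCall(150, 12, cov, defs, bins, seed = 424)$metrics$sensitivity,
    numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_identical(sens[3], 1)
})
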