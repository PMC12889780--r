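test_that("unadjusted 2x2 analysis reproduces printed cohort statistics", {
  # TECAC: 38/1584 carriers in cases, 12/647 in controls
  tecac <- unadjustedOR(38, 1546, 12, 635)
  expect_equal(round(tecac$or, 2), 1.30)
  expect_equal(round(tecac$ci95, 2), c(0.68, 2.51))
  expect_equal(round(tecac$p_value, 2), 0.53)
  # UKB: 11/785 carriers in cases, 2932/195290 in controls
  ukb <- unadjustedOR(11, 774, 2932, 192358)
  expect_equal(round(ukb$or, 2), 0.93)
  expect_equal(round(ukb$ci95, 2), c(0.51, 1.69))
  expect_equal(round(ukb$p_value, 2), 0.93)
  # symmetric table: OR exactly 1
  expect_identical(unadjustedOR(10, 90, 10, 90)$or, 1)
  # zero cell: OR undefined, flagged toward the penalized fit
  z <- unadjustedOR(0, 100, 5, 95)
  expect_true(is.na(z$or))
  expect_match(z$flag, "fitFirth")
})

test_that("Firth fit matches a brute-force penalized-likelihood maximizer", {
  # battery of random 2x2 datasets, including separated ones
  withr::with_seed(271828, {
    for (rep in 1:24) {
      n1 <- sample(30:120, 1)
      n0 <- sample(30:120, 1)
      x <- c(1, 0, 1, 0)
      y <- c(1, 1, 0, 0)
      a <- rbinom(1, n1, runif(1, 0, 0.3))   # carriers among cases
      cc <- if (rep <= 6) 0 else rbinom(1, n0, runif(1, 0, 0.3))
      w <- c(a, n1 - a, cc, n0 - cc)
      if (sum(w[c(1, 3)]) == 0) w[1] <- 1    # keep the covariate informative
      oracle <- oracleFirth2x2(x, y, w)
      fit <- fitFirth(cbind(1, carrier = x), y, weights = w, ci = "wald")
      expect_lt(max(abs(fit$coefficients - oracle)), 1e-3)
      expect_true(all(is.finite(fit$coefficients)))
      expect_true(fit$converged)
    }
  })
})

test_that("estimates stay finite and positive under complete separation", {
  # 0 carriers among 100 controls, 5 among 100 cases: ML diverges
  fit <- fitFirth(cbind(1, carrier = c(1, 0, 1, 0)), c(1, 1, 0, 0),
                  weights = c(5, 95, 0, 100))
  expect_true(fit$converged)
  expect_true(is.finite(fit$coefficients[2]))
  expect_gt(fit$coefficients[2], 0)
  expect_true(all(is.finite(fit$ci95["carrier", ])))
})

test_that("balanced symmetric data give a zero carrier coefficient", {
  # equal outcome proportions in both predictor groups
  fit <- fitFirth(cbind(1, carrier = c(1, 1, 0, 0)), c(1, 0, 1, 0),
                  weights = c(30, 30, 60, 60), ci = "wald")
  expect_equal(unname(fit$coefficients[2]), 0, tolerance = 1e-8)
})

test_that("Firth and plain ML agree at large n without sparsity", {
  withr::with_seed(1009, {
    n <- 2000
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-1 + log(2) * x))
  })
  fit <- fitFirth(cbind(1, x = x), y, ci = "wald")
  ml <- stats::glm(y ~ x, family = stats::binomial)
  expect_equal(unname(round(fit$coefficients, 2)),
               unname(round(stats::coef(ml), 2)))
})

test_that("weighted fits equal expanded-row fits", {
  x <- c(1, 0, 1, 0); y <- c(1, 1, 0, 0); w <- c(7, 53, 3, 61)
  fw <- fitFirth(cbind(1, carrier = x), y, weights = w, ci = "wald")
  X <- cbind(1, carrier = rep(x, w))
  fe <- fitFirth(X, rep(y, w), ci = "wald")
  expect_equal(fw$coefficients, fe$coefficients, tolerance = 1e-8)
  expect_equal(fw$penalized_loglik, fe$penalized_loglik, tolerance = 1e-8)
})

test_that("2x2 Firth converges to the unadjusted OR as all cells grow", {
  # at the published TECAC scale (smallest cell 12) the penalized estimate
  # is visibly shrunk (1.27 vs 1.30); at 10x the cells it agrees to 2 d.p.
  fit1 <- fitFirth(cbind(1, carrier = c(1, 0, 1, 0)), c(1, 1, 0, 0),
                   weights = c(38, 1546, 12, 635), ci = "wald")
  expect_equal(round(exp(fit1$coefficients[[2]]), 2), 1.27)
  fit10 <- fitFirth(cbind(1, carrier = c(1, 0, 1, 0)), c(1, 1, 0, 0),
                    weights = 10 * c(38, 1546, 12, 635), ci = "wald")
  expect_equal(round(exp(fit10$coefficients[[2]]), 2),
               round((38 * 635) / (1546 * 12), 2))
})

test_that("design validation: collinearity named, degenerate outcomes refused", {
  X <- cbind("(Intercept)" = 1, a = c(1, 0, 1, 0), b = 2 * c(1, 0, 1, 0))
  err <- tryCatch(fitFirth(X, c(1, 0, 1, 0)), error = identity)
  expect_s3_class(err, "azfc_collinear")
  expect_match(conditionMessage(err), "b")
  expect_error(fitFirth(cbind(1, x = c(1, 0)), c(1, 1), weights = c(5, 5)),
               class = "azfc_config_error")  # constant outcome
})

test_that("covariate-adjusted association behaves sensibly", {
  withr::with_seed(42, {
    n <- 400
    tab <- data.frame(sample_id = sprintf("s%03d", 1:n),
                      carrier = rbinom(n, 1, 0.1),
                      cov1 = rnorm(n), cov2 = rnorm(n), cov3 = rnorm(n))
    tab$phenotype <- rbinom(n, 1, plogis(-1 + log(2) * tab$carrier))
  })
  f0 <- assocWithCovariates(tab, n_covariates = 0, ci = "wald")
  # all-zero covariates change nothing
  tabz <- tab; tabz$cov1 <- 0; tabz$cov2 <- 0; tabz$cov3 <- 0
  fz <- assocWithCovariates(tabz, n_covariates = 3, ci = "wald")
  expect_equal(fz$or_adjusted, f0$or_adjusted, tolerance = 1e-10)
  # missing covariate values are reported by sample
  tabm <- tab; tabm$cov2[c(3, 7)] <- NA
  err <- tryCatch(assocWithCovariates(tabm, n_covariates = 3),
                  error = identity)
  expect_s3_class(err, "azfc_missing_covariate")
  expect_match(conditionMessage(err), "s003")
})

test_that("adjustment moves the estimate toward the generative OR under confounding", {
  withr::with_seed(2718, {
    n <- 4000
    z <- rnorm(n)                       # confounder: drives carrier and outcome
    carrier <- rbinom(n, 1, plogis(-2 + 1.5 * z))
    y <- rbinom(n, 1, plogis(-1 + log(1.5) * carrier + 1.2 * z))
    tab <- data.frame(sample_id = seq_len(n), carrier = carrier,
                      phenotype = y, cov1 = z)
  })
  unadj <- assocWithCovariates(tab, n_covariates = 0, ci = "wald")
  adj <- assocWithCovariates(tab, n_covariates = 1, ci = "wald")
  expect_lt(abs(log(adj$or_adjusted) - log(1.5)),
            abs(log(unadj$or_adjusted) - log(1.5)))
})

test_that("profile penalized-likelihood CIs cover the null effect ~95%", {
  # modest replicate battery; the full-scale calibration lives in the
  # acceptance suite
  withr::with_seed(909, { seeds <- sample.int(1e6, 60) })
  cover <- vapply(seeds, function(s) {
    withr::with_seed(s, {
      n1 <- 300; n0 <- 300
      a <- rbinom(1, n1, 0.05); cc <- rbinom(1, n0, 0.05)
    })
    w <- c(a, n1 - a, cc, n0 - cc)
    if (w[1] + w[3] == 0) return(NA)    # no carriers drawn at all
    fit <- fitFirth(cbind(1, carrier = c(1, 0, 1, 0)), c(1, 1, 0, 0),
                    weights = w, ci_coefs = 2)
    ci <- fit$ci95["carrier", ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover, na.rm = TRUE), 0.85)
})
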