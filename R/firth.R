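# ---- penalized-likelihood engine -------------------------------------------
# Firth's bias reduction: maximize l(beta) + 0.5 * log det I(beta) (Jeffreys
# prior) by Newton iteration on the modified score
#   U*_r = sum_i [ w_i (y_i - pi_i) + h_i (1/2 - pi_i) ] x_ir
# with h the hat diagonal of the weighted information. Frequency weights w
# (counts of identical rows) give exactly the likelihood of the expanded
# data, including the penalty. Coefficients listed in `fixed` are held
# constant (used for profile CIs and penalized LR tests); the penalty is
# always computed from the full information matrix.

firthPL <- function(X, beta, y, w) {
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  pi <- stats::plogis(eta)
  W <- w * pi * (1 - pi)
  I <- crossprod(X, X * W)
  ch <- tryCatch(chol(I), error = function(e) NULL)
  if (is.null(ch)) return(list(pl = -Inf))
  logdet <- 2 * sum(log(diag(ch)))
  pl <- sum(w * (y * log(pi) + (1 - y) * log(1 - pi))) + 0.5 * logdet
  Iinv <- chol2inv(ch)
  h <- W * rowSums((X %*% Iinv) * X)
  U <- drop(crossprod(X, w * (y - pi) + h * (0.5 - pi)))
  list(pl = pl, pi = pi, I = I, Iinv = Iinv, U = U)
}

firthEngine <- function(X, y, w = NULL, fixed = NULL, start = NULL,
                        maxit = 100L, tol = 1e-8) {
  p <- ncol(X)
  if (is.null(w)) w <- rep(1, nrow(X))
  beta <- if (is.null(start)) rep(0, p) else start
  free <- setdiff(seq_len(p), if (is.null(fixed)) integer(0)
                  else as.integer(names(fixed)))
  if (!is.null(fixed)) beta[as.integer(names(fixed))] <- as.numeric(fixed)
  st <- firthPL(X, beta, y, w)
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    if (length(free) == 0L) { converged <- TRUE; break }
    Uf <- st$U[free]
    If <- st$I[free, free, drop = FALSE]
    delta <- tryCatch(solve(If, Uf), error = function(e) NULL)
    if (is.null(delta)) break
    # cap implausible jumps, then halve until the penalized loglik improves
    if (max(abs(delta)) > 5) delta <- delta * (5 / max(abs(delta)))
    step <- 1
    improved <- FALSE
    repeat {
      cand <- beta
      cand[free] <- beta[free] + step * delta
      st2 <- firthPL(X, cand, y, w)
      if (st2$pl >= st$pl - 1e-12) { improved <- TRUE; break }
      if (step < 1e-4) break
      step <- step / 2
    }
    if (!improved) break  # no ascent direction left; report current point
    moved <- max(abs(step * delta))
    beta <- cand
    st <- st2
    if (max(abs(st$U[free])) < tol || moved < tol) { converged <- TRUE; break }
  }
  list(beta = beta, pl = st$pl, converged = converged, n_iter = iter,
       I = st$I, Iinv = st$Iinv, U = st$U)
}

# ---- user-facing fits ------------------------------------------------------

#' Firth's bias-reduced logistic regression
#'
#' Maximum penalized likelihood \eqn{l(\beta) + \frac{1}{2}\log\det
#' I(\beta)} (Jeffreys-prior penalty) by Newton iteration on the
#' Firth-modified score, with step halving so the penalized log-likelihood
#' never decreases across accepted steps. Estimates exist and are finite
#' under complete or quasi-complete separation, the regime (rare carriers,
#' extreme case-control imbalance) that motivates the method.
#'
#' Confidence intervals default to profile penalized likelihood (each bound
#' solves \eqn{2[pl(\hat\beta) - pl_{profile}(b)] = \chi^2_{1,level}});
#' Wald intervals are available via \code{ci = "wald"} and the method used
#' is recorded. Per-coefficient p-values are penalized likelihood-ratio
#' tests (refit with the coefficient fixed at zero).
#'
#' @param X Design matrix, n x (k+1), including an intercept column.
#' @param y 0/1 outcome vector (length n), not constant.
#' @param weights Optional frequency weights (counts of identical rows);
#'   the fit is identical to expanding the rows.
#' @param ci \code{"profile"} (default) or \code{"wald"}.
#' @param level Confidence level; default 0.95.
#' @param ci_coefs Indices of coefficients to compute CIs for; default all.
#' @param maxit,tol Newton iteration cap (100) and convergence tolerance
#'   (1e-8 on both the modified score and the step).
#' @return List of class \code{"FirthFit"}: \code{coefficients},
#'   \code{se} (from the inverse penalized information), \code{vcov},
#'   \code{ci95} (matrix, rows = coefficients), \code{ci_method},
#'   \code{p_values} (penalized LR), \code{penalized_loglik},
#'   \code{converged}, \code{n_iter}.
#' @export
fitFirth <- function(X, y, weights = NULL, ci = c("profile", "wald"),
                     level = 0.95, ci_coefs = NULL, maxit = 100L,
                     tol = 1e-8) {
  ci <- match.arg(ci)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    azfcError("azfc_config_error", "outcome must be 0/1")
  if (length(unique(y)) < 2L)
    azfcError("azfc_config_error", "outcome is constant")
  if (nrow(X) <= ncol(X) && is.null(weights))
    azfcError("azfc_config_error", "need n > number of coefficients")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    azfcError("azfc_collinear",
              sprintf("collinear design column(s): %s",
                      paste(bad, collapse = ", ")))
  }
  fit <- firthEngine(X, y, w = weights, maxit = maxit, tol = tol)
  se <- sqrt(diag(fit$Iinv))
  p <- ncol(X)
  if (is.null(ci_coefs)) ci_coefs <- seq_len(p)

  # penalized LR p-value per coefficient
  pvals <- vapply(seq_len(p), function(j) {
    f0 <- firthEngine(X, y, w = weights, fixed = stats::setNames(0, j),
                      start = fit$beta, maxit = maxit, tol = tol)
    stats::pchisq(max(0, 2 * (fit$pl - f0$pl)), df = 1, lower.tail = FALSE)
  }, numeric(1))

  cimat <- matrix(NA_real_, p, 2, dimnames = list(colnames(X), c("low", "high")))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  if (ci == "wald") {
    cimat[, 1] <- fit$beta - zq * se
    cimat[, 2] <- fit$beta + zq * se
  } else {
    drop_pl <- fit$pl - stats::qchisq(level, 1) / 2
    for (j in ci_coefs) {
      cimat[j, ] <- profileBounds(X, y, weights, j, fit, drop_pl, se[j],
                                  maxit, tol)
    }
  }
  structure(list(coefficients = stats::setNames(fit$beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)), vcov = fit$Iinv,
                 ci95 = cimat, ci_method = ci, level = level,
                 p_values = stats::setNames(pvals, colnames(X)),
                 penalized_loglik = fit$pl, converged = fit$converged,
                 n_iter = fit$n_iter, n = sum(if (is.null(weights))
                   rep(1, nrow(X)) else weights)),
            class = "FirthFit")
}

# profile the penalized likelihood for coefficient j: find the two values b
# where the constrained maximum drops by qchisq(level, 1) / 2
profileBounds <- function(X, y, w, j, fit, drop_pl, sej, maxit, tol) {
  f <- function(b) {
    firthEngine(X, y, w = w, fixed = stats::setNames(b, j), start = fit$beta,
                maxit = maxit, tol = tol)$pl - drop_pl
  }
  bound <- function(dir) {
    step <- max(sej, 1e-3)
    lo <- fit$beta[j]
    for (k in 1:40) {
      hi <- fit$beta[j] + dir * step * 2^(k - 1)
      if (f(hi) < 0) {
        r <- stats::uniroot(f, sort(c(lo, hi)), tol = 1e-7)
        return(r$root)
      }
      lo <- hi
    }
    dir * Inf  # likelihood too flat to bound within 2^40 SEs
  }
  c(bound(-1), bound(1))
}

#' @export
print.FirthFit <- function(x, ...) {
  cat(sprintf("Firth bias-reduced logistic regression (n = %g, %s, %d iter)\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    or = exp(x$coefficients),
                    ci_low = exp(x$ci95[, 1]), ci_high = exp(x$ci95[, 2]),
                    p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("CI method: %s; penalized loglik %.4f\n", x$ci_method,
              x$penalized_loglik))
  invisible(x)
}

#' Unadjusted 2x2 odds ratio with Woolf CI and Yates chi-square
#'
#' \code{OR = (a d)/(b c)}; 95\% CI \code{exp(ln OR +/- 1.959964
#' sqrt(1/a + 1/b + 1/c + 1/d))} (Woolf); p-value from the chi-square test
#' with Yates continuity correction (df = 1). With any zero cell the OR is
#' undefined and reported as \code{NA} with a flag directing users to
#' \code{\link{fitFirth}}, which remains finite.
#'
#' @param a Carriers among cases.
#' @param b Non-carriers among cases.
#' @param c Carriers among controls.
#' @param d Non-carriers among controls.
#' @return List of class \code{"azfc_unadjusted"}: \code{or}, \code{ci95},
#'   \code{chi2_yates}, \code{p_value}, \code{cells}, \code{flag}.
#' @examples
#' unadjustedOR(38, 1546, 12, 635)  # OR 1.30, CI 0.68-2.51, p 0.53
#' @export
unadjustedOR <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    azfcError("azfc_config_error", "cells must be non-negative integers")
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("carrier", "non_carrier")))
  chi <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  if (any(cells == 0)) {
    return(structure(list(or = NA_real_, ci95 = c(NA_real_, NA_real_),
                          chi2_yates = unname(chi$statistic),
                          p_value = chi$p.value, cells = cells,
                          flag = "ZERO_CELL: OR undefined; use fitFirth()"),
                     class = "azfc_unadjusted"))
  }
  or <- (a * d) / (b * c)
  se <- sqrt(sum(1 / cells))
  z <- 1.959964  # qnorm(.975) at the precision used for printed CIs
  structure(list(or = or,
                 ci95 = exp(log(or) + c(-1, 1) * z * se),
                 chi2_yates = unname(chi$statistic),
                 p_value = chi$p.value, cells = cells, flag = NA_character_),
            class = "azfc_unadjusted")
}

#' @export
print.azfc_unadjusted <- function(x, ...) {
  if (is.na(x$or)) {
    cat("OR undefined (zero cell); chi2 p =", format(x$p_value, digits = 3),
        "\n", x$flag, "\n")
  } else {
    cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), Yates chi2 = %.3f, p = %.2f\n",
                x$or, x$ci95[1], x$ci95[2], x$chi2_yates, x$p_value))
  }
  invisible(x)
}

#' Covariate-adjusted carrier association from an association table
#'
#' Fits \code{phenotype ~ carrier + cov1 + ... + covN} by
#' \code{\link{fitFirth}} and reports the carrier effect as an odds ratio
#' with CI and penalized LR p-value. Covariates (e.g. ancestry principal
#' components) are taken as given numeric columns; computing them is out of
#' scope.
#'
#' @param table Association \code{data.frame} from
#'   \code{\link{filterForAssociation}}: columns \code{carrier},
#'   \code{phenotype} and \code{cov1..covN}.
#' @param n_covariates Number of covariate columns to include; default 0.
#' @param ... Passed to \code{\link{fitFirth}} (e.g. \code{ci = "wald"}).
#' @return A \code{"FirthFit"} with extra elements \code{or_adjusted},
#'   \code{or_ci95} and \code{or_p} for the carrier coefficient.
#' @export
assocWithCovariates <- function(table, n_covariates = 0, ...) {
  covcols <- if (n_covariates > 0) paste0("cov", seq_len(n_covariates))
             else character(0)
  missing_cols <- setdiff(c("carrier", "phenotype", covcols), colnames(table))
  if (length(missing_cols))
    azfcError("azfc_config_error",
              sprintf("association table lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  covs <- as.matrix(table[, covcols, drop = FALSE])
  if (length(covcols) && any(!stats::complete.cases(covs))) {
    bad <- table$sample_id[!stats::complete.cases(covs)]
    azfcError("azfc_missing_covariate",
              sprintf("missing covariate values for sample(s): %s",
                      paste(bad, collapse = ", ")))
  }
  # an all-zero covariate carries no information: drop it rather than fail
  # the collinearity check, so the fit equals the covariate-free one
  if (ncol(covs)) {
    zero <- apply(covs == 0, 2, all)
    if (any(zero)) {
      message("dropping all-zero covariate column(s): ",
              paste(colnames(covs)[zero], collapse = ", "))
      covs <- covs[, !zero, drop = FALSE]
    }
  }
  X <- cbind("(Intercept)" = 1, carrier = table$carrier, covs)
  fit <- fitFirth(X, table$phenotype, ...)
  fit$or_adjusted <- unname(exp(fit$coefficients["carrier"]))
  fit$or_ci95 <- exp(fit$ci95["carrier", ])
  fit$or_p <- unname(fit$p_values["carrier"])
  fit
}
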