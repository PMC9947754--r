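# Posterior summaries: linear effect tables with equal-tailed 95% credible
# intervals and significance flags, smooth-effect curves with bands,
# spatial posterior means with three-class significance, and convergence
# diagnostics (effective sample size and split-chain R-hat).

.ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), names = FALSE, type = 7))
}

#' Posterior table of linear effects
#'
#' One row per linear coefficient of each parameter: posterior mean,
#' equal-tailed 95% credible interval, and a significance flag that is
#' `TRUE` exactly when the interval excludes zero.
#'
#' @param draws a [run_chain()] result.
#' @param level credible level (default 0.95).
#' @return data frame with `parameter`, `term`, `mean`, `lower`, `upper`,
#'   `significant`.
#' @export
summarize_linear <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  out <- NULL
  for (j in seq_along(draws$blocks)) {
    b <- draws$blocks[[j]]
    if (b$kind != "linear") next
    M <- draws$draws[[j]]
    if (nrow(M) == 0) .gbp_error("empty chain", "gbp_summary_error")
    for (c0 in seq_len(ncol(M))) {
      ci <- .ci(M[, c0], level)
      out <- rbind(out, data.frame(
        parameter = b$param, term = colnames(M)[c0], mean = mean(M[, c0]),
        lower = ci[1], upper = ci[2],
        significant = ci[1] > 0 || ci[2] < 0, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

.find_block <- function(draws, param, kind, covariate = NULL) {
  for (j in seq_along(draws$blocks)) {
    b <- draws$blocks[[j]]
    if (b$param == param && b$kind == kind &&
        (is.null(covariate) || identical(b$covariate, covariate)))
      return(j)
  }
  .gbp_error(sprintf("no %s block for %s%s", kind, param,
                     if (is.null(covariate)) "" else paste0(" on ", covariate)),
             "gbp_summary_error")
}

#' Posterior curve of a smooth effect
#'
#' Evaluates the fitted smooth `f(w) = B(w) beta` for every kept draw on a
#' grid inside the fitted covariate range and returns the pointwise
#' posterior mean and equal-tailed credible band.  Curves are centred over
#' the fitting data by the sampler's identifiability constraint.
#'
#' @param draws a [run_chain()] result.
#' @param param `"mu1"`, `"mu2"` or `"rho"`.
#' @param covariate name of the smooth covariate.
#' @param grid evaluation points (default: 50 equidistant points over the
#'   fitted range).  Points outside the range are an error.
#' @param level credible level.
#' @return data frame with `grid`, `mean`, `lower`, `upper`.
#' @export
summarize_curve <- function(draws, param, covariate, grid = NULL, level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  j <- .find_block(draws, param, "spline", covariate)
  b <- draws$blocks[[j]]
  if (is.null(grid)) grid <- seq(b$lo, b$hi, length.out = 50)
  if (any(grid < b$lo - 1e-9) || any(grid > b$hi + 1e-9))
    .gbp_error("grid outside the fitted covariate range", "gbp_extrapolation_error")
  eps <- 1e-9 * (b$hi - b$lo)
  x <- pmin(pmax(grid, b$lo), b$hi - eps)
  B <- splines::splineDesign(b$knots, x, ord = b$degree + 1)
  f <- B %*% t(draws$draws[[j]])  # grid x kept
  a <- (1 - level) / 2
  data.frame(grid = grid, mean = rowMeans(f),
             lower = apply(f, 1, quantile, probs = a, names = FALSE),
             upper = apply(f, 1, quantile, probs = 1 - a, names = FALSE))
}

#' Posterior spatial effects with three-class significance
#'
#' Per-region posterior mean and credible interval of the spatial effect,
#' classified `+1` when the interval lies above zero (significant positive
#' effect), `-1` when below zero, and `0` otherwise (no significance).
#'
#' @param draws a [run_chain()] result.
#' @param param `"mu1"`, `"mu2"` or `"rho"`.
#' @param level credible level.
#' @return data frame with `region`, `mean`, `lower`, `upper`, `class`.
#' @export
summarize_spatial <- function(draws, param, level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  j <- .find_block(draws, param, "spatial")
  b <- draws$blocks[[j]]
  M <- draws$draws[[j]]
  lw <- apply(M, 2, quantile, probs = (1 - level) / 2, names = FALSE)
  up <- apply(M, 2, quantile, probs = 1 - (1 - level) / 2, names = FALSE)
  cls <- ifelse(lw > 0, 1L, ifelse(up < 0, -1L, 0L))
  data.frame(region = b$regions, mean = colMeans(M), lower = lw, upper = up,
             class = cls, stringsAsFactors = FALSE)
}

#' Posterior mean predictors and fitted correlation per record
#'
#' Posterior mean of each record's three predictors (mean of `eta` over
#' draws, which equals the design applied to the posterior mean
#' coefficients) and the fitted latent correlation
#' `rho_hat = tanh(mean eta_rho)`.
#'
#' @param draws a [run_chain()] result.
#' @return data frame with `eta_mu1`, `eta_mu2`, `eta_rho`, `rho_hat`.
#' @export
fitted_predictors <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  eta <- list(mu1 = 0, mu2 = 0, rho = 0)
  for (j in seq_along(draws$blocks)) {
    b <- draws$blocks[[j]]
    bm <- colMeans(draws$draws[[j]])
    eta[[b$param]] <- eta[[b$param]] + drop(block_design_matrix(b) %*% bm)
  }
  data.frame(eta_mu1 = eta$mu1, eta_mu2 = eta$mu2, eta_rho = eta$rho,
             rho_hat = tanh(eta$rho))
}

# Effective sample size by Geyer's initial monotone positive sequence.
.ess <- function(x) {
  L <- length(x)
  v <- var(x)
  if (!is.finite(v) || v <= 0) return(1)
  lag_max <- min(L - 1, 1000)
  rho <- drop(acf(x, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf)
  # pair sums Gamma_m = rho(2m) + rho(2m+1); keep while positive and
  # non-increasing
  npair <- floor((lag_max + 1) / 2)
  gsum <- 0
  prev <- Inf
  for (m in seq_len(npair)) {
    g <- rho[2 * m - 1] + if (2 * m <= lag_max + 1) rho[2 * m] else 0
    if (m == 1) g <- g - 1  # exclude lag-0 from the correction term
    gm <- min(g, prev)
    if (m > 1 && gm <= 0) break
    gsum <- gsum + gm
    prev <- gm
  }
  max(1, min(L, L / (1 + 2 * gsum)))
}

.split_rhat <- function(x) {
  L <- floor(length(x) / 2)
  if (L < 2) return(NA_real_)
  halves <- cbind(x[seq_len(L)], x[L + seq_len(L)])
  m <- colMeans(halves)
  W <- mean(apply(halves, 2, var))
  B <- L * var(m)
  if (W <= 0) return(1)
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Convergence diagnostics for every scalar chain
#'
#' Effective sample size (Geyer initial monotone sequence estimator) and
#' split-chain R-hat for each coefficient and each smoothing variance.
#' Chains with `Rhat > 1.1` or `ESS < 100` are flagged.
#'
#' @param draws a [run_chain()] result with at least 100 kept draws.
#' @return data frame with `chain`, `ess`, `rhat`, `flagged`.
#' @export
convergence_diagnostics <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$n_kept < 100)
    .gbp_error("need at least 100 kept draws for diagnostics", "gbp_summary_error")
  M <- as_chain_matrix(draws)
  ess <- apply(M, 2, .ess)
  rhat <- apply(M, 2, .split_rhat)
  out <- data.frame(chain = colnames(M), ess = ess, rhat = rhat,
                    flagged = ess < 100 | (!is.na(rhat) & rhat > 1.1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (any(out$flagged))
    warning(sum(out$flagged), " chain(s) flagged (ESS < 100 or Rhat > 1.1)",
            call. = FALSE)
  out
}

#' Flatten all chains into one matrix
#'
#' One column per scalar parameter (every block coefficient, every
#' smoothing variance, the log-likelihood), suitable for export and for
#' generic MCMC diagnostic tools.
#'
#' @param draws a [run_chain()] result.
#' @return numeric matrix, kept draws x scalars.
#' @export
as_chain_matrix <- function(draws) {
  mats <- lapply(seq_along(draws$blocks), function(j) {
    M <- draws$draws[[j]]
    colnames(M) <- paste0(draws$blocks[[j]]$label, ":", colnames(M))
    M
  })
  out <- do.call(cbind, c(mats, list(draws$tau2)))
  cbind(out, loglik = draws$loglik)
}
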