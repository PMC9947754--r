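# Posterior simulation: Metropolis-Hastings within Gibbs with IWLS
# Gaussian proposals per coefficient block and conjugate inverse-gamma
# draws for the smoothing variances.  The sweep updates all mu1 blocks,
# then mu2, then rho, then the variances.

#' Sampler configuration
#'
#' @param iterations total MCMC sweeps.
#' @param burnin sweeps discarded before storage (`iterations > burnin`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; chains are a pure function of (data, spec,
#'   config, seed).
#' @param ig_a,ig_b inverse-gamma hyperprior parameters for every
#'   smoothing variance (defaults 0.001, the conventional weakly
#'   informative choice).
#' @param tau2_init initial smoothing variance.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(iterations = 12000, burnin = 2000, thin = 10,
                           seed = 1, ig_a = 0.001, ig_b = 0.001,
                           tau2_init = 0.1) {
  stopifnot(iterations > burnin, burnin >= 0, thin >= 1, ig_a > 0, ig_b > 0,
            tau2_init > 0)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), ig_a = ig_a, ig_b = ig_b,
                 tau2_init = tau2_init),
            class = "sampler_config")
}

#' Initial sampler state
#'
#' Intercepts start at the probit of the marginal prevalences
#' (`qnorm(mean(y))`), the correlation intercept at 0, every other
#' coefficient at 0 and every smoothing variance at `tau2_init`.
#'
#' @param designs a [build_designs()] result.
#' @param ds the matching `bp_dataset`.
#' @param config a [sampler_config()].
#' @return list of per-block coefficient vectors and variances, in block
#'   order mu1, mu2, rho.
#' @export
init_state <- function(designs, ds, config = sampler_config()) {
  prev <- c(mu1 = mean(ds$y1), mu2 = mean(ds$y2))
  prev <- pmin(pmax(prev, 1 / (2 * ds$n)), 1 - 1 / (2 * ds$n))
  state <- list()
  for (k in c("mu1", "mu2", "rho")) {
    for (b in designs[[k]]) {
      beta <- rep(0, b$d)
      if (b$kind == "linear")
        beta[1] <- if (k == "rho") 0 else qnorm(prev[[k]])
      state[[b$label]] <- list(beta = beta,
                               tau2 = if (b$kind == "linear") NA_real_
                                      else config$tau2_init)
    }
  }
  state
}

# block in the layout the C++ core expects (0-based indices)
.as_cblock <- function(b, beta0 = NULL, tau2 = 0.1) {
  param <- match(b$param, c("mu1", "mu2", "rho")) - 1L
  d <- b$d %||% ncol(b$Z)
  out <- list(param = param, d = as.integer(d), penalized = b$kind != "linear",
              tau2 = tau2)
  if (b$kind == "linear") {
    out$type <- 0L
    out$Z <- unname(b$Z)
  } else if (b$kind == "spline") {
    out$type <- 1L
    out$Bx <- b$Bx
    out$Bi <- as.integer(b$Bi - 1L)
    out$K <- b$K
    out$rank <- as.numeric(b$rank)
  } else {
    out$type <- 2L
    out$ri <- as.integer(b$ri - 1L)
    out$free <- as.integer(b$free - 1L)
    out$K <- b$K
    out$rank <- as.numeric(b$rank)
  }
  if (!is.null(beta0)) out$beta0 <- as.numeric(beta0)
  out
}

#' Run the MCMC chain
#'
#' Sweeps all coefficient blocks of mu1, mu2 and rho with MH-IWLS updates
#' against the exact bivariate probit likelihood, recentres spline and
#' spatial blocks into the intercept for identifiability, then draws every
#' smoothing variance from its conjugate inverse-gamma full conditional.
#' Aborts with a diagnostic if the log-likelihood ever becomes non-finite.
#'
#' @param ds a `bp_dataset`.
#' @param designs a [build_designs()] result for `ds`.
#' @param config a [sampler_config()].
#' @return object of class `posterior_draws`: per-block coefficient chains,
#'   smoothing-variance chains, log-likelihood trace, per-block acceptance
#'   rates, plus the design metadata needed by the `summarize_*` functions.
#' @export
run_chain <- function(ds, designs, config = sampler_config()) {
  stopifnot(inherits(designs, "design_set"), inherits(config, "sampler_config"))
  state <- init_state(designs, ds, config)
  blocks <- list()
  meta <- list()
  for (k in c("mu1", "mu2", "rho")) {
    for (b in designs[[k]]) {
      st <- state[[b$label]]
      blocks[[length(blocks) + 1]] <-
        .as_cblock(b, beta0 = st$beta,
                   tau2 = if (is.na(st$tau2)) 0.1 else st$tau2)
      meta[[length(meta) + 1]] <- b
    }
  }
  set.seed(config$seed)
  res <- C_run_chain(as.integer(ds$y1), as.integer(ds$y2), blocks,
                     list(iterations = config$iterations, burnin = config$burnin,
                          thin = config$thin, ig_a = config$ig_a,
                          ig_b = config$ig_b))
  draws <- res$draws
  labels <- vapply(meta, function(b) b$label, "")
  names(draws) <- labels
  for (j in seq_along(draws)) colnames(draws[[j]]) <- meta[[j]]$coef_names
  pen <- vapply(meta, function(b) b$kind != "linear", TRUE)
  if (any(pen)) {
    tau2 <- res$tau2
    colnames(tau2) <- paste0("tau2(", labels[pen], ")")
  } else {
    tau2 <- matrix(numeric(0), nrow = res$kept, ncol = 0)
  }
  structure(list(draws = draws, tau2 = tau2, loglik = as.numeric(res$loglik),
                 accept_rate = setNames(as.numeric(res$accept_rate), labels),
                 blocks = meta, config = config, n = ds$n,
                 n_kept = res$kept),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d kept draws (%d iterations, burn-in %d, thin %d)\n",
              x$n_kept, x$config$iterations, x$config$burnin, x$config$thin))
  cat(sprintf("  blocks: %s\n", paste(names(x$draws), collapse = ", ")))
  cat(sprintf("  acceptance rates: %s\n",
              paste(sprintf("%s %.2f", names(x$accept_rate), x$accept_rate),
                    collapse = ", ")))
  invisible(x)
}

#' Conjugate draw of a smoothing variance
#'
#' `tau2 ~ InverseGamma(a + rank(K)/2, b + t(beta) K beta / 2)`, the exact
#' full conditional under the partially improper Gaussian prior with
#' precision `K / tau2` and an IG(a, b) hyperprior.
#'
#' @param block a penalized block from [build_designs()] (needs `K` and
#'   `rank`), or any list with those fields.
#' @param beta current coefficient vector of the block.
#' @param config a [sampler_config()] supplying `ig_a`, `ig_b`.
#' @return one draw of `tau2`.
#' @export
update_variance <- function(block, beta, config = sampler_config()) {
  quad <- drop(crossprod(beta, block$K %*% beta))
  if (quad < -1e-8) .gbp_error("negative penalty quadratic form", "gbp_numeric_error")
  quad <- max(quad, 0)
  shape <- config$ig_a + block$rank / 2
  rate <- config$ig_b + quad / 2
  1 / rgamma(1, shape = shape, rate = rate)
}

#' Single MH-IWLS update of one coefficient block
#'
#' Proposes from the Gaussian with precision `Z' W Z + K / tau2` and mean
#' the IWLS solve of the working response built from the score and the
#' expected information of the bivariate probit likelihood with respect to
#' the block's predictor, then accepts with the Metropolis-Hastings ratio
#' including the proposal asymmetry (the reverse proposal is rebuilt at the
#' proposed state).  With `flat_likelihood = TRUE` the likelihood is
#' replaced by a constant, so the chain targets the block's Gaussian prior
#' conditional (useful for validating the sampler against the analytic
#' prior; this needs a full-rank `K`).
#'
#' @param ds a `bp_dataset` (or list with `y1`, `y2`).
#' @param block a block from [build_designs()], or for custom checks a list
#'   with fields `kind = "linear"`, `param`, `Z`, and optionally `K`,
#'   `rank` (a supplied `K` marks the block as penalized).
#' @param beta current coefficient vector.
#' @param eta_mu1,eta_mu2,eta_rho current full predictors of all three
#'   parameters (including this block's contribution).
#' @param tau2 current smoothing variance of the block.
#' @param flat_likelihood replace the likelihood by a constant.
#' @return list with `beta` (new coefficients) and `accepted`.
#' @export
update_coefficient_block <- function(ds, block, beta, eta_mu1, eta_mu2,
                                     eta_rho, tau2 = 0.1,
                                     flat_likelihood = FALSE) {
  cb <- .custom_cblock(block, beta, tau2)
  etas <- list(mu1 = as.numeric(eta_mu1), mu2 = as.numeric(eta_mu2),
               rho = as.numeric(eta_rho))
  etab <- .block_eta_r(block, beta)
  k <- block$param
  res <- C_update_block(as.integer(ds$y1), as.integer(ds$y2), cb,
                        etas$mu1, etas$mu2, etas$rho,
                        etas[[k]] - etab, isTRUE(flat_likelihood))
  list(beta = as.numeric(res$beta), accepted = res$accepted)
}

.custom_cblock <- function(block, beta, tau2) {
  if (block$kind == "linear" && !is.null(block$K)) {
    # custom penalized linear block (validation use)
    param <- match(block$param, c("mu1", "mu2", "rho")) - 1L
    list(param = param, type = 0L, d = ncol(block$Z), Z = unname(block$Z),
         K = block$K, rank = as.numeric(block$rank %||% qr(block$K)$rank),
         penalized = TRUE, center = FALSE, tau2 = tau2,
         beta0 = as.numeric(beta))
  } else {
    .as_cblock(block, beta0 = beta, tau2 = tau2)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.block_eta_r <- function(block, beta) {
  if (block$kind == "linear") return(drop(block$Z %*% beta))
  drop(block_design_matrix(block) %*% beta)
}
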