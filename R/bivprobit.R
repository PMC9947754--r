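# Probability core of the bivariate probit: links, orthant probabilities,
# per-record cell probabilities and the exact log-likelihood.

#' Fisher-z link for the latent correlation
#'
#' The correlation between the two latent Gaussian utilities is mapped to
#' the real line by the Fisher z-transformation `atanh(rho)`; its inverse
#' `tanh(eta)` constrains any real predictor value to (-1, 1).
#'
#' @param eta real predictor value(s).
#' @return correlation value(s) in (-1, 1).
#' @examples
#' rho_link_inv(0)            # 0
#' rho_link(rho_link_inv(.9)) # .9
#' @export
rho_link_inv <- function(eta) {
  if (any(!is.finite(eta))) .gbp_error("non-finite predictor for rho", "gbp_domain_error")
  tanh(eta)
}

#' @rdname rho_link_inv
#' @param rho correlation value(s) in (-1, 1).
#' @export
rho_link <- function(rho) {
  if (any(abs(rho) >= 1)) .gbp_error("|rho| must be < 1", "gbp_domain_error")
  atanh(rho)
}

#' Standard bivariate normal distribution function
#'
#' `P(Z1 <= a, Z2 <= b)` for a standard bivariate normal pair with
#' correlation `rho`, computed by the Genz (2004) quadrature rewrite of the
#' Drezner-Wesolowsky algorithm (absolute accuracy well below 1e-8).
#' Arguments are recycled to a common length; infinite thresholds reduce to
#' the univariate marginals.
#'
#' @param a,b thresholds (may be `Inf` / `-Inf`).
#' @param rho correlation(s), strictly inside (-1, 1).
#' @return vector of probabilities.
#' @examples
#' binorm_cdf(0, 0, 0)    # 0.25
#' binorm_cdf(0, 0, 0.5)  # 1/4 + asin(0.5) / (2 * pi) = 1/3
#' @export
binorm_cdf <- function(a, b, rho) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1))
    .gbp_error("correlation must satisfy |rho| < 1", "gbp_domain_error")
  n <- max(length(a), length(b), length(rho))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  rho <- rep_len(as.numeric(rho), n)
  out <- numeric(n)
  fin <- is.finite(a) & is.finite(b)
  if (any(fin)) out[fin] <- C_bvn_cdf(a[fin], b[fin], rho[fin])
  if (any(!fin)) {
    ia <- !is.finite(a); ib <- !is.finite(b)
    out[ia & a < 0] <- 0
    out[ib & b < 0] <- 0
    ponly_b <- ia & a > 0 & is.finite(b)
    out[ponly_b] <- pnorm(b[ponly_b])
    ponly_a <- ib & b > 0 & is.finite(a)
    out[ponly_a] <- pnorm(a[ponly_a])
    out[ia & ib & a > 0 & b > 0] <- 1
  }
  out
}

#' Bivariate probit cell probabilities
#'
#' Probability of an observed outcome pair under the latent-variable model:
#' each outcome is 1 when its latent Gaussian utility (mean `mu`, variance
#' 1) is positive, so `P(Y1 = 1, Y2 = 1) = binorm_cdf(mu1, mu2, rho)` and
#' the other three cells follow by inclusion-exclusion with the univariate
#' margins.  The four cells are non-negative and sum to one.
#'
#' @param y1,y2 observed outcomes, 0 or 1 (recycled).
#' @param mu1,mu2 latent means (probit predictors).
#' @param rho latent correlation(s), |rho| < 1.
#' @return probability of the observed cell, vectorised.
#' @seealso [cell_probabilities()] for all four cells at once.
#' @examples
#' cell_probability(1, 1, 0, 0, 0)    # 0.25
#' cell_probability(1, 0, 0, 0, 0.5)  # 1/6
#' @export
cell_probability <- function(y1, y2, mu1, mu2, rho) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1))
    .gbp_error("correlation must satisfy |rho| < 1", "gbp_domain_error")
  if (!all(y1 %in% c(0, 1)) || !all(y2 %in% c(0, 1)))
    .gbp_error("outcomes must be 0/1", "gbp_domain_error")
  n <- max(length(y1), length(y2), length(mu1), length(mu2), length(rho))
  cells <- C_cell_probs(rep_len(as.numeric(mu1), n), rep_len(as.numeric(mu2), n),
                        rep_len(as.numeric(rho), n))
  y1 <- rep_len(y1, n); y2 <- rep_len(y2, n)
  col <- ifelse(y1 == 1, ifelse(y2 == 1, 1L, 2L), ifelse(y2 == 1, 3L, 4L))
  cells[cbind(seq_len(n), col)]
}

#' @rdname cell_probability
#' @return `cell_probabilities()` returns an n x 4 matrix with columns
#'   `p11`, `p10`, `p01`, `p00`.
#' @export
cell_probabilities <- function(mu1, mu2, rho) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1))
    .gbp_error("correlation must satisfy |rho| < 1", "gbp_domain_error")
  n <- max(length(mu1), length(mu2), length(rho))
  out <- C_cell_probs(rep_len(as.numeric(mu1), n), rep_len(as.numeric(mu2), n),
                      rep_len(as.numeric(rho), n))
  colnames(out) <- c("p11", "p10", "p01", "p00")
  out
}

#' Per-record parameter state of the distributional model
#'
#' Bundles the three predictor vectors (probit means and the Fisher-z
#' transformed correlation) evaluated per record, with the derived
#' correlation `rho = tanh(eta_rho)`.
#'
#' @param eta_mu1,eta_mu2 probit-mean predictors (identity link).
#' @param eta_rho correlation predictor on the Fisher-z scale.
#' @return object of class `parameter_state`.
#' @export
parameter_state <- function(eta_mu1, eta_mu2, eta_rho) {
  if (!all(is.finite(eta_mu1), is.finite(eta_mu2), is.finite(eta_rho)))
    .gbp_error("predictors must be finite", "gbp_domain_error")
  n <- length(eta_mu1)
  if (length(eta_mu2) != n || length(eta_rho) != n)
    .gbp_error("predictor vectors must have equal length", "gbp_domain_error")
  structure(list(eta_mu1 = as.numeric(eta_mu1), eta_mu2 = as.numeric(eta_mu2),
                 eta_rho = as.numeric(eta_rho), rho = tanh(eta_rho), n = n),
            class = "parameter_state")
}

#' Bivariate probit log-likelihood
#'
#' Sum over records of the log cell probability of the observed outcome
#' pair at the given parameter state.  Probabilities are floored at 1e-300
#' before taking logs so the result is always finite.
#'
#' @param ds a dataset built by [read_table()] / [simulate_dataset()], or any
#'   list with 0/1 vectors `y1` and `y2`.
#' @param state a [parameter_state()] aligned with `ds`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(ds, state) {
  y1 <- ds$y1; y2 <- ds$y2
  if (!inherits(state, "parameter_state"))
    state <- parameter_state(state$eta_mu1, state$eta_mu2, state$eta_rho)
  if (length(y1) != state$n || length(y2) != state$n)
    .gbp_error("dataset and state have different lengths", "gbp_domain_error")
  C_loglik(as.integer(y1), as.integer(y2), state$eta_mu1, state$eta_mu2,
           state$eta_rho)
}
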