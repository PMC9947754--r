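# Synthetic data with known linear, smooth and spatial effects on both
# probit means and the Fisher-z correlation, so inference can be checked by
# parameter recovery.  The default preset mirrors the motivating study's
# scale: about 2000 children on a 72-region map, stunting/wasting style
# prevalences near 40.7% and 9.7%.

.scheme_study <- list(
  wealth = c("poorest", "poorer", "middle", "richer", "richest"),
  toilet = c("unimproved", "improved"),
  food_security = c("secure", "mild", "moderate", "severe")
)

.scheme_binary <- list(
  improved_toilet = c("no", "yes"),
  fever_recent = c("no", "yes"),
  currently_breastfed = c("no", "yes")
)

.zero_fun <- function(lo, hi) list(fun = function(x) rep(0, length(x)), lo = lo, hi = hi)

.centred_fun <- function(f, lo, hi) {
  grid <- seq(lo, hi, length.out = 1001)
  offset <- mean(f(grid))
  list(fun = function(x) f(x) - offset, lo = lo, hi = hi)
}

.zero_linear <- function(scheme)
  lapply(scheme, function(lv) setNames(rep(0, length(lv)), lv))

#' Rook-adjacency lattice map
#'
#' A rows x cols grid of square regions where regions sharing an edge are
#' neighbours; a cheap stand-in for a district map.
#'
#' @param rows,cols positive integers.
#' @return an [adjacency_graph()] with `rows * cols` regions labelled
#'   row-major (`S01`, `S02`, ...); grid dimensions kept in
#'   `attr(, "lattice_dims")` for plotting.
#' @export
make_lattice_map <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  S <- rows * cols
  idx <- function(r, c) (r - 1) * cols + c
  neighbours <- vector("list", S)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    nb <- integer(0)
    if (r > 1) nb <- c(nb, idx(r - 1, c))
    if (r < rows) nb <- c(nb, idx(r + 1, c))
    if (c > 1) nb <- c(nb, idx(r, c - 1))
    if (c < cols) nb <- c(nb, idx(r, c + 1))
    neighbours[[idx(r, c)]] <- nb
  }
  labels <- sprintf("S%02d", seq_len(S))
  g <- suppressWarnings(adjacency_graph(labels, neighbours))
  attr(g, "lattice_dims") <- c(rows = rows, cols = cols)
  g
}

#' Ground-truth effects for a simulation scenario
#'
#' Builds the known effect decomposition the generator injects into each of
#' the three distribution parameters (mu1 = stunting mean, mu2 = wasting
#' mean, rho = Fisher-z correlation): an intercept, per-level linear
#' effects of the categorical covariates (reference level 0), centred
#' smooth functions of child and mother age, and a centred spatial effect
#' vector over the regions of `g`.
#'
#' Scenarios: `"null"` (everything zero, 50% prevalences),
#' `"intercepts_only"` (prevalence-matched intercepts
#' `qnorm(0.407)`, `qnorm(0.097)`, zero correlation; all effects zero),
#' `"linear_only"` (prevalence-matched intercepts plus linear effects of
#' three binary covariates), and `"full_geoadditive"` (study-style
#' categorical covariates, sinusoidal age effects, and spatial effects
#' drawn from a proper GMRF surrogate with precision `K + 1e-6 I`, centred
#' to sum to zero, then rescaled to fixed marginal spread so effect size is
#' comparable across seeds).
#'
#' @param g an [adjacency_graph()].
#' @param scenario scenario name, see above.
#' @param seed integer seed (only the spatial draw consumes randomness).
#' @return object of class `true_effects`.
#' @export
sample_true_effects <- function(g, scenario = c("null", "intercepts_only",
                                                "linear_only", "full_geoadditive"),
                                seed = 1) {
  if (!is.character(scenario) || !scenario[1] %in%
      c("null", "intercepts_only", "linear_only", "full_geoadditive"))
    .gbp_error(paste0("unknown scenario: ", scenario[1]), "gbp_scenario_error")
  scenario <- scenario[1]
  S <- length(g$regions)
  ages <- list(child_age_months = c(6, 59), mother_age_years = c(15, 49))
  zero_smooth <- lapply(ages, function(rg) .zero_fun(rg[1], rg[2]))
  zero_spatial <- setNames(rep(0, S), g$regions)
  eff <- list(scenario = scenario, regions = g$regions,
              intercepts = c(mu1 = 0, mu2 = 0, rho = 0))
  if (scenario %in% c("null", "intercepts_only", "full_geoadditive"))
    scheme <- .scheme_study else scheme <- .scheme_binary
  eff$scheme <- scheme
  eff$linear <- list(mu1 = .zero_linear(scheme), mu2 = .zero_linear(scheme),
                     rho = .zero_linear(scheme))
  eff$smooth <- list(mu1 = zero_smooth, mu2 = zero_smooth, rho = zero_smooth)
  eff$spatial <- list(mu1 = zero_spatial, mu2 = zero_spatial, rho = zero_spatial)

  if (scenario != "null")
    eff$intercepts <- c(mu1 = qnorm(0.407), mu2 = qnorm(0.097), rho = 0)

  if (scenario == "linear_only") {
    eff$intercepts["rho"] <- atanh(0.2)
    eff$linear$mu1 <- list(improved_toilet = c(no = 0, yes = -0.35),
                           fever_recent = c(no = 0, yes = 0.30),
                           currently_breastfed = c(no = 0, yes = 0.20))
    eff$linear$mu2 <- list(improved_toilet = c(no = 0, yes = -0.30),
                           fever_recent = c(no = 0, yes = 0.25),
                           currently_breastfed = c(no = 0, yes = 0.30))
    eff$linear$rho <- list(improved_toilet = c(no = 0, yes = 0.15),
                           fever_recent = c(no = 0, yes = -0.15),
                           currently_breastfed = c(no = 0, yes = 0.10))
  }

  if (scenario == "full_geoadditive") {
    eff$intercepts["rho"] <- atanh(0.15)
    eff$linear$mu1 <- list(
      wealth = c(poorest = 0, poorer = -0.10, middle = -0.18, richer = -0.28,
                 richest = -0.45),
      toilet = c(unimproved = 0, improved = -0.30),
      food_security = c(secure = 0, mild = 0.10, moderate = 0.20, severe = 0.35))
    eff$linear$mu2 <- list(
      wealth = c(poorest = 0, poorer = -0.05, middle = -0.08, richer = -0.02,
                 richest = -0.10),
      toilet = c(unimproved = 0, improved = -0.15),
      food_security = c(secure = 0, mild = 0.05, moderate = 0.15, severe = 0.30))
    eff$linear$rho <- list(
      wealth = c(poorest = 0, poorer = -0.15, middle = -0.05, richer = 0,
                 richest = 0.05),
      toilet = c(unimproved = 0, improved = 0.05),
      food_security = c(secure = 0, mild = 0.05, moderate = 0.10, severe = 0.20))
    eff$smooth$mu1 <- list(
      child_age_months = .centred_fun(function(x) 0.35 * sin(2 * pi * (x - 6) / 53), 6, 59),
      mother_age_years = .centred_fun(function(x) 0.25 * cos(2 * pi * (x - 15) / 34), 15, 49))
    eff$smooth$mu2 <- list(
      child_age_months = .centred_fun(function(x) -0.30 * sin(pi * (x - 6) / 53), 6, 59),
      mother_age_years = .centred_fun(function(x) 0.20 * sin(2 * pi * (x - 15) / 34), 15, 49))
    eff$smooth$rho <- list(
      child_age_months = .centred_fun(function(x) 0.20 * cos(2 * pi * (x - 6) / 53), 6, 59),
      mother_age_years = .centred_fun(function(x) 0.15 * sin(pi * (x - 15) / 34), 15, 49))
    set.seed(seed)
    sds <- c(mu1 = 0.30, mu2 = 0.25, rho = 0.15)
    K <- gmrf_precision(g)
    R <- chol(K + diag(1e-6, S))
    for (k in names(sds)) {
      v <- backsolve(R, rnorm(S))
      v <- v - mean(v)
      if (sd(v) > 0) v <- v * sds[[k]] / sd(v)
      eff$spatial[[k]] <- setNames(v, g$regions)
    }
  }
  class(eff) <- "true_effects"
  eff
}

#' @export
print.true_effects <- function(x, ...) {
  cat(sprintf("<true_effects> scenario '%s', %d regions, covariates: %s\n",
              x$scenario, length(x$regions), paste(names(x$scheme), collapse = ", ")))
  invisible(x)
}

# Per-record predictor of one parameter under the ground truth.
.true_eta <- function(eff, k, cat_df, cont_df, region) {
  eta <- rep(eff$intercepts[[k]], nrow(cat_df))
  for (cn in names(eff$linear[[k]]))
    eta <- eta + eff$linear[[k]][[cn]][as.character(cat_df[[cn]])]
  for (cn in names(eff$smooth[[k]]))
    eta <- eta + eff$smooth[[k]][[cn]]$fun(cont_df[[cn]])
  eta + eff$spatial[[k]][region]
}

#' Simulate a dataset from the ground-truth model
#'
#' Draws covariates (categorical levels uniform, child age uniform on
#' months 6-59, mother age uniform on years 15-49, regions uniform over the
#' map), assembles the three predictors from `effects`, and draws each
#' record's latent pair from the bivariate normal with means
#' `(eta_mu1, eta_mu2)`, unit variances and record-specific correlation
#' `tanh(eta_rho)` (per-record Cholesky construction).  Outcomes indicate a
#' positive latent utility.
#'
#' @param g an [adjacency_graph()].
#' @param effects a [sample_true_effects()] object.
#' @param n number of records.
#' @param seed integer seed.
#' @return a `bp_dataset`; the true per-record predictors are attached as
#'   `attr(, "true_eta")` for recovery scoring.
#' @export
simulate_dataset <- function(g, effects, n, seed = 1) {
  stopifnot(inherits(effects, "true_effects"), n >= 1)
  set.seed(seed)
  scheme <- effects$scheme
  cat_df <- as.data.frame(lapply(scheme, function(lv)
    factor(sample(lv, n, replace = TRUE), levels = lv)),
    stringsAsFactors = TRUE)
  cont_df <- data.frame(child_age_months = runif(n, 6, 59),
                        mother_age_years = runif(n, 15, 49))
  region <- sample(g$regions, n, replace = TRUE)
  eta1 <- .true_eta(effects, "mu1", cat_df, cont_df, region)
  eta2 <- .true_eta(effects, "mu2", cat_df, cont_df, region)
  etar <- .true_eta(effects, "rho", cat_df, cont_df, region)
  rho <- tanh(etar)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  df <- cbind(data.frame(y1 = as.integer(eta1 + z1 > 0),
                         y2 = as.integer(eta2 + z2 > 0)),
              as.data.frame(lapply(cat_df, as.character), stringsAsFactors = FALSE),
              cont_df, data.frame(region = region, stringsAsFactors = FALSE))
  schema <- table_schema(y1 = "y1", y2 = "y2", categorical = names(scheme),
                         continuous = names(cont_df), region = "region",
                         ref_levels = lapply(scheme, `[`, 1))
  ds <- as_bp_dataset(df, schema)
  attr(ds, "true_eta") <- data.frame(eta_mu1 = eta1, eta_mu2 = eta2,
                                     eta_rho = etar)
  ds
}

#' Write ground-truth effects to JSON
#'
#' Evaluates the smooth functions on a grid and stores intercepts, linear
#' per-level effects, smooth grids and spatial vectors so an analysis run
#' can be scored against the truth without R objects.
#'
#' @param effects a [sample_true_effects()] object.
#' @param path output JSON path.
#' @param grid_n grid points per smooth covariate.
#' @return `path`, invisibly.
#' @export
write_truth <- function(effects, path, grid_n = 50) {
  sm <- lapply(effects$smooth, function(terms)
    lapply(terms, function(tm) {
      grid <- seq(tm$lo, tm$hi, length.out = grid_n)
      list(grid = grid, value = tm$fun(grid))
    }))
  out <- list(scenario = effects$scenario,
              intercepts = as.list(effects$intercepts),
              linear = effects$linear, smooth = sm,
              spatial = lapply(effects$spatial, as.list),
              regions = effects$regions)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}
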