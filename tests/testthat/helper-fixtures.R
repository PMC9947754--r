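# Shared fixtures.  Heavy MCMC fits are computed once per test run and
# reused across files (test files run alphabetically, so the acceptance
# file populates the cache first).

fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(name, expr) {
  if (!exists(name, envir = fit_cache))
    assign(name, force(expr), envir = fit_cache)
  get(name, envir = fit_cache)
}

# study-scale map used throughout
study_map <- function() make_lattice_map(8, 9)

# 20 null-scenario calibration fits (n = 2000, 72 regions, 4000 sweeps)
null_calibration <- function(n_rep = 20) cached_fit("null_calibration", {
  g <- study_map()
  out <- NULL
  for (s in seq_len(n_rep)) {
    eff <- sample_true_effects(g, "null", seed = s)
    ds <- simulate_dataset(g, eff, 2000, seed = 100 + s)
    dsn <- build_designs(ds, default_model_spec(linear = names(ds$cat)), g)
    dr <- run_chain(ds, dsn, sampler_config(iterations = 4000, burnin = 1000,
                                            thin = 5, seed = 10 + s))
    lin <- summarize_linear(dr)
    lin <- lin[lin$term != "(Intercept)", ]
    out <- rbind(out, cbind(replicate_seed = s, lin))
  }
  out
})

# linear-effect recovery fit (linear_only scenario, n = 4000)
linear_recovery <- function() cached_fit("linear_recovery", {
  g <- study_map()
  eff <- sample_true_effects(g, "linear_only", seed = 1)
  ds <- simulate_dataset(g, eff, 4000, seed = 201)
  dsn <- build_designs(ds, default_model_spec(names(ds$cat),
                                              smooth = character(),
                                              spatial = FALSE))
  dr <- run_chain(ds, dsn, sampler_config(4000, 1000, 5, seed = 21))
  list(draws = dr, effects = eff, ds = ds)
})

# full geoadditive recovery fit (n = 4000)
full_recovery <- function() cached_fit("full_recovery", {
  g <- study_map()
  eff <- sample_true_effects(g, "full_geoadditive", seed = 2)
  ds <- simulate_dataset(g, eff, 4000, seed = 202)
  dsn <- build_designs(ds, default_model_spec(names(ds$cat)), g)
  dr <- run_chain(ds, dsn, sampler_config(4000, 1000, 5, seed = 22))
  list(draws = dr, effects = eff, ds = ds, graph = g)
})

# small fit for summary/pipeline structure tests
small_fit <- function() cached_fit("small_fit", {
  g <- make_lattice_map(3, 3)
  eff <- sample_true_effects(g, "full_geoadditive", seed = 5)
  ds <- simulate_dataset(g, eff, 500, seed = 50)
  dsn <- build_designs(ds, default_model_spec(names(ds$cat), n_knots = 10), g)
  dr <- run_chain(ds, dsn, sampler_config(600, 100, 1, seed = 51))
  list(draws = dr, effects = eff, ds = ds, graph = g)
})

# hand-assembled posterior_draws holding a single linear block
fake_linear_draws <- function(M, param = "mu1") {
  colnames(M) <- colnames(M) %||% paste0("b", seq_len(ncol(M)))
  structure(list(
    draws = setNames(list(M), paste0(param, ":linear")),
    tau2 = matrix(numeric(0), nrow(M), 0),
    loglik = rep(0, nrow(M)),
    accept_rate = setNames(1, paste0(param, ":linear")),
    blocks = list(list(kind = "linear", param = param,
                       label = paste0(param, ":linear"), d = ncol(M),
                       Z = matrix(1, 1, ncol(M)),
                       coef_names = colnames(M))),
    config = sampler_config(iterations = nrow(M) + 1, burnin = 0, thin = 1),
    n = 1, n_kept = nrow(M)), class = "posterior_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent 1-D-reduction quadrature oracle for the bivariate normal CDF
bvn_quad <- function(a, b, r)
  integrate(function(x) dnorm(x) * pnorm((b - r * x) / sqrt(1 - r^2)),
            -Inf, a, rel.tol = 1e-12)$value

cell_quad <- function(y1, y2, m1, m2, r) {
  p11 <- bvn_quad(m1, m2, r)
  if (y1 == 1 && y2 == 1) p11
  else if (y1 == 1) pnorm(m1) - p11
  else if (y2 == 1) pnorm(m2) - p11
  else 1 - pnorm(m1) - pnorm(m2) + p11
}
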