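# Sampler mechanics: initialisation, conjugate variance step, single-block
# MH-IWLS updates, reproducibility, and posterior behaviour under growing n.

test_that("initial state puts intercepts at the probit of the prevalences", {
  g <- make_lattice_map(2, 2)
  eff <- sample_true_effects(g, "intercepts_only")
  ds <- simulate_dataset(g, eff, 5000, seed = 42)
  dsn <- build_designs(ds, default_model_spec(names(ds$cat)), g)
  st <- init_state(dsn, ds)
  expect_equal(st[["mu1:linear"]]$beta[1], qnorm(mean(ds$y1)))
  expect_equal(st[["mu2:linear"]]$beta[1], qnorm(mean(ds$y2)))
  expect_equal(st[["rho:linear"]]$beta[1], 0)
  expect_true(all(st[["mu1:linear"]]$beta[-1] == 0))
  expect_equal(st[["mu1:s(child_age_months)"]]$tau2, 0.1)
  # the paper-scale prevalences imply the documented intercepts
  expect_equal(qnorm(c(0.407, 0.097)), c(-0.2353, -1.2988), tolerance = 1e-4)
})

test_that("sampler configuration is validated", {
  expect_error(sampler_config(iterations = 100, burnin = 100))
  expect_error(sampler_config(thin = 0))
  expect_error(sampler_config(ig_a = 0))
})

test_that("chains are a pure function of data, spec, config and seed", {
  fit <- small_fit()
  g <- fit$graph
  dsn <- build_designs(fit$ds, default_model_spec(names(fit$ds$cat),
                                                  n_knots = 10), g)
  cfg <- sampler_config(600, 100, 1, seed = 51)
  again <- run_chain(fit$ds, dsn, cfg)
  expect_identical(again$draws, fit$draws$draws)
  expect_identical(again$tau2, fit$draws$tau2)
  expect_identical(again$loglik, fit$draws$loglik)
})

test_that("conjugate variance step reduces to the prior-rate draw in the null space", {
  K <- rw2_penalty(10)
  block <- list(K = unclass(K), rank = attr(K, "rank"))
  cfg <- sampler_config(ig_a = 2, ig_b = 3)
  beta <- 2.5 + 0.4 * seq_len(10)  # constant + linear: K beta = 0
  set.seed(40)
  draws <- replicate(5000, update_variance(block, beta, cfg))
  shape <- 2 + 8 / 2; rate <- 3
  expect_equal(mean(draws), rate / (shape - 1), tolerance = 0.05)
  # arithmetic of the full conditional: a = b = 0.001, rank 20, qform 10
  K22 <- rw2_penalty(22)
  b22 <- list(K = unclass(K22), rank = attr(K22, "rank"))
  beta22 <- rnorm(22)
  qf <- drop(crossprod(beta22, b22$K %*% beta22))
  scl <- sqrt(10 / qf)
  set.seed(41)
  d2 <- replicate(20000, update_variance(b22, beta22 * scl, sampler_config()))
  expect_equal(mean(d2), 5.001 / (10.001 - 1), tolerance = 0.02)
})

test_that("conjugate variance draws match an independent inverse-gamma sampler", {
  K <- rw2_penalty(15)
  block <- list(K = unclass(K), rank = attr(K, "rank"))
  cfg <- sampler_config()
  set.seed(55)
  beta <- rnorm(15, 0, 0.7)
  qf <- drop(crossprod(beta, block$K %*% beta))
  set.seed(56)
  mine <- replicate(1e4, update_variance(block, beta, cfg))
  set.seed(57)
  ref <- 1 / rgamma(1e4, shape = cfg$ig_a + block$rank / 2,
                    rate = cfg$ig_b + qf / 2)
  expect_gt(suppressWarnings(ks.test(mine, ref)$p.value), 0.01)
})

test_that("with a flat likelihood the block update samples the prior conditional", {
  n <- 6
  set.seed(61)
  blk <- list(kind = "linear", param = "mu1", Z = matrix(rnorm(n * 3), n, 3),
              K = diag(3), rank = 3)
  ds <- list(y1 = rep(0L, n), y2 = rep(0L, n))
  tau2 <- 0.5
  beta <- rnorm(3)
  acc <- 0
  draws <- matrix(NA_real_, 3000, 3)
  for (i in 1:3000) {
    r <- update_coefficient_block(ds, blk, beta, rep(0, n), rep(0, n),
                                  rep(0, n), tau2 = tau2,
                                  flat_likelihood = TRUE)
    acc <- acc + r$accepted
    beta <- r$beta
    draws[i, ] <- beta
  }
  expect_gt(acc / 3000, 0.999)  # proposal equals the target
  expect_equal(unname(apply(draws, 2, sd)), rep(sqrt(tau2), 3), tolerance = 0.08)
  expect_equal(unname(colMeans(draws)), rep(0, 3), tolerance = 0.05)
})

test_that("with other predictors fixed at truth the intercept chain finds the profile optimum", {
  g <- make_lattice_map(2, 2)
  eff <- sample_true_effects(g, "intercepts_only")
  ds <- simulate_dataset(g, eff, 2000, seed = 71)
  n <- ds$n
  te <- attr(ds, "true_eta")
  blk <- list(kind = "linear", param = "mu1",
              Z = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  opt <- optimize(function(c)
    log_likelihood(ds, parameter_state(rep(c, n), te$eta_mu2, te$eta_rho)),
    c(-2, 2), maximum = TRUE)$maximum
  set.seed(72)
  beta <- 0
  chain <- numeric(800)
  for (i in seq_along(chain)) {
    r <- update_coefficient_block(ds, blk, beta, rep(beta, n), te$eta_mu2,
                                  te$eta_rho)
    beta <- r$beta
    chain[i] <- beta
  }
  kept <- chain[-(1:100)]
  mcse <- sd(kept) / sqrt(length(kept) / 10)  # conservative autocorrelation
  expect_lt(abs(mean(kept) - opt), 2 * mcse + 0.005)
})

test_that("acceptance rates stay in a workable band on the default study-scale fit", {
  fit <- full_recovery()
  expect_true(all(fit$draws$accept_rate >= 0.2))
  expect_true(all(fit$draws$accept_rate <= 1))
})

test_that("fitted per-record correlations track the truth on the default scenario", {
  fit <- full_recovery()
  pr <- fitted_predictors(fit$draws)
  te <- attr(fit$ds, "true_eta")
  expect_gt(cor(pr$rho_hat, tanh(te$eta_rho)), 0.6)
})

test_that("doubling the sample size shrinks credible intervals of linear effects", {
  g <- make_lattice_map(2, 2)
  widths <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    eff <- sample_true_effects(g, "linear_only", seed = s)
    for (j in 1:2) {
      n <- c(600, 1200)[j]
      ds <- simulate_dataset(g, eff, n, seed = 300 + 10 * s + j)
      dsn <- build_designs(ds, default_model_spec(names(ds$cat),
                                                  smooth = character(),
                                                  spatial = FALSE))
      dr <- run_chain(ds, dsn, sampler_config(1000, 300, 2, seed = 90 + s))
      lin <- summarize_linear(dr)
      lin <- lin[lin$term != "(Intercept)" & lin$parameter %in% c("mu1", "mu2"), ]
      widths[s, j] <- mean(lin$upper - lin$lower)
    }
  }
  expect_lt(mean(widths[, 2]), mean(widths[, 1]))
  expect_gte(sum(widths[, 2] < widths[, 1]), 4)
})
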