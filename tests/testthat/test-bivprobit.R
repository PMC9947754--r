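# Links, bivariate normal CDF, cell probabilities and the log-likelihood.

test_that("Fisher-z link and its inverse round-trip", {
  expect_equal(rho_link_inv(0), 0)
  expect_equal(rho_link_inv(atanh(0.95)), 0.95, tolerance = 1e-12)
  expect_equal(rho_link_inv(0.5), 0.46211716, tolerance = 1e-8)
  expect_equal(rho_link(rho_link_inv(-2.3)), -2.3, tolerance = 1e-12)
  expect_error(rho_link(1), class = "gbp_domain_error")
  expect_error(rho_link_inv(NaN), class = "gbp_domain_error")
})

test_that("bivariate normal CDF agrees with quadrature and handles marginals", {
  expect_equal(binorm_cdf(0, 0, 0), 0.25)
  expect_equal(binorm_cdf(0, 0, 0.5), 1 / 4 + asin(0.5) / (2 * pi),
               tolerance = 1e-10)
  expect_equal(binorm_cdf(Inf, 0.7, 0.3), pnorm(0.7), tolerance = 1e-12)
  expect_equal(binorm_cdf(-Inf, 0.7, 0.3), 0)
  expect_equal(binorm_cdf(1.2, Inf, -0.8), pnorm(1.2), tolerance = 1e-12)
  expect_error(binorm_cdf(0, 0, 1), class = "gbp_domain_error")

  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(1, 0, 2); b <- rnorm(1, 0, 2); r <- runif(1, -0.995, 0.995)
    expect_equal(binorm_cdf(a, b, r), bvn_quad(a, b, r), tolerance = 1e-8)
  }
})

test_that("the CDF agrees with direct 2-D integration of the density", {
  dens <- function(x, y, r) {
    s2 <- 1 - r^2
    exp(-(x^2 - 2 * r * x * y + y^2) / (2 * s2)) / (2 * pi * sqrt(s2))
  }
  # moderate correlations: the adaptive cubature itself is only reliable
  # away from the near-singular ridge (the sharper 1-D reduction oracle
  # below covers the full correlation range)
  cases <- list(c(0.4, -0.3, 0.5), c(-1.1, 0.8, -0.7), c(1.5, 1.2, 0.6))
  for (cs in cases) {
    q <- pracma::integral2(function(x, y) dens(x, y, cs[3]),
                           -8, cs[1], -8, cs[2], reltol = 1e-10)$Q
    expect_equal(binorm_cdf(cs[1], cs[2], cs[3]), q, tolerance = 1e-6)
  }
})

test_that("the CDF is nondecreasing in both thresholds and in rho at zero", {
  a <- seq(-3, 3, length.out = 41)
  expect_true(all(diff(binorm_cdf(a, 0.4, 0.6)) >= 0))
  expect_true(all(diff(binorm_cdf(-0.2, a, -0.6)) >= 0))
  r <- seq(-0.99, 0.99, length.out = 81)
  expect_true(all(diff(binorm_cdf(0, 0, r)) >= 0))
})

test_that("cell probabilities factorise at rho = 0 and complement correctly", {
  expect_equal(unname(cell_probabilities(0, 0, 0)[1, ]), rep(0.25, 4))
  set.seed(12)
  m1 <- rnorm(20); m2 <- rnorm(20)
  cells <- cell_probabilities(m1, m2, 0)
  expect_equal(cells[, "p11"], pnorm(m1) * pnorm(m2), tolerance = 1e-12)
  expect_equal(cells[, "p10"], pnorm(m1) * pnorm(-m2), tolerance = 1e-12)
  expect_equal(cells[, "p00"], pnorm(-m1) * pnorm(-m2), tolerance = 1e-12)
  expect_equal(cell_probability(1, 1, 0, 0, 0.5), 1 / 3, tolerance = 1e-10)
  expect_equal(cell_probability(0, 0, 0, 0, 0.5), 1 / 3, tolerance = 1e-10)
  expect_error(cell_probability(2, 0, 0, 0, 0), class = "gbp_domain_error")
})

test_that("log-likelihood is the sum of log cell probabilities and is additive", {
  one <- list(y1 = 1L, y2 = 1L)
  st <- parameter_state(0, 0, 0)
  expect_equal(log_likelihood(one, st), log(0.25))

  g <- make_lattice_map(2, 2)
  eff <- sample_true_effects(g, "linear_only", seed = 3)
  ds <- simulate_dataset(g, eff, 80, seed = 31)
  te <- attr(ds, "true_eta")
  st <- parameter_state(te$eta_mu1, te$eta_mu2, te$eta_rho)
  ll <- log_likelihood(ds, st)
  dbl <- list(y1 = rep(ds$y1, 2), y2 = rep(ds$y2, 2))
  st2 <- parameter_state(rep(te$eta_mu1, 2), rep(te$eta_mu2, 2),
                         rep(te$eta_rho, 2))
  expect_equal(log_likelihood(dbl, st2), 2 * ll, tolerance = 1e-10)
  expect_error(log_likelihood(ds, parameter_state(0, 0, 0)),
               class = "gbp_domain_error")
  # extreme predictors stay finite through the probability floor
  stx <- parameter_state(rep(-40, ds$n), rep(40, ds$n), rep(0, ds$n))
  expect_true(is.finite(log_likelihood(ds, stx)))
})

test_that("the true parameters beat perturbed parameters on large samples", {
  g <- make_lattice_map(2, 2)
  eff <- sample_true_effects(g, "linear_only", seed = 6)
  ds <- simulate_dataset(g, eff, 20000, seed = 61)
  te <- attr(ds, "true_eta")
  st <- parameter_state(te$eta_mu1, te$eta_mu2, te$eta_rho)
  ll_true <- log_likelihood(ds, st)
  set.seed(62)
  for (i in 1:5) {
    pert <- parameter_state(te$eta_mu1 + rnorm(1, 0, 0.2),
                            te$eta_mu2 + rnorm(1, 0, 0.2),
                            te$eta_rho + rnorm(1, 0, 0.2))
    expect_gt(ll_true, log_likelihood(ds, pert))
  }
})
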