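# Posterior summaries: effect tables, curves, spatial classes, diagnostics.

test_that("linear summaries flag significance exactly when the interval excludes zero", {
  const <- fake_linear_draws(matrix(0.5, 200, 1, dimnames = list(NULL, "b")))
  s1 <- summarize_linear(const)
  expect_equal(s1$mean, 0.5)
  expect_equal(s1$lower, 0.5)
  expect_equal(s1$upper, 0.5)
  expect_true(s1$significant)

  set.seed(1)
  sym <- fake_linear_draws(matrix(rnorm(5000), ncol = 1,
                                  dimnames = list(NULL, "b")))
  expect_false(summarize_linear(sym)$significant)

  set.seed(2)
  z <- fake_linear_draws(matrix(rnorm(1e4), ncol = 1,
                                dimnames = list(NULL, "b")))
  sz <- summarize_linear(z)
  expect_equal(sz$lower, -1.96, tolerance = 0.05 / 1.96)
  expect_equal(sz$upper, 1.96, tolerance = 0.05 / 1.96)

  fit <- small_fit()
  lin <- summarize_linear(fit$draws)
  expect_true(all(lin$lower <= lin$mean & lin$mean <= lin$upper))
  expect_equal(lin$significant, lin$lower > 0 | lin$upper < 0)
})

test_that("curves are centred over the fitting data and zero for zero coefficients", {
  fit <- small_fit()
  dr0 <- fit$draws
  j <- which(vapply(dr0$blocks, function(b)
    b$kind == "spline" && b$param == "mu1" &&
      b$covariate == "child_age_months", TRUE))[1]
  # centring: per kept draw the fitted curve averages to zero over the data
  B <- block_design_matrix(dr0$blocks[[j]])
  fvals <- B %*% t(dr0$draws[[j]])
  expect_lt(max(abs(colMeans(fvals))), 1e-8)

  dr0$draws[[j]][] <- 0
  cv <- summarize_curve(dr0, "mu1", "child_age_months")
  expect_true(all(cv$mean == 0))
  expect_true(all(cv$upper - cv$lower == 0))
  expect_error(summarize_curve(dr0, "mu1", "child_age_months",
                               grid = c(5, 30)),
               class = "gbp_extrapolation_error")
})

test_that("spatial classes follow the interval sign and are antisymmetric", {
  fit <- small_fit()
  sp <- summarize_spatial(fit$draws, "mu1")
  expect_equal(sp$class, ifelse(sp$lower > 0, 1L, ifelse(sp$upper < 0, -1L, 0L)))

  neg <- fit$draws
  j <- which(vapply(neg$blocks, function(b)
    b$kind == "spatial" && b$param == "mu1", TRUE))[1]
  neg$draws[[j]] <- -neg$draws[[j]]
  spn <- summarize_spatial(neg, "mu1")
  expect_equal(spn$class, -sp$class)
  expect_equal(spn$mean, -sp$mean)
})

test_that("strong true spatial effects are classified positive more than mid-range ones", {
  fit <- full_recovery()
  sp <- summarize_spatial(fit$draws, "mu1")
  truth <- fit$effects$spatial$mu1[sp$region]
  top <- order(truth, decreasing = TRUE)[1:8]
  mid <- order(abs(truth))[1:8]
  expect_gt(mean(sp$class[top]), mean(sp$class[mid]))
  expect_gt(mean(sp$class[top]), 0)
})

test_that("effective sample size behaves like iid, degenerate and AR(1) theory", {
  set.seed(7)
  iid <- fake_linear_draws(matrix(rnorm(4000), ncol = 1,
                                  dimnames = list(NULL, "b")))
  d <- suppressWarnings(convergence_diagnostics(iid))  # constant loglik column
  expect_gt(d$ess[1], 0.8 * 4000)
  expect_lt(d$ess[1], 1.2 * 4000)

  const <- fake_linear_draws(matrix(1, 500, 1, dimnames = list(NULL, "b")))
  dc <- suppressWarnings(convergence_diagnostics(const))
  expect_lte(dc$ess[1], 1)
  expect_true(dc$flagged[1])

  L <- 5000
  phi <- 0.9
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = phi), L))
  da <- suppressWarnings(convergence_diagnostics(
    fake_linear_draws(matrix(x, ncol = 1, dimnames = list(NULL, "b")))))
  target <- L * (1 - phi) / (1 + phi)
  expect_gt(da$ess[1], target / 1.5)
  expect_lt(da$ess[1], target * 1.5)
})

test_that("split-chain Rhat flags a mean shift and accepts stationary chains", {
  set.seed(9)
  drift <- fake_linear_draws(matrix(c(rnorm(1000), rnorm(1000, 3)), ncol = 1,
                                    dimnames = list(NULL, "b")))
  dd <- suppressWarnings(convergence_diagnostics(drift))
  expect_gt(dd$rhat[1], 1.1)
  expect_true(dd$flagged[1])

  fit <- small_fit()
  dg <- suppressWarnings(convergence_diagnostics(fit$draws))
  ncols <- ncol(as_chain_matrix(fit$draws))
  expect_equal(nrow(dg), ncols)
  expect_true(all(is.finite(dg$ess)))
})
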