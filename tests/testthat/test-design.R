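# B-spline bases, penalty matrices and the assembled design blocks.

test_that("B-spline basis has the counting rule, partition of unity and indicator limit", {
  w <- runif(200, 6, 59)
  B <- bspline_basis(w, n_knots = 20, degree = 3)
  expect_equal(ncol(B), 22)  # n_knots + degree - 1
  expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
  expect_true(all(B >= 0))

  B8 <- bspline_basis(w, n_knots = 8, degree = 2)
  expect_equal(ncol(B8), 9)
  expect_lt(max(abs(rowSums(B8) - 1)), 1e-12)

  B0 <- bspline_basis(c(0, 0.3, 0.5, 0.99, 1), n_knots = 4, degree = 0)
  expect_equal(ncol(B0), 3)
  expect_true(all(rowSums(B0 == 1) == 1))  # one indicator per row
  expect_true(all(rowSums(B0) == 1))

  expect_error(bspline_basis(rep(2, 10)), class = "gbp_design_error")
})

test_that("RW2 penalty is the explicit second-difference cross-product", {
  K4 <- unclass(rw2_penalty(4))
  expect_equal(K4, matrix(c(1, -2, 1, 0,
                            -2, 5, -4, 1,
                            1, -4, 5, -2,
                            0, 1, -2, 1), 4, byrow = TRUE),
               ignore_attr = TRUE)
  expect_error(rw2_penalty(2), class = "gbp_design_error")
})

test_that("GMRF precision encodes neighbour counts and adjacency", {
  g2 <- adjacency_graph(c("A", "B"), list(2L, 1L))
  expect_equal(unclass(gmrf_precision(g2)),
               matrix(c(1, -1, -1, 1), 2,
                      dimnames = list(c("A", "B"), c("A", "B"))),
               ignore_attr = TRUE)
  path <- adjacency_graph(c("A", "B", "C"), list(2L, c(1L, 3L), 2L))
  expect_equal(unname(diag(gmrf_precision(path))), c(1, 2, 1))
  # islands yield an all-zero row and reduce the rank per extra component
  gi <- suppressWarnings(adjacency_graph(c("A", "B", "C"), list(2L, 1L, integer(0))))
  Ki <- gmrf_precision(gi)
  expect_equal(unname(Ki[3, ]), c(0, 0, 0))
  expect_equal(attr(Ki, "rank"), 1)
  expect_equal(attr(Ki, "n_components"), 2)
})

test_that("all penalty matrices are positive semidefinite", {
  for (d in c(3, 7, 22)) {
    ev <- eigen(unclass(rw2_penalty(d)), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
  set.seed(14)
  for (dims in list(c(2, 5), c(6, 6), c(1, 9))) {
    K <- gmrf_precision(make_lattice_map(dims[1], dims[2]))
    ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("design blocks carry dummy coding, indicators, penalties and the declared structure", {
  g <- make_lattice_map(8, 9)
  eff <- sample_true_effects(g, "full_geoadditive", seed = 1)
  ds <- simulate_dataset(g, eff, 300, seed = 15)
  dsn <- build_designs(ds, default_model_spec(linear = names(ds$cat)), g)

  for (k in c("mu1", "mu2", "rho")) {
    kinds <- vapply(dsn[[k]], `[[`, "", "kind")
    expect_equal(kinds, c("linear", "spline", "spline", "spatial"))
  }
  lin <- dsn$mu1[[1]]
  # wealth has 5 levels with reference poorest -> 4 dummies
  expect_equal(sum(grepl("^wealth", lin$coef_names)), 4)
  expect_false("wealthpoorest" %in% lin$coef_names)
  expect_equal(lin$coef_names[1], "(Intercept)")
  # dummy columns sum to category counts
  expect_equal(unname(colSums(lin$Z[, grepl("^wealth", lin$coef_names)])),
               unname(table(ds$cat$wealth)[-1]), ignore_attr = TRUE)

  spat <- dsn$mu1[[4]]
  Zs <- block_design_matrix(spat)
  i <- 7
  expect_equal(unname(which(Zs[i, ] == 1)), match(ds$region[i], g$regions))
  expect_equal(rowSums(Zs), rep(1, ds$n))

  spl <- dsn$mu1[[2]]
  expect_equal(spl$d, 22)
  expect_equal(spl$rank, 20)
  B <- block_design_matrix(spl)
  Bref <- bspline_basis(ds$cont$child_age_months)
  expect_equal(unname(B), unname(matrix(Bref, nrow(Bref))), tolerance = 1e-12)
})

test_that("moving a constant between a centred block and the intercept leaves eta unchanged", {
  g <- make_lattice_map(3, 3)
  eff <- sample_true_effects(g, "full_geoadditive", seed = 2)
  ds <- simulate_dataset(g, eff, 120, seed = 16)
  dsn <- build_designs(ds, default_model_spec(names(ds$cat), n_knots = 8), g)
  lin <- dsn$mu1[[1]]; spl <- dsn$mu1[[2]]
  set.seed(3)
  bl <- rnorm(lin$d); bs <- rnorm(spl$d)
  eta <- drop(lin$Z %*% bl) + drop(block_design_matrix(spl) %*% bs)
  cshift <- 0.73
  bl2 <- bl; bl2[1] <- bl[1] - cshift
  eta2 <- drop(lin$Z %*% bl2) + drop(block_design_matrix(spl) %*% (bs + cshift))
  expect_equal(eta2, eta, tolerance = 1e-12)
})

test_that("unknown covariates and regions are design errors", {
  g <- make_lattice_map(2, 2)
  eff <- sample_true_effects(g, "intercepts_only")
  ds <- simulate_dataset(g, eff, 50, seed = 1)
  expect_error(build_designs(ds, default_model_spec("nope"), g),
               class = "gbp_design_error")
  spec <- default_model_spec(names(ds$cat), smooth = "not_a_column")
  expect_error(build_designs(ds, spec, g), class = "gbp_design_error")
  ds$region[1] <- "ZZ"
  expect_error(build_designs(ds, default_model_spec(names(ds$cat)), g),
               class = "gbp_design_error")
})
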