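# Design and penalty blocks for the three geoadditive predictors:
# dummy-coded linear designs (flat prior), cubic B-spline bases with
# second-order random-walk penalties, and intrinsic GMRF precision matrices
# for discrete spatial units.

#' Cubic B-spline basis on equidistant knots
#'
#' Basis of `n_knots + degree - 1` B-splines of the given degree on
#' `n_knots` equidistant knots spanning the covariate range (the knot grid
#' is extended by `degree` equidistant knots on each side).  Rows form a
#' partition of unity on the covariate range.
#'
#' @param w covariate vector with at least two distinct values.
#' @param n_knots number of equidistant knots (default 20, giving 22 cubic
#'   basis functions).
#' @param degree spline degree (default 3, cubic).
#' @return n x D basis matrix with attributes `knots` (full extended
#'   vector), `lo`, `hi`, `n_knots`, `degree`.
#' @export
bspline_basis <- function(w, n_knots = 20, degree = 3) {
  if (length(unique(w)) < 2)
    .gbp_error("constant covariate: cannot build a spline basis", "gbp_design_error")
  stopifnot(n_knots >= 2, degree >= 0)
  lo <- min(w); hi <- max(w)
  if (any(w < lo | w > hi)) .gbp_error("values outside range", "gbp_design_error")
  step <- (hi - lo) / (n_knots - 1)
  # anchor the grid on lo so the boundary knot equals min(w) exactly
  knots <- lo + step * seq(-degree, n_knots - 1 + degree)
  # guard the right boundary against floating-point inclusion checks
  x <- pmin(pmax(w, lo), hi)
  eps <- 1e-9 * (hi - lo)
  x[x >= hi] <- hi - eps
  B <- splines::splineDesign(knots, x, ord = degree + 1)
  structure(B, knots = knots, lo = lo, hi = hi, n_knots = n_knots,
            degree = degree)
}

# compact row storage: first active column + the degree+1 active values
.bspline_compact <- function(B) {
  degree <- attr(B, "degree")
  n_knots <- attr(B, "n_knots")
  lo <- attr(B, "lo"); hi <- attr(B, "hi")
  D <- ncol(B)
  q <- degree + 1
  first <- max.col(B != 0, ties.method = "first")
  first <- pmin(first, D - degree)
  Bx <- matrix(0, nrow(B), q)
  for (j in seq_len(q)) Bx[, j] <- B[cbind(seq_len(nrow(B)), first + j - 1)]
  list(Bx = Bx, Bi = first, d = D)
}

#' Second-order random-walk penalty matrix
#'
#' `K = t(D2) %*% D2` with `D2` the second-difference operator, the
#' precision of an RW2 prior over adjacent B-spline coefficients.  `K`
#' annihilates constant and linear coefficient vectors; rank `d - 2`.
#'
#' @param d basis dimension, at least 3.
#' @return d x d penalty matrix with `attr(, "rank") = d - 2`.
#' @export
rw2_penalty <- function(d) {
  if (d < 3) .gbp_error("RW2 penalty needs dimension >= 3", "gbp_design_error")
  D2 <- diff(diag(d), differences = 2)
  structure(crossprod(D2), rank = d - 2)
}

#' Intrinsic GMRF precision matrix of an adjacency graph
#'
#' `K = diag(|N(s)|) - A` with `A` the adjacency matrix: the precision of
#' the intrinsic conditional-autoregressive prior whose full conditional
#' for region `s` is Gaussian with mean the average effect of its
#' neighbours and variance inversely proportional to the neighbour count.
#' Row sums are zero; the rank is `S` minus the number of connected
#' components (islands contribute a zero row and are flagged by the graph).
#'
#' @param g an [adjacency_graph()].
#' @return S x S precision matrix with region dimnames and attributes
#'   `rank` and `n_components`.
#' @export
gmrf_precision <- function(g) {
  S <- length(g$regions)
  K <- matrix(0, S, S, dimnames = list(g$regions, g$regions))
  for (s in seq_len(S)) {
    nb <- g$neighbours[[s]]
    K[s, s] <- length(nb)
    K[s, nb] <- -1
  }
  ncomp <- .n_components(g)
  structure(K, rank = S - ncomp, n_components = ncomp)
}

.n_components <- function(g) {
  S <- length(g$regions)
  seen <- logical(S)
  ncomp <- 0L
  for (s0 in seq_len(S)) {
    if (seen[s0]) next
    ncomp <- ncomp + 1L
    queue <- s0
    seen[s0] <- TRUE
    while (length(queue)) {
      s <- queue[1]; queue <- queue[-1]
      for (r in g$neighbours[[s]]) if (!seen[r]) {
        seen[r] <- TRUE
        queue <- c(queue, r)
      }
    }
  }
  ncomp
}

#' Smooth-term declaration
#'
#' @param covariate name of a continuous covariate.
#' @param n_knots,degree basis settings, see [bspline_basis()].
#' @return smooth-term descriptor for [model_spec()].
#' @export
sm <- function(covariate, n_knots = 20, degree = 3) {
  list(covariate = covariate, n_knots = n_knots, degree = degree)
}

#' Term lists for one distribution parameter
#'
#' @param linear character vector of categorical covariates entering as
#'   dummy-coded linear effects (an intercept is always included).
#' @param smooth list of [sm()] terms.
#' @param spatial logical: include a GMRF spatial term over the map regions.
#' @return parameter term descriptor for [model_spec()].
#' @export
param_terms <- function(linear = character(), smooth = list(), spatial = TRUE) {
  list(linear = linear, smooth = smooth, spatial = spatial)
}

#' Model specification for the three distribution parameters
#'
#' Declares, for each of mu1 (stunting probit mean), mu2 (wasting probit
#' mean) and rho (Fisher-z latent correlation), which terms enter its
#' predictor.  Links are fixed: identity for the means, Fisher-z for the
#' correlation.
#'
#' @param mu1,mu2,rho [param_terms()] objects.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(mu1, mu2, rho) {
  structure(list(mu1 = mu1, mu2 = mu2, rho = rho), class = "model_spec")
}

#' Default specification: same terms on all three parameters
#'
#' The correlation carries the same covariate set as the means, so linear,
#' nonlinear and spatial effects are reported for all three parameters.
#'
#' @param linear categorical covariates for the linear parts.
#' @param smooth continuous covariates modelled as cubic P-splines.
#' @param spatial include the spatial term.
#' @param n_knots knots per smooth term.
#' @return a [model_spec()].
#' @export
default_model_spec <- function(linear,
                               smooth = c("child_age_months", "mother_age_years"),
                               spatial = TRUE, n_knots = 20) {
  pt <- param_terms(linear = linear,
                    smooth = lapply(smooth, sm, n_knots = n_knots),
                    spatial = spatial)
  model_spec(pt, pt, pt)
}

#' Build design and penalty blocks for every predictor term
#'
#' Linear terms become one dummy-coded block per parameter (intercept plus
#' treatment contrasts with the dataset's declared reference levels);
#' smooth terms become B-spline blocks with RW2 penalties; the spatial term
#' becomes a region-indicator block (design row is the indicator of the
#' record's region) with the intrinsic GMRF precision.  Spline and spatial
#' blocks are identified by sum-to-zero centring absorbed into the
#' intercept during sampling.
#'
#' @param ds a `bp_dataset`.
#' @param spec a [model_spec()].
#' @param g an [adjacency_graph()] (required when any parameter has a
#'   spatial term).
#' @return object of class `design_set`: per-parameter lists of blocks.
#' @export
build_designs <- function(ds, spec, g = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  out <- list()
  for (k in c("mu1", "mu2", "rho")) {
    terms <- spec[[k]]
    blocks <- list()
    unknown <- setdiff(terms$linear, names(ds$cat))
    if (length(unknown))
      .gbp_error(paste0("unknown categorical covariate(s): ",
                        paste(unknown, collapse = ", ")), "gbp_design_error")
    if (length(terms$linear)) {
      Z <- model.matrix(~ ., ds$cat[, terms$linear, drop = FALSE])
    } else {
      Z <- matrix(1, ds$n, 1, dimnames = list(NULL, "(Intercept)"))
    }
    blocks[[length(blocks) + 1]] <- list(
      kind = "linear", param = k, label = paste0(k, ":linear"),
      d = ncol(Z), Z = Z, coef_names = colnames(Z))
    for (tm in terms$smooth) {
      if (!tm$covariate %in% names(ds$cont))
        .gbp_error(paste0("unknown continuous covariate: ", tm$covariate),
                   "gbp_design_error")
      B <- bspline_basis(ds$cont[[tm$covariate]], tm$n_knots, tm$degree)
      cp <- .bspline_compact(B)
      K <- rw2_penalty(cp$d)
      blocks[[length(blocks) + 1]] <- list(
        kind = "spline", param = k, label = paste0(k, ":s(", tm$covariate, ")"),
        d = cp$d, Bx = cp$Bx, Bi = cp$Bi, covariate = tm$covariate,
        knots = attr(B, "knots"), lo = attr(B, "lo"), hi = attr(B, "hi"),
        n_knots = tm$n_knots, degree = tm$degree, K = unclass(K),
        rank = attr(K, "rank"),
        coef_names = paste0("s(", tm$covariate, ").", seq_len(cp$d)))
    }
    if (isTRUE(terms$spatial)) {
      if (is.null(g)) .gbp_error("spatial term requires an adjacency graph",
                                 "gbp_design_error")
      ri <- match(ds$region, g$regions)
      if (anyNA(ri))
        .gbp_error(paste0("region(s) not in graph: ",
                          paste(unique(ds$region[is.na(ri)]), collapse = ", ")),
                   "gbp_design_error")
      K <- gmrf_precision(g)
      deg <- lengths(g$neighbours)
      blocks[[length(blocks) + 1]] <- list(
        kind = "spatial", param = k, label = paste0(k, ":spatial"),
        d = length(g$regions), ri = ri, regions = g$regions,
        free = which(deg > 0L), K = unclass(K), rank = attr(K, "rank"),
        coef_names = paste0("spat.", g$regions))
    }
    out[[k]] <- blocks
  }
  structure(out, class = "design_set", n = ds$n)
}

#' Dense design matrix of a block (for inspection and export)
#'
#' @param block one block of a [build_designs()] result.
#' @return the n x d design matrix.
#' @export
block_design_matrix <- function(block) {
  if (block$kind == "linear") return(block$Z)
  n <- if (block$kind == "spline") nrow(block$Bx) else length(block$ri)
  Z <- matrix(0, n, block$d)
  if (block$kind == "spline") {
    q <- ncol(block$Bx)
    for (j in seq_len(q))
      Z[cbind(seq_len(n), block$Bi + j - 1)] <- block$Bx[, j]
  } else {
    Z[cbind(seq_len(n), block$ri)] <- 1
  }
  colnames(Z) <- block$coef_names
  Z
}

#' @export
print.design_set <- function(x, ...) {
  for (k in c("mu1", "mu2", "rho")) {
    labs <- vapply(x[[k]], function(b) sprintf("%s[%d]", b$label, b$d), "")
    cat(sprintf("%s: %s\n", k, paste(labs, collapse = " + ")))
  }
  invisible(x)
}
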