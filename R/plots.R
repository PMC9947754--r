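# Base-graphics figures: smooth-effect curves with dashed credible bands,
# and lattice heat / three-class significance maps for spatial effects.

#' Plot the smooth-effect curves with credible bands
#'
#' One panel per (parameter, covariate): posterior mean as a solid line,
#' 95% credible band as dashed lines.
#'
#' @param draws a [run_chain()] result.
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly `NULL`.
#' @export
plot_curves <- function(draws, file = NULL) {
  panels <- list()
  for (b in draws$blocks) if (b$kind == "spline")
    panels[[length(panels) + 1]] <- list(param = b$param, cov = b$covariate)
  if (!length(panels)) return(invisible(NULL))
  if (!is.null(file)) {
    grDevices::png(file, width = 400 * min(length(panels), 3),
                   height = 320 * ceiling(length(panels) / 3), res = 96)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(ceiling(length(panels) / 3),
                                min(length(panels), 3)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (p in panels) {
    cv <- summarize_curve(draws, p$param, p$cov)
    graphics::plot(cv$grid, cv$mean, type = "l", lwd = 2,
                   ylim = range(cv$lower, cv$upper),
                   xlab = p$cov, ylab = "effect",
                   main = sprintf("%s: s(%s)", p$param, p$cov))
    graphics::lines(cv$grid, cv$lower, lty = 2)
    graphics::lines(cv$grid, cv$upper, lty = 2)
    graphics::abline(h = 0, col = "grey70")
  }
  invisible(NULL)
}

#' Plot spatial posterior means and significance classes
#'
#' For lattice maps (built by [make_lattice_map()]) draws a heat map of
#' posterior means (top row) and a three-class significance map (bottom
#' row: white = significantly positive, black = significantly negative,
#' grey = not significant) for each parameter with a spatial term.  For
#' general graphs falls back to per-region interval plots.
#'
#' @param draws a [run_chain()] result.
#' @param g the [adjacency_graph()] used in the fit.
#' @param file optional PNG path.
#' @return invisibly `NULL`.
#' @export
plot_spatial <- function(draws, g, file = NULL) {
  params <- unique(vapply(Filter(function(b) b$kind == "spatial",
                                 draws$blocks), `[[`, "", "param"))
  if (!length(params)) return(invisible(NULL))
  dims <- attr(g, "lattice_dims")
  if (!is.null(file)) {
    grDevices::png(file, width = 360 * length(params), height = 640, res = 96)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, length(params)), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (k in params) {
    sp <- summarize_spatial(draws, k)
    if (!is.null(dims)) {
      M <- matrix(sp$mean, dims["rows"], dims["cols"], byrow = TRUE)
      graphics::image(t(M)[, dims["rows"]:1],
                      col = grDevices::hcl.colors(25, "RdYlGn", rev = TRUE),
                      axes = FALSE, main = paste0(k, ": posterior mean"))
    } else {
      graphics::plot(seq_len(nrow(sp)), sp$mean, ylim = range(sp$lower, sp$upper),
                     pch = 19, xlab = "region", ylab = "effect",
                     main = paste0(k, ": posterior mean"))
      graphics::segments(seq_len(nrow(sp)), sp$lower, seq_len(nrow(sp)), sp$upper)
      graphics::abline(h = 0, col = "grey70")
    }
  }
  for (k in params) {
    sp <- summarize_spatial(draws, k)
    if (!is.null(dims)) {
      M <- matrix(sp$class, dims["rows"], dims["cols"], byrow = TRUE)
      graphics::image(t(M)[, dims["rows"]:1], zlim = c(-1, 1),
                      col = c("black", "grey70", "white"), axes = FALSE,
                      main = paste0(k, ": 95% CrI class"))
    } else {
      graphics::plot(seq_len(nrow(sp)), sp$class, pch = 19, ylim = c(-1.2, 1.2),
                     xlab = "region", ylab = "class",
                     main = paste0(k, ": 95% CrI class"))
    }
  }
  invisible(NULL)
}
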