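# Pre-modelling screening: Pearson chi-square independence tests of each
# categorical covariate against each outcome, the p < alpha union selection
# rule, and the variance inflation factor multicollinearity check on the
# dummy-coded linear design.

#' Pearson chi-square test of independence
#'
#' Plain Pearson test on an r x c contingency table:
#' `X2 = sum((O - E)^2 / E)` with expected counts from the margins,
#' `df = (r - 1)(c - 1)`, p-value from the upper chi-square tail.  No
#' continuity correction.
#'
#' @param tab matrix of non-negative counts (at least 2 x 2).
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_independence(matrix(c(30, 10, 10, 30), 2))  # X2 = 20, df = 1
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0 || nrow(tab) < 2 || ncol(tab) < 2)
    .gbp_error("need an r x c table of non-negative counts with r, c >= 2",
               "gbp_degenerate_table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    .gbp_error("degenerate table: zero row or column margin", "gbp_degenerate_table")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Screen categorical covariates by association with either outcome
#'
#' For every categorical covariate, cross-tabulates it against stunting and
#' against wasting and runs [chi_square_independence()]; a covariate is
#' selected when the smaller of the two p-values is below `alpha` (union
#' rule: association with either outcome suffices).  Covariates with a
#' degenerate table are skipped with a message and reported with `NA`
#' p-values.  Continuous covariates are not screened; they always enter the
#' model as smooth terms.
#'
#' @param ds a `bp_dataset`.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return data frame with `covariate`, `p_stunting`, `p_wasting`,
#'   `selected` (class `screening_report`).
#' @export
select_model_variables <- function(ds, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  covs <- names(ds$cat)
  out <- data.frame(covariate = covs, p_stunting = NA_real_,
                    p_wasting = NA_real_, selected = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(covs)) {
    ps <- try({
      t1 <- table(ds$cat[[covs[i]]], factor(ds$y1, levels = 0:1))
      chi_square_independence(t1)$p_value
    }, silent = TRUE)
    pw <- try({
      t2 <- table(ds$cat[[covs[i]]], factor(ds$y2, levels = 0:1))
      chi_square_independence(t2)$p_value
    }, silent = TRUE)
    if (inherits(ps, "try-error") || inherits(pw, "try-error")) {
      message(sprintf("covariate '%s' skipped: degenerate contingency table",
                      covs[i]))
      next
    }
    out$p_stunting[i] <- ps
    out$p_wasting[i] <- pw
    out$selected[i] <- min(ps, pw) < alpha
  }
  class(out) <- c("screening_report", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Variance inflation factors of the dummy-coded linear design
#'
#' For each non-intercept column of the dummy-coded design built from the
#' given covariates, `VIF = 1 / (1 - R^2)` where `R^2` comes from
#' regressing the column on all other columns.  Exact collinearity is
#' flagged as `Inf` rather than raising an error.
#'
#' @param ds a `bp_dataset`.
#' @param covariates at least two covariate names (categorical or
#'   continuous columns of `ds`).
#' @return named numeric vector of VIFs, one per design column.
#' @export
compute_vif <- function(ds, covariates) {
  if (length(covariates) < 2)
    .gbp_error("VIF needs at least two covariates", "gbp_design_error")
  df <- data.frame(row.names = seq_len(ds$n))
  for (cn in covariates) {
    if (cn %in% names(ds$cat)) df[[cn]] <- ds$cat[[cn]]
    else if (cn %in% names(ds$cont)) df[[cn]] <- ds$cont[[cn]]
    else .gbp_error(paste0("unknown covariate: ", cn), "gbp_design_error")
  }
  X <- model.matrix(~ ., df)[, -1, drop = FALSE]
  if (ncol(X) < 2)
    .gbp_error("dummy design has fewer than two columns", "gbp_design_error")
  vif <- setNames(numeric(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    vif[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  vif
}
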