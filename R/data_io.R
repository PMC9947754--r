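# Reading, writing and validating child-record tables and region adjacency
# graphs; derivation of the binary undernutrition outcomes from z-scores.

#' Declare column roles for a child-record table
#'
#' Maps columns of a CSV file onto the roles the model needs.  Either both
#' binary outcome columns (`y1` = stunting, `y2` = wasting) or both raw
#' z-score columns (`haz` = height-for-age, `whz` = weight-for-height) must
#' be declared; in the latter case outcomes are derived with
#' [derive_outcomes()].
#'
#' @param y1,y2 names of the 0/1 outcome columns (optional if z-scores given).
#' @param haz,whz names of the z-score columns (optional if outcomes given).
#' @param categorical character vector of categorical covariate columns.
#' @param continuous character vector of continuous covariate columns
#'   (e.g. child age in months, mother age in years).
#' @param region name of the region-label column.
#' @param ref_levels named list: reference level per categorical covariate
#'   (defaults to the first level in data order).
#' @return object of class `table_schema`.
#' @export
table_schema <- function(y1 = NULL, y2 = NULL, haz = NULL, whz = NULL,
                         categorical = character(), continuous = character(),
                         region, ref_levels = list()) {
  if ((is.null(y1) || is.null(y2)) && (is.null(haz) || is.null(whz)))
    .gbp_error("declare either both outcome columns or both z-score columns",
               "gbp_schema_error")
  structure(list(y1 = y1, y2 = y2, haz = haz, whz = whz,
                 categorical = categorical, continuous = continuous,
                 region = region, ref_levels = ref_levels),
            class = "table_schema")
}

#' Derive binary stunting/wasting outcomes from anthropometric z-scores
#'
#' A child is classified stunted when the height-for-age z-score is
#' strictly below -2 standard deviations of the WHO growth-standard median,
#' and wasted when the weight-for-height z-score is strictly below -2.
#' Values exactly equal to -2 are non-cases.
#'
#' @param haz height-for-age z-scores (finite).
#' @param whz weight-for-height z-scores (finite).
#' @return list with integer 0/1 vectors `y1` (stunting) and `y2` (wasting).
#' @examples
#' derive_outcomes(c(-2.5, -2, 0), c(0, -3, -2))  # y1 = 1,0,0; y2 = 0,1,0
#' @export
derive_outcomes <- function(haz, whz) {
  if (any(!is.finite(haz)) || any(!is.finite(whz)))
    .gbp_error("z-scores must be finite", "gbp_validation_error")
  list(y1 = as.integer(haz < -2), y2 = as.integer(whz < -2))
}

.modelled_columns <- function(schema) {
  out <- c(schema$categorical, schema$continuous, schema$region)
  if (!is.null(schema$y1)) out <- c(schema$y1, schema$y2, out)
  if (!is.null(schema$haz)) out <- c(schema$haz, schema$whz, out)
  out
}

#' Build a modelling dataset from a data frame
#'
#' Applies a [table_schema()] to a raw data frame: checks declared columns,
#' drops rows with missing values in any modelled column (listwise
#' deletion; the dropped count is recorded and reported), derives outcomes
#' from z-scores when no outcome columns are declared, types categorical
#' covariates as factors with the declared reference level.
#'
#' @param df a data frame.
#' @param schema a [table_schema()].
#' @return object of class `bp_dataset` with elements `y1`, `y2`,
#'   `cat` (data frame of factors), `cont` (data frame of numerics),
#'   `region` (character), optional `haz`/`whz`, `n`, `n_dropped`.
#' @export
as_bp_dataset <- function(df, schema) {
  stopifnot(inherits(schema, "table_schema"))
  missing_cols <- setdiff(.modelled_columns(schema), names(df))
  if (length(missing_cols))
    .gbp_error(paste0("columns missing from table: ",
                      paste(missing_cols, collapse = ", ")), "gbp_schema_error")
  n_raw <- nrow(df)
  keep <- stats::complete.cases(df[, .modelled_columns(schema), drop = FALSE])
  df <- df[keep, , drop = FALSE]
  n_dropped <- n_raw - nrow(df)
  if (n_dropped > 0)
    message(sprintf("%d row(s) dropped for missing values in modelled columns",
                    n_dropped))
  if (nrow(df) == 0)
    .gbp_error("no complete records left after listwise deletion", "gbp_data_error")
  if (!is.null(schema$y1)) {
    y1 <- df[[schema$y1]]; y2 <- df[[schema$y2]]
    if (!all(y1 %in% c(0, 1)) || !all(y2 %in% c(0, 1)))
      .gbp_error("outcome columns must be 0/1", "gbp_data_error")
    y1 <- as.integer(y1); y2 <- as.integer(y2)
  } else {
    oc <- derive_outcomes(df[[schema$haz]], df[[schema$whz]])
    y1 <- oc$y1; y2 <- oc$y2
  }
  cat_df <- df[, schema$categorical, drop = FALSE]
  for (cn in schema$categorical) {
    f <- factor(cat_df[[cn]])
    ref <- schema$ref_levels[[cn]]
    if (!is.null(ref)) {
      if (!ref %in% levels(f))
        .gbp_error(sprintf("reference level '%s' not found in '%s'", ref, cn),
                   "gbp_schema_error")
      f <- stats::relevel(f, ref = ref)
    }
    cat_df[[cn]] <- f
  }
  cont_df <- df[, schema$continuous, drop = FALSE]
  for (cn in schema$continuous) cont_df[[cn]] <- as.numeric(cont_df[[cn]])
  ds <- structure(list(y1 = y1, y2 = y2, cat = cat_df, cont = cont_df,
                       region = as.character(df[[schema$region]]),
                       n = nrow(df), n_dropped = n_dropped, schema = schema),
                  class = "bp_dataset")
  if (!is.null(schema$haz)) {
    ds$haz <- as.numeric(df[[schema$haz]])
    ds$whz <- as.numeric(df[[schema$whz]])
  }
  ds
}

#' Read a child-record CSV
#'
#' @param path CSV file path.
#' @param schema a [table_schema()] describing the columns.
#' @return a `bp_dataset`; see [as_bp_dataset()].
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) .gbp_error(paste0("file not found: ", path), "gbp_data_error")
  as_bp_dataset(read.csv(path, stringsAsFactors = FALSE), schema)
}

#' Write a dataset back to CSV
#'
#' Writes outcomes, covariates and region labels in a layout [read_table()]
#' round-trips losslessly.
#'
#' @param ds a `bp_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(ds, path) {
  df <- data.frame(y1 = ds$y1, y2 = ds$y2, stringsAsFactors = FALSE)
  for (cn in names(ds$cat)) df[[cn]] <- as.character(ds$cat[[cn]])
  for (cn in names(ds$cont)) df[[cn]] <- ds$cont[[cn]]
  df$region <- ds$region
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.bp_dataset <- function(x, ...) {
  cat(sprintf("<bp_dataset> %d records (%d dropped on read)\n", x$n, x$n_dropped))
  cat(sprintf("  outcomes: stunting %.1f%%, wasting %.1f%%\n",
              100 * mean(x$y1), 100 * mean(x$y2)))
  cat(sprintf("  categorical: %s\n", paste(names(x$cat), collapse = ", ")))
  cat(sprintf("  continuous:  %s\n", paste(names(x$cont), collapse = ", ")))
  cat(sprintf("  regions: %d distinct\n", length(unique(x$region))))
  invisible(x)
}

#' Region adjacency graph
#'
#' @param regions ordered character vector of region labels.
#' @param neighbours list of integer vectors: for each region, 1-based
#'   indices of its neighbours in `regions`.  Must be symmetric and free of
#'   self-neighbours; regions without neighbours (islands) are permitted
#'   but flagged with a warning.
#' @return object of class `adjacency_graph`.
#' @export
adjacency_graph <- function(regions, neighbours) {
  regions <- as.character(regions)
  S <- length(regions)
  if (anyDuplicated(regions)) .gbp_error("duplicate region labels", "gbp_graph_error")
  if (length(neighbours) != S) .gbp_error("one neighbour list per region required",
                                          "gbp_graph_error")
  neighbours <- lapply(neighbours, function(v) sort(as.integer(v)))
  for (s in seq_len(S)) {
    nb <- neighbours[[s]]
    if (any(nb < 1 | nb > S)) .gbp_error("neighbour index out of range", "gbp_parse_error")
    if (s %in% nb) .gbp_error(sprintf("region '%s' lists itself as neighbour",
                                      regions[s]), "gbp_graph_error")
    for (r in nb) if (!s %in% neighbours[[r]])
      .gbp_error(sprintf("asymmetric adjacency: '%s' lists '%s' but not conversely",
                         regions[s], regions[r]), "gbp_graph_error")
  }
  islands <- regions[vapply(neighbours, length, 1L) == 0]
  if (length(islands))
    warning("island region(s) without neighbours: ",
            paste(islands, collapse = ", "), call. = FALSE)
  structure(list(regions = regions, neighbours = neighbours, islands = islands),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  ne <- sum(lengths(x$neighbours)) / 2
  cat(sprintf("<adjacency_graph> %d regions, %d undirected edges", length(x$regions), ne))
  if (length(x$islands)) cat(sprintf(", %d island(s)", length(x$islands)))
  cat("\n")
  invisible(x)
}

#' Read a region adjacency graph
#'
#' Two plain-text dialects are supported.  `"gra"` (BayesX style): first
#' line the region count, then for each region its label, its neighbour
#' count and the 1-based indices of its neighbours (whitespace/newline
#' separated); asymmetric declarations are an error.  `"edges"`: one
#' undirected edge `labelA labelB` per line (a line with a single label
#' declares an island); region order is first appearance.
#'
#' @param path file path.
#' @param dialect `"gra"` or `"edges"`.
#' @return an [adjacency_graph()].
#' @export
read_adjacency <- function(path, dialect = c("gra", "edges")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .gbp_error(paste0("file not found: ", path), "gbp_data_error")
  if (dialect == "gra") {
    tok <- scan(path, what = character(), quiet = TRUE)
    S <- suppressWarnings(as.integer(tok[1]))
    if (is.na(S) || S < 1) .gbp_error("invalid region count", "gbp_parse_error")
    pos <- 2L
    regions <- character(S)
    neighbours <- vector("list", S)
    for (s in seq_len(S)) {
      if (pos + 1 > length(tok)) .gbp_error("truncated .gra file", "gbp_parse_error")
      regions[s] <- tok[pos]
      nn <- suppressWarnings(as.integer(tok[pos + 1]))
      if (is.na(nn) || nn < 0) .gbp_error("invalid neighbour count", "gbp_parse_error")
      idx <- integer(0)
      if (nn > 0) {
        idx <- suppressWarnings(as.integer(tok[pos + 1 + seq_len(nn)]))
        if (any(is.na(idx)) || any(idx < 1) || any(idx > S))
          .gbp_error("unknown region reference in neighbour list", "gbp_parse_error")
      }
      neighbours[[s]] <- idx
      pos <- pos + 2L + nn
    }
    adjacency_graph(regions, neighbours)
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    labels <- character(0)
    edges <- list()
    for (ln in lines) {
      parts <- strsplit(ln, "[[:space:],]+")[[1]]
      parts <- parts[nzchar(parts)]
      if (!length(parts) || length(parts) > 2)
        .gbp_error(paste0("cannot parse edge line: ", ln), "gbp_parse_error")
      labels <- c(labels, setdiff(parts, labels))
      if (length(parts) == 2) edges[[length(edges) + 1]] <- parts
    }
    neighbours <- rep(list(integer(0)), length(labels))
    for (e in edges) {
      i <- match(e[1], labels); j <- match(e[2], labels)
      if (i == j) .gbp_error(sprintf("self edge on '%s'", e[1]), "gbp_graph_error")
      neighbours[[i]] <- union(neighbours[[i]], j)
      neighbours[[j]] <- union(neighbours[[j]], i)
    }
    adjacency_graph(labels, neighbours)
  }
}

#' Write a region adjacency graph
#'
#' Inverse of [read_adjacency()]; both dialects round-trip valid graphs.
#'
#' @param g an [adjacency_graph()].
#' @param path output file path.
#' @param dialect `"gra"` or `"edges"`.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(g, path, dialect = c("gra", "edges")) {
  dialect <- match.arg(dialect)
  if (dialect == "gra") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(length(g$regions)), con)
    for (s in seq_along(g$regions)) {
      writeLines(g$regions[s], con)
      writeLines(as.character(length(g$neighbours[[s]])), con)
      if (length(g$neighbours[[s]]))
        writeLines(paste(g$neighbours[[s]], collapse = " "), con)
    }
  } else {
    # declare every region first so file order fixes region order (and
    # islands are representable), then one line per undirected edge
    out <- g$regions
    for (s in seq_along(g$regions)) {
      nb <- g$neighbours[[s]]
      nb <- nb[nb > s]
      if (length(nb)) out <- c(out, paste(g$regions[s], g$regions[nb]))
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Validate a dataset against its adjacency graph
#'
#' Report-only check: lists region labels absent from the graph, constant
#' covariate columns, and factor levels with an empty cell for either
#' outcome (zero stunted or zero wasted children in the level), which can
#' destabilise screening tables and linear effects.
#'
#' @param ds a `bp_dataset`.
#' @param g an [adjacency_graph()].
#' @return object of class `validation_report` (also convertible to JSON
#'   with [report_json()]).
#' @export
validate_dataset <- function(ds, g) {
  unknown <- sort(unique(ds$region[!ds$region %in% g$regions]))
  const_cols <- character(0)
  for (cn in names(ds$cat)) if (length(unique(ds$cat[[cn]])) < 2)
    const_cols <- c(const_cols, cn)
  for (cn in names(ds$cont)) if (length(unique(ds$cont[[cn]])) < 2)
    const_cols <- c(const_cols, cn)
  zero <- data.frame(covariate = character(), level = character(),
                     outcome = character(), stringsAsFactors = FALSE)
  for (cn in names(ds$cat)) {
    for (lv in levels(ds$cat[[cn]])) {
      in_lv <- ds$cat[[cn]] == lv
      if (any(in_lv)) {
        if (sum(ds$y1[in_lv]) == 0)
          zero <- rbind(zero, data.frame(covariate = cn, level = lv,
                                         outcome = "stunting"))
        if (sum(ds$y2[in_lv]) == 0)
          zero <- rbind(zero, data.frame(covariate = cn, level = lv,
                                         outcome = "wasting"))
      }
    }
  }
  structure(list(unknown_regions = unknown, constant_columns = const_cols,
                 zero_cells = zero, n = ds$n, n_dropped = ds$n_dropped,
                 clean = !length(unknown) && !length(const_cols) && !nrow(zero)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d (%d dropped on read)\n", x$n, x$n_dropped))
  if (x$clean) {
    cat("  no issues found\n")
  } else {
    if (length(x$unknown_regions))
      cat("  unknown regions:", paste(x$unknown_regions, collapse = ", "), "\n")
    if (length(x$constant_columns))
      cat("  constant columns:", paste(x$constant_columns, collapse = ", "), "\n")
    if (nrow(x$zero_cells)) {
      cat(sprintf("  %d factor level(s) with an empty outcome cell:\n", nrow(x$zero_cells)))
      for (i in seq_len(nrow(x$zero_cells)))
        cat(sprintf("    %s=%s: no %s cases\n", x$zero_cells$covariate[i],
                    x$zero_cells$level[i], x$zero_cells$outcome[i]))
    }
  }
  invisible(x)
}

#' Serialise a validation or screening report to JSON
#'
#' @param x a report object.
#' @param path optional file to write to.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
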