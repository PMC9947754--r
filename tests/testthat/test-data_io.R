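# Reading child-record tables, outcome derivation from z-scores, adjacency
# parsing, and dataset validation.

make_csv <- function(df) {
  tf <- tempfile(fileext = ".csv")
  write.csv(df, tf, row.names = FALSE)
  tf
}

base_schema <- table_schema(y1 = "y1", y2 = "y2", categorical = "grp",
                            continuous = "child_age_months", region = "region")

test_that("rows with missing modelled values are dropped and counted", {
  df <- data.frame(y1 = c(1, 0, NA, 1, 0), y2 = c(0, 0, 1, 1, 0),
                   grp = letters[1:5], child_age_months = c(10, 20, 30, 40, 50),
                   region = rep("A", 5))
  expect_message(ds <- read_table(make_csv(df), base_schema),
                 "1 row\\(s\\) dropped")
  expect_equal(ds$n, 4)
  expect_equal(ds$n_dropped, 1)
  expect_equal(ds$n + ds$n_dropped, nrow(df))
})

test_that("a missing outcome column is a schema error", {
  df <- data.frame(y1 = c(1, 0), grp = c("a", "b"),
                   child_age_months = c(8, 9), region = "A")
  expect_error(read_table(make_csv(df), base_schema), class = "gbp_schema_error")
  expect_error(table_schema(y1 = "y1", region = "region"),
               class = "gbp_schema_error")
})

test_that("outcome coding is strictly below -2 and depends only on sign(z + 2)", {
  oc <- derive_outcomes(c(-2.5, -2, 0, -1.999, -2.001), c(0, -3, -2, 5, -2.5))
  expect_identical(oc$y1, c(1L, 0L, 0L, 0L, 1L))
  expect_identical(oc$y2, c(0L, 1L, 0L, 0L, 1L))
  expect_error(derive_outcomes(c(NA, 0), c(0, 0)), class = "gbp_validation_error")
  expect_error(derive_outcomes(0, Inf), class = "gbp_validation_error")
  set.seed(8)
  z <- runif(200, -4, 0)
  oc1 <- derive_outcomes(z, z)
  expect_identical(oc1$y1, as.integer(sign(z + 2) < 0))
  # idempotence through write/read of the derived outcomes
  expect_identical(derive_outcomes(z, z), oc1)
})

test_that("gra files parse with symmetric neighbour lists and preserve order", {
  tf <- tempfile()
  writeLines(c("3", "A", "1", "2", "B", "2", "1 3", "C", "1", "2"), tf)
  g <- read_adjacency(tf, "gra")
  expect_equal(g$regions, c("A", "B", "C"))
  expect_equal(g$neighbours[[2]], c(1L, 3L))
  expect_equal(g$neighbours[[1]], 2L)

  bad <- tempfile()
  writeLines(c("2", "A", "1", "2", "B", "0"), bad)  # A -> B but not B -> A
  expect_error(read_adjacency(bad, "gra"), class = "gbp_graph_error")

  oob <- tempfile()
  writeLines(c("2", "A", "1", "5", "B", "0"), oob)  # unknown region index
  expect_error(read_adjacency(oob, "gra"), class = "gbp_parse_error")
})

test_that("adjacency round-trips in both dialects", {
  g <- make_lattice_map(4, 4)
  for (dia in c("gra", "edges")) {
    tf <- tempfile()
    write_adjacency(g, tf, dia)
    g2 <- read_adjacency(tf, dia)
    expect_equal(g2$regions, g$regions)
    expect_equal(g2$neighbours, g$neighbours)
  }
  # islands survive the edge-list dialect
  gi <- suppressWarnings(adjacency_graph(c("A", "B", "C"),
                                         list(2L, 1L, integer(0))))
  tf <- tempfile()
  write_adjacency(gi, tf, "edges")
  g3 <- suppressWarnings(read_adjacency(tf, "edges"))
  expect_equal(g3$regions, gi$regions)
  expect_equal(g3$neighbours, gi$neighbours)
})

test_that("self-neighbours and asymmetry are rejected at construction", {
  expect_error(adjacency_graph(c("A", "B"), list(c(1L, 2L), 1L)),
               class = "gbp_graph_error")
  expect_error(adjacency_graph(c("A", "B"), list(2L, integer(0))),
               class = "gbp_graph_error")
  expect_warning(adjacency_graph("A", list(integer(0))), "island")
})

test_that("synthetic tables round-trip through CSV", {
  g <- make_lattice_map(2, 2)
  eff <- sample_true_effects(g, "linear_only", seed = 4)
  ds <- simulate_dataset(g, eff, 40, seed = 6)
  tf <- tempfile(fileext = ".csv")
  write_table(ds, tf)
  ds2 <- read_table(tf, synthetic_schema("linear_only"))
  expect_identical(ds2$y1, ds$y1)
  expect_identical(ds2$y2, ds$y2)
  expect_identical(ds2$region, ds$region)
  expect_equal(ds2$cont, ds$cont, ignore_attr = TRUE)
  expect_identical(lapply(ds2$cat, as.character), lapply(ds$cat, as.character))
  expect_identical(lapply(ds2$cat, levels), lapply(ds$cat, levels))
})

test_that("validation reports unknown regions, constant columns and empty outcome cells", {
  g <- make_lattice_map(2, 2)
  df <- data.frame(y1 = c(1, 0, 1, 0), y2 = c(0, 0, 0, 0),
                   grp = c("a", "a", "b", "b"), child_age_months = 6:9,
                   region = c("S01", "S02", "Z", "S04"))
  ds <- as_bp_dataset(df, base_schema)
  rep <- validate_dataset(ds, g)
  expect_false(rep$clean)
  expect_equal(rep$unknown_regions, "Z")
  expect_true(all(c("a", "b") %in% rep$zero_cells$level))  # no wasted children
  expect_true(all(rep$zero_cells$outcome == "wasting"))

  eff <- sample_true_effects(g, "intercepts_only")
  ok <- simulate_dataset(g, eff, 400, seed = 2)
  rep2 <- validate_dataset(ok, g)
  expect_true(rep2$clean)
  expect_match(report_json(rep2), "\"clean\": true")
})
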