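test_that("a singleton grid yields one row with the base triplet", {
  db <- build_database(grid_spec(a = 0.0012, b = 3, d = 10, k_low = 0.1))
  expect_identical(nrow(db), 1L)
  expect_identical(db$model_id, 0L)
  expect_equal(db$sfa, 0.46, tolerance = 0.05)
  expect_identical(db$rheo, 3.5)
  expect_identical(db$pir, -5.0)
  expect_false(db$all_undefined)
})

test_that("a 2x2x2x2 grid yields 16 rows with ids 0..15, reproducibly", {
  g <- grid_spec(a = c(0.0008, 0.0012), b = c(2, 3), d = c(6, 10),
                 k_low = c(0.08, 0.1))
  db1 <- build_database(g)
  db2 <- build_database(g)
  expect_identical(nrow(db1), 16L)
  expect_identical(db1$model_id, 0:15)
  expect_identical(db1, db2)
})

test_that("empty or invalid grids are rejected", {
  expect_error(grid_spec(a = numeric(0), b = 3, d = 10, k_low = 0.1),
               "non-empty")
  expect_error(grid_spec(a = -0.001, b = 3, d = 10, k_low = 0.1), "positive")
  expect_error(grid_spec(a = 0.0012, b = 3, d = -1, k_low = 0.1),
               "non-negative")
})

test_that("default grid values contain the default parameter point", {
  g <- default_grid_spec(6)
  expect_true(0.0012 %in% g$a)
  expect_true(3 %in% g$b)
  expect_true(10 %in% g$d)
  expect_true(0.1 %in% g$k_low)
})

test_that("feature histograms match independent binning of the exported CSV", {
  db <- test_db()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_database_csv(db, tmp)
  raw <- utils::read.csv(tmp)
  for (feat in c("sfa", "rheo", "pir")) {
    bin <- if (feat == "sfa") 0.05 else 0.5
    h <- feature_histogram(db, feat)
    v <- raw[[feat]]
    v <- v[!is.na(v)]
    # oracle: cut() over explicitly constructed right-open edges
    edges <- seq(min(h$lower), max(h$upper), by = bin)
    oracle <- as.integer(table(cut(v, edges, right = FALSE)))
    expect_identical(as.integer(h$count), oracle)
    expect_identical(sum(h$count), as.numeric(length(v)))
  }
})

test_that("tertile boundaries agree with an order-statistics oracle", {
  db <- test_db()
  bands <- test_bands()
  # independent type-7 quantile: linear interpolation of sorted values
  q7 <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p
    lo <- floor(h)
    v[lo + 1] + (h - lo) * (v[min(lo + 2, length(v))] - v[lo + 1])
  }
  for (feat in c("sfa", "rheo", "pir")) {
    v <- db[[feat]]
    v <- v[!is.na(v)]
    expect_equal(bands[[feat]]$breaks,
                 c(q7(v, 1 / 3), q7(v, 2 / 3)))
  }
})

test_that("narrow bands are strictly inside broad bands", {
  bands <- test_bands()
  for (feat in c("sfa", "rheo", "pir")) {
    b <- bands[[feat]]
    expect_gt(b$narrow[1], b$broad[1])
    expect_lt(b$narrow[2], b$broad[2])
  }
})

test_that("the base cell classifies [H, M, L] on the reference grid", {
  db <- test_db()
  bands <- test_bands()
  cls <- classify_triplet(attr(db, "base_triplet"), bands)
  expect_identical(unname(cls), c("H", "M", "L"))
})

test_that("selected populations satisfy their band constraints draw by draw", {
  db <- test_db()
  bands <- test_bands()
  sel <- select_population(db, bands, c("H", "M", "L"), size = 200, seed = 11)
  expect_length(sel$params, 200)
  rows <- match(sel$model_ids, db$model_id)
  expect_true(all(in_band(db$sfa[rows], bands, "sfa", "H")))
  expect_true(all(in_band(db$rheo[rows], bands, "rheo", "M")))
  expect_true(all(in_band(db$pir[rows], bands, "pir", "L")))
  # the base model is among the qualifying rows
  base_row <- which(db$a == 0.0012 & db$b == 3 & db$d == 10 & db$k_low == 0.1)
  expect_length(base_row, 1)
  expect_true(db$model_id[base_row] %in% sel$qualifying_ids)
  # distinct-model count equals brute-force filtering of the exported CSV
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_database_csv(db, tmp)
  raw <- utils::read.csv(tmp)
  n_brute <- sum(!is.na(raw$sfa) & raw$sfa > bands$sfa$breaks[2] &
                   !is.na(raw$rheo) & raw$rheo > bands$rheo$breaks[1] &
                   raw$rheo <= bands$rheo$breaks[2] &
                   !is.na(raw$pir) & raw$pir <= bands$pir$breaks[1])
  expect_identical(sel$n_distinct, as.integer(n_brute))
})

test_that("selection is reproducible under a fixed seed", {
  db <- test_db()
  bands <- test_bands()
  s1 <- select_population(db, bands, c("L", "M", "L"), size = 50, seed = 5)
  s2 <- select_population(db, bands, c("L", "M", "L"), size = 50, seed = 5)
  expect_identical(s1$model_ids, s2$model_ids)
})

test_that("a singleton database degenerates bands to its own values", {
  db <- build_database(grid_spec(a = 0.0012, b = 3, d = 10, k_low = 0.1))
  bands <- derive_bands(db)
  # all mass sits in the L band (closed lower tertile); selecting it
  # returns the single row, other bands are empty
  sel <- select_population(db, bands, c("L", "L", "L"), size = 3, seed = 1)
  expect_identical(unique(sel$model_ids), 0L)
  expect_error(select_population(db, bands, c("H", "L", "L"), size = 1,
                                 seed = 1),
               "empty selection")
})

test_that("database CSV round-trips through read_database_csv", {
  db <- test_db()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_database_csv(db, tmp)
  back <- read_database_csv(tmp)
  expect_s3_class(back, "model_database")
  expect_equal(back$sfa, db$sfa)
  expect_equal(back$rheo, db$rheo)
  expect_identical(db_cell_params(back, 2), db_cell_params(db, 2))
})
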