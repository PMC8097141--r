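test_that("zero connection probabilities give zero edges", {
  cfg <- small_config(n_pyr = 50, n_pv = 5,
                      p = list(ee = 0, ei = 0, ie = 0.001, ii = 0))
  set.seed(1)
  conn <- build_connectivity(cfg)
  expect_identical(unname(conn$counts[c("ee", "ei", "ii")]), c(0, 0, 0))
})

test_that("realized edge counts follow the binomial wiring law", {
  cfg <- network_config(n_pyr = 1000, n_pv = 0, duration = 100, seed = 1)
  cfg$p$ee <- 0.01
  set.seed(99)
  conn <- build_connectivity(cfg)
  mu <- 0.01 * 1000 * 999
  sdv <- sqrt(1000 * 999 * 0.01 * 0.99)
  expect_lt(abs(conn$counts[["ee"]] - mu), 4 * sdv)
  # no self-connections
  expect_false(any(conn$ee$from == conn$ee$to))
})

test_that("config validation enforces the documented constraints", {
  expect_silent(validate_network_config(network_config()))
  expect_error(network_config(p = list(ee = 0.008, ei = 0.3, ie = 0.05,
                                       ii = 0.12)),
               "PV->PYR")
  expect_error(network_config(p = list(ee = 0.02, ei = 0.05, ie = 0.3,
                                       ii = 0.12)),
               "sparse")
  expect_error(network_config(p = list(ee = 1.2, ei = 0.05, ie = 0.3,
                                       ii = 0.12)),
               "probabilities")
  expect_error(network_config(duration = -5), "positive")
})

test_that("scaling preserves per-projection count x probability x weight", {
  cfg <- network_config(seed = 2)
  id <- scale_network(cfg, 1)
  expect_identical(id$n_pyr, cfg$n_pyr)
  expect_identical(id$syn$ee$weight, cfg$syn$ee$weight)
  sc <- scale_network(cfg, 0.1)
  expect_identical(sc$n_pyr, 1000L)
  expect_identical(sc$n_pv, 50L)
  pre <- c(ee = "n_pyr", ei = "n_pyr", ie = "n_pv", ii = "n_pv")
  for (pr in names(pre)) {
    before <- cfg[[pre[[pr]]]] * cfg$p[[pr]] * cfg$syn[[pr]]$weight
    after <- sc[[pre[[pr]]]] * sc$p[[pr]] * sc$syn[[pr]]$weight
    expect_equal(after, before)
  }
})

test_that("scaling replicates a heterogeneous population to the new size", {
  db <- test_db()
  bands <- test_bands()
  cfg <- network_config(seed = 3)
  cfg$pyr_params <- select_population(db, bands, c("H", "M", "L"),
                                      size = cfg$n_pyr, seed = 3)
  sc <- scale_network(cfg, 0.01)
  expect_identical(sc$n_pyr, 100L)
  expect_length(pyr_param_list <- ca1theta:::pyr_param_list(sc), 100L)
})

test_that("a weightless, driveless network stays silent", {
  cfg <- small_config(
    n_pyr = 50, n_pv = 5, duration = 1000,
    syn = list(ee = synapse_params(0, 6, -15), ei = synapse_params(0, 3, -15),
               ie = synapse_params(0, 8, -85), ii = synapse_params(0, 3, -85)),
    drive = list(pyr = list(mean = 0, amplitude = 0),
                 pv = list(mean = 0, amplitude = 0)))
  raster <- simulate_network(cfg)
  expect_identical(nrow(raster$spikes), 0L)
})

test_that("identical config and seed give bit-identical rasters", {
  cfg <- small_config(n_pyr = 80, n_pv = 4, duration = 800, seed = 123,
                      drive = list(pyr = list(mean = 5, amplitude = 30),
                                   pv = list(mean = 120, amplitude = 20)))
  r1 <- simulate_network(cfg)
  r2 <- simulate_network(cfg)
  expect_identical(r1$spikes, r2$spikes)
  cfg$seed <- 124L
  r3 <- simulate_network(cfg)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("raster spike times are ordered per cell and within the recording", {
  cfg <- small_config(n_pyr = 60, n_pv = 4, duration = 1000, seed = 9,
                      drive = list(pyr = list(mean = 10, amplitude = 30),
                                   pv = list(mean = 130, amplitude = 20)))
  raster <- simulate_network(cfg)
  expect_gt(nrow(raster$spikes), 0)
  expect_true(all(raster$spikes$spike_time_ms >= 0 &
                    raster$spikes$spike_time_ms <= raster$duration))
  by_cell <- split(raster$spikes$spike_time_ms,
                   paste(raster$spikes$population, raster$spikes$cell_id))
  expect_true(all(vapply(by_cell, function(t) all(diff(t) > 0), logical(1))))
})

test_that("raster CSV and metadata JSON exports are readable", {
  cfg <- small_config(n_pyr = 30, n_pv = 2, duration = 600, seed = 4,
                      drive = list(pyr = list(mean = 10, amplitude = 30),
                                   pv = list(mean = 0, amplitude = 0)))
  raster <- simulate_network(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_raster_csv(raster, f1)
  write_run_metadata(raster, f2)
  back <- utils::read.csv(f1)
  expect_named(back, c("population", "cell_id", "spike_time_ms"))
  meta <- jsonlite::read_json(f2)
  expect_identical(meta$seed, 4L)
  expect_named(meta$edge_counts, c("ee", "ei", "ie", "ii"))
})
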