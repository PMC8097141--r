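#' Validate the base feature triplet of the default cell
#'
#' Phenotypes the default strongly adapting PYR cell and compares the
#' result against the base triplet `[SFA, Rheo, PIR]` the default
#' parameters are expected to produce. Intended as an install-time sanity
#' check: a deliberately coarse integration step (for instance `dt = 5`)
#' makes it fail.
#'
#' @param dt integration step (ms).
#' @param expected expected triplet (SFA Hz/pA, Rheo pA, PIR pA).
#' @param tol_sfa absolute tolerance on SFA; Rheo and PIR must match their
#'   0.5 pA grid values exactly.
#' @return An object of class `base_validation`: list with `triplet`,
#'   `expected`, `pass` (logical), `checks` (per-feature logical).
#' @export
run_base_validation <- function(dt = 0.04,
                                expected = c(sfa = 0.46, rheo = 3.5,
                                             pir = -5.0),
                                tol_sfa = 0.02) {
  tri <- quantify_features(pyr_default_params(), dt = dt)
  checks <- c(
    sfa = !is.na(tri$sfa) && abs(tri$sfa - expected[["sfa"]]) <= tol_sfa,
    rheo = !is.na(tri$rheo) && tri$rheo == expected[["rheo"]],
    pir = !is.na(tri$pir) && tri$pir == expected[["pir"]])
  structure(list(triplet = tri, expected = expected, checks = checks,
                 pass = all(checks), dt = dt),
            class = "base_validation")
}

#' @export
print.base_validation <- function(x, ...) {
  cat(if (x$pass) "PASS" else "FAIL",
      sprintf(": base triplet [%.4g, %.4g, %.4g] vs expected [%g, %g, %g] (dt = %g ms)\n",
              x$triplet$sfa, x$triplet$rheo, x$triplet$pir,
              x$expected[["sfa"]], x$expected[["rheo"]], x$expected[["pir"]],
              x$dt))
  invisible(x)
}

# all 27 L/M/H triplets in a stable order
lmh_triplets <- function() {
  g <- expand.grid(pir = c("L", "M", "H"), rheo = c("L", "M", "H"),
                   sfa = c("L", "M", "H"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) c(g$sfa[i], g$rheo[i], g$pir[i]))
}

#' Frequency/power sweep over feature-band triplets
#'
#' For each requested `[SFA, Rheo, PIR]` band triplet, selects a
#' heterogeneous PYR population from the database, simulates an E-I
#' network built from the template config, and records the rhythm metrics.
#' Triplets with no qualifying models are kept as rows with `NA` metrics
#' and `feasible = FALSE` (the missing vertices of the feature triangle).
#'
#' @param db a `model_database`.
#' @param bands a [derive_bands()] result.
#' @param template a `network_config` used for all runs; its `n_pyr`
#'   determines the population size drawn per triplet.
#' @param triplets list of character band triplets (default all 27 L/M/H
#'   combinations).
#' @param seed integer seed; each triplet uses `seed + its index`.
#' @param band rhythm search band (Hz).
#' @param burn_in_ms transient discarded before spectral analysis (ms).
#' @return A data.frame with one row per triplet: `sfa_band`, `rheo_band`,
#'   `pir_band`, `feasible`, `n_distinct`, `peak_frequency_Hz`,
#'   `peak_power`, `is_rhythmic`.
#' @export
run_triangle_sweep <- function(db, bands, template,
                               triplets = lmh_triplets(), seed = 1,
                               band = c(3, 12), burn_in_ms = 500) {
  stopifnot(inherits(db, "model_database"), inherits(bands, "band_spec"),
            inherits(template, "network_config"))
  rows <- vector("list", length(triplets))
  for (j in seq_along(triplets)) {
    tri <- triplets[[j]]
    row <- data.frame(sfa_band = tri[1], rheo_band = tri[2],
                      pir_band = tri[3], feasible = FALSE,
                      n_distinct = NA_integer_,
                      peak_frequency_Hz = NA_real_, peak_power = NA_real_,
                      is_rhythmic = NA)
    sel <- tryCatch(select_population(db, bands, tri, size = template$n_pyr,
                                      seed = seed + j),
                    error = function(e) NULL)
    if (!is.null(sel)) {
      cfg <- template
      cfg$pyr_params <- sel
      cfg$seed <- as.integer(seed + j)
      raster <- simulate_network(cfg)
      met <- rhythm_metrics(population_activity(raster, bin_ms = 1),
                            band = band, burn_in_ms = burn_in_ms)
      row$feasible <- TRUE
      row$n_distinct <- sel$n_distinct
      row$peak_frequency_Hz <- met$peak_frequency
      row$peak_power <- met$peak_power
      row$is_rhythmic <- met$is_rhythmic
    }
    rows[[j]] <- row
  }
  do.call(rbind, rows)
}

#' PRC study over the slow/medium/fast population triplets
#'
#' Selects the three feature-band populations whose networks exhibit the
#' slow, medium and fast burst regimes (`MMH`, `HML`, `LML` by default;
#' `HML` is the band triplet containing the base model), and runs
#' [prc_population_study()] over the distinct qualifying models of each,
#' capped at `max_models` per population.
#'
#' @param db a `model_database`.
#' @param bands a [derive_bands()] result.
#' @param triplets named list of band triplets.
#' @param currents tonic currents (pA).
#' @param max_models cap on distinct models per population (keeps run time
#'   proportionate; the study design uses every distinct model).
#' @param seed integer seed for the per-population subsampling.
#' @param ... passed to [compute_prc()].
#' @return The [prc_population_study()] table.
#' @export
run_prc_study <- function(db, bands,
                          triplets = list(slow = c("M", "M", "H"),
                                          medium = c("H", "M", "L"),
                                          fast = c("L", "M", "L")),
                          currents = seq(20, 30, by = 2),
                          max_models = 10, seed = 1, ...) {
  stopifnot(inherits(db, "model_database"), inherits(bands, "band_spec"))
  populations <- list()
  for (nm in names(triplets)) {
    sel <- select_population(db, bands, triplets[[nm]], size = 1, seed = seed)
    ids <- sel$qualifying_ids
    if (length(ids) > max_models) {
      set.seed(seed)
      ids <- sort(sample(ids, max_models))
    }
    rows <- match(ids, db$model_id)
    populations[[nm]] <- lapply(rows, function(r) db_cell_params(db, r))
  }
  prc_population_study(populations, currents = currents, ...)
}

#' Read and write workflow configuration blocks
#'
#' Grid, band and network settings serialize to YAML or JSON (chosen by
#' file extension) as plain named lists; seeds are mandatory fields of the
#' objects that consume randomness.
#'
#' @param x a named list.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_config`: the path, invisibly. `read_config`: the list.
#' @export
write_config <- function(x, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Run manifest
#'
#' A small provenance record emitted by end-to-end drivers: configuration
#' snapshot, seeds, package version, output paths and wall time.
#'
#' @param config config snapshot (named list).
#' @param seeds named list of seeds used.
#' @param outputs named list of output file paths.
#' @param wall_s elapsed wall time (s).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds, outputs, wall_s) {
  for (f in unlist(outputs))
    if (!file.exists(f)) stop("manifest references missing output: ", f,
                              call. = FALSE)
  structure(list(config = config, seeds = seeds, outputs = outputs,
                 wall_s = wall_s,
                 version = as.character(utils::packageVersion("ca1theta"))),
            class = "run_manifest")
}
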