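#' Parameter grid specification for the model database
#'
#' The heterogeneous pyramidal-cell database is built by a regular sweep of
#' the four parameters that shape the building-block features -- `a`, `b`,
#' `d` and `k_low` -- with all other parameters fixed at their defaults.
#'
#' @param a,b,d,k_low numeric vectors of values to sweep.
#' @param base the fixed base [cell_params()] whose remaining fields are
#'   held constant.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(a, b, d, k_low, base = pyr_default_params()) {
  vals <- list(a = as.numeric(a), b = as.numeric(b),
               d = as.numeric(d), k_low = as.numeric(k_low))
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) == 0 || any(!is.finite(v)))
      stop("grid values for ", nm, " must be non-empty and finite", call. = FALSE)
    if (nm %in% c("a", "k_low") && any(v <= 0))
      stop(nm, " values must be positive", call. = FALSE)
    if (nm == "d" && any(v < 0))
      stop("d values must be non-negative", call. = FALSE)
  }
  structure(c(vals, list(base = base)), class = "grid_spec")
}

#' Reference parameter grid bracketing the default cell
#'
#' Builds per-parameter value lists bracketing the default values
#' (`a`: 0.0006--0.0016 and `k_low`: 0.04--0.12, geometrically spaced;
#' `b`: 1.5--4 and `d`: 2--11, arithmetically spaced). In each list the
#' value closest to the default is replaced by the default itself, so the
#' base cell is always a grid member. With `n_per_param = 10` the full
#' product has 10,000 models.
#'
#' The ranges are chosen so that the resulting feature distributions place
#' the base cell's triplet in the \[High SFA, Medium Rheo, Low PIR\] bands
#' of [derive_bands()] and leave the slow/medium/fast study populations
#' (MMH, HML, LML) non-empty -- the qualitative structure the downstream
#' network and PRC workflows assume. The grid is a reference fixture only;
#' any [grid_spec()] can be swept instead.
#'
#' @param n_per_param number of values per parameter.
#' @return A `grid_spec`.
#' @export
default_grid_spec <- function(n_per_param = 10) {
  stopifnot(n_per_param >= 2)
  geo <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))
  with_default <- function(v, def) {
    v[which.min(abs(v - def))] <- def
    sort(unique(v))
  }
  grid_spec(a = with_default(geo(6e-4, 1.6e-3, n_per_param), 0.0012),
            b = with_default(seq(1.5, 4, length.out = n_per_param), 3),
            d = with_default(seq(2, 11, length.out = n_per_param), 10),
            k_low = with_default(geo(0.04, 0.12, n_per_param), 0.1))
}

#' Build the heterogeneous model database
#'
#' Takes the Cartesian product of the grid values, phenotypes every
#' parameter combination with [quantify_features()], and returns one row
#' per model. Rows whose three features are all undefined are retained but
#' flagged.
#'
#' @param grid a [grid_spec()].
#' @param dt integration step (ms) used for all phenotyping protocols.
#' @param progress print a progress line every `progress` models (0 = quiet).
#' @return An object of class `model_database`: a data.frame with columns
#'   `model_id` (0-based), `a`, `b`, `d`, `k_low`, `sfa`, `rheo`, `pir`,
#'   `all_undefined`. The fixed base parameters are kept in
#'   `attr(, "base_params")` and the base cell's triplet in
#'   `attr(, "base_triplet")`.
#' @examples
#' db <- build_database(grid_spec(a = 0.0012, b = 3, d = c(5, 10),
#'                                k_low = 0.1))
#' nrow(db)
#' @export
build_database <- function(grid, dt = 0.04, progress = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  combos <- expand.grid(a = grid$a, b = grid$b, d = grid$d,
                        k_low = grid$k_low, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(combos)
  base <- grid$base
  sfa <- rheo <- pir <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- cell_params(C_m = base[["C_m"]], v_r = base[["v_r"]],
                     v_t = base[["v_t"]], v_peak = base[["v_peak"]],
                     a = combos$a[i], b = combos$b[i], c = base[["c"]],
                     d = combos$d[i], k_low = combos$k_low[i],
                     k_high = base[["k_high"]])
    tri <- quantify_features(p, dt = dt)
    sfa[i] <- tri$sfa; rheo[i] <- tri$rheo; pir[i] <- tri$pir
    if (progress > 0 && i %% progress == 0)
      message(sprintf("phenotyped %d / %d models", i, n))
  }
  db <- data.frame(model_id = seq_len(n) - 1L, combos,
                   sfa = sfa, rheo = rheo, pir = pir,
                   all_undefined = is.na(sfa) & is.na(rheo) & is.na(pir))
  attr(db, "base_params") <- base
  attr(db, "base_triplet") <- quantify_features(base, dt = dt)
  class(db) <- c("model_database", "data.frame")
  db
}

#' Reconstruct the full parameter set for a database row
#'
#' @param db a `model_database`.
#' @param row a single row index (1-based) into `db`.
#' @return A [cell_params()] object.
#' @export
db_cell_params <- function(db, row) {
  stopifnot(inherits(db, "model_database"), length(row) == 1)
  base <- attr(db, "base_params")
  cell_params(C_m = base[["C_m"]], v_r = base[["v_r"]], v_t = base[["v_t"]],
              v_peak = base[["v_peak"]], a = db$a[row], b = db$b[row],
              c = base[["c"]], d = db$d[row], k_low = db$k_low[row],
              k_high = base[["k_high"]])
}

#' Histogram of a database feature
#'
#' Counts defined feature values in fixed-width bins aligned to the origin
#' (bin edges at integer multiples of `bin`, right-open), the layout used
#' for the database's feature-distribution summaries: 0.05 Hz/pA bins for
#' SFA and 0.5 pA bins for Rheo and PIR.
#'
#' @param db a `model_database`.
#' @param feature one of `"sfa"`, `"rheo"`, `"pir"`.
#' @param bin bin width; defaults to 0.05 for SFA, 0.5 otherwise.
#' @return A data.frame with `lower`, `upper`, `mid`, `count` (empty bins
#'   inside the observed range included).
#' @export
feature_histogram <- function(db, feature, bin = NULL) {
  stopifnot(inherits(db, "model_database"))
  feature <- match.arg(feature, c("sfa", "rheo", "pir"))
  if (is.null(bin)) bin <- if (feature == "sfa") 0.05 else 0.5
  v <- db[[feature]]
  v <- v[!is.na(v)]
  if (length(v) == 0)
    stop("feature '", feature, "' is undefined for every model", call. = FALSE)
  idx <- floor(v / bin + 1e-9)
  rng <- seq(min(idx), max(idx))
  counts <- vapply(rng, function(i) sum(idx == i), numeric(1))
  data.frame(lower = rng * bin, upper = (rng + 1) * bin,
             mid = (rng + 0.5) * bin, count = counts)
}

#' Derive feature bands from a model database
#'
#' For every feature (SFA, Rheo, PIR) two band systems are computed over
#' the rows with that feature defined:
#' \itemize{
#'   \item Low/Medium/High: a tertile split of the defined values. The
#'     interior boundaries are the 1/3 and 2/3 quantiles; Low is
#'     `[min, q13]`, Medium `(q13, q23]`, High `(q23, max]`.
#'   \item Narrow/Broad: symmetric intervals about the base cell's feature
#'     value spanning a fraction of the observed range (defaults: narrow
#'     20%, broad 60% of the range, so narrow is always inside broad).
#' }
#'
#' @param db a `model_database` from [build_database()].
#' @param narrow_frac,broad_frac fractions of each feature's observed range
#'   covered by the Narrow and Broad intervals.
#' @return An object of class `band_spec`: per feature, a list with
#'   `range`, the tertile `breaks`, and `narrow`/`broad` intervals plus the
#'   `base` value.
#' @export
derive_bands <- function(db, narrow_frac = 0.2, broad_frac = 0.6) {
  stopifnot(inherits(db, "model_database"))
  if (!(narrow_frac > 0 && narrow_frac < broad_frac))
    stop("require 0 < narrow_frac < broad_frac", call. = FALSE)
  base_tri <- attr(db, "base_triplet")
  out <- lapply(c("sfa", "rheo", "pir"), function(feat) {
    v <- db[[feat]]
    v <- v[!is.na(v)]
    if (length(v) == 0)
      stop("feature '", feat, "' is undefined for every model", call. = FALSE)
    q <- unname(stats::quantile(v, c(1 / 3, 2 / 3), type = 7))
    base <- base_tri[[feat]]
    half_n <- narrow_frac * diff(range(v)) / 2
    half_b <- broad_frac * diff(range(v)) / 2
    list(range = range(v), breaks = q,
         narrow = c(base - half_n, base + half_n),
         broad = c(base - half_b, base + half_b),
         base = base)
  })
  names(out) <- c("sfa", "rheo", "pir")
  structure(out, class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  for (feat in names(x)) {
    b <- x[[feat]]
    cat(sprintf(
      "%-4s range [%.3g, %.3g]; L/M/H breaks %.3g, %.3g; N [%.3g, %.3g]; B [%.3g, %.3g]\n",
      toupper(feat), b$range[1], b$range[2], b$breaks[1], b$breaks[2],
      b$narrow[1], b$narrow[2], b$broad[1], b$broad[2]))
  }
  invisible(x)
}

#' Band membership of feature values
#'
#' @param x feature values.
#' @param bands a [derive_bands()] result.
#' @param feature one of `"sfa"`, `"rheo"`, `"pir"`.
#' @param band one of `"L"`, `"M"`, `"H"`, `"N"`, `"B"`.
#' @return Logical vector; `NA` inputs are never members.
#' @export
in_band <- function(x, bands, feature, band) {
  stopifnot(inherits(bands, "band_spec"))
  b <- bands[[match.arg(feature, c("sfa", "rheo", "pir"))]]
  band <- match.arg(band, c("L", "M", "H", "N", "B"))
  res <- switch(band,
    L = x <= b$breaks[1],
    M = x > b$breaks[1] & x <= b$breaks[2],
    H = x > b$breaks[2],
    N = x >= b$narrow[1] & x <= b$narrow[2],
    B = x >= b$broad[1] & x <= b$broad[2])
  res & !is.na(x)
}

#' Classify each feature of a triplet into its L/M/H band
#'
#' @param triplet a `feature_triplet` (or a list with `sfa`, `rheo`, `pir`).
#' @param bands a [derive_bands()] result.
#' @return Character vector of length 3 (`sfa`, `rheo`, `pir`), values
#'   `"L"`, `"M"`, `"H"` or `NA`.
#' @export
classify_triplet <- function(triplet, bands) {
  vapply(c("sfa", "rheo", "pir"), function(feat) {
    x <- triplet[[feat]]
    if (is.na(x)) return(NA_character_)
    for (band in c("L", "M", "H"))
      if (in_band(x, bands, feat, band)) return(band)
    NA_character_
  }, character(1))
}

#' Select a heterogeneous population from the database
#'
#' Filters database rows whose feature triplet satisfies the requested band
#' for all three features, then samples rows uniformly with replacement up
#' to the requested population size. Sampling with replacement lets a small
#' set of distinct models populate an arbitrarily large network, as in the
#' study design where e.g. 25 distinct models fill 10,000 network cells.
#'
#' @param db a `model_database`.
#' @param bands a [derive_bands()] result.
#' @param triplet character vector of length 3: the band for SFA, Rheo and
#'   PIR in that order, each `"L"`, `"M"`, `"H"`, `"N"` or `"B"`.
#' @param size number of cells to draw.
#' @param seed integer seed for the draw.
#' @return An object of class `population_selection`: list with `params`
#'   (list of [cell_params()], length `size`), `model_ids` (drawn rows'
#'   ids), `qualifying_ids`, `n_distinct` (number of distinct qualifying
#'   models), `triplet`, `seed`.
#' @export
select_population <- function(db, bands, triplet, size, seed) {
  stopifnot(inherits(db, "model_database"), inherits(bands, "band_spec"),
            length(triplet) == 3, size > 0)
  keep <- in_band(db$sfa, bands, "sfa", triplet[1]) &
    in_band(db$rheo, bands, "rheo", triplet[2]) &
    in_band(db$pir, bands, "pir", triplet[3])
  rows <- which(keep)
  if (length(rows) == 0)
    stop("empty selection: no database model has [SFA,Rheo,PIR] in bands [",
         paste(triplet, collapse = ","), "]", call. = FALSE)
  set.seed(seed)
  draw <- sample(rows, size, replace = TRUE)
  structure(list(params = lapply(draw, function(r) db_cell_params(db, r)),
                 model_ids = db$model_id[draw],
                 qualifying_ids = db$model_id[rows],
                 n_distinct = length(rows),
                 triplet = triplet, seed = seed),
            class = "population_selection")
}

#' @export
print.population_selection <- function(x, ...) {
  cat(sprintf(
    "population of %d cells drawn from %d distinct models (bands [%s], seed %d)\n",
    length(x$params), x$n_distinct, paste(x$triplet, collapse = ","), x$seed))
  invisible(x)
}

#' Write / read a model database as CSV
#'
#' The CSV holds the phenotyping report columns (`model_id, a, b, d, k_low,
#' sfa, rheo, pir, all_undefined`); undefined features are empty fields.
#' The fixed base parameters are not stored in the CSV, so `read_database_csv`
#' takes them as an argument (defaults match [pyr_default_params()]).
#'
#' @param db a `model_database`.
#' @param path file path.
#' @param base_params base [cell_params()] for reconstruction.
#' @param dt integration step used to re-quantify the base triplet.
#' @return `write_database_csv`: the path, invisibly.
#'   `read_database_csv`: a `model_database`.
#' @export
write_database_csv <- function(db, path) {
  stopifnot(inherits(db, "model_database"))
  out <- as.data.frame(db)
  # full %.17g precision so parameter values round-trip bit-exactly
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), NA, sprintf("%.17g", x)))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_database_csv
#' @export
read_database_csv <- function(path, base_params = pyr_default_params(),
                              dt = 0.04) {
  db <- utils::read.csv(path)
  attr(db, "base_params") <- base_params
  attr(db, "base_triplet") <- quantify_features(base_params, dt = dt)
  class(db) <- c("model_database", "data.frame")
  db
}
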