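#' Population firing-rate activity from a raster
#'
#' Bins all spikes of one population into contiguous bins over
#' `[0, duration]` and normalizes to an instantaneous rate in Hz per cell
#' (spikes / cells / bin width).
#'
#' @param raster a `spike_raster`.
#' @param bin_ms bin width (ms), positive.
#' @param population which population to bin (default `"PYR"`).
#' @return An object of class `population_activity`: list with `centers`
#'   (bin centers, ms), `rate` (Hz per cell), `bin_ms`, `n_cells`,
#'   `duration`. An empty raster gives all-zero activity.
#' @export
population_activity <- function(raster, bin_ms = 1, population = "PYR") {
  stopifnot(inherits(raster, "spike_raster"))
  if (!is.finite(bin_ms) || bin_ms <= 0) stop("bin_ms must be > 0", call. = FALSE)
  if (!population %in% names(raster$n_cells))
    stop("unknown population '", population, "'", call. = FALSE)
  n_cells <- raster$n_cells[[population]]
  breaks <- seq(0, raster$duration, by = bin_ms)
  if (breaks[length(breaks)] < raster$duration)
    breaks <- c(breaks, raster$duration)
  t <- raster$spikes$spike_time_ms[raster$spikes$population == population]
  counts <- if (length(t)) {
    # right-closed bins; a spike exactly at 0 goes in the first bin
    tabulate(findInterval(t, breaks, left.open = TRUE, all.inside = TRUE),
             nbins = length(breaks) - 1)
  } else rep(0L, length(breaks) - 1)
  widths <- diff(breaks)
  structure(list(centers = breaks[-length(breaks)] + widths / 2,
                 rate = counts / (n_cells * widths / 1000),
                 bin_ms = bin_ms, n_cells = n_cells,
                 duration = raster$duration),
            class = "population_activity")
}

#' Welch averaged periodogram
#'
#' Splits a regularly sampled signal into 50%-overlapping Hann-windowed
#' segments, removes each segment's mean, and averages the segment
#' periodograms into a one-sided power spectral density.
#'
#' @param x numeric signal.
#' @param fs sampling frequency (Hz).
#' @param window_len segment length in samples.
#' @param overlap fractional segment overlap (default 0.5).
#' @return A data.frame with columns `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, window_len = 2048, overlap = 0.5) {
  n <- length(x)
  window_len <- min(window_len, n)
  step <- max(1, floor(window_len * (1 - overlap)))
  starts <- seq(1, n - window_len + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(window_len) / (window_len + 1)))
  norm <- fs * sum(w^2)
  nf <- window_len %/% 2
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + window_len - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2 / norm
    acc <- acc + 2 * sp[2:(nf + 1)] # one-sided (DC dropped)
  }
  data.frame(freq = fs * seq_len(nf) / window_len, psd = acc / length(starts))
}

#' Quantify rhythm frequency, power and strength
#'
#' Discards an initial transient, computes a Welch power spectral density
#' of the mean-subtracted population rate, and reports the spectral peak
#' within the search band. The activity is classified as rhythmic when the
#' peak density exceeds `threshold` times the median density within the
#' band -- a scale-free criterion, since the study's power units are
#' arbitrary.
#'
#' @param activity a [population_activity()] result.
#' @param band frequency search band (Hz), default the 3-12 Hz theta band.
#' @param burn_in_ms transient discarded before analysis (ms).
#' @param window_ms Welch segment length (ms).
#' @param threshold rhythmicity threshold (peak / band median).
#' @return An object of class `rhythm_metrics`: list with `peak_frequency`
#'   (Hz), `peak_power`, `band_median`, `is_rhythmic`, `band`,
#'   `resolution_hz`.
#' @export
rhythm_metrics <- function(activity, band = c(3, 12), burn_in_ms = 500,
                           window_ms = 2048, threshold = 5) {
  stopifnot(inherits(activity, "population_activity"))
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop("band must be an increasing positive pair (Hz)", call. = FALSE)
  keep <- activity$centers >= burn_in_ms
  analysed_ms <- activity$duration - burn_in_ms
  if (analysed_ms < 10 * 1000 / band[1])
    stop("recording too short: need at least 10 cycles of the band minimum (",
         sprintf("%.0f ms", 10 * 1000 / band[1]), ") after burn-in", call. = FALSE)
  fs <- 1000 / activity$bin_ms
  spec <- welch_psd(activity$rate[keep], fs,
                    window_len = round(window_ms / activity$bin_ms))
  inb <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(inb)) stop("no spectral estimate inside the band", call. = FALSE)
  pk <- which.max(spec$psd[inb])
  peak_f <- spec$freq[inb][pk]
  peak_p <- spec$psd[inb][pk]
  med <- stats::median(spec$psd[inb])
  structure(list(peak_frequency = peak_f, peak_power = peak_p,
                 band_median = med,
                 is_rhythmic = med > 0 && peak_p >= threshold * med,
                 band = band,
                 resolution_hz = fs / round(window_ms / activity$bin_ms),
                 spectrum = spec),
            class = "rhythm_metrics")
}

#' @export
print.rhythm_metrics <- function(x, ...) {
  cat(sprintf(
    "rhythm_metrics: peak %.2f Hz (power %.3g, %.1fx band median) in %g-%g Hz -> %s\n",
    x$peak_frequency, x$peak_power,
    if (x$band_median > 0) x$peak_power / x$band_median else Inf,
    x$band[1], x$band[2], if (x$is_rhythmic) "rhythmic" else "not rhythmic"))
  invisible(x)
}

#' Write rhythm metrics as a JSON record
#'
#' @param metrics a `rhythm_metrics` result.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "rhythm_metrics"))
  jsonlite::write_json(metrics[c("peak_frequency", "peak_power",
                                 "band_median", "is_rhythmic", "band",
                                 "resolution_hz")],
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Per-cycle participation of a population in the rhythm
#'
#' Splits the analysed interval into consecutive cycle windows of the
#' rhythm period and reports the mean fraction of cells of the population
#' that spike at least once per window. Used to contrast the dense firing
#' of purely excitatory networks with the sparse participation that
#' inhibition enforces in E-I networks.
#'
#' @param raster a `spike_raster`.
#' @param frequency_hz rhythm frequency defining the cycle length.
#' @param population population to measure (default `"PYR"`).
#' @param burn_in_ms initial transient to discard (ms).
#' @return Mean fraction of cells spiking per cycle, in \[0, 1\].
#' @export
burst_participation <- function(raster, frequency_hz, population = "PYR",
                                burn_in_ms = 500) {
  stopifnot(inherits(raster, "spike_raster"), frequency_hz > 0)
  cycle_ms <- 1000 / frequency_hz
  edges <- seq(burn_in_ms, raster$duration, by = cycle_ms)
  if (length(edges) < 2)
    stop("recording shorter than one cycle after burn-in", call. = FALSE)
  sp <- raster$spikes[raster$spikes$population == population &
                        raster$spikes$spike_time_ms >= burn_in_ms &
                        raster$spikes$spike_time_ms < edges[length(edges)], ]
  n_cells <- raster$n_cells[[population]]
  if (nrow(sp) == 0) return(0)
  win <- findInterval(sp$spike_time_ms, edges)
  per_cycle <- tapply(sp$cell_id, win, function(x) length(unique(x)))
  counts <- rep(0, length(edges) - 1)
  counts[as.integer(names(per_cycle))] <- per_cycle
  mean(counts) / n_cells
}

#' Sinusoidally modulated Poisson raster
#'
#' Generates independent inhomogeneous Poisson spike trains with rate
#' `base_rate * (1 + depth * sin(2 pi f t))`, discretized at 1 ms
#' resolution. Used as a ground-truth input for validating rhythm
#' detection; `depth = 0` gives a homogeneous (white-noise) raster.
#'
#' @param n_cells number of cells.
#' @param duration_ms recording length (ms).
#' @param base_rate_hz mean firing rate per cell (Hz).
#' @param mod_freq_hz modulation frequency (Hz).
#' @param depth modulation depth in \[0, 1\].
#' @param seed integer seed.
#' @return A `spike_raster` with a single `"PYR"` population.
#' @export
simulate_modulated_poisson_raster <- function(n_cells, duration_ms,
                                              base_rate_hz, mod_freq_hz,
                                              depth, seed) {
  stopifnot(n_cells > 0, duration_ms > 0, base_rate_hz >= 0,
            depth >= 0, depth <= 1)
  set.seed(seed)
  dt_ms <- 1
  tt <- seq(dt_ms / 2, duration_ms - dt_ms / 2, by = dt_ms)
  p <- base_rate_hz * (1 + depth * sin(2 * pi * mod_freq_hz * tt / 1000)) *
    dt_ms / 1000
  spikes <- lapply(seq_len(n_cells), function(cell) {
    hit <- which(stats::runif(length(tt)) < p)
    if (length(hit))
      data.frame(population = "PYR", cell_id = cell, spike_time_ms = tt[hit])
  })
  spikes <- do.call(rbind, spikes)
  if (is.null(spikes))
    spikes <- data.frame(population = character(), cell_id = integer(),
                         spike_time_ms = numeric())
  new_spike_raster(spikes, n_cells = c(PYR = n_cells),
                   duration = duration_ms,
                   meta = list(seed = seed, generator = "modulated_poisson",
                               mod_freq_hz = mod_freq_hz, depth = depth))
}
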