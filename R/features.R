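#' Quantify rheobase by a constant-current sweep
#'
#' Sweeps constant currents in ascending order (default -25 to 25 pA in
#' 0.5 pA increments), each applied from the resting state `(v_r, 0)`, and
#' returns the smallest current for which a spike occurs within the
#' detection window (default the first 500 ms). `NA` if no sweep current
#' elicits a spike.
#'
#' @param params a [cell_params()] object.
#' @param currents sweep amplitudes (pA), ascending.
#' @param window_ms spike-detection window from stimulus onset (ms).
#' @param dt integration step (ms).
#' @return The rheobase (pA) or `NA_real_`.
#' @examples
#' quantify_rheobase(pyr_default_params())
#' @export
quantify_rheobase <- function(params, currents = seq(-25, 25, by = 0.5),
                              window_ms = 500, dt = 0.04) {
  stopifnot(inherits(params, "cell_params"))
  for (I in currents) {
    tr <- integrate_cell(params, step_protocol(I, window_ms, dt = dt),
                         store_trace = FALSE, max_spikes = 1L)
    if (length(tr$spike_times) > 0) return(I)
  }
  NA_real_
}

#' Quantify post-inhibitory rebound by a hyperpolarizing-step sweep
#'
#' Applies 1 s hyperpolarizing steps from 0 to -25 pA in -0.5 pA increments,
#' each from `(v_r, 0)` and released to zero current, and returns the first
#' step value at which a spike occurs after step offset while no rebound
#' spike occurred at the previous (less negative) step value. `NA` if no
#' step elicits a rebound spike.
#'
#' @param params a [cell_params()] object.
#' @param steps sweep step amplitudes (pA), from 0 downward.
#' @param step_ms hyperpolarizing step duration (ms).
#' @param window_ms rebound-detection window after step offset (ms).
#' @param dt integration step (ms).
#' @return The PIR step value (pA, non-positive) or `NA_real_`.
#' @examples
#' quantify_pir(pyr_default_params())
#' @export
quantify_pir <- function(params, steps = seq(0, -25, by = -0.5),
                         step_ms = 1000, window_ms = 500, dt = 0.04) {
  stopifnot(inherits(params, "cell_params"))
  prev_rebound <- FALSE
  for (I in steps) {
    tr <- integrate_cell(params,
                         step_protocol(I, step_ms, post_ms = window_ms, dt = dt),
                         store_trace = FALSE)
    rebound <- any(tr$spike_times > step_ms)
    if (rebound && !prev_rebound) return(I)
    prev_rebound <- rebound
  }
  NA_real_
}

#' Least-squares f-I slopes for the adaptation contrast
#'
#' Fits one straight line to the initial-frequency series and one to the
#' final-frequency series over the same set of currents and returns both
#' slopes and their difference. Exposed separately so that the fitting step
#' can be exercised (and cross-checked) independently of the simulations.
#'
#' @param currents qualifying step currents (pA).
#' @param init_freq,final_freq per-current frequencies (Hz).
#' @return A list with `init_slope`, `final_slope` and `sfa`
#'   (`init_slope - final_slope`, Hz/pA).
#' @export
fit_fi_slopes <- function(currents, init_freq, final_freq) {
  stopifnot(length(currents) == length(init_freq),
            length(currents) == length(final_freq))
  if (length(currents) < 2)
    stop("need at least two qualifying currents to fit f-I slopes", call. = FALSE)
  init_slope <- unname(stats::coef(stats::lm(init_freq ~ currents))[2])
  final_slope <- unname(stats::coef(stats::lm(final_freq ~ currents))[2])
  list(init_slope = init_slope, final_slope = final_slope,
       sfa = init_slope - final_slope)
}

#' Quantify spike-frequency adaptation from f-I curves
#'
#' Applies 1 s constant-current steps from 0 to 98 pA (inclusive) in 2 pA
#' increments, each from `(v_r, 0)`. For each step the initial frequency is
#' the inverse of the first interspike interval and the final frequency the
#' inverse of the last. Straight lines are fitted to the two
#' frequency-vs-current series over qualifying currents and SFA is the
#' difference of their slopes (initial minus final): larger values mean
#' stronger adaptation.
#'
#' Only steps eliciting at least `min_spikes` spikes qualify (with exactly
#' two spikes the initial and final intervals coincide and carry no
#' adaptation contrast); both series use the same qualifying set so the
#' slopes are comparable.
#'
#' @param params a [cell_params()] object.
#' @param currents step currents (pA).
#' @param step_ms step duration (ms).
#' @param min_spikes minimum spike count for a step to qualify (default 3).
#' @param dt integration step (ms).
#' @return An object of class `fi_curve_fit`: list with `currents`,
#'   `init_freq`, `final_freq` (qualifying steps only), `init_slope`,
#'   `final_slope`, `sfa` (Hz/pA). When fewer than two steps qualify,
#'   `sfa` is `NA_real_` and `reason` explains why.
#' @examples
#' fit <- quantify_sfa(pyr_default_params())
#' fit$sfa
#' @export
quantify_sfa <- function(params, currents = seq(0, 98, by = 2),
                         step_ms = 1000, min_spikes = 3, dt = 0.04) {
  stopifnot(inherits(params, "cell_params"))
  init_f <- final_f <- rep(NA_real_, length(currents))
  for (j in seq_along(currents)) {
    tr <- integrate_cell(params, step_protocol(currents[j], step_ms, dt = dt),
                         store_trace = FALSE)
    s <- tr$spike_times
    if (length(s) >= min_spikes) {
      init_f[j] <- 1000 / (s[2] - s[1])
      final_f[j] <- 1000 / (s[length(s)] - s[length(s) - 1])
    }
  }
  ok <- !is.na(init_f)
  out <- list(currents = currents[ok], init_freq = init_f[ok],
              final_freq = final_f[ok],
              init_slope = NA_real_, final_slope = NA_real_,
              sfa = NA_real_, reason = NULL)
  if (sum(ok) < 2) {
    out$reason <- sprintf(
      "only %d step(s) elicited >= %d spikes; cannot fit f-I lines",
      sum(ok), min_spikes)
  } else {
    fit <- fit_fi_slopes(currents[ok], init_f[ok], final_f[ok])
    out[c("init_slope", "final_slope", "sfa")] <- fit
  }
  structure(out, class = "fi_curve_fit")
}

#' @export
print.fi_curve_fit <- function(x, ...) {
  if (is.na(x$sfa)) {
    cat("f-I fit: SFA undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "f-I fit over %d currents: init slope %.4f, final slope %.4f, SFA %.4f Hz/pA\n",
      length(x$currents), x$init_slope, x$final_slope, x$sfa))
  }
  invisible(x)
}

#' Quantify the full building-block feature triplet
#'
#' Runs the three current-step protocols and returns the quantified
#' spike-frequency adaptation, rheobase and post-inhibitory rebound of a
#' cell. All protocols restart from the resting state `(v_r, 0)` at every
#' sweep step, so repeated quantification is bit-reproducible.
#'
#' @param params a [cell_params()] object.
#' @param dt integration step (ms).
#' @return An object of class `feature_triplet`: list with numeric `sfa`
#'   (Hz/pA), `rheo` (pA), `pir` (pA); undefined features are `NA_real_`.
#' @examples
#' quantify_features(pyr_default_params())
#' @export
quantify_features <- function(params, dt = 0.04) {
  structure(list(sfa = quantify_sfa(params, dt = dt)$sfa,
                 rheo = quantify_rheobase(params, dt = dt),
                 pir = quantify_pir(params, dt = dt)),
            class = "feature_triplet")
}

#' @export
print.feature_triplet <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else format(v)
  cat(sprintf("[SFA, Rheo, PIR] = [%s Hz/pA, %s pA, %s pA]\n",
              fmt(x$sfa), fmt(x$rheo), fmt(x$pir)))
  invisible(x)
}

#' One-row phenotyping report for a cell
#'
#' @param model_id identifier for the row.
#' @param params a [cell_params()] object.
#' @param triplet optional precomputed [quantify_features()] result.
#' @param dt integration step used if `triplet` is missing.
#' @return A one-row data.frame with columns `model_id, a, b, d, k_low,
#'   sfa, rheo, pir` (undefined features as `NA`).
#' @export
phenotype_row <- function(model_id, params, triplet = NULL, dt = 0.04) {
  if (is.null(triplet)) triplet <- quantify_features(params, dt = dt)
  data.frame(model_id = model_id,
             a = params[["a"]], b = params[["b"]], d = params[["d"]],
             k_low = params[["k_low"]],
             sfa = triplet$sfa, rheo = triplet$rheo, pir = triplet$pir)
}
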