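#' Izhikevich cell parameters
#'
#' Construct a validated parameter set for the two-regime Izhikevich neuron
#'
#' \deqn{C_m \dot V = k (V - v_r)(V - v_t) - u + I_{other}}
#' \deqn{\dot u = a [ b (V - v_r) - u ]}
#'
#' with the hybrid reset: if \eqn{V \ge v_{peak}} then \eqn{V \leftarrow c},
#' \eqn{u \leftarrow u + d}. The scaling factor \eqn{k} is piecewise:
#' \eqn{k = k_{low}} when \eqn{V \le v_t} and \eqn{k = k_{high}} above, which
#' gives the model its sharp spike upstroke while keeping realistic
#' subthreshold behaviour.
#'
#' Defaults are the strongly adapting CA1 pyramidal-cell fit used throughout
#' the package; [pyr_default_params()] returns them unchanged.
#'
#' @param C_m membrane capacitance (pF); must be positive.
#' @param v_r resting membrane potential (mV).
#' @param v_t instantaneous threshold potential (mV); must exceed `v_r`.
#' @param v_peak spike cut-off (mV); must exceed `v_t`.
#' @param a recovery time constant (1/ms); must be positive.
#' @param b recovery sensitivity to subthreshold voltage (nS); may be
#'   negative (as in fast-firing PV+ fits).
#' @param c voltage reset after a spike (mV); must be below `v_peak`.
#' @param d after-spike recovery increment (pA); must be non-negative.
#' @param k_low subthreshold scaling factor (nS/mV); must be positive.
#' @param k_high suprathreshold scaling factor (nS/mV); must be positive.
#'
#' @return An object of class `cell_params`: a named numeric vector with the
#'   ten fields above.
#' @examples
#' p <- cell_params()         # strongly adapting PYR defaults
#' p["a"]
#' @export
cell_params <- function(C_m = 115, v_r = -61.8, v_t = -57, v_peak = 22.6,
                        a = 0.0012, b = 3, c = -65.8, d = 10,
                        k_low = 0.1, k_high = 3.3) {
  p <- c(C_m = C_m, v_r = v_r, v_t = v_t, v_peak = v_peak, a = a, b = b,
         c = c, d = d, k_low = k_low, k_high = k_high)
  if (!is.numeric(p) || length(p) != 10L || any(!is.finite(p)))
    stop("all cell parameters must be finite numbers", call. = FALSE)
  if (!(v_r < v_t && v_t < v_peak))
    stop("require v_r < v_t < v_peak", call. = FALSE)
  if (!(c < v_peak)) stop("require c < v_peak", call. = FALSE)
  if (C_m <= 0 || k_low <= 0 || k_high <= 0 || a <= 0 || d < 0)
    stop("require C_m, k_low, k_high, a > 0 and d >= 0", call. = FALSE)
  structure(p, class = "cell_params")
}

#' Default strongly adapting PYR cell parameters
#' @return A `cell_params` object with the default pyramidal-cell fit.
#' @export
pyr_default_params <- function() cell_params()

#' Fast-firing PV+ interneuron parameter preset
#'
#' Single-compartment Izhikevich fit for fast-firing parvalbumin-positive
#' CA1 interneurons, taken from the published whole-hippocampus fitting work
#' this package's network presets build on. Shipped as a preset, not a
#' quantity estimated here.
#'
#' @return A `cell_params` object.
#' @export
pv_default_params <- function() {
  cell_params(C_m = 90, v_r = -60.6, v_t = -43.1, v_peak = 2.5,
              a = 0.1, b = -0.1, c = -67, d = 0.1,
              k_low = 1.7, k_high = 1.7)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Izhikevich cell parameters:\n")
  print(unclass(x))
  invisible(x)
}

#' Piecewise-constant current protocol
#'
#' A stimulus for single-cell integration: an ordered list of constant
#' current segments, optionally with a per-step noise trace added pointwise.
#'
#' @param durations segment durations (ms); all positive.
#' @param amplitudes segment amplitudes (pA); same length as `durations`.
#' @param dt integration step (ms), default 0.04.
#' @param noise optional numeric vector of per-step current noise (pA),
#'   length `round(sum(durations) / dt)`.
#' @return An object of class `current_protocol`.
#' @examples
#' # 1 s hyperpolarizing step followed by 500 ms release
#' current_protocol(c(1000, 500), c(-5, 0))
#' @export
current_protocol <- function(durations, amplitudes, dt = 0.04, noise = NULL) {
  if (length(durations) == 0L || length(durations) != length(amplitudes))
    stop("durations and amplitudes must be non-empty and equal length", call. = FALSE)
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("segment durations must be positive and finite", call. = FALSE)
  if (any(!is.finite(amplitudes)))
    stop("segment amplitudes must be finite", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  n_steps <- as.integer(round(sum(durations) / dt))
  if (!is.null(noise)) {
    if (length(noise) != n_steps || any(!is.finite(noise)))
      stop("noise must be finite with one value per integration step (",
           n_steps, ")", call. = FALSE)
  }
  structure(list(durations = as.numeric(durations),
                 amplitudes = as.numeric(amplitudes),
                 dt = dt, noise = noise,
                 total_ms = sum(durations)),
            class = "current_protocol")
}

#' Constant-current step protocol
#'
#' Convenience wrapper: a single constant segment, optionally followed by a
#' release period at a different amplitude (used by the rebound protocol).
#'
#' @param amplitude step amplitude (pA).
#' @param duration step duration (ms).
#' @param post_ms duration of the release segment (ms); 0 for none.
#' @param post_amplitude amplitude during release (pA).
#' @inheritParams current_protocol
#' @return A `current_protocol`.
#' @export
step_protocol <- function(amplitude, duration, post_ms = 0,
                          post_amplitude = 0, dt = 0.04) {
  if (post_ms > 0)
    current_protocol(c(duration, post_ms), c(amplitude, post_amplitude), dt = dt)
  else
    current_protocol(duration, amplitude, dt = dt)
}

#' Integrate a single cell under a current protocol
#'
#' Fixed-step forward-Euler integration of the two-regime Izhikevich model.
#' Whenever the updated membrane potential reaches `v_peak` within a step, a
#' spike is recorded at that step's time, the potential is reset to `c` and
#' the recovery variable is incremented by `d` (at most once per step). The
#' piecewise scaling factor (`k_low` for V at or below `v_t`, `k_high`
#' above) is applied per step.
#'
#' @param params a [cell_params()] object.
#' @param protocol a [current_protocol()].
#' @param V0,u0 initial state; defaults to the resting fixed point
#'   `(v_r, 0)` of the model at zero input.
#' @param store_trace logical; keep the full V/u sample paths (default TRUE).
#'   With FALSE only spike times and the final state are returned.
#' @param max_spikes stop integration after this many spikes (0 = run the
#'   full protocol).
#' @return An object of class `cell_trace` with elements `times`, `V`, `u`
#'   (when `store_trace`), `spike_times` (ms), `duration`, `dt`, and the
#'   final state `V_end`, `u_end`.
#' @examples
#' tr <- integrate_cell(pyr_default_params(), step_protocol(20, 1000))
#' length(tr$spike_times)
#' @export
integrate_cell <- function(params, protocol, V0 = params[["v_r"]], u0 = 0,
                           store_trace = TRUE, max_spikes = 0L) {
  stopifnot(inherits(params, "cell_params"), inherits(protocol, "current_protocol"))
  if (!is.finite(V0) || !is.finite(u0))
    stop("initial state must be finite", call. = FALSE)
  if (V0 > params[["v_peak"]])
    stop("initial V must not exceed v_peak", call. = FALSE)
  noise <- protocol$noise
  if (is.null(noise)) noise <- numeric(0)
  out <- izh_integrate_cpp(as.numeric(params), V0, u0,
                           protocol$durations, protocol$amplitudes,
                           noise, protocol$dt, store_trace,
                           as.integer(max_spikes))
  out$params <- params
  class(out) <- "cell_trace"
  out
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("cell_trace: %.0f ms at dt = %g ms, %d spike(s)\n",
              x$duration, x$dt, length(x$spike_times)))
  invisible(x)
}

#' Export a voltage trace or its spike times to CSV
#'
#' `write_trace_csv()` writes columns `time_ms, V_mV, u_pA`;
#' `write_spikes_csv()` writes a single column `time_ms`.
#'
#' @param trace a `cell_trace` from [integrate_cell()] (with a stored trace).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cell_trace"))
  if (is.null(trace$times))
    stop("trace was integrated with store_trace = FALSE", call. = FALSE)
  utils::write.csv(data.frame(time_ms = trace$times, V_mV = trace$V,
                              u_pA = trace$u),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_spikes_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cell_trace"))
  utils::write.csv(data.frame(time_ms = trace$spike_times), path,
                   row.names = FALSE)
  invisible(path)
}
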