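#' Synapse parameters for one projection
#'
#' Synapses are conductance-based with instantaneous rise and
#' single-exponential decay: each presynaptic spike increments the target's
#' conductance by `weight`, and the synaptic current is
#' `g * (E_rev - V)` (nS x mV = pA).
#'
#' @param weight conductance increment per spike (nS), non-negative.
#' @param tau_decay decay time constant (ms), positive.
#' @param E_rev reversal potential (mV).
#' @return A list of class `synapse_params`.
#' @export
synapse_params <- function(weight, tau_decay, E_rev) {
  if (!is.finite(weight) || weight < 0) stop("weight must be >= 0", call. = FALSE)
  if (!is.finite(tau_decay) || tau_decay <= 0) stop("tau_decay must be > 0", call. = FALSE)
  structure(list(weight = weight, tau_decay = tau_decay, E_rev = E_rev),
            class = "synapse_params")
}

#' E-I network configuration
#'
#' Describes a sparse excitatory-inhibitory network of Izhikevich PYR and
#' fast-firing PV+ cells. The reference scale is 10,000 PYR + 500 PV+
#' cells with sparse (< 1%) PYR-to-PYR coupling and an asymmetric
#' inter-population connectivity: the PV+ to PYR connection probability
#' exceeds the PYR to PV+ one, as required by the EPSC/IPSC amplitude-ratio
#' constraint of the design lineage. Synaptic weights, time constants,
#' reversal potentials, PV+ cell parameters and drive statistics are
#' presets from that modelling lineage and are all overridable.
#'
#' Drive is delivered per population as a mean current plus zero-mean noise
#' whose `amplitude` is interpreted peak-to-peak (the Gaussian SD is
#' amplitude/4). The default noise is an Ornstein-Uhlenbeck current with
#' correlation time `ou_tau` (10 ms): the PYR membrane time constant is of
#' order 200 ms, so noise must carry power at sub-100 Hz frequencies to
#' move the membrane at these amplitudes. Piecewise-constant white noise
#' resampled every `noise_dt` ms is available with `noise = "white"`.
#'
#' @param n_pyr,n_pv cell counts.
#' @param pyr_params a single [cell_params()] (homogeneous population), a
#'   [select_population()] result, or a list of `cell_params` of length
#'   `n_pyr`.
#' @param pv_params a single [cell_params()] for the PV+ population.
#' @param p named list of connection probabilities `ee` (PYR->PYR),
#'   `ei` (PYR->PV), `ie` (PV->PYR), `ii` (PV->PV).
#' @param syn named list of [synapse_params()] per projection
#'   (`ee`, `ei`, `ie`, `ii`).
#' @param drive named list with elements `pyr` and `pv`, each a list with
#'   `mean` (pA) and `amplitude` (peak-to-peak fluctuation, pA).
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param seed integer seed (mandatory; drives both wiring and noise).
#' @param noise `"ou"` or `"white"`.
#' @param noise_dt resampling interval of the white drive noise (ms).
#' @param ou_tau correlation time of the OU drive noise (ms).
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_pyr = 10000, n_pv = 500,
                           pyr_params = pyr_default_params(),
                           pv_params = pv_default_params(),
                           p = list(ee = 0.008, ei = 0.05, ie = 0.3, ii = 0.12),
                           syn = list(
                             ee = synapse_params(0.1, 6, -15),
                             ei = synapse_params(0.1, 3, -15),
                             ie = synapse_params(0.01, 8, -85),
                             ii = synapse_params(0.55, 3, -85)),
                           drive = list(pyr = list(mean = 0, amplitude = 30),
                                        pv = list(mean = 120, amplitude = 20)),
                           duration = 5000, dt = 0.04, seed = 1,
                           noise = c("ou", "white"), noise_dt = 1,
                           ou_tau = 10) {
  noise <- match.arg(noise)
  cfg <- structure(list(n_pyr = as.integer(n_pyr), n_pv = as.integer(n_pv),
                        pyr_params = pyr_params, pv_params = pv_params,
                        p = p, syn = syn, drive = drive,
                        duration = duration, dt = dt,
                        seed = as.integer(seed), noise = noise,
                        noise_dt = noise_dt, ou_tau = ou_tau),
                   class = "network_config")
  validate_network_config(cfg)
  cfg
}

#' Validate a network configuration
#'
#' Checks probability bounds, the sparse PYR-PYR coupling requirement at
#' reference scale, and the asymmetry `p(PV->PYR) > p(PYR->PV)`.
#'
#' @param cfg a `network_config`.
#' @return The config, invisibly; errors describe the first violation.
#' @export
validate_network_config <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  if (cfg$n_pyr < 0 || cfg$n_pv < 0) stop("negative cell count", call. = FALSE)
  pv <- unlist(cfg$p[c("ee", "ei", "ie", "ii")])
  if (length(pv) != 4 || any(!is.finite(pv)) || any(pv < 0) || any(pv > 1))
    stop("connection probabilities must all lie in [0, 1]", call. = FALSE)
  if (cfg$n_pyr >= 10000 && cfg$p$ee >= 0.01)
    stop("PYR->PYR coupling must be sparse (< 1%) at reference scale",
         call. = FALSE)
  if (cfg$n_pv > 0 && cfg$p$ie <= cfg$p$ei)
    stop("require p(PV->PYR) > p(PYR->PV)", call. = FALSE)
  if (!(cfg$duration > 0) || !(cfg$dt > 0))
    stop("duration and dt must be positive", call. = FALSE)
  for (pop in c("pyr", "pv")) {
    dr <- cfg$drive[[pop]]
    if (!is.finite(dr$mean) || !is.finite(dr$amplitude) || dr$amplitude < 0)
      stop("invalid drive for population ", pop, call. = FALSE)
  }
  invisible(cfg)
}

# Bernoulli wiring of one projection: independent draws per ordered pair,
# realized as a binomial out-degree per presynaptic cell plus a uniform
# subset of targets (distributionally identical, linear in realized edges).
random_projection <- function(n_pre, n_post, p, exclude_self = FALSE) {
  from <- vector("list", n_pre)
  to <- vector("list", n_pre)
  if (n_pre > 0 && n_post > 0 && p > 0) {
    for (i in seq_len(n_pre)) {
      pool_size <- n_post - as.integer(exclude_self)
      k <- stats::rbinom(1, pool_size, p)
      if (k > 0) {
        tgt <- sample.int(pool_size, k)
        if (exclude_self) tgt <- tgt + (tgt >= i) # skip self index
        from[[i]] <- rep.int(i, k)
        to[[i]] <- tgt
      }
    }
  }
  list(from = unlist(from) %||% integer(0), to = unlist(to) %||% integer(0))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Draw the random connectivity of a network
#'
#' Independent Bernoulli draws per ordered cell pair (no self-connections),
#' consuming the current RNG state. Called internally by
#' [simulate_network()] after seeding; call [set.seed()] first when using
#' it directly.
#'
#' @param cfg a `network_config`.
#' @return A list with per-projection edge lists (`ee`, `ei`, `ie`, `ii`,
#'   each with 1-based `from`/`to` within the pre/post population) and
#'   `counts`, the realized edge count per projection.
#' @export
build_connectivity <- function(cfg) {
  validate_network_config(cfg)
  proj <- list(
    ee = random_projection(cfg$n_pyr, cfg$n_pyr, cfg$p$ee, exclude_self = TRUE),
    ei = random_projection(cfg$n_pyr, cfg$n_pv, cfg$p$ei),
    ie = random_projection(cfg$n_pv, cfg$n_pyr, cfg$p$ie),
    ii = random_projection(cfg$n_pv, cfg$n_pv, cfg$p$ii, exclude_self = TRUE))
  proj$counts <- vapply(proj[c("ee", "ei", "ie", "ii")],
                        function(e) length(e$from), numeric(1))
  proj
}

#' Rescale a network, preserving per-cell synaptic load
#'
#' Multiplies the cell counts by `factor` and compensates each projection's
#' synaptic weight so that the product (presynaptic count x connection
#' probability x weight) -- the expected total conductance a target cell
#' receives -- is unchanged. Probabilities are held fixed, so the expected
#' in-degree shrinks with the network and the compensating weight grows.
#'
#' @param cfg a `network_config`.
#' @param factor positive scaling ratio applied to the cell counts.
#' @return A rescaled `network_config`.
#' @export
scale_network <- function(cfg, factor) {
  validate_network_config(cfg)
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0", call. = FALSE)
  new_pyr <- as.integer(round(cfg$n_pyr * factor))
  new_pv <- as.integer(round(cfg$n_pv * factor))
  if ((cfg$n_pyr > 0 && new_pyr == 0) || (cfg$n_pv > 0 && new_pv == 0))
    stop("scaling factor collapses a population to zero cells", call. = FALSE)
  pre_old <- c(ee = cfg$n_pyr, ei = cfg$n_pyr, ie = cfg$n_pv, ii = cfg$n_pv)
  pre_new <- c(ee = new_pyr, ei = new_pyr, ie = new_pv, ii = new_pv)
  out <- cfg
  out$n_pyr <- new_pyr
  out$n_pv <- new_pv
  for (pr in names(pre_old)) {
    if (pre_new[[pr]] > 0)
      out$syn[[pr]]$weight <- cfg$syn[[pr]]$weight * pre_old[[pr]] / pre_new[[pr]]
  }
  if (inherits(cfg$pyr_params, "population_selection") ||
      (is.list(cfg$pyr_params) && !inherits(cfg$pyr_params, "cell_params"))) {
    plist <- pyr_param_list(cfg)
    if (length(plist) != new_pyr)
      out$pyr_params <- plist[rep_len(seq_along(plist), new_pyr)]
  }
  out
}

# Expand pyr_params to a list of cell_params of length n_pyr.
pyr_param_list <- function(cfg) {
  pp <- cfg$pyr_params
  if (inherits(pp, "cell_params")) return(rep(list(pp), cfg$n_pyr))
  if (inherits(pp, "population_selection")) pp <- pp$params
  stopifnot(is.list(pp), all(vapply(pp, inherits, logical(1), "cell_params")))
  if (length(pp) != cfg$n_pyr)
    stop("heterogeneous pyr_params must supply one cell_params per PYR cell (",
         cfg$n_pyr, ")", call. = FALSE)
  pp
}

#' Simulate a spiking network
#'
#' Integrates all cells (forward Euler, shared `dt`) with their synaptic
#' conductances and noisy drive. Spikes are delivered to targets with a
#' one-step delay; each spike increments the target conductance by the
#' projection weight, and conductances decay exponentially. The wiring and
#' every noise sample are drawn from the config seed, so identical configs
#' give bit-identical rasters.
#'
#' @param cfg a `network_config`.
#' @return An object of class `spike_raster`: list with `spikes` (a
#'   data.frame `population`, `cell_id`, `spike_time_ms`), `n_cells`
#'   (named counts), `duration`, and `meta` (seed and realized edge
#'   counts).
#' @export
simulate_network <- function(cfg) {
  validate_network_config(cfg)
  set.seed(cfg$seed)
  conn <- build_connectivity(cfg)
  n <- cfg$n_pyr + cfg$n_pv
  par_list <- c(pyr_param_list(cfg), rep(list(cfg$pv_params), cfg$n_pv))
  par_mat <- do.call(rbind, lapply(par_list, as.numeric))
  # global 0-based adjacency: targets per presynaptic cell
  adj <- vector("list", n)
  add_edges <- function(adj, from, to, pre_off, post_off) {
    if (length(from)) {
      gl_from <- from + pre_off
      gl_to <- to + post_off - 1L # to 0-based
      sp <- split(gl_to, gl_from)
      for (nm in names(sp)) {
        i <- as.integer(nm)
        adj[[i]] <- c(adj[[i]], sp[[nm]])
      }
    }
    adj
  }
  adj <- add_edges(adj, conn$ee$from, conn$ee$to, 0L, 0L)
  adj <- add_edges(adj, conn$ei$from, conn$ei$to, 0L, cfg$n_pyr)
  adj <- add_edges(adj, conn$ie$from, conn$ie$to, cfg$n_pyr, 0L)
  adj <- add_edges(adj, conn$ii$from, conn$ii$to, cfg$n_pyr, cfg$n_pyr)
  adj <- lapply(adj, function(x) as.integer(x %||% integer(0)))
  syn <- cfg$syn
  res <- simulate_network_cpp(
    par_mat, cfg$n_pyr, adj,
    vapply(syn[c("ee", "ei", "ie", "ii")], `[[`, numeric(1), "weight"),
    vapply(syn[c("ee", "ei", "ie", "ii")], `[[`, numeric(1), "tau_decay"),
    vapply(syn[c("ee", "ei", "ie", "ii")], `[[`, numeric(1), "E_rev"),
    c(cfg$drive$pyr$mean, cfg$drive$pv$mean),
    c(cfg$drive$pyr$amplitude, cfg$drive$pv$amplitude) / 4,
    cfg$duration, cfg$dt, cfg$noise_dt, cfg$noise == "ou", cfg$ou_tau)
  cell <- res$spike_cell
  is_pyr <- cell < cfg$n_pyr
  spikes <- data.frame(
    population = ifelse(is_pyr, "PYR", "PV"),
    cell_id = ifelse(is_pyr, cell + 1L, cell - cfg$n_pyr + 1L),
    spike_time_ms = res$spike_time)
  new_spike_raster(spikes,
                   n_cells = c(PYR = cfg$n_pyr, PV = cfg$n_pv),
                   duration = cfg$duration,
                   meta = list(seed = cfg$seed,
                               edge_counts = as.list(conn$counts)))
}

#' Construct a spike raster
#'
#' @param spikes data.frame with columns `population`, `cell_id`,
#'   `spike_time_ms`.
#' @param n_cells named integer vector of cell counts per population.
#' @param duration recording duration (ms).
#' @param meta optional metadata list.
#' @return An object of class `spike_raster`.
#' @export
new_spike_raster <- function(spikes, n_cells, duration, meta = list()) {
  stopifnot(is.data.frame(spikes),
            all(c("population", "cell_id", "spike_time_ms") %in% names(spikes)))
  if (nrow(spikes) && (any(spikes$spike_time_ms < 0) ||
                       any(spikes$spike_time_ms > duration)))
    stop("spike times must lie in [0, duration]", call. = FALSE)
  structure(list(spikes = spikes, n_cells = n_cells, duration = duration,
                 meta = meta),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cnt <- table(factor(x$spikes$population, levels = names(x$n_cells)))
  cat(sprintf("spike_raster: %.0f ms, %s\n", x$duration,
              paste(sprintf("%s %d cells / %d spikes", names(x$n_cells),
                            x$n_cells, as.integer(cnt)), collapse = "; ")))
  invisible(x)
}

#' Export a raster and its run metadata
#'
#' `write_raster_csv()` writes the spike table (`population, cell_id,
#' spike_time_ms`); `write_run_metadata()` writes a JSON record with the
#' seed, realized edge counts and package version.
#'
#' @param raster a `spike_raster`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  utils::write.csv(raster$spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
write_run_metadata <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  meta <- c(raster$meta,
            list(n_cells = as.list(raster$n_cells),
                 duration_ms = raster$duration,
                 version = as.character(utils::packageVersion("ca1theta"))))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
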