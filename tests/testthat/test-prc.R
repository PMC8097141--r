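test_that("a zero-amplitude pulse yields an exactly zero PRC", {
  prc <- compute_prc(pyr_default_params(), I_tonic = 20, pulse_amp = 0,
                     n_phases = 25)
  expect_identical(unique(prc$shifts), 0)
  expect_identical(prc$phases, (1:25) / 25)
})

test_that("inhibitory pulses delay mid-to-late phases; shifts match a trace oracle", {
  p <- pyr_default_params()
  prc <- compute_prc(p, I_tonic = 20)
  # the rebound-capable default cell shows an early-phase advance region,
  # but from mid-cycle onwards the inhibitory pulse delays the next spike
  expect_true(all(prc$shifts[prc$phases >= 0.4] <= 0))
  expect_lt(min(prc$shifts), 0)
  # trace-differencing oracle at a few phases: re-simulate, detect spikes
  # from the reset discontinuity in the stored voltage, and rebuild the
  # perturbed period independently of the spike recorder
  base <- intrinsic_period(p, 20, n_spikes = 11)
  t10 <- base$spike_times[10]
  lam_ref <- base$spike_times[11] - t10
  for (i in c(10, 30, 50)) {
    t_pulse <- t10 + i * (prc$lam / 100)
    tr <- integrate_cell(p, current_protocol(
      c(t_pulse, 1, 4 * prc$lam), c(20, 20 - 500, 20)))
    drops <- which(diff(tr$V) < -(p[["v_peak"]] - p[["c"]]) / 2)
    sp <- tr$times[drops + 1]
    lam_p <- sp[11] - sp[10]
    expect_equal(prc$shifts[i], (lam_ref - lam_p) / lam_ref,
                 tolerance = 1e-10)
  }
})

test_that("a depolarizing mid-phase pulse advances the next spike", {
  prc <- compute_prc(pyr_default_params(), I_tonic = 20, pulse_amp = 500,
                     n_phases = 10)
  expect_gte(prc$shifts[5], 0)
})

test_that("intrinsic frequency is non-decreasing over the 20:2:30 pA sweep", {
  freqs <- vapply(seq(20, 30, by = 2), function(I)
    intrinsic_period(pyr_default_params(), I)$frequency, numeric(1))
  expect_true(all(diff(freqs) >= 0))
})

test_that("shifts are invariant to the phase evaluation order", {
  p <- pyr_default_params()
  prc5 <- compute_prc(p, I_tonic = 20, n_phases = 5)
  prc10 <- compute_prc(p, I_tonic = 20, n_phases = 10)
  # shared phases i/5 = 2i/10 receive the pulse at identical times and
  # must agree bitwise, each phase being an independent run
  expect_identical(prc5$shifts, prc10$shifts[c(2, 4, 6, 8, 10)])
})

test_that("non-oscillating cells are reported as such", {
  expect_error(intrinsic_period(pyr_default_params(), -10, max_ms = 10000),
               "repetitively")
})

test_that("mean PRC matches brute-force recomputation and its edge cases", {
  p1 <- pyr_default_params()
  p2 <- cell_params(d = 8)
  prcs <- list(compute_prc(p1, 20, n_phases = 20),
               compute_prc(p2, 20, n_phases = 20))
  mp <- mean_prc(prcs)
  stacked <- rbind(prcs[[1]]$shifts, prcs[[2]]$shifts)
  expect_equal(mp$mean, colMeans(stacked))
  expect_equal(mp$sd, apply(stacked, 2, stats::sd))
  # single-member population: mean is the curve itself, SD is zero
  m1 <- mean_prc(prcs[1])
  expect_identical(m1$mean, prcs[[1]]$shifts)
  expect_identical(unique(m1$sd), 0)
  # mirror-image pair averages to exactly zero
  mirror <- prcs[[1]]
  mirror$shifts <- -mirror$shifts
  m0 <- mean_prc(list(prcs[[1]], mirror))
  expect_identical(unique(m0$mean), 0)
  # mixed tonic currents are rejected
  other <- prcs[[2]]
  other$I_tonic <- 22
  expect_error(mean_prc(list(prcs[[1]], other)), "tonic")
})

test_that("PRC features vanish for constant and linear mean PRCs", {
  fake <- function(vals) structure(
    list(phases = (1:100) / 100, mean = vals, sd = rep(0, 100), n = 1,
         I_tonic = 20),
    class = "mean_prc")
  expect_identical(extract_prc_features(fake(rep(0.2, 100)))$deriv_variance, 0)
  lin <- extract_prc_features(fake(0.3 * (1:100) / 100 - 0.1))
  expect_equal(lin$deriv_variance, 0, tolerance = 1e-20)
  expect_equal(lin$shift_at_0p3, 0.3 * 0.3 - 0.1)
})

test_that("derivative variance equals an independent two-pass computation", {
  set.seed(8)
  vals <- stats::rnorm(100, sd = 0.05)
  m <- structure(list(phases = (1:100) / 100, mean = vals,
                      sd = rep(0, 100), n = 1, I_tonic = 20),
                 class = "mean_prc")
  feat <- extract_prc_features(m)
  dq <- (vals[-1] - vals[-100]) / (1 / 100)
  expect_length(dq, 99)
  mu <- sum(dq) / 99
  two_pass <- sum((dq - mu)^2) / 98
  expect_equal(feat$deriv_variance, two_pass)
  # grids lacking phase 0.3 are rejected
  m$phases <- m$phases + 0.001
  expect_error(extract_prc_features(m), "0.3")
})

test_that("population study rows compose the per-model operations", {
  pops <- list(one = list(pyr_default_params()),
               two = list(pyr_default_params(), cell_params(d = 8)))
  tab <- prc_population_study(pops, currents = c(20, 26), n_phases = 20)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$n_models, c(1L, 1L, 2L, 2L))
  # composition oracle for one row
  prcs <- lapply(pops$two, compute_prc, I_tonic = 26, n_phases = 20)
  feat <- extract_prc_features(mean_prc(prcs))
  row <- tab[tab$population == "two" & tab$I_tonic_pA == 26, ]
  expect_equal(row$shift_at_0p3, feat$shift_at_0p3)
  expect_equal(row$deriv_variance, feat$deriv_variance)
  expect_equal(row$mean_freq_Hz,
               mean(vapply(prcs, `[[`, numeric(1), "intrinsic_frequency")))
  # frequencies rise with current within each population
  for (pop in unique(tab$population)) {
    f <- tab$mean_freq_Hz[tab$population == pop]
    expect_true(all(diff(f) > 0))
  }
})

test_that("PRC CSV exports round-trip", {
  prc <- compute_prc(pyr_default_params(), 20, n_phases = 20)
  mp <- mean_prc(list(prc))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_prc_csv(prc, f1)
  write_mean_prc_csv(mp, f2)
  expect_equal(utils::read.csv(f1)$shift, prc$shifts)
  expect_equal(utils::read.csv(f2)$mean, mp$mean)
})
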