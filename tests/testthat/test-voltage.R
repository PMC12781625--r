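test_that("trace construction enforces uniform increasing time", {
  expect_error(as_trace(c(0, 1, 1), c(1, 1, 1)), "strictly increasing")
  expect_error(as_trace(c(0, 1, 3), c(1, 1, 1)), "uniformly spaced")
  expect_error(as_trace(0:2, c(1, NA, 1)), "finite")
  tr <- as_trace(seq(0, 10, 0.1), rep(1, 101))
  expect_equal(attr(tr, "frame_dt"), 0.1, tolerance = 1e-9)
})

test_that("bleach correction flattens exponential decay and leaves constants alone", {
  t <- seq(0, 100, 0.1)
  const <- as_trace(t, rep(5, length(t)))
  cc <- suppressWarnings(correct_bleach(const))
  expect_lt(max(abs(cc$I - 5)) / 5, 0.001)

  dec <- as_trace(t, 3 * exp(-t / 40) + 1)
  cd <- correct_bleach(dec)
  expect_lt((max(cd$I) - min(cd$I)) / cd$I[1], 0.001)
  expect_equal(attr(cd, "bleach_tau_s"), 40, tolerance = 0.01)

  expect_error(correct_bleach(as_trace(seq(0, 4, 0.1), rep(1, 41))), "50 frames")
})

test_that("bleach correction equalizes cycle amplitudes of a modulated trace", {
  tv <- simulate_voltage_trace(duration_s = 300, bleach_tau_s = 300,
                               noise_sd = 0, seed = 1)
  cb <- correct_bleach(tv)
  norm <- bin_and_filter(cb)
  ex <- detect_extrema(norm)
  amps <- norm$I[ex$maxima[-1]] - norm$I[ex$minima]
  expect_lt(diff(range(amps)) / mean(amps), 0.05)
})

test_that("binning and filtering honor the passband contract", {
  t <- seq(0, 299.94, 0.06)
  dc <- as_trace(t, rep(3, length(t)))
  ndc <- bin_and_filter(dc)
  expect_equal(ndc$I, rep(1, length(ndc$I)), tolerance = 1e-9)
  expect_equal(attr(ndc, "frame_dt"), 0.6, tolerance = 1e-9)
  expect_equal(attr(ndc, "stage"), "normalized")

  # gains measured on the binned sampling grid (600 ms)
  fs <- 1 / 0.6
  tb <- seq(0, 1200, 0.6)
  gain <- function(f) {
    x <- sin(2 * pi * f * tb)
    y <- proteodyn:::lowpass_trace(x, fs, 0.05)
    core <- 200:(length(tb) - 200)
    stats::sd(y[core]) / stats::sd(x[core])
  }
  expect_gt(gain(1 / 60), 0.9)                  # < 10% loss in the passband
  expect_lt(20 * log10(gain(0.5)), -30)         # >= 30 dB in the stopband
  expect_lt(20 * log10(gain(0.12)), -30)

  expect_error(bin_and_filter(as_trace(seq(0, 4.9, 0.1), rep(1, 50))), "too short")
})

test_that("filtering is near-idempotent", {
  set.seed(31)
  tb <- seq(0, 600, 0.6)
  x <- sin(2 * pi * tb / 60) + stats::rnorm(length(tb), 0, 0.1)
  once <- proteodyn:::lowpass_trace(x, 1 / 0.6, 0.05)
  twice <- proteodyn:::lowpass_trace(once, 1 / 0.6, 0.05)
  expect_lt(sqrt(mean((twice - once)^2)) / stats::sd(once), 0.01)
})

test_that("extrema detection applies prominence and separation rules", {
  t <- seq(0, 299.4, 0.6)
  ramp <- as_trace(t, seq(0.5, 1, length.out = length(t)), stage = "normalized")
  ex <- detect_extrema(ramp)
  expect_equal(length(ex$maxima), 0)
  expect_equal(length(ex$minima), 0)

  # 2% ripple is rejected by the 3% prominence rule
  ripple <- as_trace(t, 0.98 + 0.01 * sin(2 * pi * t / 60), stage = "normalized")
  expect_equal(length(detect_extrema(ripple)$maxima), 0)

  # 10% modulation is kept, with ~100-frame spacing
  wave <- as_trace(t, 0.9 + 0.1 * sin(2 * pi * t / 60), stage = "normalized")
  exw <- detect_extrema(wave)
  expect_gte(length(exw$maxima), 4)
  expect_equal(mean(diff(exw$maxima)), 100, tolerance = 0.02)

  # peaks closer than the minimum distance are merged (highest kept)
  y <- rep(0.5, 500); y[c(100, 120)] <- c(0.9, 0.95)
  close_peaks <- as_trace(t, y, stage = "normalized")
  expect_equal(detect_extrema(close_peaks)$maxima, 120)
})

test_that("intensity rate follows the three documented branches", {
  t <- seq(0, 99.4, 0.6)
  # no extrema: whole-trace branch on a linear ramp 0 -> 1 over ~100 s
  ramp <- as_trace(t, seq(0, 1, length.out = length(t)), stage = "normalized")
  exr <- detect_extrema(ramp)
  r <- intensity_rate(ramp, exr)
  expect_equal(attr(r, "branch"), "whole_trace")
  expect_equal(as.numeric(r), 1 / max(t), tolerance = 1e-6)

  # first-minimum-to-closest-maximum arithmetic
  t2 <- seq(0, 120, 0.6)
  y2 <- 0.5 - 0.3 * cos(2 * pi * t2 / 60)   # maxima at 30/90, interior min at 60
  tr2 <- as_trace(t2, y2 / max(y2), stage = "normalized")
  ex2 <- detect_extrema(tr2, min_distance = 20)
  r2 <- intensity_rate(tr2, ex2)
  expect_equal(attr(r2, "branch"), "first_min_to_closest_max")
  expect_equal(as.numeric(r2), (max(tr2$I) - min(tr2$I)) /
                 abs(tr2$t[ex2$maxima[1]] - tr2$t[ex2$minima[1]]),
               tolerance = 1e-9)

  # single extremum: to the global opposite extremum
  y3 <- c(seq(0.2, 1, length.out = 50), seq(1, 0.6, length.out = 51)[-1])
  tr3 <- as_trace(seq(0, 59.4, 0.6), y3, stage = "normalized")
  ex3 <- detect_extrema(tr3, min_distance = 10)
  expect_equal(length(ex3$maxima), 1)
  expect_equal(length(ex3$minima), 0)
  r3 <- intensity_rate(tr3, ex3)
  expect_equal(attr(r3, "branch"), "single_extremum_to_global_opposite")
  expect_gt(as.numeric(r3), 0)

  # constant trace: rate 0
  flat <- as_trace(t, rep(1, length(t)), stage = "normalized")
  expect_equal(as.numeric(intensity_rate(flat, detect_extrema(flat))), 0)
})

test_that("the full pipeline recovers period and rate of a responsive trace", {
  tv <- simulate_voltage_trace(duration_s = 300, step_period_s = 30,
                               response_amplitude = 0.2, bleach_tau_s = 300,
                               noise_sd = 0.02, seed = 8)
  res <- voltage_response(tv)
  spacing <- c(diff(res$extrema$maxima), diff(res$extrema$minima))
  expect_lte(abs(stats::median(spacing) - 100), 1)
  expect_lt(abs(res$rate - 0.2 / 30) / (0.2 / 30), 0.15)
  expect_equal(res$branch, "first_min_to_closest_max")
})

test_that("a non-responsive bleaching trace yields a near-zero rate", {
  tf <- simulate_voltage_trace(response_amplitude = 0, bleach_tau_s = 300,
                               noise_sd = 0.02, seed = 9)
  res <- voltage_response(tf)
  expect_lt(abs(res$rate), 0.005)
})

test_that("simulated trace degenerate limits are exact", {
  pure <- simulate_voltage_trace(response_amplitude = 0, noise_sd = 0,
                                 bleach_tau_s = 100, seed = 1)
  expect_equal(pure$I, exp(-pure$t / 100), tolerance = 1e-12)

  periodic <- simulate_voltage_trace(bleach_tau_s = Inf, noise_sd = 0, seed = 1)
  truth <- attr(periodic, "truth")
  expect_equal(truth$period_s, 60)
  # noiseless, bleach-free: extrema of the raw response sit at the switches
  raw_max <- periodic$t[which(diff(sign(diff(periodic$I))) == -2) + 1]
  expect_true(all(abs((raw_max + 1e-9) %% 60 - 30) < 1))
})
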