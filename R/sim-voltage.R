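#' Simulate a voltage-step-modulated, bleaching fluorescence trace
#'
#' Produces the raw per-cell ROI trace the voltage-response pipeline consumes:
#' a square-wave membrane-potential protocol (alternating +/- levels, each
#' held for `step_period_s`) drives a fractional fluorescence response that
#' relaxes toward its level with time constant `edge_tau_s` (shaping the step
#' edges), the whole signal decays exponentially with photobleaching time
#' constant `bleach_tau_s`, and i.i.d. Gaussian noise is added.
#'
#' Ground truth stored with the trace: the noiseless bleach-free response, the
#' switch times (where the un-filtered response is extremal), and the full
#' oscillation period `2 * step_period_s`.
#'
#' @param duration_s total trace duration, s.
#' @param frame_dt_s camera frame interval, s (60 ms default).
#' @param step_period_s time spent at each voltage level, s (30 s default, so
#'   the full oscillation period is 60 s).
#' @param response_amplitude peak-to-peak fractional intensity modulation.
#' @param bleach_tau_s photobleaching time constant, s (`Inf` for none).
#' @param noise_sd additive Gaussian noise SD (baseline intensity is 1).
#' @param edge_tau_s response relaxation time constant, s. The default (4 s)
#'   lets the full modulation develop within each 30 s step while still
#'   shaping the step edges over several binned frames, as per-cell
#'   fluorescence responses to potential steps do.
#' @param seed integer seed.
#' @return an `intensity_trace` (see [as_trace()]) with attribute `truth`
#'   (list: `response`, `switch_times_s`, `period_s`, `amplitude`).
#' @export
simulate_voltage_trace <- function(duration_s = 300, frame_dt_s = 0.06,
                                   step_period_s = 30,
                                   response_amplitude = 0.2,
                                   bleach_tau_s = 300, noise_sd = 0.02,
                                   edge_tau_s = 4, seed = 1L) {
  if (step_period_s <= frame_dt_s) stop("step_period_s must exceed frame_dt_s")
  set.seed(as.integer(seed))
  t <- seq(0, duration_s - frame_dt_s, by = frame_dt_s)
  n <- length(t)
  drive <- ifelse((t %/% step_period_s) %% 2 == 0, 1, -1)
  half <- response_amplitude / 2
  r <- numeric(n)
  r[1] <- 0   # response starts at baseline when the protocol begins
  a <- 1 - exp(-frame_dt_s / edge_tau_s)
  for (i in 2:n) r[i] <- r[i - 1] + (half * drive[i] - r[i - 1]) * a
  bleach <- if (is.finite(bleach_tau_s)) exp(-t / bleach_tau_s) else rep(1, n)
  I <- (1 + r) * bleach + stats::rnorm(n, 0, noise_sd)
  switch_times <- seq(step_period_s, duration_s, by = step_period_s)
  tr <- as_trace(t, I, frame_dt = frame_dt_s, stage = "raw")
  attr(tr, "truth") <- list(response = r, switch_times_s = switch_times,
                            period_s = 2 * step_period_s,
                            amplitude = response_amplitude)
  tr
}
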