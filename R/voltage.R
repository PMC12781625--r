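#' Intensity traces
#'
#' A per-cell ROI fluorescence time series with uniform sampling. The `stage`
#' attribute records where the trace sits in the fixed processing order
#' raw -> bleach_corrected -> binned -> filtered -> normalized.
#'
#' @param t time, s (strictly increasing, uniform).
#' @param I intensity values.
#' @param frame_dt sampling interval, s (inferred from `t` if missing).
#' @param stage processing-stage tag.
#' @return data frame of class `"intensity_trace"` with columns `t`, `I`.
#' @export
as_trace <- function(t, I, frame_dt = NULL, stage = "raw") {
  if (length(t) != length(I)) stop("t and I must have equal length")
  if (any(!is.finite(I))) stop("intensities must be finite")
  d <- diff(t)
  if (any(d <= 0)) stop("t must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d)) stop("t must be uniformly spaced")
  if (is.null(frame_dt)) frame_dt <- mean(d)
  structure(data.frame(t = t, I = I), frame_dt = frame_dt, stage = stage,
            class = c("intensity_trace", "data.frame"))
}

#' Photobleaching correction by mono-exponential ratio
#'
#' Fits `I(t) = a exp(-t / tau_b) + c` to the whole trace and rescales by the
#' fitted decay, `I_corr(t) = I(t) * fit(0) / fit(t)`, flattening the bleach
#' envelope while preserving relative modulation. The fit minimizes relative
#' (not absolute) residuals, since bleaching acts multiplicatively on the
#' signal; this keeps the fitted envelope faithful late in the trace where
#' the absolute signal is small. If the fit does not converge or finds a
#' non-positive time constant the trace is returned unchanged with a warning.
#'
#' @param trace an [as_trace()] object (at least 50 frames).
#' @return bleach-corrected `intensity_trace` (stage `"bleach_corrected"`)
#'   with attribute `bleach_tau_s`.
#' @export
correct_bleach <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (nrow(trace) < 50) stop("bleach correction needs at least 50 frames")
  t <- trace$t; I <- trace$I
  rng <- max(I) - min(I)
  st <- list(a = max(rng, 1e-6), tau = max(t) / 2, c = min(I))
  w <- 1 / pmax(abs(I), 1e-6 * max(abs(I), 1e-12))^2
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(I ~ a * exp(-t / tau) + c, start = st, weights = w,
                        lower = c(a = 0, tau = 1e-6, c = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("bleach fit did not converge; trace returned unchanged")
    return(trace)
  }
  p <- stats::coef(fit)
  if (p[["tau"]] <= 0) {
    warning("non-positive bleach time constant; trace returned unchanged")
    return(trace)
  }
  f0 <- p[["a"]] + p[["c"]]
  ft <- p[["a"]] * exp(-t / p[["tau"]]) + p[["c"]]
  out <- as_trace(t, I * f0 / ft, frame_dt = attr(trace, "frame_dt"),
                  stage = "bleach_corrected")
  attr(out, "bleach_tau_s") <- p[["tau"]]
  out
}

# zero-phase Butterworth low-pass honoring the passband/stopband contract:
# order 3 at the 0.05 Hz cutoff, applied forward-backward, gives < 1 dB loss
# below 0.017 Hz and > 30 dB attenuation above 0.1 Hz at the 600 ms binned rate
lowpass_trace <- function(I, fs, passband_hz, order = 3) {
  wc <- passband_hz / (fs / 2)
  if (wc >= 1) return(I)
  bf <- signal::butter(order, wc, type = "low")
  # odd-reflection padding suppresses the forward-backward start-up transient,
  # which for this narrow band spans ~1/passband of samples
  n <- length(I)
  m <- mean(I)   # filter the demeaned signal so DC passes exactly
  x <- I - m
  pad <- min(n - 1, ceiling(3 / wc))
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  out <- as.numeric(signal::filtfilt(bf, ext))
  out[(pad + 1):(pad + n)] + m
}

#' Bin, low-pass filter and normalize an intensity trace
#'
#' Non-overlapping mean binning by `bin_factor` (10x, turning 60 ms frames
#' into 600 ms), zero-phase low-pass filtering at `passband_hz`, then
#' normalization to the trace maximum (nFI, maximum = 1).
#'
#' @param trace an [as_trace()] object (typically bleach-corrected).
#' @param bin_factor temporal binning factor.
#' @param passband_hz low-pass passband edge, Hz.
#' @return normalized `intensity_trace` (stage `"normalized"`).
#' @export
bin_and_filter <- function(trace, bin_factor = 10, passband_hz = 0.05) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- nrow(trace)
  if (n < 10 * bin_factor) stop("trace too short for ", bin_factor, "-fold binning")
  nb <- n %/% bin_factor
  idx <- rep(seq_len(nb), each = bin_factor)
  tb <- tapply(trace$t[seq_len(nb * bin_factor)], idx, mean)
  Ib <- tapply(trace$I[seq_len(nb * bin_factor)], idx, mean)
  fs <- 1 / (attr(trace, "frame_dt") * bin_factor)
  If <- lowpass_trace(as.numeric(Ib), fs, passband_hz)
  as_trace(as.numeric(tb), If / max(If), frame_dt = 1 / fs, stage = "normalized")
}

# topographic prominence of the local maxima of x (findpeaks-style):
# height above the higher of the two lowest contours separating the peak
# from higher terrain (or the trace ends)
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- if (i > 1) {
      seg <- x[(i - 1):1]
      stop_at <- which(seg > h)[1]
      min(seg[seq_len(if (is.na(stop_at)) length(seg) else stop_at)])
    } else h
    right <- if (i < length(x)) {
      seg <- x[(i + 1):length(x)]
      stop_at <- which(seg > h)[1]
      min(seg[seq_len(if (is.na(stop_at)) length(seg) else stop_at)])
    } else h
    h - max(left, right)
  }, numeric(1))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

find_peaks <- function(x, min_prominence, min_distance) {
  idx <- local_maxima(x)
  if (!length(idx)) return(integer(0))
  prom <- peak_prominence(x, idx)
  idx <- idx[prom >= min_prominence]
  if (length(idx) < 2) return(idx)
  # enforce minimum separation, keeping higher peaks first
  ord <- idx[order(x[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) if (!length(kept) || all(abs(kept - i) >= min_distance)) kept <- c(kept, i)
  sort(kept)
}

#' Detect trace extrema by prominence
#'
#' Maxima of the normalized trace and of its negative, each required to have
#' topographic prominence of at least `prominence` (3% of the normalized
#' scale by default) and pairwise separation of at least `min_distance`
#' frames (50 by default).
#'
#' @param trace a normalized `intensity_trace`.
#' @param prominence minimum prominence in normalized units.
#' @param min_distance minimum separation in (binned) frames.
#' @return list of class `"extrema_set"`: `maxima`, `minima` (indices),
#'   `t_max`, `t_min` (s).
#' @export
detect_extrema <- function(trace, prominence = 0.03, min_distance = 50) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (!identical(attr(trace, "stage"), "normalized"))
    warning("extrema detection expects a normalized trace")
  mx <- find_peaks(trace$I, prominence, min_distance)
  mn <- find_peaks(-trace$I, prominence, min_distance)
  structure(list(maxima = mx, minima = mn,
                 t_max = trace$t[mx], t_min = trace$t[mn],
                 prominence = prominence, min_distance = min_distance),
            class = "extrema_set")
}

#' Intensity-rate of a normalized trace
#'
#' Branches exactly as specified for the per-cell response rate, in
#' normalized fluorescence units per second (nFI/s):
#' with at least one detected minimum and one maximum, the intensity increase
#' from the first minimum to the maximum closest to it in time, over their
#' separation; with a single detected extremum, from that extremum to the
#' trace's global opposite extremum; with none, from the global minimum to
#' the global maximum of the whole trace over their time separation. The sign
#' of the intensity change is preserved.
#'
#' @param trace a normalized `intensity_trace`.
#' @param extrema a [detect_extrema()] result for `trace`.
#' @return scalar rate, nFI/s; 0 for a constant trace. Attribute `branch`
#'   records which rule applied.
#' @export
intensity_rate <- function(trace, extrema) {
  I <- trace$I; t <- trace$t
  n_mx <- length(extrema$maxima); n_mn <- length(extrema$minima)
  rate_between <- function(i_from, i_to) {
    dtm <- abs(t[i_to] - t[i_from])
    if (dtm == 0) return(0)
    (I[i_to] - I[i_from]) / dtm
  }
  if (n_mn >= 1 && n_mx >= 1) {
    i_min <- extrema$minima[1]
    i_max <- extrema$maxima[which.min(abs(t[extrema$maxima] - t[i_min]))]
    r <- rate_between(i_min, i_max)
    branch <- "first_min_to_closest_max"
  } else if (n_mn + n_mx == 1) {
    if (n_mx == 1) {
      r <- rate_between(which.min(I), extrema$maxima[1])
    } else {
      r <- rate_between(extrema$minima[1], which.max(I))
    }
    branch <- "single_extremum_to_global_opposite"
  } else {
    r <- rate_between(which.min(I), which.max(I))
    branch <- "whole_trace"
  }
  structure(r, branch = branch)
}

#' Run the full voltage-response trace pipeline
#'
#' Fixed stage order: bleach correction, 10x temporal binning, zero-phase
#' 0.05 Hz low-pass, normalization to maximum, prominence-based extrema
#' detection, intensity-rate extraction.
#'
#' @param trace a raw `intensity_trace`.
#' @param bin_factor,passband_hz see [bin_and_filter()].
#' @param prominence,min_distance see [detect_extrema()].
#' @return object of class `"voltage_result"`: `rate` (nFI/s), `branch`,
#'   `extrema`, staged traces (`corrected`, `normalized`),
#'   `bleach_tau_s`.
#' @export
voltage_response <- function(trace, bin_factor = 10, passband_hz = 0.05,
                             prominence = 0.03, min_distance = 50) {
  corrected <- correct_bleach(trace)
  norm <- bin_and_filter(corrected, bin_factor, passband_hz)
  ex <- detect_extrema(norm, prominence, min_distance)
  r <- intensity_rate(norm, ex)
  structure(list(rate = as.numeric(r), branch = attr(r, "branch"),
                 extrema = ex, corrected = corrected, normalized = norm,
                 bleach_tau_s = attr(corrected, "bleach_tau_s")),
            class = "voltage_result")
}

#' @export
print.voltage_result <- function(x, ...) {
  cat(sprintf("voltage-response analysis: rate %.5f nFI/s (%s branch)\n",
              x$rate, x$branch))
  cat(sprintf("  %d maxima, %d minima detected\n",
              length(x$extrema$maxima), length(x$extrema$minima)))
  invisible(x)
}
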