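#' Tracking parameters
#'
#' Defaults follow the single-molecule tracking recipe this package
#' implements: a 1-5 pixel bandpass, local maxima above 4 background SDs,
#' spots with effective radius under 8 px, links of at most 6 px per frame and
#' retention of tracks longer than 6 frames (at least 7 points).
#'
#' @param bandpass_low_px,bandpass_high_px difference-of-Gaussians scales, px.
#' @param snr_k detection threshold in robust background SDs.
#' @param max_radius_px spots at or above this fitted radius are not linked.
#' @param max_jump_px maximum frame-to-frame displacement, px.
#' @param min_track_frames minimum retained track length in points.
#' @param fit_window_px side of the square sub-pixel fit window (odd).
#' @return list of class `"tracking_params"`.
#' @export
tracking_params <- function(bandpass_low_px = 1, bandpass_high_px = 5,
                            snr_k = 4, max_radius_px = 8, max_jump_px = 6,
                            min_track_frames = 7, fit_window_px = 7) {
  if (bandpass_low_px >= bandpass_high_px) stop("bandpass: low must be < high")
  if (max_jump_px <= 0) stop("max_jump_px must be positive")
  if (min_track_frames < 2) stop("min_track_frames must be >= 2")
  if (fit_window_px %% 2 != 1) stop("fit_window_px must be odd")
  structure(list(bandpass_low_px = bandpass_low_px,
                 bandpass_high_px = bandpass_high_px, snr_k = snr_k,
                 max_radius_px = max_radius_px, max_jump_px = max_jump_px,
                 min_track_frames = min_track_frames,
                 fit_window_px = fit_window_px),
            class = "tracking_params")
}

#' Difference-of-Gaussians bandpass filter
#'
#' Suppresses the flat background and structures larger than `high_px` while
#' keeping spot-scale features: the frame blurred at `low_px` minus the frame
#' blurred at `high_px`, clipped at zero.
#'
#' @param frame 2-D numeric matrix.
#' @param low_px,high_px Gaussian SDs of the band edges, px.
#' @return filtered matrix of the same size, non-negative.
#' @export
bandpass_filter <- function(frame, low_px = 1, high_px = 5) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  if (low_px >= high_px) stop("low_px must be < high_px")
  if (min(dim(frame)) < 2 * high_px + 1) stop("frame too small for the bandpass scales")
  # replicate boundary: circular convolution would wrap intensity across
  # opposite edges and seed artifactual maxima along the border
  lo <- EBImage::gblur(frame, sigma = low_px, boundary = "replicate")
  hi <- EBImage::gblur(frame, sigma = high_px, boundary = "replicate")
  pmax(lo - hi, 0)
}

#' Detect candidate spots as thresholded local maxima
#'
#' Operates on a bandpassed frame: 8-connected local maxima whose value
#' exceeds the robust background (median) by `snr_k` robust SDs
#' (1.4826 x MAD).
#'
#' @param frame bandpassed 2-D matrix.
#' @param params a [tracking_params()].
#' @return data frame `x`, `y` (0-based integer pixel coordinates), `value`;
#'   empty for an empty frame.
#' @export
detect_spots <- function(frame, params = tracking_params()) {
  ny <- nrow(frame); nx <- ncol(frame)
  bg <- stats::median(frame)
  s <- stats::mad(frame)
  # bandpassed frames are clipped at zero, which deflates the MAD; the upper
  # quartile of centred noise still estimates sigma (Q3 = 0.6745 sigma)
  s <- max(s, (stats::quantile(frame, 0.75, names = FALSE) - bg) / 0.6745)
  thr <- bg + params$snr_k * s
  empty <- data.frame(x = integer(0), y = integer(0), value = numeric(0))
  # vectorized 8-connected local-maximum test via shifted copies
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- frame
  is_max <- frame > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & frame >= pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
  }
  # the bandpass response is unreliable within its own support of the border
  margin <- ceiling(params$bandpass_high_px)
  is_max[c(seq_len(margin), ny - seq_len(margin) + 1), ] <- FALSE
  is_max[, c(seq_len(margin), nx - seq_len(margin) + 1)] <- FALSE
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  # collapse plateau ties: keep the first of any pair of adjacent maxima
  ord <- order(frame[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  taken <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!taken[k]) next
    if (k < nrow(cand)) {
      later <- (k + 1):nrow(cand)
      close_by <- abs(cand[later, 1] - cand[k, 1]) <= 1 &
                  abs(cand[later, 2] - cand[k, 2]) <= 1
      taken[later][close_by] <- FALSE
    }
  }
  cand <- cand[taken, , drop = FALSE]
  data.frame(x = cand[, 2] - 1L, y = cand[, 1] - 1L, value = frame[cand])
}

# least-squares symmetric 2-D Gaussian + offset on one window; returns NULL on
# failure so callers can drop the candidate
fit_gaussian_window <- function(win, x_off, y_off) {
  ny <- nrow(win); nx <- ncol(win)
  xs <- rep(seq_len(nx) - 1, each = ny); ys <- rep(seq_len(ny) - 1, nx)
  z <- as.vector(win)
  if (max(z) - min(z) <= 0) return(NULL)
  pk <- which.max(z)
  st <- list(A = max(z) - min(z), x0 = xs[pk], y0 = ys[pk], s = 1.3, c = min(z))
  fit <- tryCatch(
    suppressWarnings(
    minpack.lm::nlsLM(z ~ A * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * s^2)) + c,
                      start = st,
                      lower = c(A = 1e-9, x0 = -1, y0 = -1, s = 0.3, c = -Inf),
                      upper = c(A = Inf, x0 = nx, y0 = ny, s = max(nx, ny), c = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  if (p[["A"]] <= 0 || p[["s"]] <= 0) return(NULL)
  res_sd <- stats::sd(stats::resid(fit))
  list(x = p[["x0"]] + x_off, y = p[["y0"]] + y_off, amplitude = p[["A"]],
       background = p[["c"]], sigma_px = p[["s"]],
       snr = p[["A"]] / max(res_sd, .Machine$double.eps))
}

#' Sub-pixel localization by 2-D Gaussian PSF fitting
#'
#' Fits a symmetric 2-D Gaussian plus constant offset to a square window of
#' the raw frame around each candidate maximum. Failed or degenerate fits are
#' dropped (their count is reported in the `n_dropped` attribute); windows
#' clipped by the frame edge are fitted on the truncated window and flagged.
#'
#' @param frame raw 2-D matrix (not bandpassed).
#' @param candidates data frame from [detect_spots()].
#' @param fit_window_px window side in pixels (odd).
#' @return data frame of detections: `x`, `y` (sub-pixel, 0-based px),
#'   `amplitude`, `background`, `sigma_px`, `radius_px` (= 2 sigma), `snr`,
#'   `edge_clipped`.
#' @export
localize_subpixel <- function(frame, candidates, fit_window_px = 7) {
  half <- (fit_window_px - 1) %/% 2
  ny <- nrow(frame); nx <- ncol(frame)
  out <- vector("list", nrow(candidates))
  dropped <- 0L
  for (k in seq_len(nrow(candidates))) {
    cx <- candidates$x[k]; cy <- candidates$y[k]
    x0 <- max(0, cx - half); x1 <- min(nx - 1, cx + half)
    y0 <- max(0, cy - half); y1 <- min(ny - 1, cy + half)
    clipped <- (x1 - x0 + 1L) < fit_window_px || (y1 - y0 + 1L) < fit_window_px
    win <- frame[(y0:y1) + 1, (x0:x1) + 1, drop = FALSE]
    f <- fit_gaussian_window(win, x0, y0)
    if (is.null(f) || f$x < x0 - 0.5 || f$x > x1 + 0.5 ||
        f$y < y0 - 0.5 || f$y > y1 + 0.5) {
      dropped <- dropped + 1L
      next
    }
    out[[k]] <- data.frame(x = f$x, y = f$y, amplitude = f$amplitude,
                           background = f$background, sigma_px = f$sigma_px,
                           radius_px = 2 * f$sigma_px, snr = f$snr,
                           edge_clipped = clipped)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      background = numeric(0), sigma_px = numeric(0),
                      radius_px = numeric(0), snr = numeric(0),
                      edge_clipped = logical(0))
  attr(res, "n_dropped") <- dropped
  res
}
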