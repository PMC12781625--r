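#' Render trajectories into a synthetic fluorescence movie
#'
#' Each localization is drawn as a pixel-integrated 2-D Gaussian point-spread
#' function (the Gaussian CDF integrated over each pixel), photons are drawn
#' from a Poisson law on signal plus background, and Gaussian read noise is
#' added. Pixel centres sit at integer coordinates, origin at the top-left
#' pixel, 0-based; micrometre track coordinates are converted through the
#' track table's `pixel_size`.
#'
#' @param tracks an [as_tracks()] table (positions in um).
#' @param nx,ny frame size in pixels.
#' @param psf_sigma_px PSF Gaussian sigma in pixels.
#' @param photon_rate expected photons per emitter per frame.
#' @param background expected background photons per pixel per frame.
#' @param read_noise_sd read noise SD in counts.
#' @param n_frames frame count override; defaults to the frames present in
#'   `tracks` (required when `tracks` is empty, giving a pure-noise movie).
#' @param seed integer seed for the noise draws.
#' @return a `movie_stack`: list with `frames` (array `t` x `y` x `x`), `dt`,
#'   `pixel_size` and the generating `tracks` as ground truth.
#' @export
render_movie <- function(tracks, nx = 64, ny = 64, psf_sigma_px = 1.1,
                         photon_rate = 800, background = 100,
                         read_noise_sd = 2, n_frames = NULL, seed = 1L) {
  stopifnot(inherits(tracks, "spt_tracks"))
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be positive")
  px <- attr(tracks, "pixel_size")
  set.seed(as.integer(seed))
  frames_idx <- if (nrow(tracks)) sort(unique(tracks$frame))
                else seq_len(if (is.null(n_frames)) stop("empty track list needs n_frames") else n_frames) - 1L
  nt <- length(frames_idx)
  stack <- array(0, dim = c(nt, ny, nx))
  xs_px <- tracks$x_um / px
  ys_px <- tracks$y_um / px
  outside <- xs_px < 0 | xs_px > (nx - 1) | ys_px < 0 | ys_px > (ny - 1)
  if (any(outside))
    warning(sum(outside), " localizations fall outside the field and are clipped")
  half <- ceiling(4 * psf_sigma_px)
  for (ti in seq_len(nt)) {
    f <- frames_idx[ti]
    sel <- which(tracks$frame == f & !outside)
    img <- matrix(0, ny, nx)
    for (i in sel) {
      x0 <- xs_px[i]; y0 <- ys_px[i]
      cx <- round(x0); cy <- round(y0)
      xr <- max(0, cx - half):min(nx - 1, cx + half)
      yr <- max(0, cy - half):min(ny - 1, cy + half)
      # integral of the unit Gaussian over each pixel [-0.5, 0.5] around centre
      gx <- stats::pnorm(xr + 0.5, x0, psf_sigma_px) - stats::pnorm(xr - 0.5, x0, psf_sigma_px)
      gy <- stats::pnorm(yr + 0.5, y0, psf_sigma_px) - stats::pnorm(yr - 0.5, y0, psf_sigma_px)
      img[yr + 1, xr + 1] <- img[yr + 1, xr + 1] + photon_rate * outer(gy, gx)
    }
    noisy <- matrix(stats::rpois(nx * ny, img + background), ny, nx) +
      matrix(stats::rnorm(nx * ny, 0, read_noise_sd), ny, nx)
    stack[ti, , ] <- pmax(noisy, 0)
  }
  structure(list(frames = stack, frame_index = frames_idx,
                 dt = attr(tracks, "dt"), pixel_size = px,
                 ground_truth = tracks),
            class = "movie_stack")
}

#' Write / read a movie stack as multi-page TIFF
#'
#' Thin wrappers around the `tiff` package; intensities are scaled to
#' `[0, 1]` on write and restored through the stored scale factor on read via
#' a sidecar is not needed because analysis is scale-invariant.
#' @param movie a `movie_stack`.
#' @param path file path.
#' @param dt,pixel_size acquisition metadata attached on read.
#' @return `read_movie` returns a `movie_stack` without ground truth.
#' @export
write_movie <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required")
  mx <- max(movie$frames)
  pages <- lapply(seq_len(dim(movie$frames)[1]),
                  function(i) movie$frames[i, , ] / max(mx, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path, dt = 0.005, pixel_size = 0.107) {
  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nt <- length(pages); ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  stack <- array(0, dim = c(nt, ny, nx))
  for (i in seq_len(nt)) stack[i, , ] <- pages[[i]] * 65535
  structure(list(frames = stack, frame_index = seq_len(nt) - 1L,
                 dt = dt, pixel_size = pixel_size, ground_truth = NULL),
            class = "movie_stack")
}
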