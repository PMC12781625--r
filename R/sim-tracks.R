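#' Specify a synthetic tracking experiment
#'
#' A simulation spec bundles the populations of particles to simulate with the
#' acquisition settings. Each population is a list with a `model`
#' (`"brownian"`, `"confined"` or `"directed"`), a diffusion coefficient `D`
#' in um^2/s, a `fraction` of the total track count, and for confined motion a
#' `cage_radius` (um) or for directed motion a `velocity` (um/s).
#'
#' Defaults mirror the live-cell tracking regime this package targets: 5 ms
#' frames, 107 nm pixels and 25 nm localization noise per coordinate.
#'
#' @param populations list of population descriptors (see Details).
#' @param n_tracks total number of tracks across populations.
#' @param n_frames frames per track.
#' @param dt frame interval, s.
#' @param pixel_size um per pixel.
#' @param noise_sd localization noise SD per coordinate, um.
#' @param field_um side of the square region particles start in, um.
#' @param seed integer seed; identical specs give bit-identical output.
#' @return list of class `"sim_spec"`.
#' @export
sim_spec <- function(populations = list(list(model = "brownian", D = 1, fraction = 1)),
                     n_tracks = 100, n_frames = 50, dt = 0.005,
                     pixel_size = 0.107, noise_sd = 0.025,
                     field_um = 20, seed = 1L) {
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8) stop("population fractions must sum to 1")
  for (p in populations) {
    if (!p$model %in% c("brownian", "confined", "directed"))
      stop("unknown motion model: ", p$model)
    if (is.null(p$D) || p$D < 0) stop("D must be >= 0")
    if (p$model == "confined" && (is.null(p$cage_radius) || p$cage_radius <= 0))
      stop("confined populations need cage_radius > 0")
    if (p$model == "directed" && is.null(p$velocity))
      stop("directed populations need a velocity")
  }
  if (n_frames < 2) stop("n_frames must be at least 2")
  if (dt <= 0 || pixel_size <= 0 || noise_sd < 0) stop("invalid acquisition parameters")
  structure(list(populations = populations, n_tracks = n_tracks,
                 n_frames = n_frames, dt = dt, pixel_size = pixel_size,
                 noise_sd = noise_sd, field_um = field_um,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# one Brownian track: cumulative Gaussian increments, variance 2*D*dt per axis
sim_one_brownian <- function(n, D, dt, x0, y0) {
  s <- sqrt(2 * D * dt)
  list(x = x0 + c(0, cumsum(stats::rnorm(n - 1, 0, s))),
       y = y0 + c(0, cumsum(stats::rnorm(n - 1, 0, s))))
}

# Brownian steps reflected at a circular cage boundary of radius R around
# (cx, cy): a point landing outside is mirrored across the boundary radially.
# The stationary distribution is uniform in the disk, so the long-lag MSD
# plateau is E|dr|^2 = R^2.
sim_one_confined <- function(n, D, dt, R, cx, cy) {
  s <- sqrt(2 * D * dt)
  x <- numeric(n); y <- numeric(n)
  x[1] <- cx; y[1] <- cy
  dxs <- stats::rnorm(n - 1, 0, s); dys <- stats::rnorm(n - 1, 0, s)
  for (i in 2:n) {
    px <- x[i - 1] + dxs[i - 1]; py <- y[i - 1] + dys[i - 1]
    r <- sqrt((px - cx)^2 + (py - cy)^2)
    while (r > R) {
      f <- (2 * R - r) / r   # radial mirror across the boundary
      px <- cx + (px - cx) * f; py <- cy + (py - cy) * f
      r <- abs(2 * R - r)
    }
    x[i] <- px; y[i] <- py
  }
  list(x = x, y = y)
}

sim_one_directed <- function(n, D, dt, v, x0, y0) {
  theta <- stats::runif(1, 0, 2 * pi)   # fixed random direction per track
  t <- (seq_len(n) - 1) * dt
  b <- sim_one_brownian(n, D, dt, 0, 0)
  list(x = x0 + v * t * cos(theta) + b$x, y = y0 + v * t * sin(theta) + b$y)
}

#' Simulate single-particle trajectories with known ground truth
#'
#' `simulate_tracks()` draws trajectories from the populations in a
#' [sim_spec()]: Brownian motion with per-axis increment variance `2*D*dt`,
#' Brownian motion reflected inside a circular cage of radius `cage_radius`,
#' or directed transport at fixed velocity along a random per-track direction
#' superimposed on Brownian motion. Independent Gaussian localization noise of
#' SD `noise_sd` is then added to every coordinate. `simulate_brownian()`,
#' `simulate_confined()` and `simulate_directed()` are strict variants that
#' require every population to use that model.
#'
#' @param spec a [sim_spec()].
#' @return an [as_tracks()] table with a `truth` attribute: one row per track
#'   with the generating `model`, `D`, `cage_radius`, `velocity` and
#'   population index.
#' @examples
#' sp <- sim_spec(list(list(model = "brownian", D = 0.5, fraction = 1)),
#'                n_tracks = 5, n_frames = 20, seed = 42)
#' tr <- simulate_tracks(sp)
#' attr(tr, "truth")
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  fr <- vapply(spec$populations, function(p) p$fraction, numeric(1))
  counts <- diff(round(cumsum(c(0, fr)) * spec$n_tracks))
  rows <- vector("list", sum(counts))
  truth <- vector("list", sum(counts))
  id <- 0L
  for (pi in seq_along(spec$populations)) {
    p <- spec$populations[[pi]]
    for (k in seq_len(counts[pi])) {
      id <- id + 1L
      x0 <- stats::runif(1, 0, spec$field_um)
      y0 <- stats::runif(1, 0, spec$field_um)
      pos <- switch(p$model,
        brownian = sim_one_brownian(spec$n_frames, p$D, spec$dt, x0, y0),
        confined = sim_one_confined(spec$n_frames, p$D, spec$dt,
                                    p$cage_radius, x0, y0),
        directed = sim_one_directed(spec$n_frames, p$D, spec$dt, p$velocity,
                                    x0, y0))
      if (spec$noise_sd > 0) {
        pos$x <- pos$x + stats::rnorm(spec$n_frames, 0, spec$noise_sd)
        pos$y <- pos$y + stats::rnorm(spec$n_frames, 0, spec$noise_sd)
      }
      rows[[id]] <- data.frame(track_id = id, frame = seq_len(spec$n_frames) - 1L,
                               x_um = pos$x, y_um = pos$y)
      truth[[id]] <- data.frame(track_id = id, population = pi, model = p$model,
                                D = p$D,
                                cage_radius = if (is.null(p$cage_radius)) NA_real_ else p$cage_radius,
                                velocity = if (is.null(p$velocity)) NA_real_ else p$velocity)
    }
  }
  out <- as_tracks(do.call(rbind, rows), dt = spec$dt, pixel_size = spec$pixel_size)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' @rdname simulate_tracks
#' @export
simulate_brownian <- function(spec) {
  if (!all(vapply(spec$populations, function(p) p$model, "") == "brownian"))
    stop("simulate_brownian requires all populations to have model = 'brownian'")
  simulate_tracks(spec)
}

#' @rdname simulate_tracks
#' @export
simulate_confined <- function(spec) {
  if (!all(vapply(spec$populations, function(p) p$model, "") == "confined"))
    stop("simulate_confined requires all populations to have model = 'confined'")
  simulate_tracks(spec)
}

#' @rdname simulate_tracks
#' @export
simulate_directed <- function(spec) {
  if (!all(vapply(spec$populations, function(p) p$model, "") == "directed"))
    stop("simulate_directed requires all populations to have model = 'directed'")
  simulate_tracks(spec)
}
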