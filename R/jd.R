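#' Pool squared frame-to-frame displacements from a cell's tracks
#'
#' One squared jump distance per consecutive frame pair per track, in um^2;
#' the sample size is the sum of (track length - 1) over tracks. All tracks
#' must share the same frame interval (they do by construction of the track
#' table).
#'
#' @param tracks an [as_tracks()] table.
#' @return list of class `"jump_sample"`: `r2` (um^2), `dt` (s), `n`,
#'   `track_ids`.
#' @export
collect_jumps <- function(tracks) {
  stopifnot(inherits(tracks, "spt_tracks"))
  dt <- attr(tracks, "dt")
  parts <- split_tracks(tracks)
  r2 <- unlist(lapply(parts, function(d) diff(d$x_um)^2 + diff(d$y_um)^2),
               use.names = FALSE)
  structure(list(r2 = r2, dt = dt, n = length(r2),
                 track_ids = as.integer(names(parts))),
            class = "jump_sample")
}

#' Jump-distance probability density of squared displacements
#'
#' For 2-D Brownian motion the squared jump `r^2` over one frame interval is
#' exponentially distributed with mean `4 D dt`; a heterogeneous pool of `m`
#' populations with fractions `f_j` gives the mixture density
#' `sum_j f_j / (4 D_j dt) * exp(-r^2 / (4 D_j dt))`, which integrates to 1
#' over `r^2` in `[0, Inf)` for any valid parameters.
#'
#' @param r2 squared displacements, um^2.
#' @param D vector of diffusion coefficients, um^2/s.
#' @param f vector of population fractions (same length as `D`, summing to 1).
#' @param dt frame interval, s.
#' @return density values at `r2`.
#' @export
jd_density <- function(r2, D, f, dt) {
  if (length(D) != length(f)) stop("D and f must have equal length")
  mu <- 4 * D * dt
  rowSums(vapply(seq_along(D),
                 function(j) f[j] * exp(-r2 / mu[j]) / mu[j],
                 numeric(length(r2))))
}

# Freedman-Diaconis histogram of r2 with Poisson weights for the fit
jd_histogram <- function(r2, bins = "FD") {
  h <- graphics::hist(r2, breaks = bins, plot = FALSE)
  list(mid = h$mids, density = h$density, counts = h$counts,
       width = diff(h$breaks))
}

jd_weighted_r2 <- function(obs, fit, w) {
  1 - sum(w * (obs - fit)^2) / sum(w * (obs - stats::weighted.mean(obs, w))^2)
}

#' Fit an exponential-mixture diffusion model to pooled jump distances
#'
#' Fits the `m`-population jump-distance density (see [jd_density()]) to the
#' histogram of squared displacements by weighted least squares (weights
#' `1/count`, the Poisson variance of each bin) with multi-start optimization
#' from quantile-split moment estimates. With `m = "auto"` the single
#' population model is fitted first and kept if its weighted coefficient of
#' determination exceeds 0.9; otherwise the two-population fit is returned
#' (the published selection rule). Populations are reported in descending
#' order of D.
#'
#' @param sample a [collect_jumps()] sample, or an [as_tracks()] table
#'   (pooled automatically).
#' @param m number of populations: 1, 2 or `"auto"`.
#' @param bins histogram rule passed to [graphics::hist()] (default
#'   Freedman-Diaconis).
#' @param min_jumps minimum pooled sample size (default 100).
#' @param r2_gate weighted-R-squared threshold of the auto selection rule.
#' @return object of class `"jd_fit"`: `m`, `D` (descending, um^2/s), `f`,
#'   `r_squared` (weighted, against the histogram density), `dt`, `n`,
#'   histogram and fitted density for plotting.
#' @examples
#' sp <- sim_spec(list(list(model = "brownian", D = 1, fraction = 1)),
#'                n_tracks = 200, n_frames = 20, noise_sd = 0, seed = 7)
#' fit <- jd_fit(collect_jumps(simulate_tracks(sp)), m = 1)
#' coef(fit)
#' @export
jd_fit <- function(sample, m = "auto", bins = "FD", min_jumps = 100,
                   r2_gate = 0.9) {
  if (inherits(sample, "spt_tracks")) sample <- collect_jumps(sample)
  stopifnot(inherits(sample, "jump_sample"))
  if (sample$n < min_jumps)
    stop("need at least ", min_jumps, " pooled jumps (got ", sample$n, ")")
  if (all(sample$r2 == 0)) stop("degenerate jump sample: all displacements are zero")
  if (!identical(m, "auto") && !m %in% c(1, 2))
    stop("m must be 1, 2 or \"auto\"; models with three or more populations are not supported")
  h <- jd_histogram(sample$r2, bins)
  w <- 1 / pmax(h$counts, 1)
  if (identical(m, "auto")) {
    f1 <- jd_fit_m(sample, h, w, 1L)
    if (f1$r_squared > r2_gate) return(f1)
    return(jd_fit_m(sample, h, w, 2L))
  }
  jd_fit_m(sample, h, w, as.integer(m))
}

jd_fit_m <- function(sample, h, w, m) {
  dt <- sample$dt
  x <- h$mid; d <- h$density
  if (m == 1L) {
    obj <- function(logD) sum(w * (d - jd_density(x, exp(logD), 1, dt))^2)
    D0 <- mean(sample$r2) / (4 * dt)
    o <- stats::optimize(obj, c(log(D0) - 4, log(D0) + 4))
    D <- exp(o$minimum); f <- 1
  } else {
    dens2 <- function(p) jd_density(x, exp(p[1:2]), c(stats::plogis(p[3]), 1 - stats::plogis(p[3])), dt)
    obj <- function(p) sum(w * (d - dens2(p))^2)
    best <- NULL
    for (q in c(0.3, 0.5, 0.7)) {   # quantile-split moment starts
      cut <- stats::quantile(sample$r2, q)
      Dlo <- max(mean(sample$r2[sample$r2 <= cut]) / (4 * dt), 1e-6)
      Dhi <- max(mean(sample$r2[sample$r2 > cut]) / (4 * dt), 2 * Dlo)
      p0 <- c(log(Dhi), log(Dlo), stats::qlogis(1 - q))
      o <- tryCatch(stats::optim(p0, obj, method = "Nelder-Mead",
                                 control = list(maxit = 5000, reltol = 1e-12)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best))
      stop("two-population jump-distance fit failed to converge from all starts")
    D <- exp(best$par[1:2])
    f <- c(stats::plogis(best$par[3]), 1 - stats::plogis(best$par[3]))
    ord <- order(D, decreasing = TRUE)   # resolve label switching
    D <- D[ord]; f <- f[ord]
  }
  fitted <- jd_density(x, D, f, dt)
  structure(list(m = m, D = unname(D), f = unname(f),
                 r_squared = jd_weighted_r2(d, fitted, w),
                 dt = dt, n = sample$n,
                 histogram = h, fitted_density = fitted,
                 fit_method = "weighted-ls-histogram"),
            class = "jd_fit")
}

#' Select the jump-distance population count by the R-squared rule
#'
#' Convenience wrapper for `jd_fit(sample, m = "auto")`: keep the single
#' population fit when its (weighted) R-squared exceeds 0.9, otherwise return
#' the two-population fit.
#'
#' @inheritParams jd_fit
#' @return a `"jd_fit"`.
#' @export
select_model <- function(sample, bins = "FD", min_jumps = 100, r2_gate = 0.9) {
  jd_fit(sample, m = "auto", bins = bins, min_jumps = min_jumps, r2_gate = r2_gate)
}

#' @export
print.jd_fit <- function(x, ...) {
  cat("Jump-distance exponential-mixture fit (m =", x$m, ")\n")
  cat(sprintf("  n jumps: %d, dt: %g s, weighted R-squared: %.4f\n", x$n, x$dt, x$r_squared))
  for (j in seq_len(x$m))
    cat(sprintf("  population %d: D = %.4g um^2/s, fraction = %.3f\n", j, x$D[j], x$f[j]))
  invisible(x)
}

#' @export
summary.jd_fit <- function(object, ...) {
  out <- data.frame(population = seq_len(object$m), D_um2_s = object$D,
                    fraction = object$f)
  attr(out, "r_squared") <- object$r_squared
  attr(out, "n") <- object$n
  class(out) <- c("summary.jd_fit", "data.frame")
  out
}

#' @export
print.summary.jd_fit <- function(x, ...) {
  print.data.frame(x)
  cat(sprintf("weighted R-squared: %.4f on %d jumps\n",
              attr(x, "r_squared"), attr(x, "n")))
  invisible(x)
}

#' @export
coef.jd_fit <- function(object, ...) {
  stats::setNames(c(object$D, object$f),
                  c(paste0("D", seq_len(object$m)), paste0("f", seq_len(object$m))))
}

#' @export
predict.jd_fit <- function(object, newdata = NULL, ...) {
  r2 <- if (is.null(newdata)) object$histogram$mid else newdata
  jd_density(r2, object$D, object$f, object$dt)
}

#' Draw squared displacements from a fitted jump-distance model
#' @param object a `jd_fit`.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param ... unused.
#' @export
simulate.jd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$m, nsim, replace = TRUE, prob = object$f)
  stats::rexp(nsim, rate = 1 / (4 * object$D[comp] * object$dt))
}

#' @export
plot.jd_fit <- function(x, ...) {
  graphics::plot(x$histogram$mid, x$histogram$density, type = "h", col = "grey60",
                 xlab = expression(r^2 ~ (mu * m^2)), ylab = "density",
                 main = sprintf("JD mixture fit, m = %d", x$m), ...)
  graphics::lines(x$histogram$mid, x$fitted_density, col = "red", lwd = 2)
  invisible(x)
}
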