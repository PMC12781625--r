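# Independent oracles used across tests; deliberately naive implementations.

# EM maximum-likelihood fit of an m-component exponential mixture on squared
# jumps; independent of the histogram-based weighted-LS path in the package.
em_exp_mixture <- function(r2, dt, m = 2, iters = 400, tol = 1e-10) {
  qs <- stats::quantile(r2, seq(0.2, 0.8, length.out = m))
  mu <- sort(as.numeric(qs), decreasing = TRUE)
  f <- rep(1 / m, m)
  ll_old <- -Inf
  for (it in seq_len(iters)) {
    dens <- vapply(seq_len(m), function(j) f[j] * exp(-r2 / mu[j]) / mu[j],
                   numeric(length(r2)))
    tot <- rowSums(dens)
    ll <- sum(log(tot))
    gamma <- dens / tot
    f <- colMeans(gamma)
    mu <- colSums(gamma * r2) / colSums(gamma)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu, decreasing = TRUE)
  list(D = mu[ord] / (4 * dt), f = f[ord])
}

# brute-force double-loop time-averaged MSD
msd_brute_force <- function(x, y, dt, kmax) {
  n <- length(x)
  msd <- numeric(kmax)
  for (k in seq_len(kmax)) {
    acc <- 0
    for (i in seq_len(n - k)) {
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    }
    msd[k] <- acc / (n - k)
  }
  data.frame(lag_s = seq_len(kmax) * dt, msd = msd)
}

# a single-track table with attributes, bypassing the simulator
make_track <- function(x, y, dt = 0.005, pixel_size = 0.107, id = 1L) {
  as_tracks(data.frame(track_id = id, frame = seq_along(x) - 1L,
                       x_um = x, y_um = y),
            dt = dt, pixel_size = pixel_size)
}

# noiseless pixel-integrated Gaussian spot on a ny x nx frame (0-based centre)
render_spot <- function(nx, ny, x0, y0, sigma = 1.2, amplitude = 1000,
                        background = 100) {
  gx <- stats::pnorm(0:(nx - 1) + 0.5, x0, sigma) - stats::pnorm(0:(nx - 1) - 0.5, x0, sigma)
  gy <- stats::pnorm(0:(ny - 1) + 0.5, y0, sigma) - stats::pnorm(0:(ny - 1) - 0.5, y0, sigma)
  amplitude * outer(gy, gx) + background
}
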