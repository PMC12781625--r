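test_that("bandpass rejects DC and preserves spot-scale structure", {
  flat <- matrix(50, 40, 40)
  out <- bandpass_filter(flat)
  expect_lt(max(abs(out)), 1e-8)

  imp <- matrix(0, 41, 41); imp[21, 21] <- 100
  bp <- bandpass_filter(imp)
  expect_equal(which(bp == max(bp), arr.ind = TRUE)[1, ], c(row = 21, col = 21),
               ignore_attr = TRUE)
  expect_gt(max(bp), 0)

  # spot on a tilted background plane: plane removed, spot preserved
  nx <- 61
  plane <- outer(seq_len(nx), seq_len(nx), function(i, j) 0.5 * i + 0.3 * j)
  spot <- render_spot(nx, nx, 30, 30, sigma = 1.2, amplitude = 2000, background = 0)
  bp_plane <- bandpass_filter(spot + plane)
  bp_spot <- bandpass_filter(spot)
  expect_lt(abs(max(bp_plane) - max(bp_spot)) / max(bp_spot), 0.02)
  far <- bp_plane[5:10, 45:55]   # away from the spot: plane residual only
  expect_lt(max(far) / max(bp_plane), 0.01)

  expect_error(bandpass_filter(matrix(0, 5, 5)), "too small")
  expect_error(bandpass_filter(flat, low_px = 5, high_px = 1), "low_px")
})

test_that("spot detection finds isolated emitters and little else", {
  frame <- render_spot(64, 64, 20.0, 31.0, amplitude = 1500)
  set.seed(1)
  noisy <- matrix(stats::rpois(64 * 64, frame), 64, 64)
  cand <- detect_spots(bandpass_filter(noisy))
  expect_gte(nrow(cand), 1)
  best <- cand[which.max(cand$value), ]
  expect_lt(sqrt((best$x - 20)^2 + (best$y - 31)^2), 1)

  two <- render_spot(64, 64, 20, 20, amplitude = 1500) +
         render_spot(64, 64, 40, 20, amplitude = 1500) - 100
  set.seed(2)
  noisy2 <- matrix(stats::rpois(64 * 64, two), 64, 64)
  cand2 <- detect_spots(bandpass_filter(noisy2))
  top2 <- cand2[order(cand2$value, decreasing = TRUE)[1:2], ]
  expect_equal(sort(top2$x), c(20, 40), tolerance = 1)

  expect_equal(nrow(detect_spots(matrix(0, 32, 32))), 0)
})

test_that("pure-noise false positives are rare at the 4-sigma threshold", {
  set.seed(42)
  fp <- 0
  for (i in 1:5) {
    noise <- matrix(stats::rnorm(128 * 128, 100, 10), 128, 128)
    fp <- fp + nrow(detect_spots(bandpass_filter(noise)))
  }
  # < 0.05% of pixels across frames (the DoG correlates neighbouring pixels,
  # so the raw Gaussian tail bound applies per effective resolution element)
  expect_lt(fp / (5 * 128 * 128), 5e-4)
})

test_that("sub-pixel localization recovers noiseless centres to 0.02 px", {
  frame <- render_spot(40, 40, 10.30, 20.70, sigma = 1.2, amplitude = 1000)
  loc <- localize_subpixel(frame, data.frame(x = 10, y = 21, value = 1))
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$x - 10.30), 0.02)
  expect_lt(abs(loc$y - 20.70), 0.02)
  expect_equal(loc$radius_px, 2 * loc$sigma_px)

  flat <- matrix(100, 40, 40)
  locf <- localize_subpixel(flat, data.frame(x = 20, y = 20, value = 1))
  expect_equal(nrow(locf), 0)
  expect_equal(attr(locf, "n_dropped"), 1L)
})

test_that("localization RMSE at SNR ~ 10 stays below 0.2 px", {
  set.seed(7)
  errs <- numeric(0)
  for (i in 1:40) {
    x0 <- stats::runif(1, 12, 28); y0 <- stats::runif(1, 12, 28)
    clean <- render_spot(40, 40, x0, y0, sigma = 1.1, amplitude = 800 * 0.13 / 0.105)
    noisy <- matrix(stats::rpois(40 * 40, clean), 40, 40) +
             matrix(stats::rnorm(40 * 40, 0, 2), 40, 40)
    loc <- localize_subpixel(noisy, data.frame(x = round(x0), y = round(y0), value = 1))
    if (nrow(loc)) errs <- c(errs, sqrt((loc$x[1] - x0)^2 + (loc$y[1] - y0)^2))
  }
  expect_gt(length(errs), 35)
  expect_lte(sqrt(mean(errs^2)), 0.2)
})

test_that("linking respects the jump limit and the retention rule", {
  # one static detection over 10 frames -> one 10-point track
  det <- data.frame(frame = 0:9, x = 5, y = 5, radius_px = 2)
  tr <- link_tracks(det)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)

  # a 7 px jump with max_jump 6 breaks the track; the 5-frame tail is dropped
  det2 <- data.frame(frame = 0:11, x = c(rep(5, 7), rep(12, 5)), y = 5,
                     radius_px = 2)
  tr2 <- link_tracks(det2)
  expect_equal(length(unique(tr2$track_id)), 1)
  expect_equal(nrow(tr2), 7)

  # two parallel particles far apart: two tracks, no identity swaps
  det3 <- rbind(data.frame(frame = 0:9, x = (0:9) * 0.5 + 5, y = 5, radius_px = 2),
                data.frame(frame = 0:9, x = (0:9) * 0.5 + 5, y = 35, radius_px = 2))
  tr3 <- link_tracks(det3)
  expect_equal(length(unique(tr3$track_id)), 2)
  for (d in split_tracks(tr3)) expect_equal(diff(range(d$y_um)), 0)

  # big spots are excluded before linking
  det4 <- data.frame(frame = 0:9, x = 5, y = 5, radius_px = 9)
  expect_equal(nrow(link_tracks(det4)), 0)
  expect_equal(nrow(link_tracks(det4[0, ])), 0)
})

test_that("every linked track is gap-free with no over-long jumps", {
  set.seed(3)
  # dense random walkers to exercise conflicts
  nw <- 12
  det <- do.call(rbind, lapply(seq_len(nw), function(i) {
    data.frame(frame = 0:29,
               x = cumsum(c(stats::runif(1, 0, 60), stats::rnorm(29, 0, 1.5))),
               y = cumsum(c(stats::runif(1, 0, 60), stats::rnorm(29, 0, 1.5))),
               radius_px = 2)
  }))
  tr <- link_tracks(det, dt = 0.005, pixel_size = 1)  # pixel_size 1: um == px
  for (d in split_tracks(tr)) {
    expect_true(all(diff(d$frame) == 1))
    expect_gte(nrow(d), 7)
    jumps <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    expect_lte(max(jumps), 6)
  }
})

test_that("rendered movies carry ground truth and tracker recovers it", {
  px <- 0.107
  rows <- lapply(1:4, function(i) {
    set.seed(50 + i)
    data.frame(track_id = i, frame = 0:19,
               x_um = (10 + 12 * ((i - 1) %% 2)) * px + cumsum(c(0, stats::rnorm(19, 0, 0.02))),
               y_um = (10 + 12 * ((i - 1) %/% 2)) * px + cumsum(c(0, stats::rnorm(19, 0, 0.02))))
  })
  truth <- as_tracks(do.call(rbind, rows), dt = 0.005, pixel_size = px)
  mv <- render_movie(truth, nx = 36, ny = 36, photon_rate = 3000,
                     background = 100, read_noise_sd = 2, seed = 4)
  expect_equal(dim(mv$frames), c(20, 36, 36))
  expect_true(all(mv$frames >= 0))
  tk <- track_movie(mv)
  expect_equal(length(unique(tk$track_id)), 4)
  expect_gte(min(track_lengths(tk)), 7)
})

test_that("an empty track list renders to pure background", {
  empty <- structure(data.frame(track_id = integer(0), frame = integer(0),
                                x_um = numeric(0), y_um = numeric(0)),
                     dt = 0.005, pixel_size = 0.107,
                     class = c("spt_tracks", "data.frame"))
  mv <- render_movie(empty, nx = 32, ny = 32, background = 80, n_frames = 5,
                     seed = 1)
  expect_equal(dim(mv$frames), c(5, 32, 32))
  expect_lt(abs(mean(mv$frames) - 80) / 80, 0.02)
})
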