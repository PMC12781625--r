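test_that("chromatic registration recovers known warps", {
  set.seed(21)
  ref <- data.frame(x_nm = stats::runif(25, 0, 40000),
                    y_nm = stats::runif(25, 0, 40000))
  # identity
  map0 <- register_channels(ref, ref)
  expect_lt(map0$residual_rms_nm, 1e-6)

  # synthetic quadratic warp, inverted to < 1 nm
  warp <- function(p) data.frame(
    x_nm = 12 + 1.002 * p$x_nm - 3e-4 * p$y_nm + 2e-9 * p$x_nm^2 + 1e-9 * p$x_nm * p$y_nm,
    y_nm = -8 + 0.998 * p$y_nm + 2e-4 * p$x_nm - 1.5e-9 * p$y_nm^2)
  map <- register_channels(ref, warp(ref))
  expect_lt(map$residual_rms_nm, 1)
  tst <- data.frame(x_nm = stats::runif(50, 0, 40000),
                    y_nm = stats::runif(50, 0, 40000))
  back <- apply_registration(map, warp(tst))
  expect_lt(max(abs(back$x_nm - tst$x_nm)), 1)
  expect_lt(max(abs(back$y_nm - tst$y_nm)), 1)

  expect_error(register_channels(ref[1:5, ], ref[1:5, ]), "at least 6")
})

test_that("cluster detection finds centroids and handles empty fields", {
  set.seed(22)
  locs <- data.frame(x_nm = stats::rnorm(40, 1000, 15),
                     y_nm = stats::rnorm(40, 1500, 15), intensity = 1)
  cl <- detect_clusters(locs)
  expect_equal(nrow(cl), 1)
  expect_lt(abs(cl$x_nm - mean(locs$x_nm)), 10)
  expect_lt(abs(cl$y_nm - mean(locs$y_nm)), 10)
  expect_equal(cl$n_localizations, 40)

  two <- rbind(locs, data.frame(x_nm = stats::rnorm(40, 1500, 15),
                                y_nm = stats::rnorm(40, 1500, 15), intensity = 1))
  expect_equal(nrow(detect_clusters(two)), 2)

  expect_equal(nrow(detect_clusters(locs[0, ])), 0)
})

test_that("holoenzyme pairing is one-to-one within the radius", {
  cp <- data.frame(x_nm = c(0, 1000), y_nm = c(0, 0), intensity = 1)
  rp <- data.frame(x_nm = c(50, 1150), y_nm = c(0, 0), intensity = 1)
  p <- pair_holoenzymes(cp, rp)
  expect_equal(nrow(p$pairs), 1)          # 50 nm pairs, 150 nm does not
  expect_equal(p$pairs$cp_idx, 1)
  expect_equal(p$free_cp, 2)
  expect_equal(p$free_rp, 2)

  # tie: two CPs equidistant from one RP -> lower CP index wins
  cp2 <- data.frame(x_nm = c(-60, 60), y_nm = c(0, 0), intensity = 1)
  rp2 <- data.frame(x_nm = 0, y_nm = 0, intensity = 1)
  p2 <- pair_holoenzymes(cp2, rp2)
  expect_equal(p2$pairs$cp_idx, 1)

  # property: symmetric, one-to-one, never beyond the radius
  set.seed(23)
  cpr <- data.frame(x_nm = stats::runif(150, 0, 5000),
                    y_nm = stats::runif(150, 0, 5000), intensity = 1)
  rpr <- data.frame(x_nm = stats::runif(120, 0, 5000),
                    y_nm = stats::runif(120, 0, 5000), intensity = 1)
  pr <- pair_holoenzymes(cpr, rpr)
  expect_true(all(pr$pairs$dist_nm <= 100))
  expect_equal(anyDuplicated(pr$pairs$cp_idx), 0)
  expect_equal(anyDuplicated(pr$pairs$rp_idx), 0)
  expect_equal(length(pr$free_cp) + nrow(pr$pairs), 150)
  expect_equal(length(pr$free_rp) + nrow(pr$pairs), 120)
})

test_that("pairing is invariant under global translation of both channels", {
  set.seed(24)
  cp <- data.frame(x_nm = stats::runif(80, 0, 4000),
                   y_nm = stats::runif(80, 0, 4000), intensity = 1)
  rp <- data.frame(x_nm = stats::runif(80, 0, 4000),
                   y_nm = stats::runif(80, 0, 4000), intensity = 1)
  p1 <- pair_holoenzymes(cp, rp)
  shift <- function(d) transform(d, x_nm = x_nm + 5000, y_nm = y_nm - 3000)
  p2 <- pair_holoenzymes(shift(cp), shift(rp))
  expect_equal(p1$pairs$cp_idx, p2$pairs$cp_idx)
  expect_equal(p1$pairs$rp_idx, p2$pairs$rp_idx)
})

test_that("unit RP intensity comes from the primary mode", {
  expect_equal(estimate_unit_intensity(rep(100, 30)), 100, tolerance = 5)
  set.seed(25)
  mix <- c(stats::rnorm(700, 100, 10), stats::rnorm(300, 200, 20))
  expect_lt(abs(estimate_unit_intensity(mix) - 100) / 100, 0.05)
  expect_error(estimate_unit_intensity(rep(100, 10)), "at least 20")
  expect_equal(estimate_unit_intensity(mix, method = "median"),
               stats::median(mix))
})

test_that("capping fractions are exact for noiseless intensities", {
  # 2 free CP, 2 singly (RP at 1x), 1 doubly (RP at 2x), 3 free RP
  cp <- data.frame(x_nm = c(0, 500, 1000, 1500, 2000) * 10,
                   y_nm = rep(0, 5), intensity = 1)
  rp <- data.frame(x_nm = c(10030, 15030, 20030, 40000, 45000, 50000),
                   y_nm = rep(0, 6),
                   intensity = c(100, 100, 200, 100, 100, 100))
  p <- pair_holoenzymes(cp, rp)
  res <- capping_fractions(p, rp, unit_intensity = 100)
  expect_equal(unname(res$cp_fractions), c(2, 2, 1) / 5)
  # RP units: 3 free + 2 singly + 2 doubly-units = 7
  expect_equal(unname(res$rp_fractions), c(3, 2, 2) / 7)
  expect_equal(sum(res$cp_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(res$rp_fractions), 1, tolerance = 1e-9)
  # cluster-counting convention for the RP side
  res1 <- capping_fractions(p, rp, unit_intensity = 100, rp_doubly_units = 1)
  expect_equal(unname(res1$rp_fractions), c(3, 2, 1) / 6)

  none <- pair_holoenzymes(cp, rp[4:6, ])
  resn <- capping_fractions(none, rp[4:6, ], 100)
  expect_equal(unname(resn$cp_fractions["free"]), 1)
  expect_error(capping_fractions(pair_holoenzymes(cp[0, ], rp), rp, 100),
               "both channels")
})

test_that("the simulator's composition is recovered end to end", {
  compositions <- list(c(free_cp = 0.41, singly = 0.45, doubly = 0.14, free_rp = 2.3),
                       c(free_cp = 0.46, singly = 0.32, doubly = 0.22, free_rp = 1.0))
  for (fr in compositions) {
    field <- simulate_capping_field(n_clusters = 1200, fractions = fr,
                                    intensity_cv = 0.15, seed = 26)
    pairing <- pair_holoenzymes(field$cp, field$rp)
    unit <- estimate_unit_intensity(field$rp$intensity)
    res <- capping_fractions(pairing, field$rp, unit)
    expect_lt(max(abs(res$cp_fractions - fr[c("free_cp", "singly", "doubly")])),
              0.05)
    expect_equal(sum(res$rp_fractions), 1, tolerance = 1e-9)
  }
})

test_that("capping simulator honors its degenerate settings", {
  all_free <- simulate_capping_field(n_clusters = 200,
    fractions = c(free_cp = 1, singly = 0, doubly = 0, free_rp = 0), seed = 1)
  expect_equal(nrow(all_free$rp), 0)
  expect_true(all(all_free$cp$species == "free_cp"))

  exact <- simulate_capping_field(n_clusters = 200,
    fractions = c(free_cp = 0.2, singly = 0.5, doubly = 0.3, free_rp = 0.5),
    intensity_cv = 0, unit_rp_intensity = 100, seed = 2)
  doubly <- exact$rp[exact$rp$species == "doubly", ]
  expect_true(all(doubly$intensity == 200))

  expect_warning(simulate_capping_field(n_clusters = 100,
    pair_offset_sd_nm = 60, seed = 3), "within 100 nm")
  expect_error(simulate_capping_field(fractions = c(free_cp = -0.1, singly = 0.9,
    doubly = 0.2, free_rp = 1)), "non-negative")
})

test_that("compartment fractions follow the label image", {
  mask <- matrix(0L, 100, 100)
  mask[10:40, 10:40] <- 1L   # nucleus
  mask[10:40, 50:80] <- 2L   # ER
  mask[60:90, 10:80] <- 3L   # cytosol
  px <- 100

  nuc <- data.frame(x_nm = stats::runif(50, 1500, 3500),
                    y_nm = stats::runif(50, 1500, 3500))
  expect_equal(unname(compartment_fractions(nuc, mask, px)$fractions["nucleus"]), 1)

  pts <- rbind(
    data.frame(x_nm = stats::runif(50, 1500, 3500), y_nm = stats::runif(50, 1500, 3500)),
    data.frame(x_nm = stats::runif(30, 5500, 7500), y_nm = stats::runif(30, 1500, 3500)),
    data.frame(x_nm = stats::runif(20, 1500, 7500), y_nm = stats::runif(20, 6500, 8500)))
  cf <- compartment_fractions(pts, mask, px)
  expect_equal(unname(cf$fractions), c(0.5, 0.3, 0.2))
  expect_equal(sum(cf$fractions), 1)

  # points outside the cell are excluded from the denominator
  mixed <- rbind(nuc, data.frame(x_nm = rep(9990, 10), y_nm = rep(9990, 10)))
  cfm <- compartment_fractions(mixed, mask, px)
  expect_equal(cfm$n_outside, 10)
  expect_equal(unname(cfm$fractions["nucleus"]), 1)

  outside <- data.frame(x_nm = rep(9990, 5), y_nm = rep(9990, 5))
  expect_error(compartment_fractions(outside, mask, px), "inside the cell")
})
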