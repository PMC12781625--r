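#' Chromatic registration by second-order polynomial warp
#'
#' Least-squares fit of a full second-order 2-D polynomial per axis mapping
#' one channel's bead coordinates onto the other's:
#' `x' = c0 + c1 x + c2 y + c3 x^2 + c4 x y + c5 y^2` (and likewise for `y'`).
#' Requires at least six matched bead pairs; a residual RMS above 50 nm
#' triggers a warning (poor bead matching or field distortion beyond second
#' order).
#'
#' @param ref data frame `x_nm`, `y_nm`: bead positions in the reference
#'   channel.
#' @param moving data frame `x_nm`, `y_nm`: the same beads in the channel to
#'   be corrected.
#' @return object of class `"chromatic_map"` with per-axis coefficients and
#'   `residual_rms_nm`; apply with [apply_registration()].
#' @export
register_channels <- function(ref, moving) {
  if (nrow(ref) != nrow(moving)) stop("bead tables must have matching rows")
  if (nrow(ref) < 6) stop("need at least 6 matched bead pairs for a second-order warp")
  X <- cbind(1, moving$x_nm, moving$y_nm, moving$x_nm^2,
             moving$x_nm * moving$y_nm, moving$y_nm^2)
  cx <- stats::lm.fit(X, ref$x_nm)$coefficients
  cy <- stats::lm.fit(X, ref$y_nm)$coefficients
  pred <- cbind(X %*% ifelse(is.na(cx), 0, cx), X %*% ifelse(is.na(cy), 0, cy))
  res <- sqrt(mean((pred[, 1] - ref$x_nm)^2 + (pred[, 2] - ref$y_nm)^2))
  if (res > 50)
    warning(sprintf("registration residual RMS %.1f nm exceeds 50 nm", res))
  structure(list(coef_x = cx, coef_y = cy, residual_rms_nm = res,
                 n_beads = nrow(ref)),
            class = "chromatic_map")
}

#' @rdname register_channels
#' @param map a `"chromatic_map"`.
#' @param locs data frame with `x_nm`, `y_nm` to transform into the reference
#'   frame.
#' @export
apply_registration <- function(map, locs) {
  stopifnot(inherits(map, "chromatic_map"))
  X <- cbind(1, locs$x_nm, locs$y_nm, locs$x_nm^2, locs$x_nm * locs$y_nm,
             locs$y_nm^2)
  locs$x_nm <- as.vector(X %*% ifelse(is.na(map$coef_x), 0, map$coef_x))
  locs$y_nm <- as.vector(X %*% ifelse(is.na(map$coef_y), 0, map$coef_y))
  locs
}

#' @export
print.chromatic_map <- function(x, ...) {
  cat(sprintf("second-order chromatic map from %d beads; residual RMS %.2f nm\n",
              x$n_beads, x$residual_rms_nm))
  invisible(x)
}

#' Detect clusters in a localization field
#'
#' Functional equivalent of spot-counting plugins used on reconstructed SMLM
#' images: localizations are rastered into a 2-D intensity histogram,
#' Gaussian-smoothed, thresholded (robust background + `k` SDs, with a floor
#' at a small fraction of the maximum for sparse fields), and
#' connected-component labelled; each component becomes a cluster with an
#' intensity-weighted centroid over its member localizations and their summed
#' intensity.
#'
#' @param locs data frame `x_nm`, `y_nm` and optionally `intensity`
#'   (default 1 per localization).
#' @param bin_nm raster bin size.
#' @param smooth_sigma_nm Gaussian smoothing SD.
#' @param k threshold in robust SDs above the median raster value.
#' @return data frame of class `"cluster_field"`: `x_nm`, `y_nm`,
#'   `intensity`, `n_localizations`.
#' @export
detect_clusters <- function(locs, bin_nm = 20, smooth_sigma_nm = 30, k = 4) {
  empty <- structure(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                                intensity = numeric(0),
                                n_localizations = integer(0)),
                     class = c("cluster_field", "data.frame"))
  if (nrow(locs) == 0) return(empty)
  if (is.null(locs$intensity)) locs$intensity <- 1
  pad <- 4 * smooth_sigma_nm
  x0 <- min(locs$x_nm) - pad; y0 <- min(locs$y_nm) - pad
  nx <- ceiling((max(locs$x_nm) + pad - x0) / bin_nm) + 1
  ny <- ceiling((max(locs$y_nm) + pad - y0) / bin_nm) + 1
  ix <- floor((locs$x_nm - x0) / bin_nm) + 1
  iy <- floor((locs$y_nm - y0) / bin_nm) + 1
  img <- matrix(0, ny, nx)
  for (i in seq_len(nrow(locs))) img[iy[i], ix[i]] <- img[iy[i], ix[i]] + locs$intensity[i]
  sm <- EBImage::gblur(img, sigma = smooth_sigma_nm / bin_nm)
  thr <- max(stats::median(sm) + k * stats::mad(sm), 0.05 * max(sm))
  lab <- EBImage::bwlabel(sm > thr)
  memb <- lab[cbind(iy, ix)]
  keep <- memb > 0
  if (!any(keep)) return(empty)
  sp <- split(which(keep), memb[keep])
  out <- do.call(rbind, lapply(sp, function(idx) {
    w <- locs$intensity[idx]
    data.frame(x_nm = stats::weighted.mean(locs$x_nm[idx], w),
               y_nm = stats::weighted.mean(locs$y_nm[idx], w),
               intensity = sum(w), n_localizations = length(idx))
  }))
  rownames(out) <- NULL
  class(out) <- c("cluster_field", "data.frame")
  out
}

#' Pair CP and RP clusters into holoenzymes
#'
#' One-to-one greedy pairing by ascending centroid distance: all CP-RP
#' candidate pairs within `radius_nm` are sorted by distance (ties broken by
#' lower CP then RP index) and accepted if both clusters are still free.
#' Unpaired clusters are reported free.
#'
#' @param cp,rp data frames with `x_nm`, `y_nm` (and `intensity`); `rp`
#'   should already be registered onto `cp`'s channel.
#' @param radius_nm pairing radius (default 100 nm).
#' @return list of class `"holoenzyme_pairing"`: `pairs` (data frame
#'   `cp_idx`, `rp_idx`, `dist_nm`), `free_cp`, `free_rp` (index vectors),
#'   `n_cp`, `n_rp`, `radius_nm`.
#' @export
pair_holoenzymes <- function(cp, rp, radius_nm = 100) {
  n_cp <- nrow(cp); n_rp <- nrow(rp)
  pairs <- data.frame(cp_idx = integer(0), rp_idx = integer(0), dist_nm = numeric(0))
  if (n_cp > 0 && n_rp > 0) {
    d <- sqrt(outer(cp$x_nm, rp$x_nm, "-")^2 + outer(cp$y_nm, rp$y_nm, "-")^2)
    cand <- which(d <= radius_nm, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_cp <- logical(n_cp); used_rp <- logical(n_rp)
      keep <- integer(0)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_cp[i] && !used_rp[j]) {
          used_cp[i] <- TRUE; used_rp[j] <- TRUE
          keep <- c(keep, k)
        }
      }
      pairs <- data.frame(cp_idx = cand[keep, 1], rp_idx = cand[keep, 2],
                          dist_nm = d[cand[keep, , drop = FALSE]])
    }
  }
  structure(list(pairs = pairs,
                 free_cp = setdiff(seq_len(n_cp), pairs$cp_idx),
                 free_rp = setdiff(seq_len(n_rp), pairs$rp_idx),
                 n_cp = n_cp, n_rp = n_rp, radius_nm = radius_nm),
            class = "holoenzyme_pairing")
}

#' Unit RP intensity from the cluster intensity distribution
#'
#' The intensity of a single regulatory particle is taken as the primary mode
#' of the RP cluster intensity distribution (Gaussian kernel density,
#' Silverman bandwidth): a plain mean would be biased upward by doubly-capped
#' clusters carrying two units. `method = "median"` is available as a robust
#' alternative. A secondary density mode far from twice the unit triggers a
#' warning.
#'
#' @param intensities RP cluster intensities (at least 20), or a
#'   `cluster_field`.
#' @param method `"mode"` (default) or `"median"`.
#' @return scalar unit intensity.
#' @export
estimate_unit_intensity <- function(intensities, method = c("mode", "median")) {
  method <- match.arg(method)
  if (is.data.frame(intensities)) intensities <- intensities$intensity
  if (length(intensities) < 20)
    stop("need at least 20 RP clusters to estimate the unit intensity")
  if (method == "median") return(stats::median(intensities))
  dens <- stats::density(intensities, bw = "nrd0")
  unit <- dens$x[which.max(dens$y)]
  # check other prominent modes sit near the 2:1 ratio expected for capping
  ym <- dens$y
  locmax <- which(diff(sign(diff(ym))) == -2) + 1
  big <- locmax[ym[locmax] > 0.25 * max(ym)]
  if (length(big) > 1) {
    ratios <- dens$x[big] / unit
    other <- ratios[abs(ratios - 1) > 0.2]
    if (length(other) && !any(abs(other - 2) < 0.5))
      warning("secondary intensity mode not near twice the unit intensity")
  }
  unit
}

#' Capping stoichiometry from a pairing and unit intensity
#'
#' Paired CP clusters are split into singly- and doubly-capped holoenzymes by
#' their partner RP cluster intensity: below `doubly_cut` units singly,
#' at or above it doubly (clusters beyond 2.5 units are still counted doubly
#' and their count flagged). CP-side fractions are over all CP clusters. On
#' the RP side each doubly-capped holoenzyme engages two RP units, so with
#' the default `rp_doubly_units = 2` the RP denominators count free RP
#' clusters as one unit each, singly-capped partners as one and doubly-capped
#' partners as two; set `rp_doubly_units = 1` to count clusters instead.
#'
#' @param pairing a [pair_holoenzymes()] result.
#' @param rp data frame of RP clusters used in the pairing (for intensities).
#' @param unit_intensity from [estimate_unit_intensity()].
#' @param doubly_cut singly/doubly threshold in units (default 1.5, the
#'   midpoint of 1x and 2x).
#' @param rp_doubly_units RP units attributed to a doubly-capped holoenzyme.
#' @return object of class `"capping_result"`: `cp_fractions` and
#'   `rp_fractions` (each free/singly/doubly, summing to 1), counts,
#'   `unit_intensity`, `n_flagged_high` (partners beyond 2.5 units).
#' @export
capping_fractions <- function(pairing, rp, unit_intensity, doubly_cut = 1.5,
                              rp_doubly_units = 2) {
  stopifnot(inherits(pairing, "holoenzyme_pairing"))
  if (pairing$n_cp == 0 || pairing$n_rp == 0)
    stop("capping fractions need clusters in both channels")
  rp_int <- rp$intensity[pairing$pairs$rp_idx] / unit_intensity
  doubly <- rp_int >= doubly_cut
  n_singly <- sum(!doubly); n_doubly <- sum(doubly)
  n_free_cp <- length(pairing$free_cp)
  cp_fr <- c(free = n_free_cp, singly = n_singly, doubly = n_doubly) / pairing$n_cp
  n_free_rp <- length(pairing$free_rp)
  rp_units <- n_free_rp + n_singly + rp_doubly_units * n_doubly
  rp_fr <- c(free = n_free_rp, singly = n_singly,
             doubly = rp_doubly_units * n_doubly) / rp_units
  structure(list(cp_fractions = cp_fr, rp_fractions = rp_fr,
                 n_cp = pairing$n_cp, n_rp = pairing$n_rp,
                 n_singly = n_singly, n_doubly = n_doubly,
                 unit_intensity = unit_intensity,
                 n_flagged_high = sum(rp_int > 2.5)),
            class = "capping_result")
}

#' @export
print.capping_result <- function(x, ...) {
  cat("Holoenzyme capping stoichiometry\n")
  cat(sprintf("  CP (n=%d): free %.3f / singly %.3f / doubly %.3f\n", x$n_cp,
              x$cp_fractions["free"], x$cp_fractions["singly"], x$cp_fractions["doubly"]))
  cat(sprintf("  RP (n=%d): free %.3f / singly %.3f / doubly %.3f\n", x$n_rp,
              x$rp_fractions["free"], x$rp_fractions["singly"], x$rp_fractions["doubly"]))
  if (x$n_flagged_high > 0)
    cat(sprintf("  %d paired RP clusters above 2.5 units (counted doubly)\n", x$n_flagged_high))
  invisible(x)
}

#' Subcellular compartment fractions of localizations
#'
#' Assigns each localization to the compartment of the label-image pixel it
#' falls in. The label image is disjoint by construction (one label per
#' pixel) with the precedence nucleus > ER > cytosol already baked into its
#' labels: 1 = nucleus, 2 = ER, 3 = cytosol, 0 = outside the cell.
#' Localizations outside the cell are excluded from the denominator.
#'
#' @param locs data frame `x_nm`, `y_nm`.
#' @param mask integer matrix of labels (row = y, col = x, 0-based pixel
#'   origin at top-left).
#' @param pixel_size_nm label-image pixel size.
#' @return list: `fractions` (nucleus/er/cytosol, summing to 1), `n_inside`,
#'   `n_outside`.
#' @export
compartment_fractions <- function(locs, mask, pixel_size_nm) {
  ix <- floor(locs$x_nm / pixel_size_nm) + 1
  iy <- floor(locs$y_nm / pixel_size_nm) + 1
  inb <- ix >= 1 & ix <= ncol(mask) & iy >= 1 & iy <= nrow(mask)
  lab <- rep(0L, nrow(locs))
  lab[inb] <- mask[cbind(iy[inb], ix[inb])]
  inside <- lab > 0
  if (!any(inside)) stop("no localizations fall inside the cell mask")
  fr <- vapply(c(nucleus = 1L, er = 2L, cytosol = 3L),
               function(l) mean(lab[inside] == l), numeric(1))
  list(fractions = fr, n_inside = sum(inside), n_outside = sum(!inside))
}
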