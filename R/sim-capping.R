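#' Simulate a two-color SMLM cluster field with known capping composition
#'
#' Generates matched core-particle (CP) and regulatory-particle (RP) cluster
#' tables for holoenzyme stoichiometry recovery tests. CP clusters are placed
#' uniformly in a square field and are free, singly capped (one RP cluster of
#' one unit intensity nearby) or doubly capped (one RP cluster of two unit
#' intensities nearby); additional free RP clusters are placed uniformly.
#' Paired RP centroids are offset from their CP by an isotropic 2-D Gaussian
#' of SD `pair_offset_sd_nm`, so essentially all true pairs fall within the
#' 100 nm pairing radius used downstream.
#'
#' The default composition mirrors a resting HEK293A-like field: CP split
#' 0.41/0.45/0.14 into free/singly/doubly, and 2.3 free RP clusters per CP
#' cluster, which together put about three quarters of all RP units in the
#' free pool. The default 60 um field keeps chance CP-RP colocalization
#' within 100 nm below ~5% under uniform placement.
#'
#' @param n_clusters number of CP clusters.
#' @param fractions named vector with `free_cp`, `singly`, `doubly` (summing
#'   to 1 over CP clusters) and `free_rp` = free RP clusters per CP cluster.
#' @param pair_offset_sd_nm SD of the CP-RP centroid offset, nm.
#' @param unit_rp_intensity mean intensity of a single RP, arbitrary units.
#' @param intensity_cv coefficient of variation of cluster intensities.
#' @param field_nm side of the square field, nm.
#' @param seed integer seed.
#' @return list of class `"capping_field"` with elements `cp` and `rp`
#'   (data frames `x_nm`, `y_nm`, `intensity`, plus ground-truth `species`),
#'   `field_nm` and the requested composition.
#' @export
simulate_capping_field <- function(n_clusters = 2000,
                                   fractions = c(free_cp = 0.41, singly = 0.45,
                                                 doubly = 0.14, free_rp = 2.3),
                                   pair_offset_sd_nm = 25,
                                   unit_rp_intensity = 100,
                                   intensity_cv = 0.15,
                                   field_nm = 60000,
                                   seed = 1L) {
  fr <- fractions
  if (any(fr < 0)) stop("fractions must be non-negative")
  cp_fr <- fr[c("free_cp", "singly", "doubly")]
  if (abs(sum(cp_fr) - 1) > 1e-8) stop("free_cp + singly + doubly must sum to 1")
  # fraction of true pairs within the 100 nm pairing radius for this offset SD
  p_within <- 1 - exp(-100^2 / (2 * pair_offset_sd_nm^2))
  if (p_within < 0.99)
    warning(sprintf("pair_offset_sd_nm = %g leaves only %.1f%% of true pairs within 100 nm",
                    pair_offset_sd_nm, 100 * p_within))
  set.seed(as.integer(seed))
  counts <- diff(round(cumsum(c(0, cp_fr)) * n_clusters))
  names(counts) <- names(cp_fr)
  n_free_rp <- round(fr[["free_rp"]] * n_clusters)
  jitter_int <- function(mu, n) {
    if (intensity_cv == 0) rep(mu, n)
    else pmax(stats::rnorm(n, mu, intensity_cv * mu), 0.05 * mu)
  }
  cp_x <- stats::runif(n_clusters, 0, field_nm)
  cp_y <- stats::runif(n_clusters, 0, field_nm)
  species <- rep(c("free_cp", "singly", "doubly"), counts)
  cp <- data.frame(x_nm = cp_x, y_nm = cp_y,
                   intensity = jitter_int(unit_rp_intensity, n_clusters),
                   species = species)
  paired <- which(species != "free_cp")
  rp_pair <- data.frame(
    x_nm = cp_x[paired] + stats::rnorm(length(paired), 0, pair_offset_sd_nm),
    y_nm = cp_y[paired] + stats::rnorm(length(paired), 0, pair_offset_sd_nm),
    intensity = ifelse(species[paired] == "doubly",
                       jitter_int(2 * unit_rp_intensity, length(paired)),
                       jitter_int(unit_rp_intensity, length(paired))),
    species = species[paired])
  rp_free <- data.frame(x_nm = stats::runif(n_free_rp, 0, field_nm),
                        y_nm = stats::runif(n_free_rp, 0, field_nm),
                        intensity = jitter_int(unit_rp_intensity, n_free_rp),
                        species = rep("free_rp", n_free_rp))
  structure(list(cp = cp, rp = rbind(rp_pair, rp_free),
                 field_nm = field_nm, fractions = fr,
                 unit_rp_intensity = unit_rp_intensity),
            class = "capping_field")
}
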