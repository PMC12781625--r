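#' Pipeline orchestration
#'
#' `run_spt()`, `run_capping()` and `run_voltage()` chain the analysis stages
#' end to end with file input/output, a YAML-configurable parameter set, a
#' seed, and machine-readable JSON summaries; every summary echoes the
#' parameters and seed it was produced with so a run is reproducible from its
#' own output. Existing outputs are never overwritten unless `force = TRUE`.
#'
#' @name pipelines
NULL

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  config
}

prepare_out <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory ", out_dir, " is not empty; use force = TRUE to overwrite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname pipelines
#' @param config list or YAML file path. For `run_spt`: `tracks_csv` or
#'   `movie_tiff` input, optional `params` (fields of [tracking_params()]),
#'   `profile` (threshold profile), `dt`, `pixel_size`. For `run_capping`:
#'   `cp_csv`, `rp_csv` (cluster or localization tables with `x_nm,y_nm`,
#'   `intensity`), optional `beads_csv` (columns `ref_x_nm,ref_y_nm,
#'   mov_x_nm,mov_y_nm`), optional `mask_tiff` + `mask_pixel_nm`,
#'   `pairing_radius_nm`, `detect` (logical: run cluster detection on the
#'   input tables). For `run_voltage`: `trace_csv` (columns `t_s,intensity`)
#'   and optional filter settings.
#' @param out_dir output directory.
#' @param seed integer seed echoed into the run log (analysis stages are
#'   deterministic; the seed drives any simulation-backed inputs).
#' @param force overwrite existing outputs.
#' @return `run_spt` returns the summary list invisibly (written to
#'   `summary.json`); tracks, the JD fit and per-track motion classes are
#'   written alongside.
#' @export
run_spt <- function(config, out_dir, seed = 1L, force = FALSE) {
  cfg <- read_config(config)
  prepare_out(out_dir, force)
  if (!is.null(cfg$tracks_csv)) {
    if (!file.exists(cfg$tracks_csv)) stop("input error: tracks_csv not found: ", cfg$tracks_csv)
    tracks <- read_tracks(cfg$tracks_csv, dt = cfg$dt, pixel_size = cfg$pixel_size)
  } else if (!is.null(cfg$movie_tiff)) {
    if (!file.exists(cfg$movie_tiff)) stop("input error: movie_tiff not found: ", cfg$movie_tiff)
    movie <- read_movie(cfg$movie_tiff,
                        dt = if (is.null(cfg$dt)) 0.005 else cfg$dt,
                        pixel_size = if (is.null(cfg$pixel_size)) 0.107 else cfg$pixel_size)
    params <- do.call(tracking_params, if (is.null(cfg$params)) list() else cfg$params)
    tracks <- track_movie(movie, params)
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
  } else stop("input error: config needs tracks_csv or movie_tiff")
  if (nrow(tracks) == 0) stop("analysis failure: no retained tracks")
  jd <- tryCatch(jd_fit(collect_jumps(tracks), m = "auto"),
                 error = function(e) stop("analysis failure in jump-distance stage: ",
                                          conditionMessage(e)))
  profile <- if (is.null(cfg$profile)) "as_printed" else cfg$profile
  motion <- analyze_motion(tracks, class_thresholds(profile))
  utils::write.csv(motion$per_track, file.path(out_dir, "motion_per_track.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = seed, config = cfg, n_tracks = length(unique(tracks$track_id)),
    jd = list(m = jd$m, D = jd$D, f = jd$f, r_squared = jd$r_squared, n_jumps = jd$n),
    motion = list(profile = profile, fractions = as.list(motion$fractions),
                  n_classified = motion$n_classified,
                  n_discarded = motion$n_discarded,
                  mean_r_c_um = motion$mean_r_c))
  write_report(summary, file.path(out_dir, "summary.json"))
  invisible(summary)
}

read_cluster_csv <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop("input error: cannot parse ", path, ": ", conditionMessage(e)))
  need <- c("x_nm", "y_nm")
  if (!all(need %in% names(df))) {
    bad <- which(!need %in% names(df))[1]
    stop("input error: ", path, " line 1: missing column ", need[bad])
  }
  if (is.null(df$intensity)) df$intensity <- 1
  df
}

#' @rdname pipelines
#' @export
run_capping <- function(config, out_dir, seed = 1L, force = FALSE) {
  cfg <- read_config(config)
  prepare_out(out_dir, force)
  if (is.null(cfg$cp_csv) || is.null(cfg$rp_csv))
    stop("input error: config needs cp_csv and rp_csv")
  cp <- read_cluster_csv(cfg$cp_csv)
  rp <- read_cluster_csv(cfg$rp_csv)
  registration <- NULL
  if (!is.null(cfg$beads_csv)) {
    beads <- utils::read.csv(cfg$beads_csv)
    map <- register_channels(data.frame(x_nm = beads$ref_x_nm, y_nm = beads$ref_y_nm),
                             data.frame(x_nm = beads$mov_x_nm, y_nm = beads$mov_y_nm))
    rp <- apply_registration(map, rp)
    registration <- list(residual_rms_nm = map$residual_rms_nm, n_beads = map$n_beads)
  }
  if (isTRUE(cfg$detect)) {
    cp <- detect_clusters(cp)
    rp <- detect_clusters(rp)
  }
  radius <- if (is.null(cfg$pairing_radius_nm)) 100 else cfg$pairing_radius_nm
  pairing <- pair_holoenzymes(cp, rp, radius)
  unit <- estimate_unit_intensity(rp$intensity)
  res <- capping_fractions(pairing, rp, unit)
  utils::write.csv(pairing$pairs, file.path(out_dir, "pairing.csv"), row.names = FALSE)
  summary <- list(seed = seed, config = cfg, registration = registration,
                  unit_rp_intensity = unit,
                  cp_fractions = as.list(res$cp_fractions),
                  rp_fractions = as.list(res$rp_fractions),
                  n_cp = res$n_cp, n_rp = res$n_rp,
                  n_flagged_high = res$n_flagged_high)
  if (!is.null(cfg$mask_tiff)) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required")
    mask <- round(tiff::readTIFF(cfg$mask_tiff) * 255)
    comp_cp <- compartment_fractions(cp, mask, cfg$mask_pixel_nm)
    utils::write.csv(data.frame(compartment = names(comp_cp$fractions),
                                fraction = as.numeric(comp_cp$fractions)),
                     file.path(out_dir, "compartments.csv"), row.names = FALSE)
    summary$compartments <- as.list(comp_cp$fractions)
  }
  write_report(summary, file.path(out_dir, "capping.json"))
  invisible(summary)
}

#' @rdname pipelines
#' @export
run_voltage <- function(config, out_dir, seed = 1L, force = FALSE) {
  cfg <- read_config(config)
  prepare_out(out_dir, force)
  if (is.null(cfg$trace_csv)) stop("input error: config needs trace_csv")
  if (!file.exists(cfg$trace_csv)) stop("input error: trace_csv not found: ", cfg$trace_csv)
  df <- utils::read.csv(cfg$trace_csv)
  if (!all(c("t_s", "intensity") %in% names(df)))
    stop("input error: ", cfg$trace_csv, " line 1: expected header t_s,intensity")
  df$t_s <- suppressWarnings(as.numeric(df$t_s))
  df$intensity <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(!is.finite(df$t_s) | !is.finite(df$intensity))
  if (length(bad))
    stop("input error: ", cfg$trace_csv, " line ", bad[1] + 1, ": non-numeric value")
  trace <- as_trace(df$t_s, df$intensity)
  res <- voltage_response(trace,
    bin_factor = if (is.null(cfg$bin_factor)) 10 else cfg$bin_factor,
    passband_hz = if (is.null(cfg$passband_hz)) 0.05 else cfg$passband_hz,
    prominence = if (is.null(cfg$prominence)) 0.03 else cfg$prominence,
    min_distance = if (is.null(cfg$min_distance)) 50 else cfg$min_distance)
  utils::write.csv(data.frame(t_s = res$normalized$t, nFI = res$normalized$I),
                   file.path(out_dir, "trace_normalized.csv"), row.names = FALSE)
  summary <- list(seed = seed, config = cfg, rate_nfi_per_s = res$rate,
                  branch = res$branch,
                  t_maxima_s = res$extrema$t_max, t_minima_s = res$extrema$t_min,
                  bleach_tau_s = res$bleach_tau_s)
  write_report(summary, file.path(out_dir, "voltage.json"))
  invisible(summary)
}
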