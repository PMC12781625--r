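#' Trajectory tables
#'
#' Single-particle trajectories are stored as a plain data frame with one row
#' per localization and columns `track_id`, `frame`, `x_um`, `y_um` (and
#' optionally `intensity`), carrying the frame interval `dt` (seconds) and the
#' camera `pixel_size` (micrometres per pixel) as attributes. Within each
#' track, frames are strictly increasing with unit step (the tracker performs
#' no gap closing) and every track has at least two points.
#'
#' @param df data frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param dt frame interval in seconds (> 0).
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @return `df` with class `"spt_tracks"` and attributes `dt`, `pixel_size`.
#' @examples
#' tr <- as_tracks(data.frame(track_id = 1, frame = 0:4,
#'                            x_um = cumsum(rnorm(5, 0, 0.05)),
#'                            y_um = cumsum(rnorm(5, 0, 0.05))),
#'                 dt = 0.005, pixel_size = 0.107)
#' track_lengths(tr)
#' @export
as_tracks <- function(df, dt = 0.005, pixel_size = 0.107) {
  stopifnot(is.data.frame(df))
  need <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("track table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be a positive scalar")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be positive")
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  by_id <- split(df$frame, df$track_id)
  for (id in names(by_id)) {
    fr <- by_id[[id]]
    if (length(fr) < 2L) stop("track ", id, " has fewer than 2 points")
    if (any(diff(fr) != 1L)) stop("track ", id, " has non-consecutive frames")
  }
  structure(df, dt = dt, pixel_size = pixel_size,
            class = c("spt_tracks", "data.frame"))
}

#' @rdname as_tracks
#' @param x an `spt_tracks` object.
#' @export
track_lengths <- function(x) {
  vapply(split(seq_len(nrow(x)), x$track_id), length, integer(1))
}

#' Split a track table into per-track data frames
#' @param x an `spt_tracks` object.
#' @return named list of data frames, one per `track_id`, each keeping the
#'   `dt` and `pixel_size` attributes.
#' @export
split_tracks <- function(x) {
  dt <- attr(x, "dt"); px <- attr(x, "pixel_size")
  lapply(split(as.data.frame(x), x$track_id), function(d) {
    attr(d, "dt") <- dt; attr(d, "pixel_size") <- px
    d
  })
}

#' Read / write track tables as CSV
#'
#' The on-disk format is a plain CSV with header
#' `track_id,frame,x_um,y_um[,intensity]`; `dt` and `pixel_size` travel in
#' commented header lines (`# dt_s=`, `# pixel_size_um=`) so a file round-trips
#' losslessly.
#'
#' @param x an `spt_tracks` object.
#' @param path file path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` returns an
#'   `spt_tracks` object.
#' @export
write_tracks <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt_s=%.10g", attr(x, "dt")),
               sprintf("# pixel_size_um=%.10g", attr(x, "pixel_size"))), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param dt,pixel_size overrides used when the file carries no metadata lines.
#' @export
read_tracks <- function(path, dt = NULL, pixel_size = NULL) {
  head_lines <- readLines(path, n = 5L)
  meta <- grep("^#", head_lines, value = TRUE)
  get_meta <- function(key, fallback) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0("^# ", key, "="), "", hit[1])) else fallback
  }
  dt <- if (is.null(dt)) get_meta("dt_s", 0.005) else dt
  pixel_size <- if (is.null(pixel_size)) get_meta("pixel_size_um", 0.107) else pixel_size
  df <- utils::read.csv(path, comment.char = "#")
  as_tracks(df, dt = dt, pixel_size = pixel_size)
}

# Derive a stream seed for stage `k` from a master seed; keeps every stage of a
# pipeline reproducible from one integer while stages stay decoupled.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}
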