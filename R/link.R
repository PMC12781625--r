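#' Link per-frame detections into trajectories
#'
#' Greedy frame-to-frame nearest-neighbour linking: candidate links between
#' the detections of consecutive frames are taken in ascending distance, each
#' detection is used at most once, no link may exceed `max_jump_px`, and there
#' is no gap closing -- a track that finds no continuation ends and an
#' unmatched detection seeds a new track. Detections with fitted radius at or
#' above `max_radius_px` are excluded before linking, and only tracks longer
#' than 6 frames (`min_track_frames` points, default 7) are retained.
#'
#' @param detections data frame with columns `frame`, `x`, `y` in px (and
#'   optionally `radius_px`, `amplitude`), e.g. rows of [localize_subpixel()]
#'   output over frames.
#' @param params a [tracking_params()].
#' @param dt frame interval, s.
#' @param pixel_size um per px used to convert output positions.
#' @return an [as_tracks()] table in micrometres (empty data frame if nothing
#'   survives retention).
#' @export
link_tracks <- function(detections, params = tracking_params(),
                        dt = 0.005, pixel_size = 0.107) {
  if (nrow(detections) == 0)
    return(structure(data.frame(track_id = integer(0), frame = integer(0),
                                x_um = numeric(0), y_um = numeric(0)),
                     dt = dt, pixel_size = pixel_size,
                     class = c("spt_tracks", "data.frame")))
  if ("radius_px" %in% names(detections))
    detections <- detections[detections$radius_px < params$max_radius_px, , drop = FALSE]
  if (nrow(detections) == 0)
    return(structure(data.frame(track_id = integer(0), frame = integer(0),
                                x_um = numeric(0), y_um = numeric(0)),
                     dt = dt, pixel_size = pixel_size,
                     class = c("spt_tracks", "data.frame")))
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections, detections$frame)
  # active track state: list of (id, last x, y); grown frame by frame
  next_id <- 1L
  active <- list()
  store <- list()   # id -> data.frame rows
  open_track <- function(row, f) {
    id <- next_id; next_id <<- next_id + 1L
    store[[id]] <<- data.frame(track_id = id, frame = f, x = row$x, y = row$y)
    list(id = id, x = row$x, y = row$y)
  }
  first <- by_frame[[as.character(frames[1])]]
  for (r in seq_len(nrow(first))) active[[length(active) + 1]] <- open_track(first[r, ], frames[1])
  for (fi in seq_along(frames)[-1]) {
    f <- frames[fi]
    dets <- by_frame[[as.character(f)]]
    carried <- frames[fi] - frames[fi - 1] == 1L  # non-consecutive frames: all tracks end
    links <- NULL
    if (carried && length(active) && nrow(dets)) {
      ax <- vapply(active, `[[`, numeric(1), "x")
      ay <- vapply(active, `[[`, numeric(1), "y")
      dmat <- sqrt(outer(ax, dets$x, "-")^2 + outer(ay, dets$y, "-")^2)
      ok <- which(dmat <= params$max_jump_px, arr.ind = TRUE)
      if (nrow(ok)) {
        ok <- ok[order(dmat[ok]), , drop = FALSE]
        used_a <- logical(length(active)); used_d <- logical(nrow(dets))
        links <- matrix(0L, 0, 2)
        for (k in seq_len(nrow(ok))) {
          a <- ok[k, 1]; d <- ok[k, 2]
          if (!used_a[a] && !used_d[d]) {
            used_a[a] <- TRUE; used_d[d] <- TRUE
            links <- rbind(links, c(a, d))
          }
        }
      }
    }
    new_active <- list()
    if (!is.null(links) && nrow(links)) {
      for (k in seq_len(nrow(links))) {
        a <- links[k, 1]; d <- links[k, 2]
        tr <- active[[a]]
        store[[tr$id]] <- rbind(store[[tr$id]],
                                data.frame(track_id = tr$id, frame = f,
                                           x = dets$x[d], y = dets$y[d]))
        new_active[[length(new_active) + 1]] <- list(id = tr$id, x = dets$x[d], y = dets$y[d])
      }
      unmatched <- setdiff(seq_len(nrow(dets)), links[, 2])
    } else unmatched <- seq_len(nrow(dets))
    for (d in unmatched) new_active[[length(new_active) + 1]] <- open_track(dets[d, ], f)
    active <- new_active
  }
  keep <- Filter(function(d) nrow(d) >= params$min_track_frames, store)
  if (!length(keep))
    return(structure(data.frame(track_id = integer(0), frame = integer(0),
                                x_um = numeric(0), y_um = numeric(0)),
                     dt = dt, pixel_size = pixel_size,
                     class = c("spt_tracks", "data.frame")))
  all <- do.call(rbind, keep)
  out <- data.frame(track_id = match(all$track_id, unique(all$track_id)),
                    frame = all$frame,
                    x_um = all$x * pixel_size, y_um = all$y * pixel_size)
  as_tracks(out, dt = dt, pixel_size = pixel_size)
}

#' Track a movie end to end
#'
#' Runs the full detection pipeline on every frame -- bandpass, thresholded
#' local maxima, sub-pixel Gaussian localization -- then links detections into
#' retained trajectories.
#'
#' @param movie a `movie_stack` (see [render_movie()] / [read_movie()]).
#' @param params a [tracking_params()].
#' @return an [as_tracks()] table; attribute `detections` holds the per-frame
#'   localization table in pixel units, attribute `n_dropped` the count of
#'   failed sub-pixel fits.
#' @export
track_movie <- function(movie, params = tracking_params()) {
  stopifnot(inherits(movie, "movie_stack"))
  nt <- dim(movie$frames)[1]
  dets <- vector("list", nt)
  dropped <- 0L
  for (i in seq_len(nt)) {
    fr <- movie$frames[i, , ]
    bp <- bandpass_filter(fr, params$bandpass_low_px, params$bandpass_high_px)
    cand <- detect_spots(bp, params)
    if (nrow(cand) == 0) next
    loc <- localize_subpixel(fr, cand, params$fit_window_px)
    dropped <- dropped + attr(loc, "n_dropped")
    if (nrow(loc)) {
      loc$frame <- movie$frame_index[i]
      dets[[i]] <- loc
    }
  }
  dets <- do.call(rbind, dets[!vapply(dets, is.null, logical(1))])
  if (is.null(dets)) dets <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0))
  out <- link_tracks(dets, params, dt = movie$dt, pixel_size = movie$pixel_size)
  attr(out, "detections") <- dets
  attr(out, "n_dropped") <- dropped
  out
}
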