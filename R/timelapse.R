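#' Per-frame PGCC and non-PGCC counts from a time-lapse sequence
#'
#' Time-lapse experiments do not use viability staining (it affects cell
#' viability over days); nuclei are imaged through a transfected nuclear-RFP
#' channel, segmentation runs on that channel, every non-debris object is
#' treated as live, and PGCC calling is by area as usual.
#'
#' @param frames list of [mc_field]s, each with an `rfp` channel and a
#'   `timestamp` (minutes); must be time-ordered.
#' @param params optional [seg_params].
#' @param cparams a [class_params].
#' @return a `pgcc_timeseries` data.frame with columns `time`,
#'   `n_non_pgcc`, `n_pgcc`; per-frame record tables in attribute
#'   `"frame_records"`.
#' @export
count_frames <- function(frames, params = NULL, cparams = class_params()) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  times <- vapply(frames, function(f) {
    if (!inherits(f, "mc_field")) stop("frames must be mc_field objects")
    if (!"rfp" %in% names(f$channels))
      stop("frame '", f$field_id, "' has no rfp channel")
    as.numeric(f$timestamp %||% NA_real_)
  }, 0)
  if (anyNA(times)) stop("every frame needs a timestamp (minutes)")
  if (any(diff(times) <= 0)) stop("frame timestamps must be strictly increasing")
  recs <- lapply(frames, function(f) {
    p <- params %||% seg_params(magnification = f$magnification)
    r <- segment_field(f, p)
    classify_pgcc(r, cparams, magnification = f$magnification,
                  assume_live = TRUE)
  })
  ts <- data.frame(
    time = times,
    n_non_pgcc = vapply(recs, function(r) sum(r$ploidy_class == "non_pgcc"), 0L),
    n_pgcc = vapply(recs, function(r) sum(r$ploidy_class == "pgcc"), 0L))
  attr(ts, "frame_records") <- recs
  attr(ts, "field_id") <- frames[[1]]$field_id
  class(ts) <- c("pgcc_timeseries", "data.frame")
  ts
}

#' Plot a PGCC time series
#'
#' Non-PGCC counts on the left axis (black), PGCC counts on the right axis
#' (red), time in hours.
#'
#' @param x a `pgcc_timeseries`.
#' @param ... passed to the base plot call.
#' @export
plot.pgcc_timeseries <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  h <- x$time / 60
  graphics::plot(h, x$n_non_pgcc, type = "l", xlab = "time (h)",
                 ylab = "non-PGCCs", ...)
  graphics::par(new = TRUE)
  graphics::plot(h, x$n_pgcc, type = "l", col = "red3", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4, col = "red3", col.axis = "red3")
  graphics::mtext("PGCCs", side = 4, line = 2.5, col = "red3")
  invisible(x)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour assignment frame to frame: at each frame, the
#' globally closest (track, detection) pairs are matched in increasing
#' distance order, assignments farther than `max_disp` rejected. Unmatched
#' tracks persist up to `max_gap_frames` frames and are then marked lost;
#' unmatched detections start new tracks. Ties are broken by lower track id
#' then lower detection label, so linking is deterministic.
#'
#' @param frame_records list of per-frame record tables (as produced by
#'   [count_frames], attribute `"frame_records"`), debris excluded
#'   automatically.
#' @param times frame times (minutes), one per frame.
#' @param max_disp_um maximum allowed centroid displacement between
#'   consecutive linked frames, in micrometres when `pixel_size_um` is
#'   given, else in pixels.
#' @param max_gap_frames frames a track may go undetected before it is lost.
#' @param pixel_size_um physical pixel size; `NULL` means pixel units.
#' @return list of tracks: `list(track_id, status, frames)` where `frames`
#'   is a data.frame (`time`, `row`, `col`, `area_px`).
#' @export
link_tracks <- function(frame_records, times, max_disp_um,
                        max_gap_frames = 2L, pixel_size_um = NULL) {
  stopifnot(length(frame_records) == length(times))
  # with unknown pixel size the displacement bound is interpreted in px
  max_disp_px <- if (is.null(pixel_size_um)) max_disp_um else
    max_disp_um / pixel_size_um
  tracks <- list(); active <- integer(0)  # indices into tracks
  last_pos <- matrix(numeric(0), 0, 2); last_seen <- integer(0)
  new_track <- function(t, r) {
    tracks[[length(tracks) + 1L]] <<- list(
      track_id = length(tracks) + 1L, status = "ongoing",
      frames = data.frame(time = t, row = r$row, col = r$col,
                          area_px = r$area_px))
    length(tracks)
  }
  for (fi in seq_along(frame_records)) {
    det <- frame_records[[fi]]
    det <- det[det$ploidy_class != "debris", , drop = FALSE]
    det <- det[order(det$label), , drop = FALSE]
    nd <- nrow(det); na <- length(active)
    matched_det <- rep(FALSE, nd); matched_tr <- rep(FALSE, na)
    if (nd > 0L && na > 0L) {
      dmat <- sqrt(outer(last_pos[, 1], det$row, "-")^2 +
                     outer(last_pos[, 2], det$col, "-")^2)
      cand <- which(dmat <= max_disp_px, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand], cand[, 1], cand[, 2])
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!matched_tr[i] && !matched_det[j]) {
            matched_tr[i] <- TRUE; matched_det[j] <- TRUE
            ti <- active[i]
            tracks[[ti]]$frames <- rbind(
              tracks[[ti]]$frames,
              data.frame(time = times[fi], row = det$row[j],
                         col = det$col[j], area_px = det$area_px[j]))
            last_pos[i, ] <- c(det$row[j], det$col[j])
            last_seen[i] <- fi
          }
        }
      }
    }
    # expire stale tracks
    keep <- rep(TRUE, na)
    for (i in seq_len(na)) {
      if (!matched_tr[i] && fi - last_seen[i] >= max_gap_frames + 1L) {
        tracks[[active[i]]]$status <- "lost"
        keep[i] <- FALSE
      }
    }
    active <- active[keep]; last_pos <- last_pos[keep, , drop = FALSE]
    last_seen <- last_seen[keep]
    # new tracks for unmatched detections
    if (nd > 0L) {
      for (j in which(!matched_det)) {
        ti <- new_track(times[fi], det[j, ])
        active <- c(active, ti)
        last_pos <- rbind(last_pos, c(det$row[j], det$col[j]))
        last_seen <- c(last_seen, fi)
      }
    }
  }
  tracks
}

#' Detect non-PGCC to PGCC transitions along tracks
#'
#' A transition is recorded when a track's area crosses from at-or-below the
#' threshold to above it and stays above for at least `persistence_frames`
#' consecutive frames (debouncing single-frame flicker at the threshold).
#' At most one event per track; transitioned tracks get
#' `status = "transitioned"`.
#'
#' @param tracks output of [link_tracks].
#' @param threshold_px resolved pixel-area threshold (see
#'   [threshold_for_magnification]).
#' @param persistence_frames minimum consecutive super-threshold frames.
#' @return list of `tracks` (statuses updated) and `events` (data.frame
#'   `track_id`, `time` of the first super-threshold frame).
#' @export
detect_transitions <- function(tracks, threshold_px, persistence_frames = 3L) {
  events <- list()
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    above <- tr$frames$area_px > threshold_px
    n <- length(above)
    if (n < persistence_frames + 1L) next
    for (i in 2:(n - persistence_frames + 1L)) {
      if (!above[i - 1L] && all(above[i:(i + persistence_frames - 1L)])) {
        events[[length(events) + 1L]] <-
          data.frame(track_id = tr$track_id, time = tr$frames$time[i])
        tracks[[k]]$status <- "transitioned"
        break
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(track_id = integer(0), time = numeric(0))
  list(tracks = tracks, events = events)
}
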