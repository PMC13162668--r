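#' Ethogram behaviors
#'
#' The four-class ethogram used throughout: lying, standing, eating,
#' drinking.
#'
#' @return Character vector of behavior labels.
#' @export
behaviors <- function() c("lying", "standing", "eating", "drinking")

#' Feeding schedule
#'
#' Daily feed-distribution windows; feeder occupancy counts as eating
#' only inside a window (pigs explore an empty feeder outside them).
#' Times are seconds on the same axis as frame timestamps, windows are
#' half-open `[start, end)`.
#'
#' @param start,end window bounds, seconds. The default encodes the
#'   twice-daily feed distribution at 08:00 and 15:00, with feed
#'   remaining available in the trough for about five hours after each.
#' @return Data frame with columns `start`, `end`.
#' @export
feeding_schedule <- function(start = c(8 * 3600, 15 * 3600),
                             end = start + 5 * 3600) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) return(data.frame(start = numeric(), end = numeric()))
  if (any(start >= end)) stop("window start must precede end")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (any(utils::head(end, -1) > utils::tail(start, -1)))
    stop("feeding windows must not overlap")
  data.frame(start = start, end = end)
}

#' Is a timestamp inside a feeding window?
#'
#' @param timestamp seconds. Vectorised.
#' @param schedule see [feeding_schedule()].
#' @return Logical vector.
#' @export
in_feeding_window <- function(timestamp, schedule) {
  if (nrow(schedule) == 0) return(rep(FALSE, length(timestamp)))
  vapply(timestamp, function(t) any(t >= schedule$start & t < schedule$end),
         logical(1))
}

zone_rect <- function(zone) {
  if (is.data.frame(zone)) {
    stopifnot(nrow(zone) == 1)
    zone <- c(x0 = zone$x0, y0 = zone$y0, x1 = zone$x1, y1 = zone$y1)
  }
  if (zone[["x1"]] <= zone[["x0"]] || zone[["y1"]] <= zone[["y0"]])
    stop("zero-area zone")
  zone
}

#' Zone occupancy
#'
#' Fraction of a zone's area covered by the union of the detection boxes:
#' `OC = area(union of (box intersect zone)) / area(zone)`. Duplicated or
#' overlapping boxes do not count twice.
#'
#' @param detections detections data frame with pixel corners.
#' @param zone one-row zones data frame or a [px_rect()].
#' @return Occupancy fraction in `[0, 1]`.
#' @export
zone_occupancy <- function(detections, zone) {
  z <- zone_rect(zone)
  if (nrow(detections) == 0) return(0)
  x0 <- pmax(detections$x0, z[["x0"]]); y0 <- pmax(detections$y0, z[["y0"]])
  x1 <- pmin(detections$x1, z[["x1"]]); y1 <- pmin(detections$y1, z[["y1"]])
  union_rect_area(x0, y0, x1, y1) / rect_area(z)
}

# Vectorised behavior assignment over a multi-frame detections table.
# Lying detections are always lying; a standing detection becomes eating
# (feeder, inside a feeding window) or drinking (drinker, any time) when
# the occupancy rule is met; inactive feeders never produce eating.
assign_behaviors <- function(detections, zones, schedule,
                             occupancy_threshold = 0.5,
                             rule = c("zone", "detection")) {
  rule <- match.arg(rule)
  n <- nrow(detections)
  behavior <- detections$class
  if (n == 0) return(behavior)
  standing <- which(detections$class == "standing")
  if (length(standing) == 0 || nrow(zones) == 0) return(behavior)

  ts <- detections$timestamp
  if (is.null(ts)) ts <- rep(0, n)
  fed <- in_feeding_window(ts, schedule)
  frame <- detections$frame_index
  if (is.null(frame)) frame <- rep(0L, n)

  sx0 <- detections$x0[standing]; sy0 <- detections$y0[standing]
  sx1 <- detections$x1[standing]; sy1 <- detections$y1[standing]
  box_area <- (sx1 - sx0) * (sy1 - sy0)

  best_frac <- rep(-1, length(standing))
  best_role <- rep(NA_character_, length(standing))

  for (k in seq_len(nrow(zones))) {
    z <- zone_rect(zones[k, ])
    role <- zones$role[k]
    if (role == "inactive_feeder") next
    inter <- intersection_area_vec(sx0, sy0, sx1, sy1, z)
    frac_det <- inter / box_area
    if (rule == "detection") {
      qual <- frac_det >= occupancy_threshold
    } else {
      qual <- rep(FALSE, length(standing))
      touching <- which(inter > 0)
      if (length(touching) > 0) {
        for (rows in split(touching, frame[standing][touching])) {
          cx0 <- pmax(sx0[rows], z[["x0"]]); cy0 <- pmax(sy0[rows], z[["y0"]])
          cx1 <- pmin(sx1[rows], z[["x1"]]); cy1 <- pmin(sy1[rows], z[["y1"]])
          oc <- union_rect_area(cx0, cy0, cx1, cy1) / rect_area(z)
          if (oc >= occupancy_threshold) qual[rows] <- TRUE
        }
      }
    }
    if (role == "feeder") qual <- qual & fed[standing]
    upd <- qual & (frac_det > best_frac |
                     (frac_det == best_frac & role == "drinker" &
                        !is.na(best_role) & best_role == "feeder"))
    best_frac[upd] <- frac_det[upd]
    best_role[upd] <- role
  }
  behavior[standing[!is.na(best_role) & best_role == "feeder"]] <- "eating"
  behavior[standing[!is.na(best_role) & best_role == "drinker"]] <- "drinking"
  behavior
}

#' Classify one frame's detections into behaviors
#'
#' Lying detections stay lying. A standing detection whose box meets the
#' occupancy rule for a feeder (inside a feeding window) becomes eating;
#' for a drinker (any time), drinking; otherwise it remains standing.
#' Under the default `"zone"` rule the occupancy of a zone is the union
#' occupancy of all standing boxes ([zone_occupancy()]) and must reach
#' `occupancy_threshold`; under the `"detection"` rule each box qualifies
#' on its own when at least that fraction of the *box* lies in the zone.
#' A detection meeting the rule for both a feeder and a drinker goes to
#' the zone with the larger per-detection overlap fraction, ties to the
#' drinker.
#'
#' @param detections detections data frame for one frame (already
#'   confidence-filtered, two-class scheme).
#' @param zones zones data frame (see [read_zones()]).
#' @param schedule see [feeding_schedule()].
#' @param timestamp frame time, seconds.
#' @param occupancy_threshold minimum occupancy fraction (default 0.5).
#' @param rule `"zone"` (default) or `"detection"`, see above.
#' @param meta optional [video_meta()]; when it carries `n_frames` the
#'   timestamp is checked against the video span.
#' @return List with `counts` (named integer vector over the ethogram)
#'   and `assignment` (the detections with a `behavior` column).
#' @export
classify_frame <- function(detections, zones, schedule, timestamp,
                           occupancy_threshold = 0.5,
                           rule = c("zone", "detection"), meta = NULL) {
  if (!is.null(meta) && !is.null(meta$n_frames)) {
    span <- meta$n_frames / meta$fps
    if (timestamp < 0 || timestamp > span)
      stop("timestamp ", timestamp, " outside video span [0, ", span, "]")
  }
  d <- detections
  d$timestamp <- rep(timestamp, nrow(d))
  d$behavior <- assign_behaviors(d, zones, schedule, occupancy_threshold, rule)
  counts <- vapply(behaviors(), function(b) sum(d$behavior == b), integer(1))
  list(counts = counts, assignment = d)
}

#' Infer per-frame activity over a whole video
#'
#' @param frames multi-frame detections data frame with `frame_index` and
#'   `timestamp` columns (e.g. from [read_label_dir()]), already
#'   confidence-filtered.
#' @param zones zones data frame.
#' @param schedule see [feeding_schedule()].
#' @param meta [video_meta()]; `n_frames` (or the largest frame index)
#'   fixes the video span so frames without detections count as empty.
#' @inheritParams classify_frame
#' @return List with `activity` (data frame `frame_index, timestamp,
#'   lying, standing, eating, drinking`), `totals` (per-behavior frame
#'   counts summed over frames) and `assignment` (per-detection behavior).
#' @export
infer_video <- function(frames, zones, schedule, meta = video_meta(),
                        occupancy_threshold = 0.5,
                        rule = c("zone", "detection")) {
  rule <- match.arg(rule)
  if (nrow(frames) > 0) {
    ts <- tapply(frames$timestamp, frames$frame_index, function(x) length(unique(x)))
    if (any(ts > 1)) stop("duplicated frame_index with conflicting timestamps")
  }
  n_frames <- meta$n_frames
  if (is.null(n_frames))
    n_frames <- if (nrow(frames) > 0) max(frames$frame_index) + 1L else 0L
  frames$behavior <- assign_behaviors(frames, zones, schedule,
                                      occupancy_threshold, rule)
  t_offset <- if (nrow(frames) > 0)
    frames$timestamp[1] - frames$frame_index[1] / meta$fps else 0
  idx <- 0:(n_frames - 1)
  activity <- data.frame(frame_index = idx,
                         timestamp = t_offset + idx / meta$fps)
  for (b in behaviors()) {
    cnt <- integer(n_frames)
    rows <- frames$frame_index[frames$behavior == b]
    if (length(rows) > 0) {
      tab <- table(rows)
      cnt[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    activity[[b]] <- cnt
  }
  totals <- vapply(behaviors(), function(b) sum(activity[[b]]), numeric(1))
  list(activity = activity, totals = totals, assignment = frames)
}
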