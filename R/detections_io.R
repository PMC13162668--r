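#' Video metadata
#'
#' @param width,height frame dimensions in pixels (defaults 640 x 360).
#' @param fps native capture rate, frames per second (default 25).
#' @param n_frames number of frames, optional.
#' @return List of class `video_meta`.
#' @export
video_meta <- function(width = 640, height = 360, fps = 25, n_frames = NULL) {
  stopifnot(width > 0, height > 0, fps > 0)
  if (!is.null(n_frames)) stopifnot(n_frames > 0)
  structure(list(width = width, height = height, fps = fps,
                 n_frames = n_frames),
            class = "video_meta")
}

#' Default ethogram class maps
#'
#' The detector emits the two-class scheme (eating and drinking are
#' merged into standing and recovered later from zone occupancy); ground
#' truth may use the four-class scheme.
#'
#' @return Named character vector mapping class id (as name) to label.
#' @export
two_class_map <- function() c(`0` = "lying", `1` = "standing")

#' @rdname two_class_map
#' @export
four_class_map <- function() {
  c(`0` = "lying", `1` = "standing", `2` = "eating", `3` = "drinking")
}

empty_detections <- function() {
  data.frame(class_id = integer(), class = character(),
             cx = numeric(), cy = numeric(), w = numeric(), h = numeric(),
             conf = numeric(),
             x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
             stringsAsFactors = FALSE)
}

#' Parse one normalized label line
#'
#' A line holds `class_id cx cy w h [conf]`: the box centre and size as
#' fractions of the image dimensions, optionally followed by a detection
#' confidence. Pixel corners are derived with the top-left-origin
#' convention and rounded to the nearest integer; boxes extending past
#' the image border are clipped with a warning.
#'
#' @param line character scalar.
#' @param meta [video_meta()] describing the image.
#' @param class_map named vector mapping class ids to labels; unknown ids
#'   are kept with label `"unknown_<id>"` and a warning.
#' @param line_no line number used in error messages.
#' @return One-row detections data frame (normalized fields plus pixel
#'   corners `x0, y0, x1, y1`).
#' @export
parse_label_line <- function(line, meta = video_meta(),
                             class_map = two_class_map(), line_no = NA) {
  fields <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  where <- if (is.na(line_no)) "" else paste0(" (line ", line_no, ")")
  if (!length(fields) %in% c(5, 6))
    stop("malformed label line", where, ": expected 5 or 6 fields, got ",
         length(fields))
  vals <- suppressWarnings(as.numeric(fields))
  if (any(is.na(vals)))
    stop("malformed label line", where, ": non-numeric field")
  cx <- vals[2]; cy <- vals[3]; w <- vals[4]; h <- vals[5]
  if (cx < 0 || cx > 1 || cy < 0 || cy > 1)
    stop("invalid label line", where, ": centre outside [0, 1]")
  if (w <= 0 || w > 1 || h <= 0 || h > 1)
    stop("invalid label line", where, ": size outside (0, 1]")
  conf <- if (length(vals) == 6) vals[6] else NA_real_
  if (!is.na(conf) && (conf < 0 || conf > 1))
    stop("invalid label line", where, ": confidence outside [0, 1]")
  id <- as.integer(vals[1])
  label <- unname(class_map[as.character(id)])
  if (is.na(label)) {
    warning("unknown class id ", id, where, "; kept as unknown_", id)
    label <- paste0("unknown_", id)
  }
  px <- denormalize_box(cx, cy, w, h, meta)
  out <- data.frame(class_id = id, class = label,
                    cx = cx, cy = cy, w = w, h = h, conf = conf,
                    stringsAsFactors = FALSE)
  cbind(out, px)
}

#' Convert a normalized box to pixel corners
#'
#' @param cx,cy,w,h normalized centre and size (fractions). Vectorised.
#' @param meta [video_meta()].
#' @return Data frame `x0, y0, x1, y1` (pixels, rounded to integers and
#'   clipped to the image with a warning when they extend past it).
#' @export
denormalize_box <- function(cx, cy, w, h, meta = video_meta()) {
  x0 <- round((cx - w / 2) * meta$width)
  x1 <- round((cx + w / 2) * meta$width)
  y0 <- round((cy - h / 2) * meta$height)
  y1 <- round((cy + h / 2) * meta$height)
  if (any(x0 < 0 | y0 < 0 | x1 > meta$width | y1 > meta$height)) {
    warning("box extends past image border; clipped")
    x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
    x1 <- pmin(x1, meta$width); y1 <- pmin(y1, meta$height)
  }
  if (any(x1 <= x0 | y1 <= y0))
    stop("box empty after clipping to the image")
  data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Read a YOLO-format label file
#'
#' @param path label file, one line per detection.
#' @inheritParams parse_label_line
#' @return Detections data frame (zero rows for an empty file).
#' @export
read_labels <- function(path, meta = video_meta(), class_map = two_class_map()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_detections())
  rows <- lapply(seq_along(lines), function(i) {
    tryCatch(parse_label_line(lines[i], meta, class_map, line_no = i),
             error = function(e) stop("in ", path, ": ", conditionMessage(e)))
  })
  do.call(rbind, rows)
}

#' Read a directory of per-frame label files
#'
#' Files are named `<frame_index>.txt`; timestamps are derived as
#' `frame_index / fps`.
#'
#' @param dir directory containing label files.
#' @inheritParams parse_label_line
#' @return Detections data frame with `frame_index` and `timestamp`
#'   columns prepended.
#' @export
read_label_dir <- function(dir, meta = video_meta(), class_map = two_class_map()) {
  files <- list.files(dir, pattern = "^[0-9]+\\.txt$", full.names = TRUE)
  if (length(files) == 0) stop("no label files found in ", dir)
  idx <- as.integer(sub("\\.txt$", "", basename(files)))
  files <- files[order(idx)]; idx <- sort(idx)
  if (anyDuplicated(idx)) stop("duplicated frame index in ", dir)
  rows <- lapply(seq_along(files), function(i) {
    d <- read_labels(files[i], meta, class_map)
    if (nrow(d) == 0) return(NULL)
    cbind(data.frame(frame_index = idx[i], timestamp = idx[i] / meta$fps), d)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- cbind(data.frame(frame_index = integer(), timestamp = numeric()),
                 empty_detections())
  out
}

#' Write detections as YOLO-format label lines
#'
#' Inverse of [parse_label_line()] up to 6-decimal rounding; detections
#' with a confidence yield 6-field lines, ground truth 5-field lines.
#'
#' @param detections detections data frame.
#' @param path optional file to write to.
#' @return Character vector of label lines (invisibly when `path` given).
#' @export
write_labels <- function(detections, path = NULL) {
  lines <- character(0)
  if (nrow(detections) > 0) {
    lines <- vapply(seq_len(nrow(detections)), function(i) {
      d <- detections[i, ]
      base <- sprintf("%d %.6f %.6f %.6f %.6f", d$class_id, d$cx, d$cy, d$w, d$h)
      if (!is.na(d$conf)) paste(base, sprintf("%.6f", d$conf)) else base
    }, character(1))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Filter detections by confidence
#'
#' Keeps detections with confidence at or above the threshold (boxes with
#' lower values are removed). Ground-truth boxes without a confidence
#' pass untouched; input order is preserved.
#'
#' @param detections detections data frame.
#' @param threshold confidence threshold in `[0, 1]` (default 0.70).
#' @return Filtered detections data frame.
#' @export
filter_confidence <- function(detections, threshold = 0.70) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- is.na(detections$conf) | detections$conf >= threshold
  detections[keep, , drop = FALSE]
}

#' Read a zone CSV
#'
#' Expected columns: `zone_id, role, x0, y0, x1, y1` with pixel corners
#' and role one of feeder, drinker, inactive_feeder.
#'
#' @param path CSV file path.
#' @param meta optional [video_meta()]; when given, zones are checked to
#'   lie inside the image.
#' @return Zones data frame.
#' @export
read_zones <- function(path, meta = NULL) {
  z <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("zone_id", "role", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(z)))
    stop("zone file ", path, " must have columns ", paste(need, collapse = ", "))
  validate_zones(z, meta)
}

#' Validate a zones data frame
#'
#' @param zones data frame with `zone_id, role, x0, y0, x1, y1`.
#' @param meta optional [video_meta()] for bounds checking.
#' @return `zones`, validated.
#' @export
validate_zones <- function(zones, meta = NULL) {
  roles <- c("feeder", "drinker", "inactive_feeder")
  bad <- setdiff(zones$role, roles)
  if (length(bad) > 0)
    stop("unknown zone role(s): ", paste(bad, collapse = ", "))
  if (any(zones$x1 <= zones$x0 | zones$y1 <= zones$y0))
    stop("degenerate zone rectangle")
  if (anyDuplicated(zones$zone_id)) stop("duplicated zone_id")
  if (!is.null(meta) &&
      any(zones$x0 < 0 | zones$y0 < 0 |
          zones$x1 > meta$width | zones$y1 > meta$height))
    stop("zone rectangle outside image bounds")
  zones
}
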