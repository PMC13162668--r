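# Independent oracles used across the suite. They deliberately share no
# code with the package: geometry is checked by per-pixel rasterization,
# matching by exhaustive assignment, summaries by streaming one-pass
# recomputation.

# Pixel-count area of the union of boxes clipped to a window, by marking
# cells of an integer raster (half-open [x0,x1) x [y0,y1) convention).
raster_union_area <- function(boxes, window) {
  w <- window[["x1"]] - window[["x0"]]
  h <- window[["y1"]] - window[["y0"]]
  grid <- matrix(FALSE, nrow = h, ncol = w)
  for (i in seq_len(nrow(boxes))) {
    x0 <- max(boxes$x0[i], window[["x0"]]) - window[["x0"]]
    x1 <- min(boxes$x1[i], window[["x1"]]) - window[["x0"]]
    y0 <- max(boxes$y0[i], window[["y0"]]) - window[["y0"]]
    y1 <- min(boxes$y1[i], window[["y1"]]) - window[["y0"]]
    if (x1 <= x0 || y1 <= y0) next
    grid[(y0 + 1):y1, (x0 + 1):x1] <- TRUE
  }
  sum(grid)
}

raster_occupancy <- function(boxes, zone) {
  zr <- c(x0 = zone$x0, y0 = zone$y0, x1 = zone$x1, y1 = zone$y1)
  raster_union_area(boxes, zr) / ((zone$x1 - zone$x0) * (zone$y1 - zone$y0))
}

# Random integer-coordinate pixel boxes inside a width x height image.
random_boxes <- function(n, width = 640, height = 360,
                         min_size = 10, max_size = 150) {
  w <- sample(min_size:max_size, n, replace = TRUE)
  h <- sample(min_size:max_size, n, replace = TRUE)
  x0 <- vapply(w, function(wi) sample(0:(width - wi), 1), numeric(1))
  y0 <- vapply(h, function(hi) sample(0:(height - hi), 1), numeric(1))
  data.frame(x0 = x0, y0 = y0, x1 = x0 + w, y1 = y0 + h)
}

# Maximum number of prediction-truth pairs matchable with same class and
# IoU >= threshold, by exhaustive search over assignments (<= 4 a side).
optimal_match_count <- function(predictions, truths, iou_threshold) {
  np <- nrow(predictions); nt <- nrow(truths)
  if (np == 0 || nt == 0) return(0L)
  ok <- matrix(FALSE, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    if (predictions$class[i] != truths$class[j]) next
    ok[i, j] <- penwatch::iou(
      c(x0 = predictions$x0[i], y0 = predictions$y0[i],
        x1 = predictions$x1[i], y1 = predictions$y1[i]),
      c(x0 = truths$x0[j], y0 = truths$y0[j],
        x1 = truths$x1[j], y1 = truths$y1[j])) >= iou_threshold
  }
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    recurse(i + 1, used, count)  # leave prediction i unmatched
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1, used, count + 1L)
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nt), 0L)
  best
}

# One detections row in package shape from pixel corners.
det_row <- function(x0, y0, x1, y1, class = "standing", conf = NA_real_,
                    frame_index = NULL, timestamp = NULL,
                    meta = penwatch::video_meta()) {
  d <- data.frame(class_id = ifelse(class == "lying", 0L, 1L), class = class,
                  cx = (x0 + x1) / 2 / meta$width,
                  cy = (y0 + y1) / 2 / meta$height,
                  w = (x1 - x0) / meta$width, h = (y1 - y0) / meta$height,
                  conf = conf, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                  stringsAsFactors = FALSE)
  if (!is.null(frame_index))
    d <- cbind(data.frame(frame_index = frame_index,
                          timestamp = timestamp), d)
  d
}

test_zones <- function() {
  data.frame(zone_id = c("feeder_main", "drinker_1", "feeder_unused"),
             role = c("feeder", "drinker", "inactive_feeder"),
             x0 = c(40, 520, 260), y0 = c(20, 20, 300),
             x1 = c(140, 560, 360), y1 = c(70, 50, 350),
             stringsAsFactors = FALSE)
}
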