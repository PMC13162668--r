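#' Axis-aligned pixel rectangle
#'
#' Rectangles follow the image convention: origin at the top-left corner,
#' x increasing rightwards, y increasing downwards, and half-open pixel
#' ranges `[x0, x1) x [y0, y1)` so that `x1 - x0` is the width in pixels.
#'
#' @param x0,y0 top-left corner (pixels).
#' @param x1,y1 bottom-right corner (pixels), exclusive.
#' @return Named numeric vector `c(x0, y0, x1, y1)`.
#' @export
px_rect <- function(x0, y0, x1, y1) {
  r <- c(x0 = as.numeric(x0), y0 = as.numeric(y0),
         x1 = as.numeric(x1), y1 = as.numeric(y1))
  if (any(!is.finite(r))) stop("rectangle coordinates must be finite")
  if (r["x1"] <= r["x0"] || r["y1"] <= r["y0"])
    stop("degenerate rectangle: x1 > x0 and y1 > y0 required")
  r
}

rect_area <- function(r) (r[["x1"]] - r[["x0"]]) * (r[["y1"]] - r[["y0"]])

#' Intersection area of two pixel rectangles
#'
#' @param a,b rectangles from [px_rect()] (or any numeric vector with
#'   elements `x0, y0, x1, y1`).
#' @return Overlap area in px^2; 0 when disjoint.
#' @export
intersection_area <- function(a, b) {
  w <- min(a[["x1"]], b[["x1"]]) - max(a[["x0"]], b[["x0"]])
  h <- min(a[["y1"]], b[["y1"]]) - max(a[["y0"]], b[["y0"]])
  if (w <= 0 || h <= 0) return(0)
  w * h
}

#' Intersection over union of two pixel rectangles
#'
#' @inheritParams intersection_area
#' @return IoU in `[0, 1]`: 1 for identical boxes, 0 when disjoint.
#' @export
iou <- function(a, b) {
  inter <- intersection_area(a, b)
  union <- rect_area(a) + rect_area(b) - inter
  inter / union
}

# Vectorised intersection areas between one rectangle and box columns.
intersection_area_vec <- function(x0, y0, x1, y1, r) {
  w <- pmin(x1, r[["x1"]]) - pmax(x0, r[["x0"]])
  h <- pmin(y1, r[["y1"]]) - pmax(y0, r[["y0"]])
  pmax(w, 0) * pmax(h, 0)
}

# Exact union area of a set of axis-aligned rectangles by slab sweep:
# cut the x axis at every rectangle edge and, within each slab, merge the
# y intervals of the rectangles spanning it.
union_rect_area <- function(x0, y0, x1, y1) {
  keep <- x1 > x0 & y1 > y0
  x0 <- x0[keep]; y0 <- y0[keep]; x1 <- x1[keep]; y1 <- y1[keep]
  n <- length(x0)
  if (n == 0) return(0)
  if (n == 1) return((x1 - x0) * (y1 - y0))
  xs <- sort(unique(c(x0, x1)))
  total <- 0
  for (i in seq_len(length(xs) - 1)) {
    xa <- xs[i]; xb <- xs[i + 1]
    active <- x0 <= xa & x1 >= xb
    if (!any(active)) next
    total <- total + (xb - xa) * union_interval_length(y0[active], y1[active])
  }
  total
}

# Total length of the union of 1-d intervals [a, b).
union_interval_length <- function(a, b) {
  o <- order(a)
  a <- a[o]; b <- b[o]
  total <- 0
  cur_a <- a[1]; cur_b <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] > cur_b) {
      total <- total + (cur_b - cur_a)
      cur_a <- a[i]; cur_b <- b[i]
    } else if (b[i] > cur_b) {
      cur_b <- b[i]
    }
  }
  total + (cur_b - cur_a)
}
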