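`%||%` <- function(a, b) if (is.null(a)) b else a

# Pairwise IoU between rows of two corner matrices (x0, y0, x1, y1).
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ix0 <- outer(a[, 1], b[, 1], pmax); iy0 <- outer(a[, 2], b[, 2], pmax)
  ix1 <- outer(a[, 3], b[, 3], pmin); iy1 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(ix1 - ix0, 0) * pmax(iy1 - iy0, 0)
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(area_a, area_b, `+`) - inter)
}

corners <- function(d) cbind(d$x0, d$y0, d$x1, d$y1)

# Greedy matching within one frame for one class: predictions in order of
# descending confidence each consume the unmatched truth with the best
# IoU at or above the threshold. Returns per-prediction TP flag (in the
# original row order of `p`) and the matched truth index (NA when FP).
greedy_frame_match <- function(p_boxes, p_conf, t_boxes, iou_threshold) {
  np <- nrow(p_boxes); nt <- nrow(t_boxes)
  tp <- logical(np); matched_truth <- rep(NA_integer_, np)
  if (np == 0 || nt == 0)
    return(list(tp = tp, truth = matched_truth))
  iom <- iou_matrix(p_boxes, t_boxes)
  taken <- rep(FALSE, nt)
  for (i in order(-p_conf)) {
    ious <- iom[i, ]; ious[taken] <- -1
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      taken[best] <- TRUE
      tp[i] <- TRUE
      matched_truth[i] <- best
    }
  }
  list(tp = tp, truth = matched_truth)
}

#' Match predicted detections to ground truth
#'
#' Greedy protocol, frame by frame and class by class: predictions are
#' visited in order of descending confidence; each is a true positive if
#' an unmatched ground-truth box of the same class in the same frame
#' overlaps it with IoU at or above the threshold (the best-overlapping
#' one is consumed). Remaining predictions are false positives, remaining
#' truths false negatives.
#'
#' @param predictions detections data frame (pixel corners, `class`,
#'   `conf`; optional `frame_index`).
#' @param truths ground-truth data frame (same columns, `conf` ignored).
#' @param iou_threshold minimum IoU for a match, in (0, 1].
#' @return List with `per_class` (data frame `class, tp, fp, fn`) and
#'   `matches` (data frame `pred, truth, class, iou` of matched row
#'   indices into the inputs).
#' @export
match_detections <- function(predictions, truths, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]")
  classes <- sort(unique(c(predictions$class, truths$class)))
  pf <- predictions$frame_index %||% rep(0L, nrow(predictions))
  tf <- truths$frame_index %||% rep(0L, nrow(truths))
  conf <- predictions$conf %||% rep(1, nrow(predictions))
  conf[is.na(conf)] <- 1
  pb <- corners(predictions); tb <- corners(truths)
  matches <- list()
  per_class <- list()
  for (cl in classes) {
    pi_cl <- which(predictions$class == cl)
    ti_cl <- which(truths$class == cl)
    tp_total <- 0L
    for (f in unique(c(pf[pi_cl], tf[ti_cl]))) {
      pi <- pi_cl[pf[pi_cl] == f]
      ti <- ti_cl[tf[ti_cl] == f]
      m <- greedy_frame_match(pb[pi, , drop = FALSE], conf[pi],
                              tb[ti, , drop = FALSE], iou_threshold)
      hit <- which(m$tp)
      tp_total <- tp_total + length(hit)
      if (length(hit) > 0) {
        iom <- iou_matrix(pb[pi[hit], , drop = FALSE],
                          tb[ti, , drop = FALSE])
        matches[[length(matches) + 1]] <-
          data.frame(pred = pi[hit], truth = ti[m$truth[hit]], class = cl,
                     iou = iom[cbind(seq_along(hit), m$truth[hit])],
                     stringsAsFactors = FALSE)
      }
    }
    per_class[[cl]] <- data.frame(class = cl, tp = tp_total,
                                  fp = length(pi_cl) - tp_total,
                                  fn = length(ti_cl) - tp_total,
                                  stringsAsFactors = FALSE)
  }
  matches <- if (length(matches) > 0) do.call(rbind, matches) else
    data.frame(pred = integer(), truth = integer(),
               class = character(), iou = numeric(), stringsAsFactors = FALSE)
  list(per_class = do.call(rbind, unname(per_class)), matches = matches)
}

#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)`; `R = TP / (TP + FN)`. A degenerate 0/0 ratio is
#' reported as 0 with attribute `degenerate = TRUE` rather than NaN.
#'
#' @param tp,fp,fn nonnegative counts.
#' @return Fraction in `[0, 1]`.
#' @export
precision <- function(tp, fp) {
  stopifnot(tp >= 0, fp >= 0)
  if (tp + fp == 0) return(structure(0, degenerate = TRUE))
  tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(tp, fn) {
  stopifnot(tp >= 0, fn >= 0)
  if (tp + fn == 0) return(structure(0, degenerate = TRUE))
  tp / (tp + fn)
}

# Confidence-ranked TP flags for one class across the whole dataset.
# Matching is greedy within each frame, which only depends on the
# confidence ranking inside that frame, so frames can be processed
# independently and the flags pooled and re-sorted globally.
score_class <- function(predictions, truths, cl, iou_threshold) {
  keep_p <- predictions$class == cl
  keep_t <- truths$class == cl
  p <- predictions[keep_p, , drop = FALSE]
  t <- truths[keep_t, , drop = FALSE]
  n_truth <- nrow(t)
  if (nrow(p) == 0)
    return(list(tp = logical(0), conf = numeric(0), n_truth = n_truth))
  conf <- p$conf %||% rep(1, nrow(p))
  conf[is.na(conf)] <- 1
  pf <- p$frame_index %||% rep(0L, nrow(p))
  tf <- t$frame_index %||% rep(0L, nrow(t))
  pb <- corners(p); tb <- corners(t)
  tp <- logical(nrow(p))
  for (f in unique(pf)) {
    pi <- which(pf == f); ti <- which(tf == f)
    m <- greedy_frame_match(pb[pi, , drop = FALSE], conf[pi],
                            tb[ti, , drop = FALSE], iou_threshold)
    tp[pi] <- m$tp
  }
  ord <- order(-conf)
  list(tp = tp[ord], conf = conf[ord], n_truth = n_truth)
}

#' Average precision for one class
#'
#' Area under the interpolated precision-recall curve built from the
#' confidence-ranked detections. `"all_points"` (default) integrates the
#' monotone precision envelope over every recall change; `"101_point"`
#' averages the envelope at recalls 0, 0.01, ..., 1.
#'
#' @inheritParams match_detections
#' @param class class label to score.
#' @param interpolation `"all_points"` or `"101_point"`.
#' @return AP in `[0, 1]`, or NA (with a warning) when the class has no
#'   ground truth.
#' @export
average_precision <- function(predictions, truths, class,
                              iou_threshold = 0.5,
                              interpolation = c("all_points", "101_point")) {
  interpolation <- match.arg(interpolation)
  s <- score_class(predictions, truths, class, iou_threshold)
  if (s$n_truth == 0) {
    warning("no ground truth for class ", class, "; AP undefined")
    return(NA_real_)
  }
  if (length(s$tp) == 0) return(0)
  cum_tp <- cumsum(s$tp)
  rec <- cum_tp / s$n_truth
  prec <- cum_tp / seq_along(s$tp)
  env <- rev(cummax(rev(prec)))  # monotone envelope from the right
  if (interpolation == "101_point") {
    grid <- seq(0, 1, by = 0.01)
    at <- vapply(grid, function(r) {
      ok <- which(rec >= r)
      if (length(ok) == 0) 0 else env[ok[1]]
    }, numeric(1))
    return(mean(at))
  }
  sum(diff(c(0, rec)) * env)
}

#' Mean average precision over classes
#'
#' Unweighted mean of per-class APs; NA entries (classes without ground
#' truth) are dropped with a warning.
#'
#' @param ap named or unnamed numeric vector of per-class APs.
#' @return mAP.
#' @export
mean_ap <- function(ap) {
  if (anyNA(ap)) {
    warning("dropping classes with undefined AP")
    ap <- ap[!is.na(ap)]
  }
  if (length(ap) == 0) stop("no class with a defined AP")
  mean(ap)
}

#' Detection evaluation report
#'
#' Per-class precision and recall at the matching threshold, AP at IoU
#' 0.5, AP averaged over IoU 0.50-0.95 (step 0.05), and a class-mean
#' `Average` row, in the conventional detector-benchmark table shape.
#'
#' @inheritParams match_detections
#' @param interpolation passed to [average_precision()].
#' @return Data frame `class, precision, recall, ap50, ap50_95` with a
#'   final `Average` row of class means.
#' @export
evaluate_detections <- function(predictions, truths, iou_threshold = 0.5,
                                interpolation = "all_points") {
  classes <- sort(unique(truths$class))
  if (length(classes) == 0) stop("no ground-truth classes to evaluate")
  m <- match_detections(predictions, truths, iou_threshold)$per_class
  thresholds <- seq(0.5, 0.95, by = 0.05)
  rows <- lapply(classes, function(cl) {
    counts <- m[m$class == cl, ]
    aps <- vapply(thresholds, function(th)
      average_precision(predictions, truths, cl, th, interpolation),
      numeric(1))
    data.frame(class = cl,
               precision = as.numeric(precision(counts$tp, counts$fp)),
               recall = as.numeric(recall(counts$tp, counts$fn)),
               ap50 = aps[1], ap50_95 = mean(aps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  avg <- data.frame(class = "Average",
                    precision = mean(out$precision), recall = mean(out$recall),
                    ap50 = mean_ap(out$ap50), ap50_95 = mean_ap(out$ap50_95),
                    stringsAsFactors = FALSE)
  rbind(out, avg)
}

#' Duration-agreement metrics
#'
#' `MAE = mean(|y - yhat|)`, `RMSE = sqrt(mean((y - yhat)^2))`,
#' `R^2 = 1 - SS_res / SS_tot`. R-squared needs at least two
#' observations and a non-constant truth; otherwise it is NA with a
#' warning while MAE and RMSE are still returned.
#'
#' @param y_true observed values (e.g. manually recorded durations).
#' @param y_pred predicted values, same length.
#' @return List with `mae`, `rmse`, `r2`.
#' @export
duration_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("lengths differ")
  if (length(y_true) == 0) stop("empty input")
  err <- y_true - y_pred
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  r2 <- NA_real_
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (length(y_true) < 2 || ss_tot == 0) {
    warning("R^2 undefined for constant or length-1 y_true")
  } else {
    r2 <- 1 - sum(err^2) / ss_tot
  }
  list(mae = mae, rmse = rmse, r2 = r2)
}
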