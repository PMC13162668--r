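#' Model throughput in frames per second
#'
#' `FPS = 1000 / (tp + ti + tnms)` from the per-frame pre-processing,
#' inference and non-maximum-suppression times. This is the detector's
#' throughput; durations of recorded behavior are converted with the
#' camera's native capture rate instead (see [frames_to_hours()]),
#' because how long a behavior lasted depends on the capture rate, not
#' on how fast the model ran.
#'
#' @param tp pre-processing time per frame, ms.
#' @param ti inference time per frame, ms.
#' @param tnms non-maximum-suppression time per frame, ms.
#' @return Frames per second.
#' @export
fps_from_timings <- function(tp, ti, tnms) {
  stopifnot(tp >= 0, ti >= 0, tnms >= 0)
  total <- tp + ti + tnms
  if (total <= 0) stop("total per-frame time must be positive")
  1000 / total
}

#' Convert a frame count to hours
#'
#' `hours = frames / (fps * 3600)`.
#'
#' @param frame_count number of frames in which a behavior was observed.
#' @param fps capture rate, frames per second.
#' @return Hours. Vectorised and linear in `frame_count`.
#' @export
frames_to_hours <- function(frame_count, fps) {
  if (fps <= 0) stop("fps must be positive")
  stopifnot(all(frame_count >= 0))
  frame_count / (fps * 3600)
}

#' Ethogram time-budget summary
#'
#' @param hours named numeric vector of per-behavior hours (typically the
#'   four ethogram behaviors).
#' @param frame_counts optional named vector of per-behavior frame counts
#'   to carry through.
#' @param digits decimals for the reported percentage (default 2).
#' @return Data frame `behavior, hours, percent` (plus `frame_count` when
#'   given), with `percent = 100 * hours / sum(hours)` rounded for
#'   reporting; the unrounded values sum to exactly 100.
#' @export
summarize_budget <- function(hours, frame_counts = NULL, digits = 2) {
  if (length(hours) == 0 || any(hours < 0)) stop("hours must be nonnegative")
  total <- sum(hours)
  if (total <= 0) stop("all-zero budget")
  out <- data.frame(behavior = names(hours), hours = as.numeric(hours),
                    percent = round(100 * as.numeric(hours) / total, digits),
                    stringsAsFactors = FALSE)
  if (!is.null(frame_counts))
    out$frame_count <- as.numeric(frame_counts[names(hours)])
  attr(out, "total_hours") <- total
  out
}

#' Compare a manual and an automatic time budget
#'
#' @param manual,auto named numeric vectors of per-behavior hours with
#'   identical names.
#' @return Data frame `behavior, manual_hours, auto_hours, difference,
#'   abs_difference` where `difference = auto - manual`; the attribute
#'   `max_abs` names the behavior with the largest absolute difference.
#' @export
compare_budgets <- function(manual, auto) {
  if (!setequal(names(manual), names(auto)) || is.null(names(manual)))
    stop("manual and auto budgets must share the same behavior names")
  auto <- auto[names(manual)]
  diff <- as.numeric(auto) - as.numeric(manual)
  out <- data.frame(behavior = names(manual),
                    manual_hours = as.numeric(manual),
                    auto_hours = as.numeric(auto),
                    difference = diff,
                    abs_difference = abs(diff),
                    stringsAsFactors = FALSE)
  attr(out, "max_abs") <- out$behavior[which.max(out$abs_difference)]
  out
}
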