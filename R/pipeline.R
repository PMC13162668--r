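#' Load a scenario fixture directory
#'
#' Reads a fixture written by [generate_scenario()] (zones, microclimate,
#' physiology, label files, scenario settings) back into the in-memory
#' shape [run_pipeline()] consumes.
#'
#' @param dir fixture directory.
#' @return List with `detections`, `zones`, `schedule`, `microclimate`,
#'   `physiology`, `meta` and (when present) `truth_budget_hours`.
#' @export
read_scenario <- function(dir) {
  yml <- file.path(dir, "scenario.yaml")
  if (!file.exists(yml)) stop("missing scenario.yaml in ", dir)
  cfg <- yaml::read_yaml(yml)
  meta <- video_meta(fps = cfg$fps, n_frames = cfg$duration_s * cfg$fps)
  det <- read_label_dir(file.path(dir, "labels"), meta)
  det$timestamp <- det$timestamp + cfg$start_s
  gt <- NULL
  gtf <- file.path(dir, "ground_truth.json")
  if (file.exists(gtf))
    gt <- unlist(jsonlite::read_json(gtf)$truth_budget_hours)
  list(detections = det,
       zones = read_zones(file.path(dir, "zones.csv"), meta),
       schedule = feeding_schedule(unlist(cfg$schedule$start),
                                   unlist(cfg$schedule$end)),
       microclimate = read_microclimate(file.path(dir, "microclimate.csv")),
       physiology = read_physiology(file.path(dir, "physiology.csv")),
       meta = meta, truth_budget_hours = gt)
}

#' Run the full monitoring pipeline
#'
#' Confidence-filters the detections, infers per-frame behaviors from
#' zone occupancy and the feeding schedule, converts frame counts to an
#' ethogram time budget, classifies the thermal environment (BGHI) and
#' physiology, and -- when ground truth is available -- evaluates the
#' detections and compares time budgets. Deterministic given its inputs;
#' each stage is also callable on its own ([filter_confidence()],
#' [infer_video()], [summarize_budget()], [evaluate_detections()]).
#'
#' @param scenario a scenario list from [generate_scenario()] or a
#'   fixture directory readable by [read_scenario()].
#' @param confidence_threshold detection confidence cutoff (default 0.70).
#' @param occupancy_threshold zone-occupancy cutoff (default 0.5).
#' @param iou_threshold matching cutoff for evaluation (default 0.5).
#' @param rule occupancy rule, see [classify_frame()].
#' @param evaluate compute the detection evaluation report (set FALSE to
#'   skip the costly AP sweep on long videos).
#' @param out_dir optional directory for CSV/JSON reports.
#' @return List of class `penwatch_report` with elements `activity`,
#'   `budget`, `comfort`, `physiology`, and when ground truth is present
#'   `comparison` and (if `evaluate`) `evaluation`.
#' @export
run_pipeline <- function(scenario,
                         confidence_threshold = 0.70,
                         occupancy_threshold = 0.5,
                         iou_threshold = 0.5,
                         rule = "zone",
                         evaluate = TRUE,
                         out_dir = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  meta <- scenario$meta %||% scenario$config$meta
  zones <- scenario$zones %||% scenario$config$pen$zones
  schedule <- scenario$schedule %||% scenario$config$schedule

  det <- filter_confidence(scenario$detections, confidence_threshold)
  inferred <- infer_video(det, zones, schedule, meta,
                          occupancy_threshold = occupancy_threshold,
                          rule = rule)
  hours <- frames_to_hours(inferred$totals, meta$fps)
  budget <- summarize_budget(hours, frame_counts = inferred$totals)

  micro <- scenario$microclimate
  comfort <- NULL
  if (!is.null(micro)) {
    dpt <- dew_point(micro$t_air, micro$rh)
    tg <- micro$t_globe %||% micro$t_air
    idx <- bghi(tg, dpt)
    comfort <- data.frame(timestamp = micro$timestamp, t_air = micro$t_air,
                          rh = micro$rh, dew_point = dpt, bghi = idx,
                          class = classify_bghi(idx))
  }
  physio <- scenario$physiology
  if (!is.null(physio))
    physio$status <- classify_physiology(physio$rt, physio$rr)

  report <- list(activity = inferred$activity, budget = budget,
                 totals = inferred$totals, comfort = comfort,
                 physiology = physio)

  truth <- scenario[["truth"]]
  truth_hours <- scenario[["truth_budget_hours"]]
  if (is.null(truth_hours) && !is.null(truth)) {
    cnt <- vapply(behaviors(), function(b)
      sum(truth$behavior == b), numeric(1))
    truth_hours <- frames_to_hours(cnt, meta$fps)
  }
  if (!is.null(truth_hours))
    report$comparison <- compare_budgets(truth_hours[names(hours)], hours)
  if (evaluate && !is.null(truth))
    report$evaluation <- evaluate_detections(det, truth, iou_threshold)

  class(report) <- "penwatch_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle
#'
#' @param report a `penwatch_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$activity, file.path(out_dir, "activity.csv"),
                   row.names = FALSE)
  utils::write.csv(report$budget, file.path(out_dir, "budget.csv"),
                   row.names = FALSE)
  if (!is.null(report$comfort))
    utils::write.csv(report$comfort, file.path(out_dir, "comfort.csv"),
                     row.names = FALSE)
  if (!is.null(report$physiology))
    utils::write.csv(report$physiology, file.path(out_dir, "physiology.csv"),
                     row.names = FALSE)
  if (!is.null(report$comparison))
    utils::write.csv(report$comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  if (!is.null(report$evaluation))
    utils::write.csv(report$evaluation, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
  json <- list(budget = report$budget, totals = as.list(report$totals))
  if (!is.null(report$comparison)) json$comparison <- report$comparison
  if (!is.null(report$evaluation)) json$evaluation <- report$evaluation
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.penwatch_report <- function(x, ...) {
  cat("penwatch pipeline report\n")
  cat("  ethogram budget (hours, percent):\n")
  b <- x$budget
  for (i in seq_len(nrow(b)))
    cat(sprintf("    %-9s %8.4f h  (%6.2f%%)\n",
                b$behavior[i], b$hours[i], b$percent[i]))
  if (!is.null(x$comfort)) {
    tab <- table(x$comfort$class)
    cat("  thermal classes: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$comparison)) {
    mx <- attr(x$comparison, "max_abs")
    cat(sprintf("  max |manual - auto| difference: %s (%.4f h)\n", mx,
                max(x$comparison$abs_difference)))
  }
  if (!is.null(x$evaluation)) {
    avg <- x$evaluation[x$evaluation$class == "Average", ]
    cat(sprintf("  detection: P=%.3f R=%.3f mAP50=%.3f mAP50-95=%.3f\n",
                avg$precision, avg$recall, avg$ap50, avg$ap50_95))
  }
  invisible(x)
}
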