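#' Behavior transition matrices
#'
#' One-second-resolution Markov transition matrices over the four
#' ethogram behaviors, one per thermal state. They were calibrated
#' (fixed-point adjustment of the jump-destination weights for given
#' mean dwell times) so that their stationary distributions equal the
#' target time-budget fractions of detected time: comfort
#' lying/standing/eating/drinking = .680/.200/.115/.004 (normalized),
#' heat = .697/.168/.123/.012 -- heat-stressed pigs lie slightly more,
#' explore less, and drink about three times as long. Mean dwell times:
#' lying 120 s, standing 30 s, eating 60 s, drinking 15 s (20 s under
#' heat).
#'
#' @return 4 x 4 row-stochastic matrix with dimnames from [behaviors()].
#' @export
transition_matrix_comfort <- function() {
  P <- matrix(c(
    0.99166667, 0.00748991, 0.00074580, 0.00009763,
    0.02546568, 0.96666667, 0.00695694, 0.00091071,
    0.00440993, 0.01209903, 0.98333333, 0.00015771,
    0.01659706, 0.04553548, 0.00453413, 0.93333333
  ), nrow = 4, byrow = TRUE, dimnames = list(behaviors(), behaviors()))
  P / rowSums(P)
}

#' @rdname transition_matrix_comfort
#' @export
transition_matrix_heat <- function() {
  P <- matrix(c(
    0.99166667, 0.00636910, 0.00154503, 0.00041920,
    0.02642417, 0.96666667, 0.00543463, 0.00147454,
    0.00875520, 0.00742291, 0.98333333, 0.00048856,
    0.02434870, 0.02064353, 0.00500777, 0.95000000
  ), nrow = 4, byrow = TRUE, dimnames = list(behaviors(), behaviors()))
  P / rowSums(P)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the row-stochastic matrix at eigenvalue 1,
#' normalized to sum to one.
#'
#' @param P row-stochastic square matrix.
#' @return Named probability vector.
#' @export
behavior_stationary <- function(P) {
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("P must be row-stochastic")
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  stats::setNames(v, rownames(P))
}

#' Detector noise settings
#'
#' @param p_miss per-detection miss probability (occlusion, low light).
#' @param jitter_sd Gaussian sd added to each box corner, pixels.
#' @param p_fp per-frame probability of a spurious standing box at the
#'   unused (inactive) feeder, whose color resembles the animals.
#' @param conf_shapes list of Beta shape pairs for detection confidence
#'   per emitted class (`lying`, `standing`, `fp`); `NULL` means
#'   confidence 1 for all detections.
#' @return List of class `detector_noise`.
#' @export
detector_noise <- function(p_miss = 0.05, jitter_sd = 2, p_fp = 0.01,
                           conf_shapes = list(lying = c(18, 1),
                                              standing = c(14, 1),
                                              fp = c(8, 1))) {
  stopifnot(p_miss >= 0, p_miss <= 1, jitter_sd >= 0, p_fp >= 0, p_fp <= 1)
  structure(list(p_miss = p_miss, jitter_sd = jitter_sd, p_fp = p_fp,
                 conf_shapes = conf_shapes),
            class = "detector_noise")
}

#' @rdname detector_noise
#' @export
zero_noise <- function() detector_noise(0, 0, 0, NULL)

#' Diurnal climate parameters per thermal regime
#'
#' Sinusoidal dry-bulb temperature peaking mid-afternoon with additive
#' Gaussian noise; relative humidity in anti-phase. Defaults reproduce
#' the observed regime means (cooled 22.59 degC / 82.0% RH; uncooled
#' 30.43 degC / 54.6% RH) and ranges. The black-globe radiant offsets
#' are set so the mean BGHI of each regime matches the observed stall
#' means (71.45 cooled, 79.82 uncooled).
#'
#' @param regime `"cooled"` or `"uncooled"`.
#' @return List of climate parameters.
#' @export
climate_params <- function(regime = c("cooled", "uncooled")) {
  regime <- match.arg(regime)
  if (regime == "cooled") {
    list(t_mean = 22.59, t_amp = 1.9, t_sd = 0.12,
         rh_mean = 81.99, rh_amp = 7.5, rh_sd = 0.8,
         radiant_offset = 0.391, peak_hour = 14)
  } else {
    list(t_mean = 30.43, t_amp = 4.4, t_sd = 0.25,
         rh_mean = 54.62, rh_amp = 13.5, rh_sd = 1.2,
         radiant_offset = 0.597, peak_hour = 14)
  }
}

#' Generate a synthetic microclimate series
#'
#' 15-minute cadence by default, mirroring datalogger records: maximum
#' temperature in the afternoon, minimum in the morning, humidity
#' inversely proportional to temperature.
#'
#' @param regime `"cooled"` or `"uncooled"`.
#' @param n_days number of simulated days (>= 1).
#' @param seed RNG seed; a fixed seed gives identical output.
#' @param cadence_s sampling interval, seconds (default 900).
#' @param params see [climate_params()].
#' @return Microclimate data frame `timestamp, t_air, rh, t_globe`.
#' @export
generate_microclimate <- function(regime = c("cooled", "uncooled"),
                                  n_days = 1, seed = 1, cadence_s = 900,
                                  params = climate_params(regime)) {
  regime <- match.arg(regime)
  if (n_days < 1) stop("n_days must be >= 1")
  set.seed(seed)
  t0 <- as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  secs <- seq(0, n_days * 86400 - cadence_s, by = cadence_s)
  hour <- (secs %% 86400) / 3600
  phase <- cos(2 * pi * (hour - params$peak_hour) / 24)
  t_air <- params$t_mean + params$t_amp * phase +
    stats::rnorm(length(secs), 0, params$t_sd)
  rh <- params$rh_mean - params$rh_amp * phase +
    stats::rnorm(length(secs), 0, params$rh_sd)
  rh <- pmin(pmax(rh, 0), 100)
  data.frame(timestamp = t0 + secs,
             t_air = t_air, rh = rh,
             t_globe = t_air + params$radiant_offset)
}

# Piecewise-linear anchors for the physiological response to air
# temperature (rectal temperature degC, respiratory rate mov/min).
physio_anchors <- function() {
  data.frame(t_air = c(21.0, 24.9, 30.4, 33.5),
             rt = c(37.90, 38.40, 38.55, 38.75),
             rr = c(44.67, 59.67, 71.90, 73.50))
}

#' Generate synthetic physiological records
#'
#' Rectal temperature and respiratory rate as a piecewise-linear
#' response to air temperature (anchored at observed stall means) plus
#' Gaussian noise, sampled per animal at the given hours.
#'
#' @param microclimate microclimate data frame (see
#'   [generate_microclimate()]).
#' @param n_pigs animals per pen.
#' @param seed RNG seed.
#' @param hours clock hours at which records are taken.
#' @param rt_sd,rr_sd noise standard deviations.
#' @return Data frame `timestamp, animal_id, rt, rr`.
#' @export
generate_physiology <- function(microclimate, n_pigs = 3, seed = 1,
                                hours = c(8, 12, 16),
                                rt_sd = 0.08, rr_sd = 2) {
  set.seed(seed)
  a <- physio_anchors()
  hr <- as.numeric(format(microclimate$timestamp, "%H")) +
    as.numeric(format(microclimate$timestamp, "%M")) / 60
  rows <- microclimate[hr %in% hours, , drop = FALSE]
  if (nrow(rows) == 0) stop("no microclimate records at the requested hours")
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    t_air <- rows$t_air[i]
    data.frame(timestamp = rep(rows$timestamp[i], n_pigs),
               animal_id = seq_len(n_pigs),
               rt = stats::approx(a$t_air, a$rt, t_air, rule = 2)$y +
                 stats::rnorm(n_pigs, 0, rt_sd),
               rr = stats::approx(a$t_air, a$rr, t_air, rule = 2)$y +
                 stats::rnorm(n_pigs, 0, rr_sd))
  }))
  rownames(out) <- NULL
  out
}

#' Default pen geometry
#'
#' A 640 x 360 px camera view with a feeder along the top wall, a
#' drinker in the top-right corner, an unused feeder near the bottom
#' wall (the false-positive magnet), and the open floor in between.
#'
#' @return List with `zones` (data frame) and `floor` ([px_rect()]).
#' @export
default_pen <- function() {
  zones <- data.frame(
    zone_id = c("feeder_main", "drinker_1", "feeder_unused"),
    role = c("feeder", "drinker", "inactive_feeder"),
    x0 = c(40, 520, 260), y0 = c(20, 20, 300),
    x1 = c(140, 560, 360), y1 = c(70, 50, 350),
    stringsAsFactors = FALSE)
  list(zones = zones, floor = px_rect(20, 110, 620, 290))
}

#' Scenario configuration for the synthetic barn
#'
#' Bundles everything [generate_scenario()] needs: thermal regime,
#' pen geometry, herd size, video span and rate, behavior dynamics and
#' detector noise. Defaults are the emulated study conditions: 3 pigs
#' per pen, observation starting at 08:00, feeding at 08:00 and 15:00,
#' comfort/heat transition matrices switched by BGHI, and regime-
#' dependent miss rates (detection is harder in the uncooled stalls
#' because of overlap and lighting).
#'
#' @param regime `"cooled"` or `"uncooled"`.
#' @param duration_s observed span, seconds of video.
#' @param fps rendered frames per second (states advance at 1 Hz and are
#'   held for `fps` frames; must be a positive integer).
#' @param n_pigs animals per pen.
#' @param start_s clock time of the first frame, seconds after midnight.
#' @param pen see [default_pen()].
#' @param schedule see [feeding_schedule()].
#' @param noise see [detector_noise()]; default depends on regime.
#' @param climate see [climate_params()].
#' @param P_comfort,P_heat transition matrices per thermal state.
#' @param standing_box,lying_box box sizes `c(w, h)` in pixels.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(regime = c("cooled", "uncooled"),
                            duration_s = 3600, fps = 1, n_pigs = 3,
                            start_s = 8 * 3600,
                            pen = default_pen(),
                            schedule = feeding_schedule(),
                            noise = NULL,
                            climate = climate_params(regime),
                            P_comfort = transition_matrix_comfort(),
                            P_heat = transition_matrix_heat(),
                            standing_box = c(90, 60),
                            lying_box = c(110, 70)) {
  regime <- match.arg(regime)
  if (fps < 1 || fps != round(fps)) stop("fps must be a positive integer")
  if (is.null(noise))
    noise <- if (regime == "cooled") detector_noise(p_miss = 0.05)
             else detector_noise(p_miss = 0.16)
  structure(list(regime = regime, duration_s = duration_s, fps = fps,
                 n_pigs = n_pigs, start_s = start_s, pen = pen,
                 schedule = schedule, noise = noise, climate = climate,
                 P_comfort = P_comfort, P_heat = P_heat,
                 standing_box = standing_box, lying_box = lying_box,
                 meta = video_meta(640, 360, fps = fps,
                                   n_frames = duration_s * fps)),
            class = "scenario_config")
}

#' Generate per-pig behavior state sequences
#'
#' First-order Markov chain at 1-second resolution over the four
#' ethogram behaviors, with the transition matrix switched per step by
#' thermal state (comfort vs heat). When a feeding schedule is given,
#' eating proposed outside a feeding window is redirected to standing
#' (the feeder is empty then).
#'
#' @param n_steps number of 1-second steps.
#' @param P transition matrix used in comfort steps.
#' @param P_heat matrix used in heat steps (default `P`).
#' @param comfort logical vector of length `n_steps` (default all
#'   comfort).
#' @param n_pigs number of independent chains.
#' @param seed RNG seed; fixed seed gives identical sequences.
#' @param schedule optional [feeding_schedule()] for eating gating.
#' @param t0 clock time of step 1, seconds.
#' @param init initial distribution (default: stationary of `P`).
#' @return Character matrix `n_steps x n_pigs` of behavior labels.
#' @export
generate_behavior_states <- function(n_steps, P = transition_matrix_comfort(),
                                     P_heat = P, comfort = NULL,
                                     n_pigs = 3, seed = 1,
                                     schedule = NULL, t0 = 0,
                                     init = NULL) {
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8) ||
      any(P_heat < 0) || any(abs(rowSums(P_heat) - 1) > 1e-8))
    stop("transition matrices must be row-stochastic")
  set.seed(seed)
  if (is.null(comfort)) comfort <- rep(TRUE, n_steps)
  stopifnot(length(comfort) == n_steps)
  if (is.null(init)) init <- behavior_stationary(P)
  cumP <- apply(P, 1, cumsum)        # column i = cumulative row i
  cumH <- apply(P_heat, 1, cumsum)
  eat <- match("eating", behaviors())
  stand <- match("standing", behaviors())
  fed <- if (is.null(schedule)) rep(TRUE, n_steps) else
    in_feeding_window(t0 + (seq_len(n_steps) - 1), schedule)
  states <- matrix(NA_integer_, n_steps, n_pigs)
  for (p in seq_len(n_pigs)) {
    s <- findInterval(stats::runif(1), cumsum(init)) + 1L
    if (s == eat && !fed[1]) s <- stand
    states[1, p] <- s
    u <- stats::runif(n_steps - 1)
    for (i in seq_len(n_steps - 1)) {
      cp <- if (comfort[i + 1]) cumP else cumH
      s <- findInterval(u[i], cp[, s]) + 1L
      if (s == eat && !fed[i + 1]) s <- stand
      states[i + 1, p] <- s
    }
  }
  matrix(behaviors()[states], n_steps, n_pigs)
}

# Sample true boxes for each (step, pig) given behaviors. Eating and
# drinking boxes are centred on their zone (small uniform wobble along
# the trough), so a single animal satisfies the >= 50% zone-occupancy
# rule; lying and standing boxes are placed uniformly on the open floor.
place_boxes <- function(beh, config) {
  n <- length(beh)
  zones <- config$pen$zones
  floor <- config$pen$floor
  sw <- config$standing_box[1]; sh <- config$standing_box[2]
  lw <- config$lying_box[1]; lh <- config$lying_box[2]
  w <- ifelse(beh == "lying", lw, sw)
  h <- ifelse(beh == "lying", lh, sh)
  cx <- numeric(n); cy <- numeric(n)
  free <- beh %in% c("lying", "standing")
  if (any(free)) {
    cx[free] <- stats::runif(sum(free), floor[["x0"]] + w[free] / 2,
                             floor[["x1"]] - w[free] / 2)
    cy[free] <- stats::runif(sum(free), floor[["y0"]] + h[free] / 2,
                             floor[["y1"]] - h[free] / 2)
  }
  for (role in c("feeder", "drinker")) {
    at <- if (role == "feeder") beh == "eating" else beh == "drinking"
    if (!any(at)) next
    z <- zones[zones$role == role, ][1, ]
    zcx <- (z$x0 + z$x1) / 2; zcy <- (z$y0 + z$y1) / 2
    wob <- (z$x1 - z$x0) / 8
    cx[at] <- zcx + stats::runif(sum(at), -wob, wob)
    cy[at] <- zcy + stats::runif(sum(at), -2, 2)
  }
  data.frame(x0 = cx - w / 2, y0 = cy - h / 2,
             x1 = cx + w / 2, y1 = cy + h / 2)
}

clip_boxes <- function(b, meta) {
  b$x0 <- pmax(b$x0, 0); b$y0 <- pmax(b$y0, 0)
  b$x1 <- pmin(b$x1, meta$width); b$y1 <- pmin(b$y1, meta$height)
  b
}

#' Render noisy detections and ground truth from behavior states
#'
#' Each 1-second state is held for `fps` frames. True boxes are placed
#' per behavior (eating/drinking boxes covering their zone, lying and
#' standing boxes on the open floor). Detector noise then drops each
#' detection with probability `p_miss`, jitters box corners with
#' Gaussian noise, draws per-class Beta confidences, and adds spurious
#' standing boxes at the inactive feeder with per-frame rate `p_fp`.
#' Detections are emitted in the two-class scheme (eating and drinking
#' rendered as standing); ground truth keeps the four-class ethogram.
#'
#' @param states character matrix from [generate_behavior_states()].
#' @param config [scenario_config()].
#' @param seed RNG seed.
#' @return List with `truth` (frame_index, timestamp, pig, behavior,
#'   class, corners) and `detections` (frame_index, timestamp, class_id,
#'   class, normalized and pixel coordinates, conf).
#' @export
render_detections <- function(states, config, seed = 1) {
  set.seed(seed)
  meta <- config$meta
  fps <- config$fps
  n_steps <- nrow(states); n_pigs <- ncol(states)
  beh <- as.vector(states)                  # step-major within pig
  step <- rep(seq_len(n_steps), times = n_pigs)
  pig <- rep(seq_len(n_pigs), each = n_steps)
  boxes <- clip_boxes(place_boxes(beh, config), meta)

  # replicate per frame within each held state
  rep_idx <- rep(seq_along(beh), each = fps)
  sub <- rep(seq_len(fps) - 1L, times = length(beh))
  frame <- (step[rep_idx] - 1L) * fps + sub
  timestamp <- config$start_s + frame / fps
  truth <- data.frame(frame_index = frame, timestamp = timestamp,
                      pig = pig[rep_idx], behavior = beh[rep_idx],
                      class = ifelse(beh[rep_idx] == "lying", "lying", "standing"),
                      boxes[rep_idx, , drop = FALSE],
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$frame_index, truth$pig), , drop = FALSE]
  rownames(truth) <- NULL

  nz <- config$noise
  keep <- stats::runif(nrow(truth)) >= nz$p_miss
  det <- truth[keep, , drop = FALSE]
  if (nz$jitter_sd > 0 && nrow(det) > 0) {
    for (col in c("x0", "y0", "x1", "y1"))
      det[[col]] <- det[[col]] + stats::rnorm(nrow(det), 0, nz$jitter_sd)
    bad <- det$x1 <= det$x0 | det$y1 <= det$y0
    det <- clip_boxes(det[!bad, , drop = FALSE], meta)
    det <- det[det$x1 > det$x0 & det$y1 > det$y0, , drop = FALSE]
  }
  det$conf <- draw_conf(det$class, nz)

  # false positives: the unused feeder mistaken for a standing animal
  if (nz$p_fp > 0) {
    n_frames <- n_steps * fps
    fp_frames <- which(stats::runif(n_frames) < nz$p_fp) - 1L
    if (length(fp_frames) > 0) {
      iz <- config$pen$zones[config$pen$zones$role == "inactive_feeder", ]
      if (nrow(iz) == 0) iz <- data.frame(x0 = 260, y0 = 300, x1 = 360, y1 = 350)
      zcx <- (iz$x0[1] + iz$x1[1]) / 2; zcy <- (iz$y0[1] + iz$y1[1]) / 2
      sw <- config$standing_box[1]; sh <- config$standing_box[2]
      fp <- data.frame(frame_index = fp_frames,
                       timestamp = config$start_s + fp_frames / fps,
                       pig = NA_integer_, behavior = NA_character_,
                       class = "standing",
                       x0 = zcx - sw / 2 + stats::rnorm(length(fp_frames), 0, 3),
                       y0 = zcy - sh / 2 + stats::rnorm(length(fp_frames), 0, 3),
                       x1 = zcx + sw / 2 + stats::rnorm(length(fp_frames), 0, 3),
                       y1 = zcy + sh / 2 + stats::rnorm(length(fp_frames), 0, 3),
                       stringsAsFactors = FALSE)
      fp <- clip_boxes(fp, meta)
      fp$conf <- draw_conf(rep("fp", nrow(fp)), nz)
      det <- rbind(det, fp)
    }
  }
  det <- det[order(det$frame_index), , drop = FALSE]
  rownames(det) <- NULL

  det$class_id <- ifelse(det$class == "lying", 0L, 1L)
  det$cx <- (det$x0 + det$x1) / 2 / meta$width
  det$cy <- (det$y0 + det$y1) / 2 / meta$height
  det$w <- (det$x1 - det$x0) / meta$width
  det$h <- (det$y1 - det$y0) / meta$height
  det$pig <- NULL; det$behavior <- NULL
  list(truth = truth, detections = det)
}

draw_conf <- function(class, noise) {
  n <- length(class)
  if (is.null(noise$conf_shapes)) return(rep(1, n))
  conf <- numeric(n)
  for (cl in unique(class)) {
    sh <- noise$conf_shapes[[cl]] %||% noise$conf_shapes[["standing"]]
    rows <- class == cl
    conf[rows] <- stats::rbeta(sum(rows), sh[1], sh[2])
  }
  conf
}

#' Generate a complete synthetic scenario
#'
#' Runs the full simulator: microclimate, physiology, BGHI-driven
#' thermal state, per-pig behavior chains, and noisy detector output
#' with ground truth. With `out_dir` the fixture is also written to
#' disk: `zones.csv`, `microclimate.csv`, `physiology.csv`,
#' `labels/<frame>.txt`, `ground_truth.json` and `scenario.yaml`.
#'
#' @param config [scenario_config()].
#' @param seed RNG seed; all randomness derives from it, so a fixed seed
#'   reproduces the scenario exactly.
#' @param out_dir optional directory to write the fixture to.
#' @return List with `config`, `microclimate`, `physiology`, `states`,
#'   `truth`, `detections`, `truth_budget_hours` (per-behavior true
#'   hours, frame-count convention) and `truth_pig_hours` (per-pig state
#'   convention; identical when nothing is missed).
#' @export
generate_scenario <- function(config = scenario_config(), seed = 1,
                              out_dir = NULL) {
  micro <- generate_microclimate(config$regime, n_days = 1, seed = seed,
                                 params = config$climate)
  physio <- generate_physiology(micro, n_pigs = config$n_pigs,
                                seed = seed + 1)
  idx <- bghi(micro$t_globe, dew_point(micro$t_air, micro$rh))
  sec_of_day <- as.numeric(micro$timestamp) %% 86400
  n_steps <- config$duration_s
  step_time <- config$start_s + (seq_len(n_steps) - 1)
  idx_at <- stats::approx(sec_of_day, idx, step_time, rule = 2)$y
  comfort <- idx_at <= config$P_comfort_cut %||% 74
  states <- generate_behavior_states(n_steps, P = config$P_comfort,
                                     P_heat = config$P_heat,
                                     comfort = comfort,
                                     n_pigs = config$n_pigs,
                                     seed = seed + 2,
                                     schedule = config$schedule,
                                     t0 = config$start_s)
  rendered <- render_detections(states, config, seed = seed + 3)

  frame_counts <- vapply(behaviors(), function(b)
    sum(rendered$truth$behavior == b), numeric(1))
  state_counts <- vapply(behaviors(), function(b) sum(states == b), numeric(1))
  out <- list(config = config,
              microclimate = micro, physiology = physio,
              states = states,
              truth = rendered$truth, detections = rendered$detections,
              truth_budget_hours = frames_to_hours(frame_counts, config$fps),
              truth_pig_hours = state_counts / 3600)
  if (!is.null(out_dir)) write_scenario(out, out_dir)
  out
}

write_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- scenario$config
  utils::write.csv(cfg$pen$zones, file.path(out_dir, "zones.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$microclimate,
                   file.path(out_dir, "microclimate.csv"), row.names = FALSE)
  utils::write.csv(scenario$physiology,
                   file.path(out_dir, "physiology.csv"), row.names = FALSE)
  lab_dir <- file.path(out_dir, "labels")
  dir.create(lab_dir, showWarnings = FALSE)
  det <- scenario$detections
  for (f in 0:(cfg$meta$n_frames - 1)) {
    write_labels(det[det$frame_index == f, , drop = FALSE],
                 file.path(lab_dir, paste0(f, ".txt")))
  }
  jsonlite::write_json(
    list(truth_budget_hours = as.list(scenario$truth_budget_hours),
         truth_pig_hours = as.list(scenario$truth_pig_hours)),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(regime = cfg$regime, duration_s = cfg$duration_s,
                        fps = cfg$fps, n_pigs = cfg$n_pigs,
                        start_s = cfg$start_s,
                        noise = unclass(cfg$noise)[c("p_miss", "jitter_sd", "p_fp")],
                        schedule = as.list(cfg$schedule)),
                   file.path(out_dir, "scenario.yaml"))
  invisible(out_dir)
}
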