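#' Dew-point constants
#'
#' Magnus-form constants used by [dew_point()]. Defaults are the values
#' conventional for air over water in the 0-60 degC range.
#'
#' @param b temperature constant, degC (default 238.88).
#' @param c dimensionless constant (default 17.368).
#' @return List with elements `b` and `c`.
#' @export
dew_point_constants <- function(b = 238.88, c = 17.368) {
  stopifnot(is.numeric(b), is.numeric(c), b > 0, c > 0)
  list(b = b, c = c)
}

#' Dew-point temperature from dry-bulb temperature and relative humidity
#'
#' Magnus form: with `gamma(T, RH) = ln(RH/100) + c*T/(b + T)`, the dew
#' point is `DPT = b*gamma / (c - gamma)`. At saturation (RH = 100) the
#' dew point equals the dry-bulb temperature.
#'
#' @param t_air dry-bulb air temperature, degC. Vectorised.
#' @param rh relative humidity, percent, in (0, 100].
#' @param constants see [dew_point_constants()].
#' @return Dew-point temperature, degC; always `<= t_air`.
#' @export
dew_point <- function(t_air, rh, constants = dew_point_constants()) {
  if (any(!is.finite(t_air)) || any(!is.finite(rh)))
    stop("t_air and rh must be finite")
  if (any(rh <= 0 | rh > 100))
    stop("rh must lie in (0, 100]")
  if (any(t_air < -20 | t_air > 60))
    stop("t_air outside plausible range [-20, 60] degC")
  b <- constants$b; cc <- constants$c
  gamma <- log(rh / 100) + cc * t_air / (b + t_air)
  b * gamma / (cc - gamma)
}

#' Black globe humidity index
#'
#' `BGHI = Tg + 0.36 * DPT + 41.5`, combining black-globe temperature
#' (radiant plus convective load) with the dew point (humidity load).
#'
#' @param t_globe black-globe temperature, degC.
#' @param dpt dew-point temperature, degC (see [dew_point()]).
#' @return Index value (dimensionless). Vectorised.
#' @export
bghi <- function(t_globe, dpt) {
  if (any(!is.finite(t_globe)) || any(!is.finite(dpt)))
    stop("bghi requires finite inputs")
  t_globe + 0.36 * dpt + 41.5
}

#' Comfort thresholds for pigs
#'
#' Bundles the configurable classification bounds used across the
#' microclimate module: BGHI class breaks, physiological limits, and
#' per-phase air temperature/humidity ranges. All values can be
#' overridden; defaults are the standard published bounds for growing
#' and finishing pigs.
#'
#' BGHI classes are contiguous half-open intervals, upper bound
#' inclusive: stress `<= 67` < comfort `<= 74` < alert `<= 76` <
#' emergency.
#'
#' @param bghi_breaks upper bounds of the stress/comfort/alert classes.
#' @param rt_max maximum normal rectal temperature, degC.
#' @param rr_max maximum normal respiratory rate, mov/min.
#' @param air_ranges per-phase list with `optimal` and `recommended`
#'   temperature bounds `c(min, max)` in degC.
#' @param humidity_good relative-humidity range considered good, percent.
#' @param humidity_critical bounds outside which humidity is critical.
#' @return List of class `comfort_thresholds`.
#' @export
comfort_thresholds <- function(bghi_breaks = c(stress = 67, comfort = 74, alert = 76),
                               rt_max = 39.3,
                               rr_max = 60,
                               air_ranges = list(
                                 growth      = list(optimal = c(18, 21), recommended = c(8, 30)),
                                 termination = list(optimal = c(15, 18), recommended = c(5, 27))
                               ),
                               humidity_good = c(50, 70),
                               humidity_critical = c(40, 90)) {
  if (is.unsorted(bghi_breaks, strictly = TRUE))
    stop("bghi_breaks must be strictly increasing")
  if (anyDuplicated(names(bghi_breaks)))
    stop("bghi class labels must be unique")
  structure(list(bghi_breaks = bghi_breaks, rt_max = rt_max, rr_max = rr_max,
                 air_ranges = air_ranges, humidity_good = humidity_good,
                 humidity_critical = humidity_critical),
            class = "comfort_thresholds")
}

#' Classify BGHI values into thermal-comfort classes
#'
#' @param index BGHI values (see [bghi()]). Vectorised.
#' @param thresholds see [comfort_thresholds()].
#' @return Factor with ordered levels stress < comfort < alert < emergency.
#' @export
classify_bghi <- function(index, thresholds = comfort_thresholds()) {
  if (any(!is.finite(index))) stop("index must be finite")
  br <- thresholds$bghi_breaks
  labels <- c(names(br), "emergency")
  cut(index, breaks = c(-Inf, br, Inf), labels = labels,
      right = TRUE, ordered_result = TRUE)
}

#' Classify physiological heat-stress status
#'
#' An animal is heat stressed when either its rectal temperature or its
#' respiratory rate exceeds the threshold; both boundaries are inclusive
#' on the normal side (RT <= 39.3 degC and RR <= 60 mov/min are normal).
#'
#' @param rt rectal temperature, degC. Vectorised.
#' @param rr respiratory rate, movements per minute.
#' @param thresholds see [comfort_thresholds()].
#' @return Factor with levels `normal`, `heat_stress`.
#' @export
classify_physiology <- function(rt, rr, thresholds = comfort_thresholds()) {
  if (any(rt <= 0) || any(rr <= 0)) stop("rt and rr must be positive")
  stressed <- rt > thresholds$rt_max | rr > thresholds$rr_max
  factor(ifelse(stressed, "heat_stress", "normal"),
         levels = c("normal", "heat_stress"))
}

#' Classify air temperature and humidity against phase-specific ranges
#'
#' @param t_air dry-bulb temperature, degC. Vectorised.
#' @param rh relative humidity, percent.
#' @param phase production phase, `"growth"` or `"termination"`.
#' @param thresholds see [comfort_thresholds()].
#' @return Data frame with columns `temperature`
#'   (below/within/above_optimal), `recommended`
#'   (below/within/above_recommended) and `humidity`
#'   (good, below_good, above_good, critical_low, critical_high).
#'   Range boundaries are inclusive.
#' @export
classify_air <- function(t_air, rh, phase = c("growth", "termination"),
                         thresholds = comfort_thresholds()) {
  phase <- match.arg(phase)
  rng <- thresholds$air_ranges[[phase]]
  if (is.null(rng)) stop("unknown phase: ", phase)
  band <- function(x, lim, what) {
    ifelse(x < lim[1], paste0("below_", what),
           ifelse(x > lim[2], paste0("above_", what), paste0("within_", what)))
  }
  hg <- thresholds$humidity_good; hc <- thresholds$humidity_critical
  humidity <- ifelse(rh < hc[1], "critical_low",
              ifelse(rh > hc[2], "critical_high",
              ifelse(rh < hg[1], "below_good",
              ifelse(rh > hg[2], "above_good", "good"))))
  data.frame(temperature = band(t_air, rng$optimal, "optimal"),
             recommended = band(t_air, rng$recommended, "recommended"),
             humidity = humidity,
             stringsAsFactors = FALSE)
}

#' Read a microclimate CSV
#'
#' Expected columns: `timestamp` (ISO-8601), `t_air` (degC), `rh`
#' (percent), and optionally `t_globe` (degC).
#'
#' @param path CSV file path.
#' @return Data frame with `timestamp` parsed as POSIXct, validated by
#'   [validate_microclimate()].
#' @export
read_microclimate <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "t_air", "rh")
  if (!all(need %in% names(x)))
    stop("microclimate file ", path, " must have columns ",
         paste(need, collapse = ", "))
  x$timestamp <- parse_timestamps(x$timestamp)
  validate_microclimate(x)
}

# ISO-8601 parsing per element: a midnight record may be serialised
# date-only, and as.POSIXct would otherwise lock onto that format for
# the whole column.
parse_timestamps <- function(s) {
  if (inherits(s, "POSIXct")) return(s)
  t <- as.POSIXct(s, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  iso <- is.na(t)
  if (any(iso))
    t[iso] <- as.POSIXct(s[iso], tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  date_only <- is.na(t)
  if (any(date_only))
    t[date_only] <- as.POSIXct(s[date_only], tz = "UTC", format = "%Y-%m-%d")
  if (anyNA(t)) stop("unparseable timestamp: ", s[which(is.na(t))[1]])
  t
}

#' Validate a microclimate series
#'
#' @param x data frame with `timestamp`, `t_air`, `rh`, optional `t_globe`.
#' @return `x`, invisibly checked: rh in `[0, 100]`, finite t_globe,
#'   strictly increasing timestamps.
#' @export
validate_microclimate <- function(x) {
  if (any(x$rh < 0 | x$rh > 100)) stop("rh must lie in [0, 100]")
  if (!is.null(x$t_globe) && any(!is.finite(x$t_globe)))
    stop("t_globe must be finite when present")
  if (is.unsorted(x$timestamp, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  x
}

#' Read a physiological-records CSV
#'
#' Expected columns: `timestamp`, `animal_id`, `rt` (rectal temperature,
#' degC), `rr` (respiratory rate, mov/min).
#'
#' @param path CSV file path.
#' @return Data frame with parsed timestamps.
#' @export
read_physiology <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "animal_id", "rt", "rr")
  if (!all(need %in% names(x)))
    stop("physiology file ", path, " must have columns ",
         paste(need, collapse = ", "))
  x$timestamp <- parse_timestamps(x$timestamp)
  x
}

#' Summarise a microclimate series
#'
#' @param records microclimate data frame (see [read_microclimate()]).
#' @param variables columns to summarise; defaults to those present among
#'   `t_air`, `rh`, `t_globe`.
#' @return Data frame with one row per variable: `mean`, `min`, `max`.
#' @export
summarize_series <- function(records,
                             variables = intersect(c("t_air", "rh", "t_globe"),
                                                   names(records))) {
  if (nrow(records) == 0) stop("empty series")
  res <- lapply(variables, function(v) {
    x <- records[[v]]
    data.frame(variable = v, mean = mean(x), min = min(x), max = max(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
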