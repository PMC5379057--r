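# Pump and actuator quality control: actuation-time classification,
# fail-safe rerouting over redundant pump pathways, daily flow computation
# from collected volume, and stroke-volume drift normalization.

#' Classify an actuator from its actuation time
#'
#' Electromagnetic actuators are monitored in situ; the actuation time is
#' the time needed to open the valve fully. Times inside the stability
#' window indicate long-term mechanical stability; shorter times indicate
#' incomplete valve opening, longer times an actuation distance too long
#' for reliable actuation. Both window endpoints are inclusive.
#'
#' @param time_us actuation time(s) in microseconds (> 0).
#' @param low,high window bounds in microseconds (defaults 250 and 625).
#' @return character vector with values `"stable"`,
#'   `"incomplete_opening"`, `"unreliable"`.
#' @examples
#' classify_actuator(c(400, 200, 700))
#' @export
classify_actuator <- function(time_us, low = 250, high = 625) {
  stopifnot(low < high)
  if (any(!is.finite(time_us)) || any(time_us <= 0)) {
    stop("actuation times must be positive", call. = FALSE)
  }
  ifelse(time_us < low, "incomplete_opening",
         ifelse(time_us > high, "unreliable", "stable"))
}

#' Select active pump pathways given actuator statuses
#'
#' Each flow segment is served by one or more redundant pump pathways,
#' each driven by a set of actuators. The first pathway (in the given
#' order) whose actuators are all stable is activated; a segment with no
#' such pathway is flagged `FAILED`.
#'
#' @param statuses named character vector mapping actuator id to a status
#'   from [classify_actuator()].
#' @param segments named list; each element is a segment, itself a list of
#'   pathways, each pathway a character vector of actuator ids.
#' @return data frame `segment`, `pathway` (index of the active pathway,
#'   `NA` when failed), `failed` (logical).
#' @export
reroute_plan <- function(statuses, segments) {
  stopifnot(is.list(segments), length(segments) > 0)
  rows <- lapply(names(segments), function(seg) {
    pathways <- segments[[seg]]
    if (!length(pathways)) stop("segment '", seg, "' has no pathways",
                                call. = FALSE)
    chosen <- NA_integer_
    for (i in seq_along(pathways)) {
      ids <- pathways[[i]]
      st <- statuses[ids]
      if (any(is.na(st))) {
        stop("segment '", seg, "' references unknown actuator(s): ",
             paste(ids[is.na(st)], collapse = ", "), call. = FALSE)
      }
      if (all(st == "stable")) { chosen <- i; break }
    }
    data.frame(segment = seg, pathway = chosen, failed = is.na(chosen),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Through-system flow rate from the collected media volume
#'
#' Daily media collection doubles as the flow measurement: the realized
#' flow is the collected volume divided by the elapsed time.
#'
#' @param collected_volume_ul collected volume in microlitres.
#' @param elapsed_h elapsed time in hours (> 0).
#' @return flow rate in microlitres per hour.
#' @examples
#' daily_flow_rate(960, 24)  # 40, the single-tissue set point
#' daily_flow_rate(2400, 24) # 100, the five-tissue set point
#' @export
daily_flow_rate <- function(collected_volume_ul, elapsed_h) {
  if (any(elapsed_h <= 0)) stop("elapsed time must be positive",
                                call. = FALSE)
  collected_volume_ul / elapsed_h
}

#' Normalize a stroke-volume series to its initial value
#'
#' Pump stroke volumes are tracked over month-long runs normalized to the
#' first measurement, exposing drift as departure from 1. Idempotent.
#'
#' @param series numeric stroke volumes; first value must be > 0.
#' @return `series / series[1]`.
#' @export
normalize_stroke <- function(series) {
  if (!length(series)) return(numeric(0))
  if (!is.finite(series[1L]) || series[1L] <= 0) {
    stop("initial stroke volume must be positive", call. = FALSE)
  }
  series / series[1L]
}

#' Read an actuator telemetry CSV
#'
#' Columns `timestamp, actuator_id, actuation_time_us`; ISO-8601
#' timestamps.
#'
#' @param path file path.
#' @return data frame of readings.
#' @export
read_telemetry_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("timestamp", "actuator_id", "actuation_time_us")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("telemetry file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
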