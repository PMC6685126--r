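# Fitbit-derived features: step/bout statistics and sleep statistics.

#' Segment 5-min step samples into active/sedentary bouts
#'
#' An interval is sedentary when its step count is below `threshold` and
#' active at or above it (the threshold interval counts as active). Bouts
#' are maximal runs of same-kind intervals; grid gaps longer than one 5-min
#' interval terminate the current bout.
#'
#' @param steps data.frame with timestamp and steps (5-min grid)
#' @param threshold steps per 5-min interval separating sedentary from active
#' @param interval_s nominal sampling interval in seconds
#' @return data.table of bouts: kind, start, end, n_intervals, total_steps
#' @export
segment_step_bouts <- function(steps, threshold = 10, interval_s = 300) {
  dt <- data.table::as.data.table(steps)[order(timestamp)]
  empty <- data.table::data.table(
    kind = character(), start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    n_intervals = integer(), total_steps = integer())
  if (nrow(dt) == 0) return(empty)
  gap <- c(0, as.numeric(diff(dt$timestamp), units = "secs"))
  kind <- ifelse(dt$steps >= threshold, "active", "sedentary")
  brk <- gap > interval_s + 1e-9 | c(TRUE, kind[-1] != kind[-length(kind)])
  id <- cumsum(brk)
  dt[, kind := kind]
  dt[, .(kind = kind[1], start = timestamp[1],
         end = timestamp[.N] + interval_s, n_intervals = .N,
         total_steps = sum(steps)), by = .(bout = id)][, bout := NULL][]
}

#' Step features of a window
#'
#' Total steps, max steps in any 5-min sample, counts of active and
#' sedentary bouts, bout-length statistics per kind (minutes), and min/max/
#' mean steps over active bouts.
#'
#' @param steps 5-min step samples of the window
#' @param bouts output of [segment_step_bouts()] on the same samples
#' @param interval_s nominal sampling interval in seconds
#' @return named numeric feature map (all NA when no samples)
#' @export
step_features <- function(steps, bouts = NULL, interval_s = 300) {
  dt <- data.table::as.data.table(steps)
  if (nrow(dt) == 0) {
    nm <- c("steps_total", "steps_max_5min", "n_active_bouts", "n_sedentary_bouts")
    return(new_feature_map(nm, rep(NA_real_, length(nm))))
  }
  if (is.null(bouts)) bouts <- segment_step_bouts(dt, interval_s = interval_s)
  act <- bouts[kind == "active"]; sed <- bouts[kind == "sedentary"]
  f <- new_feature_map(
    c("steps_total", "steps_max_5min", "n_active_bouts", "n_sedentary_bouts"),
    c(sum(dt$steps), max(dt$steps), nrow(act), nrow(sed)))
  f <- c(f, stat_block(act$n_intervals * interval_s / 60, "active_bout"))
  f <- c(f, stat_block(sed$n_intervals * interval_s / 60, "sedentary_bout"))
  f <- c(f, stat_block(act$total_steps, "active_bout_steps"))
  f
}

#' Sleep features of a window
#'
#' Counts of asleep/restless/awake 1-min samples; weak sleep efficiency
#' (asleep + restless over asleep + restless + awake) and strong sleep
#' efficiency (asleep over the same denominator); per-state bout count/sum/
#' length statistics; and the clock hour of the start and end of the longest
#' and shortest bout of each state. Unknown samples are excluded from all
#' counts and split bouts.
#'
#' @param sleep 1-min state samples (timestamp, state)
#' @param interval_s nominal sampling interval in seconds
#' @return named numeric feature map (efficiencies NA on a zero denominator)
#' @export
sleep_features <- function(sleep, interval_s = 60) {
  dt <- data.table::as.data.table(sleep)[order(timestamp)]
  states <- c("asleep", "restless", "awake")
  base_nm <- c(paste0("n_", states), "weak_sleep_efficiency", "strong_sleep_efficiency")
  if (nrow(dt) == 0) {
    return(new_feature_map(base_nm, rep(NA_real_, length(base_nm))))
  }
  counts <- vapply(states, function(s) sum(dt$state == s), numeric(1))
  denom <- sum(counts)
  weak <- if (denom > 0) (counts["asleep"] + counts["restless"]) / denom else NA_real_
  strong <- if (denom > 0) counts["asleep"] / denom else NA_real_
  f <- new_feature_map(base_nm, c(counts, weak, strong))
  # bouts: unknown splits; gaps > one interval split
  gap <- c(0, as.numeric(diff(dt$timestamp), units = "secs"))
  brk <- gap > interval_s + 1e-9 | c(TRUE, dt$state[-1] != dt$state[-nrow(dt)])
  id <- cumsum(brk)
  bouts <- dt[, .(state = state[1], start = timestamp[1],
                  end = timestamp[.N] + interval_s, n = .N), by = .(bout = id)]
  bouts <- bouts[state != "unknown"]
  for (s in states) {
    bb <- bouts[state == s]
    mins <- bb$n * interval_s / 60
    f <- c(f, new_feature_map(paste0(s, c("_bout_count", "_bout_sum_min")),
                              c(nrow(bb), sum(mins))))
    f <- c(f, stat_block(mins, paste0(s, "_bout")))
    if (nrow(bb) > 0) {
      lo <- which.max(mins); sh <- which.min(mins)
      f <- c(f, new_feature_map(
        paste0(s, c("_longest_bout_start_h", "_longest_bout_end_h",
                    "_shortest_bout_start_h", "_shortest_bout_end_h")),
        c(hour_of(bb$start[lo]), hour_of(bb$end[lo]),
          hour_of(bb$start[sh]), hour_of(bb$end[sh]))))
    } else {
      f <- c(f, new_feature_map(
        paste0(s, c("_longest_bout_start_h", "_longest_bout_end_h",
                    "_shortest_bout_start_h", "_shortest_bout_end_h")),
        rep(NA_real_, 4)))
    }
  }
  f
}
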