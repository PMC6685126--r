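#' Epoch, day-filter and granularity vocabularies
#' @name segment_axes
#' @keywords internal
NULL

ls_epochs <- function() c("all_day", "night", "morning", "afternoon", "evening")
ls_day_filters <- function() c("all_days", "weekdays", "weekends")
ls_granularities <- function() c("semester", "half_semester", "weekly")

# clock-hour bands of the named epochs, half-open [start, end)
epoch_band <- function(epoch) {
  switch(epoch,
    all_day   = c(0, 24),
    night     = c(0, 6),
    morning   = c(6, 12),
    afternoon = c(12, 18),
    evening   = c(18, 24),
    stop("unknown epoch: ", epoch)
  )
}

#' Study calendar
#'
#' Describes the study period: a start date, a number of whole weeks and the
#' week after which the "first half" of the semester ends (the halves need
#' not be equal; the default 16-week semester splits 6 + 10 around
#' midterms).
#'
#' @param start_date Date (or coercible) of the first study day
#' @param n_weeks integer number of study weeks (>= 1)
#' @param half_split_week last week of the first half (1 <= h < n_weeks)
#' @return object of class `ls_calendar`
#' @export
study_calendar <- function(start_date, n_weeks = 16L, half_split_week = 6L) {
  start_date <- as.Date(start_date)
  n_weeks <- as.integer(n_weeks)
  half_split_week <- as.integer(half_split_week)
  if (is.na(start_date)) stop("invalid start_date")
  if (n_weeks < 1L) stop("n_weeks must be >= 1")
  if (half_split_week < 1L || half_split_week >= n_weeks)
    stop("half_split_week must satisfy 1 <= half_split_week < n_weeks")
  structure(
    list(start_date = start_date, n_weeks = n_weeks,
         half_split_week = half_split_week),
    class = "ls_calendar"
  )
}

calendar_start_time <- function(calendar) {
  as.POSIXct(paste(calendar$start_date, "00:00:00"), tz = "UTC")
}
calendar_end_time <- function(calendar) {
  calendar_start_time(calendar) + calendar$n_weeks * 7 * 86400
}

#' Enumerate time-segment specifications
#'
#' Cartesian product of epochs (5), day-of-week filters (3) and aggregation
#' granularities (3); the default configuration yields the full 5 x 3 x 3 =
#' 45 segment types.
#'
#' @param epochs,day_filters,granularities subsets of the default axes
#' @return data.table with columns epoch, day_filter, granularity
#' @export
enumerate_segment_specs <- function(epochs = ls_epochs(),
                                    day_filters = ls_day_filters(),
                                    granularities = ls_granularities()) {
  if (length(epochs) == 0 || length(day_filters) == 0 || length(granularities) == 0)
    stop("each segment axis needs at least one member")
  stopifnot(all(epochs %in% ls_epochs()),
            all(day_filters %in% ls_day_filters()),
            all(granularities %in% ls_granularities()))
  data.table::CJ(epoch = unique(epochs), day_filter = unique(day_filters),
                 granularity = unique(granularities), sorted = FALSE)[]
}

#' Materialize the concrete date windows of a segment spec
#'
#' Semester granularity gives one window over the whole calendar;
#' half-semester gives two windows split after `half_split_week`; weekly
#' gives one 7-day window per study week (weeks anchored to the calendar
#' start date's weekday).
#'
#' @param spec list/row with epoch, day_filter, granularity
#' @param calendar an `ls_calendar`
#' @return data.table with columns epoch, day_filter, granularity, start,
#'   end (POSIXct, end exclusive) and label
#' @export
materialize_windows <- function(spec, calendar) {
  stopifnot(inherits(calendar, "ls_calendar"))
  t0 <- calendar_start_time(calendar)
  wk <- 7 * 86400
  gran <- spec$granularity
  if (gran == "semester") {
    starts <- t0
    ends <- t0 + calendar$n_weeks * wk
    labels <- "semester"
  } else if (gran == "half_semester") {
    split <- t0 + calendar$half_split_week * wk
    starts <- c(t0, split)
    ends <- c(split, t0 + calendar$n_weeks * wk)
    labels <- paste("half semester", as.Date(starts, tz = "UTC"))
  } else if (gran == "weekly") {
    starts <- t0 + (seq_len(calendar$n_weeks) - 1L) * wk
    ends <- starts + wk
    labels <- paste("week", as.Date(starts, tz = "UTC"))
  } else stop("unknown granularity: ", gran)
  data.table::data.table(
    epoch = spec$epoch, day_filter = spec$day_filter, granularity = gran,
    start = starts, end = ends, label = labels
  )
}

#' Bracketed segment label used in feature names
#'
#' @param window a row of [materialize_windows()]
#' @return string like `"[evening, weekends, week 2017-03-08]"`
#' @export
segment_label <- function(window) {
  sprintf("[%s, %s, %s]", window$epoch, window$day_filter, window$label)
}

day_filter_keep <- function(t, day_filter) {
  switch(day_filter,
    all_days = rep(TRUE, length(t)),
    weekdays = !is_weekend(t),
    weekends = is_weekend(t),
    stop("unknown day filter: ", day_filter)
  )
}

#' Slice a timestamped sample stream by a time window
#'
#' Keeps samples with `start <= t < end`, clock time inside the epoch's
#' half-open band (midnight belongs to night) and weekday allowed by the
#' day filter.
#'
#' @param stream data.frame/data.table with a POSIXct `timestamp` column
#' @param window a row of [materialize_windows()]
#' @return data.table subset (possibly empty)
#' @export
slice_stream <- function(stream, window) {
  dt <- data.table::as.data.table(stream)
  if (nrow(dt) == 0) return(dt)
  t <- dt$timestamp
  keep <- t >= window$start & t < window$end
  band <- epoch_band(window$epoch)
  h <- hour_of(t)
  keep <- keep & h >= band[1] & h < band[2]
  keep <- keep & day_filter_keep(t, window$day_filter)
  dt[keep]
}

#' Allowed time intervals of a window (for clipping duration events)
#'
#' Expands a window into the list of disjoint absolute intervals obtained by
#' intersecting its date range with the epoch clock band on the days allowed
#' by the day filter.
#'
#' @param window a row of [materialize_windows()]
#' @return data.table with columns start, end (POSIXct)
#' @export
window_intervals <- function(window) {
  band <- epoch_band(window$epoch)
  days <- seq(from = as.Date(window$start, tz = "UTC"),
              to = as.Date(window$end - 1, tz = "UTC"), by = "day")
  d0 <- as.POSIXct(paste(days, "00:00:00"), tz = "UTC")
  iv <- data.table::data.table(start = d0 + band[1] * 3600,
                               end = d0 + band[2] * 3600)
  iv <- iv[day_filter_keep(start, window$day_filter)]
  iv[, start := pmax(start, window$start)]
  iv[, end := pmin(end, window$end)]
  iv[end > start]
}

#' Clip duration events to a window
#'
#' Events spanning a window/epoch boundary are attributed by clipping: each
#' event contributes the parts of `[start, end)` that intersect the window's
#' allowed intervals, so total time is conserved across the epoch partition.
#'
#' @param events data.table with POSIXct columns `start`, `end`
#' @param window a row of [materialize_windows()]
#' @return data.table of clipped events (other columns preserved)
#' @export
clip_events <- function(events, window) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0) return(ev)
  iv <- window_intervals(window)
  if (nrow(iv) == 0) return(ev[0])
  out <- lapply(seq_len(nrow(iv)), function(i) {
    s <- iv$start[i]; e <- iv$end[i]
    hit <- ev[end > s & start < e]
    if (nrow(hit) == 0) return(hit)
    hit[, start := pmax(start, s)]
    hit[, end := pmin(end, e)]
    hit
  })
  data.table::rbindlist(out)[order(start)]
}
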