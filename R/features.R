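# Orchestration: run every feature family over every materialized time
# segment of a participant's streams and emit named features ready for the
# per-feature-set matrices.

#' Feature extraction configuration
#'
#' Controls which time segments and feature families are extracted and the
#' extraction parameters. Defaults reproduce the full design: 5 epochs x 3
#' day filters x 3 granularities = 45 segment types and all 7 feature sets
#' (bluetooth, calls, campus_map, location, screen, sleep, steps).
#'
#' @param epochs,day_filters,granularities segment axes
#' @param families feature sets to extract
#' @param dbscan_eps,dbscan_min_samples significant-place DBSCAN parameters
#'   (30 m and 5 samples at the 10-min location cadence, i.e. roughly an
#'   hour of dwell defines a place)
#' @param step_threshold steps per 5-min interval separating sedentary from
#'   active
#' @param hourly_screen_indicators include the 24-hour first/last screen
#'   event indicator block
#' @return list of class `ls_feature_config`
#' @export
feature_config <- function(epochs = ls_epochs(),
                           day_filters = ls_day_filters(),
                           granularities = ls_granularities(),
                           families = c("bluetooth", "calls", "campus_map",
                                        "location", "screen", "sleep", "steps"),
                           dbscan_eps = 30, dbscan_min_samples = 5,
                           step_threshold = 10,
                           hourly_screen_indicators = TRUE) {
  structure(list(
    epochs = epochs, day_filters = day_filters, granularities = granularities,
    families = families, dbscan_eps = dbscan_eps,
    dbscan_min_samples = dbscan_min_samples, step_threshold = step_threshold,
    hourly_screen_indicators = hourly_screen_indicators
  ), class = "ls_feature_config")
}

window_covered_minutes <- function(window) {
  iv <- window_intervals(window)
  if (nrow(iv) == 0) return(0)
  sum(as.numeric(iv$end - iv$start, units = "mins"))
}

#' Extract all configured features for one participant
#'
#' Precomputes the whole-study artifacts (speed annotation, global place
#' clustering, home estimate from all nights, campus category labels,
#' Bluetooth device classification, screen sessions) and then evaluates each
#' feature family over each materialized segment window. Feature names carry
#' the bracketed segment label, e.g.
#' `"off_campus_min [evening, weekends, semester]"`.
#'
#' @param streams a participant's sensor bundle (list of stream data.tables)
#' @param campus_map campus map list
#' @param calendar an [study_calendar()]
#' @param config an [feature_config()]
#' @return data.table with columns feature_set, name, value
#' @export
extract_participant_features <- function(streams, campus_map, calendar,
                                         config = feature_config()) {
  fam <- config$families
  specs <- enumerate_segment_specs(config$epochs, config$day_filters,
                                   config$granularities)
  has_loc <- !is.null(streams$location) && nrow(streams$location) > 0

  ann <- if (has_loc) compute_speeds(streams$location) else NULL
  global_places <- NULL; home <- NULL; labeled <- NULL
  if (has_loc) {
    global_places <- cluster_static_points(ann, config$dbscan_eps,
                                           config$dbscan_min_samples, "global")
    night_win <- data.table::data.table(
      epoch = "night", day_filter = "all_days", granularity = "semester",
      start = calendar_start_time(calendar), end = calendar_end_time(calendar),
      label = "semester")
    home <- estimate_home(slice_stream(ann, night_win[1]),
                          config$dbscan_eps, config$dbscan_min_samples)
    labeled <- data.table::copy(ann)
    labeled[, category := assign_campus_category(lat, lon, campus_map)]
  }
  bt_groups <- NULL
  if ("bluetooth" %in% fam && !is.null(streams$bluetooth) &&
      nrow(streams$bluetooth) > 0) {
    bt_groups <- classify_bluetooth_devices(streams$bluetooth)$groups
  }
  sessions_all <- if (!is.null(streams$screen) && nrow(streams$screen) > 0) {
    screen_sessions(streams$screen, truncate_at = calendar_end_time(calendar))
  } else list(interaction = data.table::data.table(
    start = as.POSIXct(character(), tz = "UTC"), end = as.POSIXct(character(), tz = "UTC")),
    unlocked = data.table::data.table(
      start = as.POSIXct(character(), tz = "UTC"), end = as.POSIXct(character(), tz = "UTC")))

  out <- list()
  emit <- function(set, fmap, seg) {
    if (length(fmap) == 0) return(invisible(NULL))
    out[[length(out) + 1L]] <<- data.table::data.table(
      feature_set = set, name = paste(names(fmap), seg), value = as.numeric(fmap))
    invisible(NULL)
  }

  for (si in seq_len(nrow(specs))) {
    spec <- specs[si]
    windows <- materialize_windows(spec, calendar)
    for (wi in seq_len(nrow(windows))) {
      win <- windows[wi]
      seg <- segment_label(win)
      if ("location" %in% fam) {
        sl <- if (has_loc) slice_stream(ann, win) else
          data.table::data.table(timestamp = as.POSIXct(character(), tz = "UTC"),
                                 lat = numeric(), lon = numeric(),
                                 speed_kmh = numeric(), state = character())
        local_places <- cluster_static_points(sl, config$dbscan_eps,
                                              config$dbscan_min_samples, "local")
        fmap <- mobility_features(sl, global_places, local_places)
        fmap <- c(fmap, new_feature_map("circadian_regularity_24h",
          if (nrow(sl) >= 3) circadian_regularity(sl) else NA_real_))
        hm <- if (!is.null(home) && !is.null(home$center) && nrow(sl) > 0) {
          d <- dist_m(sl$lat, sl$lon, home$center["lat"], home$center["lon"])
          dw <- sample_dwell_min(sl$timestamp)
          new_feature_map(c("time_at_home_10m_min", "time_at_home_100m_min"),
                          c(sum(dw[d <= 10]), sum(dw[d <= 100])))
        } else new_feature_map(c("time_at_home_10m_min", "time_at_home_100m_min"),
                               c(NA_real_, NA_real_))
        emit("location", c(fmap, hm), seg)
      }
      if ("campus_map" %in% fam) {
        lb <- if (has_loc) slice_stream(labeled, win) else NULL
        fmap <- campus_features(lb %||% data.table::data.table(
          timestamp = as.POSIXct(character(), tz = "UTC"), category = character()))
        inter_w <- clip_events(sessions_all$interaction, win)
        st_w <- if (!is.null(streams$steps)) slice_stream(streams$steps, win) else NULL
        fmap <- c(fmap, new_feature_map(
          c("study_duration_min", "social_duration_min"),
          c(study_duration(lb, st_w, inter_w,
                           sedentary_threshold = config$step_threshold),
            social_duration(lb, if (!is.null(streams$audio))
              slice_stream(streams$audio, win) else NULL))))
        emit("campus_map", fmap, seg)
      }
      if ("steps" %in% fam) {
        st <- if (!is.null(streams$steps)) slice_stream(streams$steps, win) else
          data.table::data.table(timestamp = as.POSIXct(character(), tz = "UTC"),
                                 steps = integer())
        bouts <- segment_step_bouts(st, threshold = config$step_threshold)
        emit("steps", step_features(st, bouts), seg)
      }
      if ("sleep" %in% fam) {
        sl <- if (!is.null(streams$sleep)) slice_stream(streams$sleep, win) else
          data.table::data.table(timestamp = as.POSIXct(character(), tz = "UTC"),
                                 state = character())
        emit("sleep", sleep_features(sl), seg)
      }
      if ("screen" %in% fam) {
        sc <- if (!is.null(streams$screen)) slice_stream(streams$screen, win) else
          data.table::data.table(timestamp = as.POSIXct(character(), tz = "UTC"),
                                 status = character())
        sess <- list(interaction = clip_events(sessions_all$interaction, win),
                     unlocked = clip_events(sessions_all$unlocked, win))
        emit("screen", screen_features(sc, sess, window_covered_minutes(win),
                                       config$hourly_screen_indicators), seg)
      }
      if ("calls" %in% fam) {
        cl <- if (!is.null(streams$calls)) slice_stream(streams$calls, win) else NULL
        sm <- if (!is.null(streams$sms)) slice_stream(streams$sms, win) else NULL
        emit("calls", call_sms_features(cl, sm, streams$contact_groups), seg)
      }
      if ("bluetooth" %in% fam) {
        bt <- if (!is.null(streams$bluetooth)) slice_stream(streams$bluetooth, win) else
          data.table::data.table(timestamp = as.POSIXct(character(), tz = "UTC"),
                                 device_id = character())
        emit("bluetooth", bluetooth_features(bt, bt_groups %||% character()), seg)
      }
    }
  }
  data.table::rbindlist(out)
}

#' Extract the per-feature-set matrices of a whole cohort
#'
#' @param cohort an `ls_cohort`
#' @param config an [feature_config()]
#' @param verbose print progress
#' @return named list of participant x feature matrices (one per feature
#'   set), as produced by [assemble_feature_matrix()]
#' @export
extract_cohort_features <- function(cohort, config = feature_config(),
                                    verbose = FALSE) {
  longs <- lapply(cohort$participants, function(p) {
    if (verbose) message("extracting ", p$id)
    ft <- extract_participant_features(p$streams, cohort$campus_map,
                                       cohort$calendar, config)
    ft[, participant_id := p$id]
    ft
  })
  assemble_feature_matrix(data.table::rbindlist(longs))
}

#' Assemble per-feature-set matrices from long feature records
#'
#' @param feature_long data.table with participant_id, feature_set, name,
#'   value (missing values as NA)
#' @return named list of numeric matrices (rownames = participant ids,
#'   colnames = feature names with segment labels)
#' @export
assemble_feature_matrix <- function(feature_long) {
  dt <- data.table::as.data.table(feature_long)
  stopifnot(all(c("participant_id", "feature_set", "name", "value") %in% names(dt)))
  if (anyDuplicated(dt, by = c("participant_id", "feature_set", "name")))
    stop("duplicate (participant, feature, segment) records")
  sets <- sort(unique(dt$feature_set))
  out <- lapply(sets, function(s) {
    wide <- data.table::dcast(dt[feature_set == s], participant_id ~ name,
                              value.var = "value")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$participant_id
    m
  })
  names(out) <- sets
  out
}

#' Segment group of each feature column
#'
#' Parses the bracketed segment label out of feature names; used to group
#' columns for the first (within-segment) stage of nested randomized
#' logistic regression.
#'
#' @param names feature column names
#' @return character vector of segment labels
#' @export
feature_segment_groups <- function(names) {
  m <- regexpr("\\[[^]]*\\]$", names)
  out <- rep("(none)", length(names))
  out[m > 0] <- regmatches(names, m)
  out
}
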