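# Communication (calls/SMS), phone-usage (screen) and Bluetooth features,
# including the self/related/others device-classification procedure.

audience_of_group <- function(group) {
  switch(group,
    family = "family",
    friend_on_campus = "friends_on_campus",
    friend_off_campus = "friends_off_campus",
    "other"
  )
}

#' Call and SMS features of a window
#'
#' Per direction (incoming, outgoing, missed) and audience (everyone,
#' family, friends off campus, friends on campus): call counts and call
#' durations, SMS counts (no durations); plus distinct-correspondent counts
#' overall and per audience.
#'
#' @param calls call log (timestamp, direction, duration, contact_id);
#'   NULL marks the stream absent
#' @param sms SMS log (timestamp, direction, contact_id); NULL if absent
#' @param contact_groups data.frame contact_id -> group
#' @return named numeric feature map; NA markers when both streams absent
#' @export
call_sms_features <- function(calls, sms, contact_groups) {
  audiences <- c("everyone", "family", "friends_off_campus", "friends_on_campus")
  directions <- c("incoming", "outgoing", "missed")
  cg <- data.table::as.data.table(contact_groups)
  lookup <- function(ids) {
    g <- cg$group[match(ids, cg$contact_id)]
    vapply(ifelse(is.na(g), "other", g), audience_of_group, character(1))
  }
  f <- new_feature_map()
  if (is.null(calls) && is.null(sms)) {
    for (d in directions) for (a in audiences) {
      f <- c(f, new_feature_map(
        c(paste0("calls_", d, "_", a, "_count"),
          paste0("calls_", d, "_", a, "_duration_s"),
          paste0("sms_", d, "_", a, "_count")),
        rep(NA_real_, 3)))
    }
    return(f)
  }
  cl <- data.table::as.data.table(calls %||% data.table::data.table(
    timestamp = as.POSIXct(character(), tz = "UTC"), direction = character(),
    duration = numeric(), contact_id = character()))
  sm <- data.table::as.data.table(sms %||% data.table::data.table(
    timestamp = as.POSIXct(character(), tz = "UTC"), direction = character(),
    contact_id = character()))
  if (nrow(cl)) cl[, audience := lookup(contact_id)]
  if (nrow(sm)) sm[, audience := lookup(contact_id)]
  for (d in directions) {
    for (a in audiences) {
      cd <- if (nrow(cl)) cl[direction == d & (a == "everyone" | audience == a)] else cl
      sd_ <- if (nrow(sm)) sm[direction == d & (a == "everyone" | audience == a)] else sm
      f <- c(f, new_feature_map(
        c(paste0("calls_", d, "_", a, "_count"),
          paste0("calls_", d, "_", a, "_duration_s"),
          paste0("sms_", d, "_", a, "_count")),
        c(nrow(cd), sum(cd$duration), nrow(sd_))))
    }
  }
  all_ids <- unique(c(cl$contact_id, sm$contact_id))
  f <- c(f, new_feature_map("correspondents_everyone", length(all_ids)))
  aud_all <- if (length(all_ids)) lookup(all_ids) else character(0)
  for (a in audiences[-1]) {
    f <- c(f, new_feature_map(paste0("correspondents_", a), sum(aud_all == a)))
  }
  f
}

#' Build screen sessions from raw screen events
#'
#' Interaction sessions run from an unlock event to the first subsequent off
#' or lock event; unlocked sessions run from an unlock to the first
#' subsequent lock. An unmatched trailing unlock is truncated at
#' `truncate_at` (e.g. the window end) when provided, otherwise dropped.
#'
#' @param screen screen events (timestamp, status in on/off/lock/unlock)
#' @param truncate_at optional POSIXct end bound for unmatched sessions
#' @return list with data.tables `interaction` and `unlocked` (start, end)
#' @export
screen_sessions <- function(screen, truncate_at = NULL) {
  dt <- data.table::as.data.table(screen)[order(timestamp)]
  empty <- data.table::data.table(start = as.POSIXct(character(), tz = "UTC"),
                                  end = as.POSIXct(character(), tz = "UTC"))
  build <- function(enders) {
    if (nrow(dt) == 0) return(empty)
    out <- list()
    open_start <- NULL
    for (i in seq_len(nrow(dt))) {
      s <- dt$status[i]
      if (s == "unlock" && is.null(open_start)) {
        open_start <- dt$timestamp[i]
      } else if (!is.null(open_start) && s %in% enders) {
        out[[length(out) + 1L]] <- data.table::data.table(
          start = open_start, end = dt$timestamp[i])
        open_start <- NULL
      }
    }
    if (!is.null(open_start) && !is.null(truncate_at) && truncate_at > open_start) {
      out[[length(out) + 1L]] <- data.table::data.table(
        start = open_start, end = truncate_at)
    }
    if (length(out) == 0) return(empty)
    data.table::rbindlist(out)
  }
  list(interaction = build(c("off", "lock")), unlocked = build("lock"))
}

#' Screen-usage features of a window
#'
#' Unlocks per minute, total interaction and unlocked time, clock hour of
#' the first unlock/on and the last unlock/lock/on, session-length
#' statistics, and per-day-averaged indicators of the first/last event
#' falling in each hour of the day (e.g. "first unlock between 1 and 2 pm").
#'
#' @param screen sliced screen events of the window
#' @param sessions sessions clipped to the window
#'   (list with `interaction` and `unlocked`)
#' @param window_minutes covered duration of the window in minutes
#' @param hourly_indicators emit the 24-hour first/last event indicator
#'   block (share of window days whose first/last event fell in each hour)
#' @return named numeric feature map; unlock-derived features NA when the
#'   window has no unlock events
#' @export
screen_features <- function(screen, sessions, window_minutes,
                            hourly_indicators = TRUE) {
  dt <- data.table::as.data.table(screen)
  f <- new_feature_map()
  unlocks <- dt[status == "unlock"]
  ons <- dt[status == "on"]
  locks <- dt[status == "lock"]
  f <- c(f, new_feature_map("unlocks_per_min",
    if (window_minutes > 0) nrow(unlocks) / window_minutes else NA_real_))
  inter <- sessions$interaction; unl <- sessions$unlocked
  f <- c(f, new_feature_map(
    c("interaction_total_min", "unlocked_total_min"),
    c(sum(as.numeric(inter$end - inter$start, units = "mins")),
      sum(as.numeric(unl$end - unl$start, units = "mins")))))
  first_h <- function(x) if (nrow(x)) hour_of(min(x$timestamp)) else NA_real_
  last_h <- function(x) if (nrow(x)) hour_of(max(x$timestamp)) else NA_real_
  f <- c(f, new_feature_map(
    c("first_unlock_h", "first_on_h", "last_unlock_h", "last_lock_h", "last_on_h"),
    c(first_h(unlocks), first_h(ons), last_h(unlocks), last_h(locks), last_h(ons))))
  f <- c(f, stat_block(as.numeric(inter$end - inter$start, units = "mins"),
                       "interaction_session_min"))
  f <- c(f, stat_block(as.numeric(unl$end - unl$start, units = "mins"),
                       "unlocked_session_min"))
  if (hourly_indicators) {
    per_day_hour <- function(x, which_end) {
      # share of observed days whose first/last event fell in each hour
      out <- rep(NA_real_, 24)
      if (nrow(x) == 0) return(out)
      d <- x[, .(h = floor(hour_of(if (which_end == "first") min(timestamp)
                                   else max(timestamp)))),
             by = .(day = as.Date(timestamp, tz = "UTC"))]
      tab <- tabulate(d$h + 1L, 24)
      tab / nrow(d)
    }
    for (spec in list(c("first", "unlock"), c("last", "unlock"),
                      c("first", "on"), c("last", "on"), c("last", "lock"))) {
      x <- dt[status == spec[2]]
      vals <- per_day_hour(x, spec[1])
      f <- c(f, new_feature_map(
        sprintf("%s_%s_in_hour_%02d", spec[1], spec[2], 0:23), vals))
    }
  }
  f
}

#' Classify scanned Bluetooth devices into self/related/others
#'
#' Implements the seven-step score-and-cluster procedure: per device, the
#' number of distinct days it was scanned and its average daily frequency
#' (total scans / days); both are z-normalized and summed into a score;
#' K-means clusters the scores with K = 2 and K = 3 and the K with the
#' smaller total within-cluster sum of squares wins. With K = 2 the
#' higher-score cluster is self and the other others; with K = 3 the top
#' cluster is self, the bottom others, the middle related. Mean-score ties
#' break toward fewer self devices; with fewer unique devices than both K,
#' all devices are classified self.
#'
#' @param bluetooth whole-study scan log (timestamp, device_id)
#' @param seed seed for the K-means restarts (fixed for determinism)
#' @param nstart K-means restarts
#' @return list: `groups` (named character map device_id -> group),
#'   `profiles` (data.table with days/frequency/z-scores/score/group),
#'   `k_chosen`
#' @export
classify_bluetooth_devices <- function(bluetooth, seed = 17L, nstart = 10L) {
  dt <- data.table::as.data.table(bluetooth)
  if (nrow(dt) == 0) stop("no Bluetooth scans")
  prof <- dt[, .(
    number_of_days = data.table::uniqueN(as.Date(timestamp, tz = "UTC")),
    total_count = .N
  ), by = device_id]
  prof[, average_frequency := total_count / number_of_days]
  zn <- function(x) {
    s <- if (length(x) > 1) sd(x) else 0
    if (is.finite(s) && s > 0) (x - mean(x)) / s else rep(0, length(x))
  }
  prof[, z_days := zn(number_of_days)]
  prof[, z_freq := zn(average_frequency)]
  prof[, score := z_days + z_freq]
  data.table::setorder(prof, -score, device_id)
  n <- nrow(prof)
  k_sel <- NA_integer_
  if (n < 2) {
    prof[, group := "self"]
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
    fit_k <- function(k) {
      if (n < k || length(unique(prof$score)) < k) return(NULL)
      if (n == k) # each point its own cluster; kmeans rejects k = n
        return(list(cluster = seq_len(n),
                    centers = matrix(prof$score, ncol = 1),
                    tot.withinss = 0))
      kmeans(prof$score, centers = k, nstart = nstart)
    }
    fits <- list()
    for (k in 2:3) {
      fk <- fit_k(k)
      if (!is.null(fk)) fits[[as.character(k)]] <- fk
    }
    if (length(fits) == 0) {
      prof[, group := "self"]
    } else {
      wss <- vapply(fits, function(fm) fm$tot.withinss, numeric(1))
      # K = 2 wins only when its total within-cluster SSE is strictly smaller
      k_sel <- if (length(fits) == 1) as.integer(names(fits))
               else if (wss[["2"]] < wss[["3"]]) 2L else 3L
      fit <- fits[[as.character(k_sel)]]
      centers <- as.numeric(fit$centers)
      # rank clusters by mean score; ties toward fewer self devices
      sizes <- tabulate(fit$cluster, k_sel)
      ord <- order(-centers, sizes)
      rank_of <- match(fit$cluster, ord)
      grp <- if (k_sel == 2) c("self", "others")[rank_of]
             else c("self", "related", "others")[rank_of]
      prof[, group := grp]
    }
  }
  list(groups = stats::setNames(prof$group, prof$device_id),
       profiles = prof[],
       k_chosen = k_sel)
}

#' Bluetooth features of a window
#'
#' For each scope (all devices; self and related combined; others): number
#' of unique devices, scan count of the most and least frequent device, and
#' sum/mean/SD of per-device scan counts.
#'
#' @param bluetooth sliced scans of the window (timestamp, device_id)
#' @param groups named character map device_id -> group (whole-study
#'   classification)
#' @return named numeric feature map (all NA when no scans in the window)
#' @export
bluetooth_features <- function(bluetooth, groups) {
  dt <- data.table::as.data.table(bluetooth)
  scopes <- list(
    all = function(g) rep(TRUE, length(g)),
    self_related = function(g) g %in% c("self", "related"),
    others = function(g) g == "others"
  )
  f <- new_feature_map()
  for (sc in names(scopes)) {
    nm <- paste0("bt_", sc, c("_unique_devices", "_most_frequent_scans",
                              "_least_frequent_scans", "_scans_sum",
                              "_scans_mean", "_scans_sd"))
    if (nrow(dt) == 0) {
      f <- c(f, new_feature_map(nm, rep(NA_real_, 6)))
      next
    }
    g <- unname(groups[dt$device_id])
    g[is.na(g)] <- "others"
    sub <- dt[scopes[[sc]](g)]
    if (nrow(sub) == 0) {
      f <- c(f, new_feature_map(nm, c(0, NA_real_, NA_real_, 0, NA_real_, NA_real_)))
      next
    }
    cnt <- sub[, .N, by = device_id]$N
    f <- c(f, new_feature_map(nm, c(
      length(cnt), max(cnt), min(cnt), sum(cnt), mean(cnt),
      if (length(cnt) > 1) sd(cnt) else 0)))
  }
  f
}
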