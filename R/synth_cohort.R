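# Synthetic cohort generator: AWARE-style smartphone streams + Fitbit-style
# steps/sleep + UCLA-20 surveys, with planted behavioral differences between
# high- and low-loneliness participants. The planted, effect-size-scaled
# behaviors are the ones the pipeline is designed to detect: evening
# off-campus time on weekends, time at social-event houses on weekday
# evenings, overall activity level, and the timing of phone use.

M_PER_DEG_LAT <- 111320

deg_lat <- function(m) m / M_PER_DEG_LAT
deg_lon <- function(m, lat) m / (M_PER_DEG_LAT * cos(lat * pi / 180))

rect_poly <- function(lon_min, lat_min, w_m, h_m) {
  lat_max <- lat_min + deg_lat(h_m)
  lon_max <- lon_min + deg_lon(w_m, lat_min)
  data.frame(lon = c(lon_min, lon_max, lon_max, lon_min),
             lat = c(lat_min, lat_min, lat_max, lat_max))
}

campus_categories <- function() {
  c("social_event_house_1", "social_event_house_2", "student_apartments",
    "residential_halls", "athletic_facilities", "green_spaces")
}

#' Default synthetic campus map
#'
#' A ~1.2 km x 0.9 km rectangular campus with one rectangle per labeled
#' category (two social-event houses, student apartments, residential halls,
#' athletic facilities, green spaces); on-campus area outside the labeled
#' rectangles is treated as academic, everything outside the boundary as off
#' campus.
#'
#' @param center_lat,center_lon campus center in degrees
#' @return list with `boundary` (lon/lat data.frame) and `polygons`
#'   (list of `list(category, coords)`)
#' @export
default_campus_map <- function(center_lat = 40.445, center_lon = -79.945) {
  w <- 1200; h <- 900
  sw_lat <- center_lat - deg_lat(h / 2)
  sw_lon <- center_lon - deg_lon(w / 2, center_lat)
  at <- function(x_m, y_m, w_m, h_m, category) {
    list(category = category,
         coords = rect_poly(sw_lon + deg_lon(x_m, center_lat),
                            sw_lat + deg_lat(y_m), w_m, h_m))
  }
  list(
    boundary = rect_poly(sw_lon, sw_lat, w, h),
    polygons = list(
      at(80,  720, 50,  50,  "social_event_house_1"),
      at(1060, 720, 50,  50,  "social_event_house_2"),
      at(100, 90,  170, 130, "student_apartments"),
      at(880, 110, 190, 150, "residential_halls"),
      at(480, 740, 240, 130, "athletic_facilities"),
      at(500, 380, 200, 170, "green_spaces")
    )
  )
}

poly_center <- function(coords) c(lat = mean(coords$lat), lon = mean(coords$lon))

campus_poly <- function(map, category) {
  for (p in map$polygons) if (p$category == category) return(p)
  stop("category not on map: ", category)
}

#' Construct a behavior profile
#'
#' Bundles the latent loneliness of one synthetic participant with the
#' behavioral parameters the generator plants as a function of that latent.
#'
#' @param loneliness_latent real in 0..1 (pre-semester)
#' @param loneliness_latent_post real in 0..1 (post-semester)
#' @param home_center named numeric `c(lat=, lon=)`
#' @param activity_level mean steps per 5-min waking interval (>= 0)
#' @param evening_offcampus_propensity,social_event_propensity probabilities
#' @param phone_use_rate unlocks per waking hour (>= 0)
#' @param night_use_share share of phone sessions placed after midnight
#' @param sleep_midpoint clock hour of mid-sleep
#' @param device_inventory list with counts self/related/others
#' @param bounding_box optional lon/lat bounding box the home must fall in
#' @return object of class `ls_profile`
#' @export
behavior_profile <- function(loneliness_latent, home_center,
                             activity_level, evening_offcampus_propensity,
                             social_event_propensity, phone_use_rate,
                             sleep_midpoint, device_inventory,
                             loneliness_latent_post = loneliness_latent,
                             night_use_share = 0.15,
                             bounding_box = NULL) {
  probs <- c(loneliness_latent, loneliness_latent_post,
             evening_offcampus_propensity, social_event_propensity,
             night_use_share)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (activity_level < 0 || phone_use_rate < 0)
    stop("rates must be non-negative")
  if (!is.null(bounding_box)) {
    ok <- home_center["lon"] >= min(bounding_box$lon) &
      home_center["lon"] <= max(bounding_box$lon) &
      home_center["lat"] >= min(bounding_box$lat) &
      home_center["lat"] <= max(bounding_box$lat)
    if (!ok) stop("home_center outside the campus-region bounding box")
  }
  structure(list(
    loneliness_latent = loneliness_latent,
    loneliness_latent_post = loneliness_latent_post,
    home_center = home_center, activity_level = activity_level,
    evening_offcampus_propensity = evening_offcampus_propensity,
    social_event_propensity = social_event_propensity,
    phone_use_rate = phone_use_rate, night_use_share = night_use_share,
    sleep_midpoint = sleep_midpoint, device_inventory = device_inventory
  ), class = "ls_profile")
}

# latent -> planted behavior parameters, scaled by effect_size
plant_profile <- function(latent, latent_post, effect, campus_map) {
  centered <- latent - 0.5
  home_cat <- sample(c("student_apartments", "residential_halls"), 1)
  hc <- campus_poly(campus_map, home_cat)$coords
  home <- c(lat = runif(1, min(hc$lat), max(hc$lat)),
            lon = runif(1, min(hc$lon), max(hc$lon)))
  behavior_profile(
    loneliness_latent = latent,
    loneliness_latent_post = latent_post,
    home_center = home,
    activity_level = max(1, 24 * (1 - 1.1 * effect * centered) + rnorm(1, 0, 2)),
    evening_offcampus_propensity = clamp01(0.5 - 0.9 * effect * centered + rnorm(1, 0, 0.05)),
    social_event_propensity = clamp01(0.45 - 0.8 * effect * centered + rnorm(1, 0, 0.05)),
    phone_use_rate = max(0.2, 1.5 + rnorm(1, 0, 0.25)),
    night_use_share = clamp01(0.12 + 0.5 * effect * centered + rnorm(1, 0, 0.03)),
    sleep_midpoint = 3.8 + 1.6 * effect * centered + rnorm(1, 0, 0.25),
    device_inventory = list(self = 2L, related = 2L, others = 120L)
  )
}

#' Generate one wave of raw UCLA-20 responses from a profile
#'
#' Each item's post-reversal scored value is `round(1 + 3 * latent + noise)`
#' clamped to 1..4; reverse items are then mapped back to the raw
#' (unreversed) 1..4 scale, so the returned vector is what a participant
#' would actually tick on the questionnaire. With `noise_sd = 0` and latent
#' 1 every scored value is 4 (total 80).
#'
#' @param profile an `ls_profile`
#' @param wave "pre" or "post" (selects which latent is used)
#' @param noise_sd item-level Gaussian noise on the scored scale
#' @param seed optional integer seed for reproducibility
#' @return integer vector of 20 raw responses in 1..4
#' @export
generate_survey_responses <- function(profile, wave = c("pre", "post"),
                                      noise_sd = 0.55, seed = NULL) {
  wave <- match.arg(wave)
  if (!is.null(seed)) set.seed(seed)
  latent <- if (wave == "pre") profile$loneliness_latent else profile$loneliness_latent_post
  scored <- clamp(round(1 + 3 * latent + rnorm(20, 0, noise_sd)), 1, 4)
  raw <- scored
  rev <- ucla_reverse_items()
  raw[rev] <- 5 - scored[rev]
  as.integer(raw)
}

# one participant's per-day place schedule; returns data.table of episodes
# (start, end POSIXct; place, category, lat, lon, social, sporty, sleeping)
simulate_schedule <- function(profile, calendar, campus_map) {
  t0 <- calendar_start_time(calendar)
  n_days <- calendar$n_weeks * 7L
  cats <- campus_categories()
  centers <- lapply(cats, function(cc) poly_center(campus_poly(campus_map, cc)$coords))
  names(centers) <- cats
  # personal academic spots: on campus, outside labeled rectangles
  b <- campus_map$boundary
  acad <- replicate(3, {
    repeat {
      p <- c(lat = runif(1, min(b$lat) + 0.0005, max(b$lat) - 0.0005),
             lon = runif(1, min(b$lon) + 0.0005, max(b$lon) - 0.0005))
      hit <- vapply(campus_map$polygons,
                    function(pp) point_in_polygon(p["lon"], p["lat"], pp$coords),
                    logical(1))
      if (!any(hit)) return(p)
    }
  }, simplify = FALSE)
  off <- replicate(2, {
    ang <- runif(1, 0, 2 * pi); d <- runif(1, 1500, 3000)
    c(lat = mean(b$lat) + deg_lat(d * sin(ang)),
      lon = mean(b$lon) + deg_lon(d * cos(ang), mean(b$lat)))
  }, simplify = FALSE)
  home <- profile$home_center

  ep <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    day0 <- t0 + (d - 1L) * 86400
    wknd <- is_weekend(day0)
    dur <- rnorm(1, 7.4, 0.6)
    mid <- profile$sleep_midpoint + rnorm(1, 0, 0.4)
    wake <- clamp(mid + dur / 2, 6, 10.5)
    sleep_on <- clamp(mid - dur / 2, 0, 2.5) # this day's sleep starts just after midnight
    rows <- list()
    add <- function(s, e, place, category, lat, lon, social = FALSE,
                    sporty = FALSE, sleeping = FALSE) {
      if (e <= s) return(invisible(NULL))
      rows[[length(rows) + 1L]] <<- data.table::data.table(
        start = day0 + s * 3600, end = day0 + e * 3600, place = place,
        category = category, lat = lat, lon = lon, social = social,
        sporty = sporty, sleeping = sleeping)
      invisible(NULL)
    }
    home_cat <- "student_apartments" # category resolved by map lookup anyway
    add(0, sleep_on, "home", home_cat, home["lat"], home["lon"])
    add(sleep_on, wake, "home", home_cat, home["lat"], home["lon"], sleeping = TRUE)
    if (!wknd) {
      add(wake, 9, "home", home_cat, home["lat"], home["lon"])
      a1 <- acad[[sample.int(3, 1)]]; a2 <- acad[[sample.int(3, 1)]]
      add(9, 12, "acad", "academic", a1["lat"], a1["lon"])
      if (runif(1) < 0.5) {
        g <- centers$green_spaces
        add(12, 13, "green", "green_spaces", g["lat"], g["lon"], social = runif(1) < 0.4)
      } else add(12, 13, "home", home_cat, home["lat"], home["lon"])
      add(13, 16, "acad", "academic", a2["lat"], a2["lon"])
      if (runif(1) < 0.35) {
        at <- centers$athletic_facilities
        add(16, 18, "gym", "athletic_facilities", at["lat"], at["lon"], sporty = TRUE)
      } else add(16, 18, "home", home_cat, home["lat"], home["lon"])
      add(18, 19, "home", home_cat, home["lat"], home["lon"])
      if (runif(1) < profile$social_event_propensity) {
        s <- centers[[sample(c("social_event_house_1", "social_event_house_2"), 1)]]
        add(19, 22, "social", "social", s["lat"], s["lon"], social = TRUE)
      } else if (runif(1) < 0.4) {
        a3 <- acad[[sample.int(3, 1)]]
        add(19, 22, "acad", "academic", a3["lat"], a3["lon"])
      } else add(19, 22, "home", home_cat, home["lat"], home["lon"])
      add(22, 24, "home", home_cat, home["lat"], home["lon"])
    } else {
      add(wake, 12, "home", home_cat, home["lat"], home["lon"])
      if (runif(1) < 0.5) {
        g <- centers$green_spaces
        add(12, 14, "green", "green_spaces", g["lat"], g["lon"], social = runif(1) < 0.5)
      } else add(12, 14, "home", home_cat, home["lat"], home["lon"])
      if (runif(1) < 0.3) {
        o <- off[[sample.int(2, 1)]]
        add(14, 17, "off", "off_campus", o["lat"], o["lon"], social = TRUE)
      } else if (runif(1) < 0.3) {
        at <- centers$athletic_facilities
        add(14, 17, "gym", "athletic_facilities", at["lat"], at["lon"], sporty = TRUE)
      } else add(14, 17, "home", home_cat, home["lat"], home["lon"])
      add(17, 19, "home", home_cat, home["lat"], home["lon"])
      if (runif(1) < profile$evening_offcampus_propensity) {
        o <- off[[sample.int(2, 1)]]
        add(19, 23, "off", "off_campus", o["lat"], o["lon"], social = TRUE)
      } else if (runif(1) < 0.3 * profile$social_event_propensity) {
        s <- centers[[sample(c("social_event_house_1", "social_event_house_2"), 1)]]
        add(19, 23, "social", "social", s["lat"], s["lon"], social = TRUE)
      } else add(19, 23, "home", home_cat, home["lat"], home["lon"])
      add(23, 24, "home", home_cat, home["lat"], home["lon"])
    }
    ep[[d]] <- data.table::rbindlist(rows)
  }
  data.table::rbindlist(ep)
}

# map grid timestamps onto schedule episodes (episodes tile the study period)
episode_index <- function(t, sched) findInterval(as.numeric(t), as.numeric(sched$start))

simulate_streams <- function(profile, calendar, campus_map, sched,
                             gps_sigma = 10, dropout = list()) {
  t0 <- calendar_start_time(calendar); t1 <- calendar_end_time(calendar)
  n_days <- calendar$n_weeks * 7L
  day_of <- function(t) floor(as.numeric(t - t0, units = "days"))
  drop_days <- function(stream_name) {
    p <- dropout[[stream_name]] %||% 0
    if (p <= 0) return(integer(0))
    which(runif(n_days) < p) - 1L
  }
  keep_rows <- function(t, stream_name) !(day_of(t) %in% drop_days(stream_name))

  # location: 1 sample / 10 min
  tl <- seq(t0, t1 - 1, by = 600)
  idx <- episode_index(tl, sched)
  location <- data.table::data.table(
    timestamp = tl,
    lat = sched$lat[idx] + rnorm(length(tl), 0, deg_lat(gps_sigma)),
    lon = sched$lon[idx] + rnorm(length(tl), 0, deg_lon(gps_sigma, sched$lat[idx]))
  )
  location <- location[keep_rows(timestamp, "location")]

  # steps: 1 sample / 5 min
  ts <- seq(t0, t1 - 1, by = 300)
  sidx <- episode_index(ts, sched)
  lam <- ifelse(sched$sleeping[sidx], 0.05,
         ifelse(sched$sporty[sidx], profile$activity_level * 3.5,
                profile$activity_level * 0.75))
  # short walking bursts at episode changes
  lam[c(FALSE, diff(sidx) != 0)] <- profile$activity_level * 4
  steps <- data.table::data.table(timestamp = ts, steps = rpois(length(ts), lam))
  steps <- steps[keep_rows(timestamp, "steps")]

  # sleep: 1 sample / min during sleeping episodes
  slp <- sched[sleeping == TRUE]
  restless_p <- clamp01(0.07 + 0.1 * (profile$loneliness_latent - 0.5))
  sleep <- if (nrow(slp)) {
    data.table::rbindlist(lapply(seq_len(nrow(slp)), function(i) {
      tt <- seq(slp$start[i], slp$end[i] - 1, by = 60)
      st <- sample(c("asleep", "restless", "awake", "unknown"), length(tt),
                   replace = TRUE,
                   prob = c(0.88 - restless_p, restless_p, 0.09, 0.03))
      data.table::data.table(timestamp = tt, state = st)
    }))
  } else data.table::data.table(timestamp = as.POSIXct(character(), tz = "UTC"),
                                state = character())
  sleep <- sleep[keep_rows(timestamp, "sleep")]

  # screen sessions: unlock -> off -> lock (+ occasional notification on/off)
  waking <- sched[sleeping == FALSE]
  wdur <- as.numeric(waking$end - waking$start, units = "hours")
  n_sessions <- rpois(1, profile$phone_use_rate * sum(wdur) *
                        (1 - profile$night_use_share))
  tw <- waking[sample.int(nrow(waking), n_sessions, replace = TRUE, prob = wdur)]
  sess_start <- tw$start + runif(n_sessions) * as.numeric(tw$end - tw$start, units = "secs")
  night <- sched[sleeping == FALSE & hour_of(start) < 6]
  if (nrow(night) == 0) night <- waking
  n_night <- rpois(1, profile$phone_use_rate * sum(wdur) * profile$night_use_share)
  tn <- night[sample.int(nrow(night), n_night, replace = TRUE)]
  sess_start <- c(sess_start,
                  tn$start + runif(n_night) * as.numeric(tn$end - tn$start, units = "secs"))
  sess_dur <- pmax(10, rexp(length(sess_start), 1 / 180))
  screen <- data.table::rbindlist(list(
    data.table::data.table(timestamp = sess_start - 2, status = "on"),
    data.table::data.table(timestamp = sess_start, status = "unlock"),
    data.table::data.table(timestamp = sess_start + sess_dur, status = "off"),
    data.table::data.table(timestamp = sess_start + sess_dur + 30, status = "lock")
  ))[order(timestamp)][timestamp >= t0 & timestamp < t1]
  screen <- screen[keep_rows(timestamp, "screen")]

  # calls / sms with contact groups
  groups <- c("family", "friend_on_campus", "friend_off_campus", "other")
  contacts <- data.table::data.table(
    contact_id = c(paste0("fam_", 1:2), paste0("fon_", 1:3),
                   paste0("foff_", 1:2), paste0("oth_c_", 1:5)),
    group = rep(groups, times = c(2, 3, 2, 5))
  )
  sociability <- 1 + (0.5 - profile$loneliness_latent)
  n_calls <- rpois(1, 0.7 * sociability * n_days)
  twk <- waking[sample.int(nrow(waking), n_calls, replace = TRUE, prob = wdur)]
  calls <- data.table::data.table(
    timestamp = twk$start + runif(n_calls) * as.numeric(twk$end - twk$start, units = "secs"),
    direction = sample(c("incoming", "outgoing", "missed"), n_calls, TRUE,
                       prob = c(0.4, 0.45, 0.15)),
    contact_id = sample(contacts$contact_id, n_calls, TRUE,
                        prob = c(0.18, 0.12, 0.14, 0.12, 0.1, 0.08, 0.06, rep(0.04, 5)))
  )
  calls[, duration := ifelse(direction == "missed", 0,
                             round(rlnorm(.N, log(120), 0.7)))]
  calls <- calls[order(timestamp)][keep_rows(timestamp, "calls")]
  n_sms <- rpois(1, 2.2 * sociability * n_days)
  tsm <- waking[sample.int(nrow(waking), n_sms, replace = TRUE, prob = wdur)]
  sms <- data.table::data.table(
    timestamp = tsm$start + runif(n_sms) * as.numeric(tsm$end - tsm$start, units = "secs"),
    direction = sample(c("incoming", "outgoing"), n_sms, TRUE),
    contact_id = sample(contacts$contact_id, n_sms, TRUE)
  )[order(timestamp)]
  sms <- sms[keep_rows(timestamp, "sms")]

  # bluetooth: 1 scan round / 10 min; self almost always, related at home,
  # others drawn from a crowd pool sized by place category
  bidx <- episode_index(tl, sched)
  bcat <- sched$category[bidx]
  at_home <- sched$place[bidx] == "home"
  crowd <- c(academic = 3, social = 6, green_spaces = 1.5,
             athletic_facilities = 2, off_campus = 2, student_apartments = 0.7,
             residential_halls = 0.7)
  lam_b <- unname(crowd[bcat]); lam_b[is.na(lam_b)] <- 1
  lam_b[sched$sleeping[bidx]] <- 0.2
  inv <- profile$device_inventory
  nscan <- length(tl)
  bt_parts <- list()
  for (j in seq_len(inv$self)) {
    seen <- runif(nscan) < 0.93
    bt_parts[[length(bt_parts) + 1L]] <- data.table::data.table(
      timestamp = tl[seen], device_id = paste0("self_", j))
  }
  rel_p <- ifelse(at_home, 0.75, 0.05)
  for (j in seq_len(inv$related)) {
    seen <- runif(nscan) < rel_p
    bt_parts[[length(bt_parts) + 1L]] <- data.table::data.table(
      timestamp = tl[seen], device_id = paste0("rel_", j))
  }
  k <- rpois(nscan, lam_b)
  if (sum(k) > 0) {
    bt_parts[[length(bt_parts) + 1L]] <- data.table::data.table(
      timestamp = rep(tl, k),
      device_id = paste0("oth_", sample.int(inv$others, sum(k), replace = TRUE)))
  }
  bluetooth <- unique(data.table::rbindlist(bt_parts))[order(timestamp, device_id)]
  bluetooth <- bluetooth[keep_rows(timestamp, "bluetooth")]

  # audio inferences: 1 / 5 min while awake
  aidx <- episode_index(ts, sched)
  awake_a <- !sched$sleeping[aidx]
  social_a <- sched$social[aidx]
  ta <- ts[awake_a]; sa <- social_a[awake_a]
  cls <- character(length(ta))
  r <- runif(length(ta))
  cls[sa] <- ifelse(r[sa] < 0.72, "voice",
               ifelse(r[sa] < 0.9, "noise",
                 ifelse(r[sa] < 0.97, "silence", "unknown")))
  cls[!sa] <- ifelse(r[!sa] < 0.68, "silence",
                ifelse(r[!sa] < 0.82, "noise",
                  ifelse(r[!sa] < 0.94, "voice", "unknown")))
  audio <- data.table::data.table(timestamp = ta, class = cls)
  audio <- audio[keep_rows(timestamp, "audio")]

  list(location = location, bluetooth = bluetooth, screen = screen,
       calls = calls, sms = sms, audio = audio, steps = steps, sleep = sleep,
       contact_groups = contacts)
}

#' Generate a full synthetic cohort
#'
#' Draws a latent loneliness for each participant, plants effect-size-scaled
#' behavioral differences (weekend-evening off-campus time, weekday-evening
#' social-event time, activity level, night-time phone use, sleep timing)
#' and simulates all eight raw sensor streams plus pre/post UCLA-20
#' responses over the study calendar. Identical seeds give identical
#' cohorts.
#'
#' @param n_participants integer >= 1
#' @param effect_size real >= 0 scaling the planted behavior-loneliness
#'   link (0 = no link)
#' @param calendar an [study_calendar()]; default 16 weeks split 6 + 10
#' @param seed integer RNG seed
#' @param dropout named list of per-stream whole-day dropout probabilities
#' @param campus_map campus map, see [default_campus_map()]
#' @param gps_sigma GPS noise SD in meters
#' @param survey_noise_sd item noise of the survey response model
#' @return list of class `ls_cohort`: `participants` (each with id, profile,
#'   streams, pre/post raw responses), `campus_map`, `calendar`,
#'   `effect_size`, and a `truth` table of latents/totals/levels/change
#' @export
generate_cohort <- function(n_participants, effect_size = 1,
                            calendar = study_calendar("2017-01-18", 16L, 6L),
                            seed = 1L,
                            dropout = list(),
                            campus_map = default_campus_map(),
                            gps_sigma = 10,
                            survey_noise_sd = 0.55) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (effect_size < 0) stop("effect_size must be >= 0")
  set.seed(seed)
  participants <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    # latent calibrated so that roughly 60% of participants fall above
    # the 40-point cutoff under the response model
    latent <- rbeta(1, 1.35, 1.55)
    act_seed <- rnorm(1) # activity propensity used for the change drift
    latent_post <- clamp01(latent + rnorm(1, 0, 0.09) -
                             effect_size * 0.1 * act_seed)
    profile <- plant_profile(latent, latent_post, effect_size, campus_map)
    profile$activity_level <- max(1, profile$activity_level * (1 + 0.25 * act_seed))
    sched <- simulate_schedule(profile, calendar, campus_map)
    streams <- simulate_streams(profile, calendar, campus_map, sched,
                                gps_sigma = gps_sigma, dropout = dropout)
    pre <- generate_survey_responses(profile, "pre", noise_sd = survey_noise_sd)
    post <- generate_survey_responses(profile, "post", noise_sd = survey_noise_sd)
    participants[[i]] <- list(
      id = sprintf("P%03d", i), profile = profile, streams = streams,
      pre_responses = pre, post_responses = post
    )
  }
  truth <- data.table::rbindlist(lapply(participants, function(p) {
    pre_total <- score_ucla(p$pre_responses)
    post_total <- score_ucla(p$post_responses)
    data.table::data.table(
      participant_id = p$id,
      latent_pre = p$profile$loneliness_latent,
      latent_post = p$profile$loneliness_latent_post,
      pre_total = pre_total, post_total = post_total,
      pre_level = categorize_level(pre_total),
      post_level = categorize_level(post_total),
      evening_offcampus_propensity = p$profile$evening_offcampus_propensity,
      social_event_propensity = p$profile$social_event_propensity,
      activity_level = p$profile$activity_level
    )
  }))
  truth[, change := change_category(pre_level, post_level)]
  structure(list(participants = participants, campus_map = campus_map,
                 calendar = calendar, effect_size = effect_size,
                 truth = truth),
            class = "ls_cohort")
}

#' Write a cohort to CSV/GeoJSON files
#'
#' One CSV per sensor stream (AWARE-like columns, with a participant_id
#' column), `surveys.csv` with raw item responses, `contact_groups.csv`, and
#' the campus map as GeoJSON.
#'
#' @param cohort an `ls_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  streams <- c("location", "bluetooth", "screen", "calls", "sms", "audio",
               "steps", "sleep")
  for (s in streams) {
    dt <- data.table::rbindlist(lapply(cohort$participants, function(p) {
      d <- data.table::copy(p$streams[[s]])
      d[, participant_id := p$id]
      d
    }), fill = TRUE)
    data.table::setcolorder(dt, "participant_id")
    dt[, timestamp := format(timestamp, "%Y-%m-%d %H:%M:%OS3", tz = "UTC")]
    data.table::fwrite(dt, file.path(dir, paste0(s, ".csv")))
  }
  cg <- data.table::rbindlist(lapply(cohort$participants, function(p) {
    d <- data.table::copy(p$streams$contact_groups)
    d[, participant_id := p$id]
    d
  }))
  data.table::fwrite(cg, file.path(dir, "contact_groups.csv"))
  sv <- data.table::rbindlist(lapply(cohort$participants, function(p) {
    rbind(
      data.table::as.data.table(c(list(participant_id = p$id, wave = "pre"),
                                  stats::setNames(as.list(p$pre_responses), paste0("q", 1:20)))),
      data.table::as.data.table(c(list(participant_id = p$id, wave = "post"),
                                  stats::setNames(as.list(p$post_responses), paste0("q", 1:20))))
    )
  }))
  data.table::fwrite(sv, file.path(dir, "surveys.csv"))
  write_campus_geojson(cohort$campus_map, file.path(dir, "campus.geojson"))
  jsonlite::write_json(list(start_date = as.character(cohort$calendar$start_date),
                            n_weeks = cohort$calendar$n_weeks,
                            half_split_week = cohort$calendar$half_split_week,
                            effect_size = cohort$effect_size),
                       file.path(dir, "study.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort back from CSV/GeoJSON files
#'
#' Inverse of [write_cohort_csv()]. Behavior profiles and the planted truth
#' table are not persisted to the stream files; the returned object carries
#' streams, surveys (and their scored outcomes), the campus map and the
#' calendar, which is all that feature extraction and classification need.
#'
#' @param dir directory written by [write_cohort_csv()]
#' @return list of class `ls_cohort` (profiles NULL; `truth` holds the
#'   scored survey outcomes)
#' @export
read_cohort_csv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"))
  calendar <- study_calendar(meta$start_date, meta$n_weeks, meta$half_split_week)
  streams <- c("location", "bluetooth", "screen", "calls", "sms", "audio",
               "steps", "sleep")
  tabs <- lapply(streams, function(s) {
    dt <- data.table::fread(file.path(dir, paste0(s, ".csv")))
    dt[, timestamp := as.POSIXct(timestamp, tz = "UTC")]
    dt
  })
  names(tabs) <- streams
  cg <- data.table::fread(file.path(dir, "contact_groups.csv"))
  sv <- data.table::fread(file.path(dir, "surveys.csv"))
  ids <- sort(unique(sv$participant_id))
  participants <- lapply(ids, function(id) {
    st <- lapply(tabs, function(dt) dt[participant_id == id][, participant_id := NULL])
    st$contact_groups <- cg[participant_id == id][, participant_id := NULL]
    qcols <- paste0("q", 1:20)
    list(id = id, profile = NULL, streams = st,
         pre_responses = as.integer(sv[participant_id == id & wave == "pre", ..qcols]),
         post_responses = as.integer(sv[participant_id == id & wave == "post", ..qcols]))
  })
  outcomes <- score_survey_table(sv)
  truth <- outcomes[, .(participant_id, pre_total, post_total,
                        pre_level, post_level, change)]
  structure(list(participants = participants,
                 campus_map = read_campus_geojson(file.path(dir, "campus.geojson")),
                 calendar = calendar,
                 effect_size = meta$effect_size,
                 truth = truth),
            class = "ls_cohort")
}

#' Write a campus map as GeoJSON
#' @param map campus map list (boundary + labeled polygons)
#' @param path output file
#' @export
write_campus_geojson <- function(map, path) {
  ring <- function(coords) {
    m <- rbind(as.matrix(coords[c("lon", "lat")]),
               as.matrix(coords[1, c("lon", "lat")]))
    list(apply(m, 1, as.list, simplify = FALSE))
  }
  feats <- c(
    list(list(type = "Feature",
              properties = list(category = "boundary"),
              geometry = list(type = "Polygon", coordinates = ring(map$boundary)))),
    lapply(map$polygons, function(p)
      list(type = "Feature",
           properties = list(category = p$category),
           geometry = list(type = "Polygon", coordinates = ring(p$coords))))
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a campus map from GeoJSON
#' @param path GeoJSON file written by [write_campus_geojson()]
#' @return campus map list
#' @export
read_campus_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  polys <- lapply(gj$features, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(pt)
      c(lon = pt[[1]], lat = pt[[2]])))
    coords <- as.data.frame(m)[-nrow(m), , drop = FALSE] # drop closing vertex
    list(category = f$properties$category, coords = coords)
  })
  is_boundary <- vapply(polys, function(p) p$category == "boundary", logical(1))
  list(boundary = polys[[which(is_boundary)[1]]]$coords,
       polygons = polys[!is_boundary])
}
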