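# Location-derived features: speeds and moving/static labels, DBSCAN place
# clusters (global over the whole study, local within a window), mobility
# statistics, home inference, campus-map category features, the multimodal
# study/social durations, and circadian movement regularity.

#' Annotate a location stream with speeds and moving/static states
#'
#' Speed of sample i is the haversine distance from sample i-1 divided by
#' the elapsed time (first sample: 0). Samples faster than 1 km/h are
#' labeled moving, the rest static. Duplicate timestamps are dropped
#' (first occurrence kept).
#'
#' @param location data.frame with timestamp, lat, lon
#' @param moving_threshold_kmh speed threshold separating moving from static
#' @return data.table with added columns speed_kmh and state
#' @export
compute_speeds <- function(location, moving_threshold_kmh = 1) {
  dt <- data.table::as.data.table(location)[order(timestamp)]
  dt <- dt[!duplicated(timestamp)]
  if (nrow(dt) == 0) {
    dt[, `:=`(speed_kmh = numeric(0), state = character(0))]
    return(dt)
  }
  n <- nrow(dt)
  if (n == 1) {
    dt[, `:=`(speed_kmh = 0, state = "static")]
    return(dt)
  }
  d <- dist_m(dt$lat[-n], dt$lon[-n], dt$lat[-1], dt$lon[-1])
  el <- as.numeric(diff(dt$timestamp), units = "hours")
  sp <- c(0, (d / 1000) / pmax(el, 1e-9))
  dt[, speed_kmh := sp]
  dt[, state := ifelse(speed_kmh > moving_threshold_kmh, "moving", "static")]
  dt[]
}

#' DBSCAN over geographic points
#'
#' Standard DBSCAN semantics (core points have >= `min_samples` neighbours
#' within `eps` meters, counting themselves; clusters grow through core
#' points; non-core in-range points join as border points; the rest are
#' noise, labeled -1). Distances are great-circle; candidate neighbour
#' pairs come from an eps-sized cell grid on a local planar projection and
#' every pair is confirmed with the exact haversine distance, so the result
#' matches a brute-force DBSCAN. Border points reachable from several
#' clusters attach to the lowest-numbered one, making the output
#' deterministic for a fixed input order.
#'
#' @param lat,lon coordinates in degrees
#' @param eps neighbourhood radius in meters
#' @param min_samples minimum neighbourhood size of a core point
#' @return integer cluster labels (1, 2, ... or -1 for noise)
#' @export
dbscan_geo <- function(lat, lon, eps, min_samples) {
  stopifnot(eps > 0, min_samples >= 1)
  n <- length(lat)
  if (n == 0) return(integer(0))
  xy <- local_xy(lat, lon)
  # fine grid of side eps/sqrt(2): any two points sharing a cell are within
  # eps, so a cell with >= min_samples points is a clique of core points and
  # needs no pairwise distances; only points of sparse cells and
  # cell-boundary connectivity are checked explicitly. Cells farther apart
  # than Chebyshev distance 2 cannot hold a pair within eps.
  g <- eps / sqrt(2)
  kx <- as.integer(floor(xy$x / g)); ky <- as.integer(floor(xy$y / g))
  pts <- data.table::data.table(idx = seq_len(n), kx = kx, ky = ky)
  pts[, key := paste(kx, ky)]
  counts <- pts[, .(N = .N), by = .(kx, ky, key)]
  dense_keys <- counts[N >= min_samples, key]
  core <- pts$key %in% dense_keys
  core <- core[order(pts$idx)]

  # exact neighbourhoods of points in sparse cells
  offs <- data.table::CJ(dx = -2:2, dy = -2:2)
  unc <- pts[!(key %in% dense_keys)]
  nb_pairs <- NULL
  if (nrow(unc)) {
    cand <- lapply(seq_len(nrow(offs)), function(oi) {
      b <- data.table::data.table(kx = pts$kx + offs$dx[oi],
                                  ky = pts$ky + offs$dy[oi], jdx = pts$idx)
      suppressWarnings(merge(unc[, .(idx, kx, ky)], b, by = c("kx", "ky"),
                             allow.cartesian = TRUE))[, .(idx, jdx)]
    })
    cand <- data.table::rbindlist(cand)
    d <- dist_m(lat[cand$idx], lon[cand$idx], lat[cand$jdx], lon[cand$jdx])
    nb_pairs <- cand[d <= eps]
    deg <- nb_pairs[, .N, by = idx] # self included (distance 0)
    core[deg$idx[deg$N >= min_samples]] <- TRUE
  }

  labels <- rep(-1L, n)
  core_idx <- which(core)
  if (length(core_idx) == 0) return(labels)

  # connectivity of cells holding core points
  cp <- pts[core[idx]]
  nodes <- cp[, .(.N), by = .(kx, ky, key)]
  node_pts <- split(cp$idx, cp$key)
  connected <- function(p1, p2) {
    # is any cross pair within eps? chunked with early exit
    if (length(p1) > length(p2)) { tmp <- p1; p1 <- p2; p2 <- tmp }
    c2lat <- mean(lat[p2]); c2lon <- mean(lon[p2])
    p1 <- p1[order(dist_m(lat[p1], lon[p1], c2lat, c2lon))]
    for (chunk in split(p1, ceiling(seq_along(p1) / 50))) {
      dd <- outer(seq_along(chunk), seq_along(p2), function(a, b)
        dist_m(lat[chunk[a]], lon[chunk[a]], lat[p2[b]], lon[p2[b]]))
      if (any(dd <= eps)) return(TRUE)
    }
    FALSE
  }
  # candidate cell pairs: half-plane Chebyshev-2 offsets
  hoffs <- offs[dx > 0 | (dx == 0 & dy > 0)]
  edges <- list()
  for (oi in seq_len(nrow(hoffs))) {
    b <- data.table::data.table(kx = nodes$kx + hoffs$dx[oi],
                                ky = nodes$ky + hoffs$dy[oi], key2 = nodes$key)
    m <- suppressWarnings(merge(nodes[, .(kx, ky, key)], b, by = c("kx", "ky")))
    if (nrow(m)) edges[[length(edges) + 1L]] <- m[, .(key, key2)]
  }
  edges <- if (length(edges)) data.table::rbindlist(edges) else
    data.table::as.data.table(list(key = character(), key2 = character()))
  if (nrow(edges)) {
    ok <- vapply(seq_len(nrow(edges)), function(i)
      connected(node_pts[[edges$key[i]]], node_pts[[edges$key2[i]]]),
      logical(1))
    edges <- edges[ok]
  }
  # components of the cell graph by min-label propagation
  comp <- stats::setNames(seq_len(nrow(nodes)), nodes$key)
  if (nrow(edges)) {
    repeat {
      v <- pmin(comp[edges$key], comp[edges$key2])
      upd <- data.table::data.table(p = c(edges$key, edges$key2), v = c(v, v))
      mn <- upd[, .(v = min(v)), by = p]
      changed <- any(comp[mn$p] > mn$v)
      if (!changed) break
      comp[mn$p] <- pmin(comp[mn$p], mn$v)
    }
  }
  labels[cp$idx] <- unname(comp[cp$key])
  # border points: non-core within eps of a core point, attached to the
  # lowest-labeled adjacent core cluster
  if (!is.null(nb_pairs) && nrow(nb_pairs)) {
    bp <- nb_pairs[!core[idx] & core[jdx]]
    if (nrow(bp)) {
      bp[, lab := labels[jdx]]
      bmin <- bp[, .(lab = min(lab)), by = idx]
      labels[bmin$idx] <- bmin$lab
    }
  }
  seen <- unique(labels[labels > 0])
  labels[labels > 0] <- match(labels[labels > 0], seen)
  labels
}

#' Cluster the static samples of an annotated stream into places
#'
#' @param annotated output of [compute_speeds()]
#' @param eps DBSCAN radius in meters
#' @param min_samples DBSCAN density threshold
#' @param scope "global" (whole study) or "local" (within one window)
#' @return list of class `ls_places`: `assignments` (cluster id per static
#'   sample, -1 = noise), `static` (the static samples with cluster column),
#'   `centers` (per-cluster mean lat/lon and sample count), `scope`,
#'   `eps`, `min_samples`
#' @export
cluster_static_points <- function(annotated, eps = 30, min_samples = 5,
                                  scope = c("global", "local")) {
  scope <- match.arg(scope)
  st <- data.table::as.data.table(annotated)[state == "static"]
  labels <- dbscan_geo(st$lat, st$lon, eps, min_samples)
  st[, cluster := labels]
  centers <- if (nrow(st)) {
    st[cluster > 0, .(lat = mean(lat), lon = mean(lon), n = .N), by = cluster][order(-n)]
  } else st[0, .(cluster = integer(), lat = numeric(), lon = numeric(), n = integer())]
  structure(list(assignments = labels, static = st, centers = centers,
                 scope = scope, eps = eps, min_samples = min_samples),
            class = "ls_places")
}

# dwell time (minutes) represented by each sample: gap to the next sample,
# capped at twice the nominal cadence so missing stretches do not inflate time
sample_dwell_min <- function(timestamps, cadence_min = NULL) {
  n <- length(timestamps)
  if (n == 0) return(numeric(0))
  if (is.null(cadence_min)) {
    cadence_min <- if (n > 1) median(as.numeric(diff(timestamps), units = "mins")) else 10
  }
  if (n == 1) return(cadence_min)
  gaps <- as.numeric(diff(timestamps), units = "mins")
  c(pmin(gaps, 2 * cadence_min), cadence_min)
}

entropy_from_shares <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log(p))
}

# stay episodes: maximal runs of equal cluster label over the static samples
stay_lengths_min <- function(static_dt) {
  if (nrow(static_dt) == 0) return(data.table::data.table(cluster = integer(), mins = numeric()))
  ep <- rle_episodes(static_dt$cluster)
  dw <- sample_dwell_min(static_dt$timestamp)
  ep[, mins := vapply(seq_len(.N), function(i) sum(dw[start_idx[i]:end_idx[i]]), numeric(1))]
  ep[, .(cluster = as.integer(value), mins)]
}

#' Mobility features of a window
#'
#' Emits the location feature family: location variance and its log, total
#' distance traveled, mean/variance of speed, number of clusters, number of
#' transitions between (non-noise) clusters, radius of gyration, time at the
#' top-3 global and local clusters, percent time moving, percent time at
#' noise (-1) locations, stay-length statistics per cluster scope, and
#' location entropy (natural log over non-noise time shares) with its
#' normalized variant.
#'
#' @param annotated annotated (sliced) location samples of the window
#' @param global_places `ls_places` fit on the whole study
#' @param local_places `ls_places` fit on this window's static samples
#' @return named numeric feature map (all NA when the stream is empty)
#' @export
mobility_features <- function(annotated, global_places, local_places) {
  f <- new_feature_map()
  ann <- data.table::as.data.table(annotated)
  if (nrow(ann) == 0) {
    nm <- c("location_variance", "log_location_variance", "total_distance_km",
            "speed_mean_kmh", "speed_var", "pct_time_moving", "radius_of_gyration_m")
    return(new_feature_map(nm, rep(NA_real_, length(nm))))
  }
  dw_all <- sample_dwell_min(ann$timestamp)
  lv <- var(ann$lat) + var(ann$lon)
  if (!is.finite(lv)) lv <- 0
  n <- nrow(ann)
  td <- if (n > 1) sum(dist_m(ann$lat[-n], ann$lon[-n], ann$lat[-1], ann$lon[-1])) / 1000 else 0
  # time-weighted centroid and radius of gyration
  wt <- dw_all / sum(dw_all)
  clat <- sum(ann$lat * wt); clon <- sum(ann$lon * wt)
  rog <- sqrt(sum(wt * dist_m(ann$lat, ann$lon, clat, clon)^2))
  f <- c(f, new_feature_map(
    c("location_variance", "log_location_variance", "total_distance_km",
      "speed_mean_kmh", "speed_var", "pct_time_moving", "radius_of_gyration_m"),
    c(lv, log(lv + 1e-12), td, mean(ann$speed_kmh),
      if (n > 1) var(ann$speed_kmh) else 0,
      100 * sum(dw_all[ann$state == "moving"]) / sum(dw_all), rog)))
  for (scope in c("global", "local")) {
    places <- if (scope == "global") global_places else local_places
    # assignment of this window's static samples under the scope's clustering
    st <- data.table::as.data.table(annotated)[state == "static"]
    if (scope == "global") {
      key <- paste(as.numeric(st$timestamp), st$lat, st$lon)
      gkey <- paste(as.numeric(places$static$timestamp), places$static$lat, places$static$lon)
      st[, cluster := places$static$cluster[match(key, gkey)]]
      st <- st[!is.na(cluster)]
    } else {
      st <- places$static
    }
    pre <- function(x) paste0(x, "_", scope)
    if (nrow(st) == 0) {
      f <- c(f, new_feature_map(
        c(pre("n_clusters"), pre("n_transitions"), pre("pct_time_noise"),
          pre("entropy"), pre("entropy_normalized"),
          paste0("time_at_top", 1:3, "_", scope, "_min")),
        rep(NA_real_, 8)))
      f <- c(f, stat_block(numeric(0), pre("stay_length")))
      next
    }
    dw <- sample_dwell_min(st$timestamp)
    shares <- st[, .(mins = sum(dw[.I])), by = cluster]
    nn <- shares[cluster > 0][order(-mins)]
    k <- nrow(nn)
    tot_nn <- sum(nn$mins)
    ent <- if (tot_nn > 0) entropy_from_shares(nn$mins / tot_nn) else 0
    ent_norm <- if (k > 1) ent / log(k) else 0
    labs <- st$cluster[st$cluster > 0]
    trans <- if (length(labs) > 1) sum(diff(labs) != 0) else 0
    top3 <- c(nn$mins, rep(0, 3))[1:3]
    sl <- stay_lengths_min(st)[cluster > 0]
    f <- c(f, new_feature_map(
      c(pre("n_clusters"), pre("n_transitions"), pre("pct_time_noise"),
        pre("entropy"), pre("entropy_normalized"),
        paste0("time_at_top", 1:3, "_", scope, "_min")),
      c(k, trans, 100 * sum(dw[st$cluster == -1]) / sum(dw), ent, ent_norm, top3)))
    f <- c(f, stat_block(sl$mins, pre("stay_length")))
  }
  f
}

#' Estimate home location from night-epoch samples
#'
#' DBSCAN on the night (12 am - 6 am) static samples; home is the coordinate
#' mean of the most frequented cluster. Also returns time-at-home features
#' for 10 m and 100 m home radii computed over the provided samples.
#'
#' @param night_annotated annotated night-epoch location samples
#' @param eps,min_samples DBSCAN parameters
#' @return list with `center` (lat/lon or NULL) and `features` (named map:
#'   time_at_home_10m_min, time_at_home_100m_min; NA when no home found)
#' @export
estimate_home <- function(night_annotated, eps = 30, min_samples = 5) {
  na_out <- list(center = NULL,
                 features = new_feature_map(
                   c("time_at_home_10m_min", "time_at_home_100m_min"),
                   c(NA_real_, NA_real_)))
  dt <- data.table::as.data.table(night_annotated)
  if (nrow(dt) < min_samples) return(na_out)
  places <- cluster_static_points(dt, eps, min_samples, scope = "global")
  if (nrow(places$centers) == 0) return(na_out)
  center <- c(lat = places$centers$lat[1], lon = places$centers$lon[1])
  d <- dist_m(dt$lat, dt$lon, center["lat"], center["lon"])
  dw <- sample_dwell_min(dt$timestamp)
  list(center = center,
       features = new_feature_map(
         c("time_at_home_10m_min", "time_at_home_100m_min"),
         c(sum(dw[d <= 10]), sum(dw[d <= 100]))))
}

#' Assign a campus category to location samples
#'
#' Point-in-polygon against the six labeled categories; on-campus samples in
#' no labeled polygon are academic; samples outside the boundary are off
#' campus.
#'
#' @param lat,lon coordinates in degrees
#' @param campus_map campus map list
#' @return character vector of the 8 category labels
#' @export
assign_campus_category <- function(lat, lon, campus_map) {
  out <- rep(NA_character_, length(lat))
  for (p in campus_map$polygons) {
    hit <- is.na(out) & point_in_polygon(lon, lat, p$coords)
    out[hit] <- p$category
  }
  on_campus <- point_in_polygon(lon, lat, campus_map$boundary)
  out[is.na(out) & on_campus] <- "academic"
  out[is.na(out)] <- "off_campus"
  out
}

all_campus_labels <- function() c(campus_categories(), "academic", "off_campus")

# category bout episodes with gap tolerance <= max_gap_min between samples
category_bouts <- function(labeled, max_gap_min = NULL) {
  dt <- data.table::as.data.table(labeled)[order(timestamp)]
  if (nrow(dt) == 0)
    return(data.table::data.table(category = character(), start = as.POSIXct(character(), tz = "UTC"),
                                  end = as.POSIXct(character(), tz = "UTC"), mins = numeric(), n = integer()))
  cadence <- if (nrow(dt) > 1) median(as.numeric(diff(dt$timestamp), units = "mins")) else 10
  if (is.null(max_gap_min)) max_gap_min <- 1.5 * cadence
  gap <- c(0, as.numeric(diff(dt$timestamp), units = "mins"))
  new_bout <- gap > max_gap_min + 1e-9
  brk <- new_bout | c(TRUE, dt$category[-1] != dt$category[-nrow(dt)])
  id <- cumsum(brk)
  dt[, .(category = category[1], start = timestamp[1],
         end = timestamp[.N] + cadence * 60,
         mins = .N * cadence, n = .N), by = .(bout = id)][, bout := NULL][]
}

#' Campus-category features of a window
#'
#' Per category: minutes, percent of covered time, bout count, bouts of at
#' least 10/20/30 minutes, and bout-length statistics; plus the total number
#' of transitions between distinct categories. Minutes are sample counts
#' times the stream cadence, so category minutes sum to the window's covered
#' duration.
#'
#' @param labeled location samples with a `category` column
#' @return named numeric feature map (all NA when empty)
#' @export
campus_features <- function(labeled) {
  dt <- data.table::as.data.table(labeled)
  cats <- all_campus_labels()
  if (nrow(dt) == 0) {
    nm <- c(as.vector(t(outer(cats, c("_min", "_pct", "_n_bouts", "_bouts_ge10",
                                      "_bouts_ge20", "_bouts_ge30"), paste0))),
            "campus_n_transitions")
    return(new_feature_map(nm, rep(NA_real_, length(nm))))
  }
  cadence <- if (nrow(dt) > 1) median(as.numeric(diff(dt$timestamp), units = "mins")) else 10
  total_min <- nrow(dt) * cadence
  bouts <- category_bouts(dt)
  f <- new_feature_map()
  for (cc in cats) {
    nmin <- sum(dt$category == cc) * cadence
    bb <- bouts[category == cc]
    f <- c(f, new_feature_map(
      paste0(cc, c("_min", "_pct", "_n_bouts", "_bouts_ge10", "_bouts_ge20", "_bouts_ge30")),
      c(nmin, 100 * nmin / total_min, nrow(bb),
        sum(bb$mins >= 10), sum(bb$mins >= 20), sum(bb$mins >= 30))))
    f <- c(f, stat_block(bb$mins, paste0(cc, "_bout_len")))
  }
  labs <- bouts$category
  f <- c(f, new_feature_map("campus_n_transitions",
                            if (length(labs) > 1) sum(labs[-1] != labs[-length(labs)]) else 0))
  f
}

# helper: do any events overlap [s, e)?
any_overlap <- function(ev_start, ev_end, s, e) any(ev_end > s & ev_start < e)

#' Study duration of a window (minutes)
#'
#' Sums maximal episodes in which the participant stays in an academic
#' building for 30 min or more while sedentary (every overlapping 5-min step
#' interval below 10 steps) and without any phone interaction session
#' overlapping the episode.
#'
#' @param labeled location samples with `category`
#' @param steps step samples (timestamp, steps) of the window's participant
#' @param interaction_sessions data.table of interaction sessions
#'   (`start`, `end`) from [screen_sessions()]
#' @param min_episode_min episode floor in minutes
#' @param sedentary_threshold steps per 5-min interval counted as sedentary
#' @return minutes (NA_real_ if a required stream is missing/NULL)
#' @export
study_duration <- function(labeled, steps, interaction_sessions,
                           min_episode_min = 30, sedentary_threshold = 10) {
  if (is.null(labeled) || is.null(steps) || is.null(interaction_sessions))
    return(NA_real_)
  bouts <- category_bouts(labeled)[category == "academic" & mins >= min_episode_min]
  if (nrow(bouts) == 0) return(0)
  st <- data.table::as.data.table(steps)
  total <- 0
  for (i in seq_len(nrow(bouts))) {
    s <- bouts$start[i]; e <- bouts$end[i]
    ov <- st[timestamp + 300 > s & timestamp < e]
    if (nrow(ov) > 0 && any(ov$steps >= sedentary_threshold)) next
    if (nrow(interaction_sessions) > 0 &&
        any_overlap(interaction_sessions$start, interaction_sessions$end, s, e)) next
    total <- total + bouts$mins[i]
  }
  total
}

#' Social duration of a window (minutes)
#'
#' Sums maximal episodes of 20 min or more in residential buildings
#' (student apartments, residential halls) or green spaces during which 80%
#' or more of the overlapping audio inferences are voice or noise.
#'
#' @param labeled location samples with `category`
#' @param audio audio inference samples (timestamp, class)
#' @param min_episode_min episode floor in minutes
#' @param voice_share_threshold minimum voice/noise share
#' @return minutes (NA_real_ if the audio stream is missing/NULL)
#' @export
social_duration <- function(labeled, audio, min_episode_min = 20,
                            voice_share_threshold = 0.8) {
  if (is.null(labeled) || is.null(audio)) return(NA_real_)
  social_cats <- c("student_apartments", "residential_halls", "green_spaces")
  bouts <- category_bouts(labeled)[category %in% social_cats & mins >= min_episode_min]
  if (nrow(bouts) == 0) return(0)
  au <- data.table::as.data.table(audio)
  total <- 0
  for (i in seq_len(nrow(bouts))) {
    ov <- au[timestamp >= bouts$start[i] & timestamp < bouts$end[i]]
    if (nrow(ov) == 0) next
    share <- mean(ov$class %in% c("voice", "noise"))
    if (share >= voice_share_threshold) total <- total + bouts$mins[i]
  }
  total
}

#' Circadian movement regularity
#'
#' Lomb-Scargle normalized periodogram of the latitude and longitude series
#' (powers summed), evaluated at a 24-hour period. Constant location gives 0.
#'
#' @param location location samples (timestamp, lat, lon); >= 2 days
#' @param period_hours period of interest (default 24)
#' @return non-negative score
#' @export
circadian_regularity <- function(location, period_hours = 24) {
  dt <- data.table::as.data.table(location)
  if (nrow(dt) < 3) return(NA_real_)
  th <- as.numeric(dt$timestamp - dt$timestamp[1], units = "hours")
  sum(lomb_scargle_power(th, dt$lat, period_hours)) +
    sum(lomb_scargle_power(th, dt$lon, period_hours))
}
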