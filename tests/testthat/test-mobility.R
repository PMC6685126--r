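# Speeds, DBSCAN places, mobility/campus features, home, multimodal
# durations and circadian regularity.

test_that("speeds follow haversine arithmetic and the 1 km/h rule", {
  p0 <- c(-79.945, 40.445)
  p1 <- geosphere::destPoint(p0, 90, 1000) # ~1 km east
  d01 <- geosphere::distHaversine(p0, p1)
  loc <- data.table::data.table(
    timestamp = ts_at("2017-02-01 10:00:00", "2017-02-01 10:10:00"),
    lat = c(p0[2], p1[2]), lon = c(p0[1], p1[1]))
  ann <- compute_speeds(loc)
  expect_equal(ann$speed_kmh, c(0, (d01 / 1000) * 6), tolerance = 1e-6)
  expect_equal(ann$speed_kmh[2], 6, tolerance = 0.01)
  expect_identical(ann$state, c("static", "moving"))

  # identical coordinates: static
  loc2 <- data.table::data.table(timestamp = ts_seq("2017-02-01", 600, 3),
                                 lat = rep(40.445, 3), lon = rep(-79.945, 3))
  ann2 <- compute_speeds(loc2)
  expect_equal(ann2$speed_kmh, rep(0, 3))
  expect_identical(unique(ann2$state), "static")

  # 100 m in 10 min = 0.6 km/h: below threshold
  p2 <- geosphere::destPoint(p0, 0, 100)
  d02 <- geosphere::distHaversine(p0, p2)
  loc3 <- data.table::data.table(
    timestamp = ts_at("2017-02-01 10:00:00", "2017-02-01 10:10:00"),
    lat = c(p0[2], p2[2]), lon = c(p0[1], p2[1]))
  ann3 <- compute_speeds(loc3)
  expect_equal(ann3$speed_kmh[2], (d02 / 1000) * 6, tolerance = 1e-6)
  expect_equal(ann3$speed_kmh[2], 0.6, tolerance = 0.01)
  expect_identical(ann3$state[2], "static")
})

test_that("internal haversine matches geosphere", {
  set.seed(3)
  lat1 <- runif(200, 40.4, 40.5); lon1 <- runif(200, -80, -79.9)
  lat2 <- lat1 + rnorm(200, 0, 0.01); lon2 <- lon1 + rnorm(200, 0, 0.01)
  expect_equal(lonelysense:::dist_m(lat1, lon1, lat2, lon2),
               geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)),
               tolerance = 1e-9)
})

test_that("DBSCAN matches the brute-force oracle on random configurations", {
  set.seed(42)
  for (rep in 1:20) {
    n1 <- sample(5:35, 1); n2 <- sample(5:35, 1); nn <- sample(0:6, 1)
    lat <- c(rnorm(n1, 40.4450, 1.2e-4), rnorm(n2, 40.4495, 1.2e-4),
             runif(nn, 40.40, 40.49))
    lon <- c(rnorm(n1, -79.9450, 1.2e-4), rnorm(n2, -79.9450, 1.2e-4),
             runif(nn, -79.99, -79.90))
    eps <- sample(c(30, 50, 80), 1)
    ms <- sample(3:6, 1)
    a <- dbscan_geo(lat, lon, eps, ms)
    b <- brute_dbscan(lat, lon, eps, ms)
    expect_true(same_partition(a, b),
                label = sprintf("rep %d (eps=%g, min_samples=%d)", rep, eps, ms))
  }
})

test_that("DBSCAN planted two clouds and an outlier", {
  set.seed(1)
  lat <- c(rnorm(30, 40.4450, 1e-4), rnorm(30, 40.4495, 1e-4), 40.49)
  lon <- c(rnorm(30, -79.9450, 1e-4), rnorm(30, -79.9450, 1e-4), -79.90)
  lab <- dbscan_geo(lat, lon, eps = 50, min_samples = 5)
  expect_equal(length(unique(lab[lab > 0])), 2)
  expect_equal(lab[61], -1L)
  # degenerate inputs
  expect_true(all(dbscan_geo(c(40.4, 40.41), c(-79.9, -79.91), 30, 5) == -1L))
  expect_equal(unique(dbscan_geo(rep(40.4, 8), rep(-79.9, 8), 30, 5)), 1L)
  expect_identical(dbscan_geo(numeric(0), numeric(0), 30, 5), integer(0))
})

test_that("mobility features: degenerate and analytic cases", {
  # all samples in one place
  one <- mk_location("2017-02-01 08:00:00",
                     matrix(rep(c(40.4450, -79.9450), each = 60), ncol = 2))
  ann <- compute_speeds(one)
  gp <- cluster_static_points(ann, 30, 5, "global")
  lp <- cluster_static_points(ann, 30, 5, "local")
  f <- mobility_features(ann, gp, lp)
  expect_equal(unname(f["entropy_local"]), 0)
  expect_equal(unname(f["entropy_normalized_local"]), 0)
  expect_equal(unname(f["radius_of_gyration_m"]), 0, tolerance = 1e-6)
  expect_equal(unname(f["pct_time_moving"]), 0)
  expect_equal(unname(f["n_clusters_local"]), 1)

  # equal time in two distant places: entropy ln 2, normalized 1
  pA <- c(40.4450, -79.9450); pB <- c(40.4520, -79.9450)
  centers <- rbind(
    matrix(rep(pA, each = 30), ncol = 2),
    matrix(rep(pB, each = 30), ncol = 2))
  two <- mk_location("2017-02-01 08:00:00", centers)
  ann2 <- compute_speeds(two)
  gp2 <- cluster_static_points(ann2, 30, 5, "global")
  lp2 <- cluster_static_points(ann2, 30, 5, "local")
  f2 <- mobility_features(ann2, gp2, lp2)
  expect_equal(unname(f2["entropy_local"]), log(2), tolerance = 0.05)
  expect_equal(unname(f2["entropy_normalized_local"]), 1, tolerance = 0.05)
  expect_equal(unname(f2["n_transitions_local"]), 1)

  # empty stream: missing markers
  f3 <- mobility_features(ann2[0], gp2, lp2)
  expect_true(all(is.na(f3)))
})

test_that("total distance matches the planted commute path length", {
  pA <- c(40.4450, -79.9450); pB <- c(40.4520, -79.9380)
  hop <- geosphere::distHaversine(rev(pA), rev(pB))
  centers <- matrix(rep(c(pA, pB), times = 10), ncol = 2, byrow = TRUE)
  trace <- mk_location("2017-02-01 08:00:00", centers)
  ann <- compute_speeds(trace)
  gp <- cluster_static_points(ann, 30, 5)
  f <- mobility_features(ann, gp, cluster_static_points(ann, 30, 5, "local"))
  planted_km <- 19 * hop / 1000 # 19 hops between alternating places
  expect_equal(unname(f["total_distance_km"]), planted_km, tolerance = 0.01)
})

test_that("home estimation recovers the planted center", {
  set.seed(8)
  home <- c(lat = 40.4452, lon = -79.9441)
  night <- data.table::data.table(
    timestamp = ts_seq("2017-02-01 00:00:00", 600, 200),
    lat = rnorm(200, home["lat"], 10 / 111320),
    lon = rnorm(200, home["lon"], 10 / 84000))
  ann <- compute_speeds(night)
  est <- estimate_home(ann)
  expect_false(is.null(est$center))
  d <- geosphere::distHaversine(c(est$center["lon"], est$center["lat"]),
                                c(home["lon"], home["lat"]))
  expect_lt(d, 50)

  # all night samples at exactly one point
  pt <- data.table::data.table(
    timestamp = ts_seq("2017-02-01 00:00:00", 600, 36),
    lat = rep(40.4452, 36), lon = rep(-79.9441, 36))
  est2 <- estimate_home(compute_speeds(pt))
  expect_equal(unname(est2$center["lat"]), 40.4452)
  expect_equal(unname(est2$features["time_at_home_10m_min"]), 360)

  est3 <- estimate_home(compute_speeds(pt[0]))
  expect_null(est3$center)
  expect_true(all(is.na(est3$features)))
})

test_that("campus categories: labeled polygons, academic default, off campus", {
  map <- test_campus()
  g <- place_center(map, "green_spaces")
  expect_identical(assign_campus_category(g["lat"], g["lon"], map), "green_spaces")
  # on campus but in no labeled polygon
  b <- map$boundary
  inside <- c(lat = min(b$lat) + 1e-4, lon = min(b$lon) + 1e-4)
  expect_identical(assign_campus_category(inside["lat"], inside["lon"], map),
                   "academic")
  expect_identical(assign_campus_category(40.49, -79.90, map), "off_campus")
})

test_that("campus features count bouts and transitions by enumeration", {
  map <- test_campus()
  g <- place_center(map, "green_spaces")
  a <- place_center(map, "athletic_facilities")
  # single 25-min stay (2.5 samples at 10-min cadence -> use 5-min cadence)
  lb <- data.table::data.table(
    timestamp = ts_seq("2017-02-01 10:00:00", 300, 5),
    category = rep("green_spaces", 5))
  f <- campus_features(lb)
  expect_equal(unname(f["green_spaces_min"]), 25)
  expect_equal(unname(f["green_spaces_bouts_ge10"]), 1)
  expect_equal(unname(f["green_spaces_bouts_ge20"]), 1)
  expect_equal(unname(f["green_spaces_bouts_ge30"]), 0)

  # A -> B -> A -> B in equal bouts: 3 transitions, 2 bouts per category
  lb2 <- data.table::data.table(
    timestamp = ts_seq("2017-02-01 10:00:00", 600, 24),
    category = rep(rep(c("academic", "residential_halls"), 2), each = 6))
  f2 <- campus_features(lb2)
  expect_equal(unname(f2["campus_n_transitions"]), 3)
  expect_equal(unname(f2["academic_n_bouts"]), 2)
  expect_equal(unname(f2["residential_halls_n_bouts"]), 2)
  # per-category minutes partition the covered duration
  cats <- lonelysense:::all_campus_labels()
  expect_equal(sum(f2[paste0(cats, "_min")]), 240)
  expect_equal(sum(f2[paste0(cats, "_pct")]), 100)

  # entirely off campus
  lb3 <- data.table::data.table(
    timestamp = ts_seq("2017-02-01 10:00:00", 600, 6),
    category = "off_campus")
  f3 <- campus_features(lb3)
  expect_equal(unname(f3["off_campus_min"]), 60)
  expect_equal(unname(f3["academic_min"]), 0)
})

test_that("study duration applies the 30-min sedentary no-phone rule", {
  mk_lab <- function(n) data.table::data.table(
    timestamp = ts_seq("2017-02-01 10:00:00", 300, n),
    category = "academic")
  steps0 <- data.table::data.table(
    timestamp = ts_seq("2017-02-01 09:55:00", 300, 20), steps = 0L)
  no_sessions <- data.table::data.table(
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"))
  expect_equal(study_duration(mk_lab(7), steps0, no_sessions), 35)
  expect_equal(study_duration(mk_lab(5), steps0, no_sessions), 0)
  # one interaction session inside voids the episode
  sess <- data.table::data.table(start = ts_at("2017-02-01 10:10:00"),
                                 end = ts_at("2017-02-01 10:12:00"))
  expect_equal(study_duration(mk_lab(7), steps0, sess), 0)
  # an active step interval voids it too
  steps_act <- data.table::copy(steps0)[5, steps := 50L]
  expect_equal(study_duration(mk_lab(7), steps_act, no_sessions), 0)
  expect_true(is.na(study_duration(NULL, steps0, no_sessions)))
})

test_that("social duration applies the 20-min 80%-voice rule", {
  mk_lab <- function(n, cat = "residential_halls") data.table::data.table(
    timestamp = ts_seq("2017-02-01 19:00:00", 300, n), category = cat)
  # 20 audio samples at 75-s cadence sit entirely inside a 25-min bout
  mk_audio <- function(share, n = 20) data.table::data.table(
    timestamp = ts_seq("2017-02-01 19:00:00", 75, n),
    class = rep(c("voice", "silence"), round(c(share, 1 - share) * n)))
  expect_equal(social_duration(mk_lab(5), mk_audio(0.85)), 25)
  expect_equal(social_duration(mk_lab(5), mk_audio(0.70)), 0)
  expect_equal(social_duration(mk_lab(3), mk_audio(0.9)), 0) # below 20 min
  expect_true(is.na(social_duration(mk_lab(5), NULL)))
})

test_that("circadian regularity peaks at the 24-h period for a sinusoid", {
  set.seed(15)
  t_h <- seq(0, 24 * 28, by = 1 / 6) # 10-min cadence over 4 weeks
  y <- sin(2 * pi * t_h / 24)
  periods <- seq(6, 48, by = 0.5)
  pw <- lomb_scargle_power(t_h, y, periods)
  expect_equal(periods[which.max(pw)], 24)

  # periodic schedule scores higher than its time-permuted version
  lat0 <- 40.4450 + 0.004 * (sin(2 * pi * t_h / 24) > 0)
  loc <- data.table::data.table(
    timestamp = as.POSIXct("2017-02-01", tz = "UTC") + t_h * 3600,
    lat = lat0 + rnorm(length(t_h), 0, 1e-5),
    lon = -79.945 + rnorm(length(t_h), 0, 1e-5))
  score <- circadian_regularity(loc)
  perm_scores <- replicate(20, {
    shuffled <- data.table::copy(loc)[, `:=`(lat = sample(lat), lon = sample(lon))]
    circadian_regularity(shuffled)
  })
  expect_true(all(score > perm_scores))

  # constant location scores zero
  const <- data.table::data.table(timestamp = loc$timestamp,
                                  lat = 40.4, lon = -79.9)
  expect_equal(circadian_regularity(const), 0)
})
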