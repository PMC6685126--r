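# Synthetic cohort generator: contracts, determinism, planted effects.

test_that("a one-participant cohort has all eight streams non-empty", {
  coh <- generate_cohort(1, effect_size = 0.5,
                         calendar = study_calendar("2017-01-18", 2L, 1L),
                         seed = 7)
  expect_length(coh$participants, 1)
  st <- coh$participants[[1]]$streams
  for (s in c("location", "bluetooth", "screen", "calls", "sms", "audio",
              "steps", "sleep")) {
    expect_gt(nrow(st[[s]]), 0, label = paste("stream", s))
  }
  # generator cadence contract
  expect_equal(median(as.numeric(diff(st$location$timestamp), units = "mins")), 10)
  expect_equal(median(as.numeric(diff(st$steps$timestamp), units = "mins")), 5)
  expect_equal(median(as.numeric(diff(st$sleep$timestamp), units = "mins")), 1)
  # timestamps non-decreasing
  for (s in c("location", "screen", "calls", "sms", "steps", "sleep"))
    expect_true(!is.unsorted(st[[s]]$timestamp), label = paste("sorted", s))
  expect_true(all(st$steps$steps >= 0))
})

test_that("identical seeds give identical cohorts", {
  cal <- study_calendar("2017-01-18", 2L, 1L)
  a <- generate_cohort(2, effect_size = 1, calendar = cal, seed = 42)
  b <- generate_cohort(2, effect_size = 1, calendar = cal, seed = 42)
  expect_identical(a$truth, b$truth)
  expect_identical(a$participants[[2]]$streams$location,
                   b$participants[[2]]$streams$location)
  expect_identical(a$participants[[1]]$streams$bluetooth,
                   b$participants[[1]]$streams$bluetooth)
  c2 <- generate_cohort(2, effect_size = 1, calendar = cal, seed = 43)
  expect_false(identical(a$participants[[1]]$streams$location,
                         c2$participants[[1]]$streams$location))
})

test_that("argument contracts are enforced", {
  cal <- study_calendar("2017-01-18", 2L, 1L)
  expect_error(generate_cohort(0, calendar = cal, seed = 1), "n_participants")
  expect_error(generate_cohort(2, effect_size = -1, calendar = cal, seed = 1),
               "effect_size")
  expect_error(behavior_profile(1.2, c(lat = 0, lon = 0), 1, 0.5, 0.5, 1, 4,
                                list(self = 1)), "probabilities")
  expect_error(behavior_profile(0.5, c(lat = 0, lon = 0), -1, 0.5, 0.5, 1, 4,
                                list(self = 1)), "non-negative")
})

test_that("LL participants spend more weekend-evening time off campus", {
  coh <- generate_cohort(30, effect_size = 1,
                         calendar = study_calendar("2017-01-18", 4L, 2L),
                         seed = 101)
  win <- materialize_windows(list(epoch = "evening", day_filter = "weekends",
                                  granularity = "semester"), coh$calendar)[1]
  offmin <- vapply(coh$participants, function(p) {
    sl <- slice_stream(p$streams$location, win)
    cat_ <- assign_campus_category(sl$lat, sl$lon, coh$campus_map)
    10 * sum(cat_ == "off_campus")
  }, numeric(1))
  lv <- coh$truth$pre_level
  skip_if(length(unique(lv)) < 2) # both groups present at this seed
  expect_gt(mean(offmin[lv == "LL"]), mean(offmin[lv == "HL"]))
  # and the planted propensities themselves separate the groups
  expect_gt(mean(coh$truth$evening_offcampus_propensity[lv == "LL"]),
            mean(coh$truth$evening_offcampus_propensity[lv == "HL"]))
})

test_that("night-epoch location samples stay near home at default noise", {
  coh <- small_cohort()
  win <- materialize_windows(list(epoch = "night", day_filter = "all_days",
                                  granularity = "semester"), coh$calendar)[1]
  for (p in coh$participants) {
    sl <- slice_stream(p$streams$location, win)
    d <- geosphere::distHaversine(
      cbind(sl$lon, sl$lat),
      cbind(p$profile$home_center["lon"], p$profile$home_center["lat"]))
    expect_gt(mean(d <= 100), 0.9)
  }
})

test_that("survey responses track the latent and reverse correctly", {
  prof <- behavior_profile(1, c(lat = 40.445, lon = -79.945), 10, 0.5, 0.5,
                           1.5, 4, list(self = 1))
  r <- generate_survey_responses(prof, "pre", noise_sd = 0)
  expect_identical(score_ucla(r), 80L)
  # raw responses are on the unreversed scale: reversed items read 1
  expect_true(all(r[ucla_reverse_items()] == 1L))
  expect_true(all(r[setdiff(1:20, ucla_reverse_items())] == 4L))

  a <- generate_survey_responses(prof, "pre", seed = 5)
  b <- generate_survey_responses(prof, "pre", seed = 5)
  expect_identical(a, b)

  prof9 <- behavior_profile(0.9, c(lat = 40.445, lon = -79.945), 10, 0.5, 0.5,
                            1.5, 4, list(self = 1))
  set.seed(77)
  totals <- replicate(1000, score_ucla(generate_survey_responses(prof9, "pre")))
  expect_gt(mean(totals > 40), 0.9)
})

test_that("cohort round-trips through CSV/GeoJSON files", {
  coh <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort_csv(coh, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "location.csv", "bluetooth.csv", "screen.csv", "calls.csv", "sms.csv",
    "audio.csv", "steps.csv", "sleep.csv", "surveys.csv",
    "contact_groups.csv", "campus.geojson")))))
  loc <- data.table::fread(file.path(dir, "location.csv"))
  expect_equal(nrow(loc), sum(vapply(coh$participants,
                                     function(p) nrow(p$streams$location), numeric(1))))
  map2 <- read_campus_geojson(file.path(dir, "campus.geojson"))
  expect_equal(sort(vapply(map2$polygons, `[[`, character(1), "category")),
               sort(vapply(coh$campus_map$polygons, `[[`, character(1), "category")))
  expect_equal(unlist(map2$boundary), unlist(coh$campus_map$boundary),
               tolerance = 1e-9)
})
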