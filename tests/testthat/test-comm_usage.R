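# Call/SMS features, screen sessions and features, Bluetooth device
# classification and features.

cg_fixture <- data.table::data.table(
  contact_id = c("mom", "dad", "ali", "bea", "carl", "zed"),
  group = c("family", "family", "friend_on_campus", "friend_on_campus",
            "friend_off_campus", "other"))

test_that("call and SMS features enumerate by direction and audience", {
  calls <- data.table::data.table(
    timestamp = ts_seq("2017-02-01 10:00:00", 3600, 3),
    direction = c("outgoing", "outgoing", "missed"),
    duration = c(60, 120, 0),
    contact_id = c("mom", "mom", "unknown_1"))
  f <- call_sms_features(calls, NULL, cg_fixture)
  expect_equal(unname(f["calls_outgoing_family_count"]), 2)
  expect_equal(unname(f["calls_outgoing_family_duration_s"]), 180)
  expect_equal(unname(f["calls_missed_everyone_count"]), 1)
  expect_equal(unname(f["calls_incoming_everyone_count"]), 0)

  # empty but present log: zero counts
  f0 <- call_sms_features(calls[0], NULL, cg_fixture)
  expect_equal(unname(f0["calls_outgoing_everyone_count"]), 0)
  # both streams absent: missing markers
  fna <- call_sms_features(NULL, NULL, cg_fixture)
  expect_true(all(is.na(fna)))

  # distinct correspondents per audience
  calls2 <- data.table::data.table(
    timestamp = ts_seq("2017-02-01 10:00:00", 3600, 3),
    direction = "outgoing", duration = 30,
    contact_id = c("ali", "bea", "ali"))
  f2 <- call_sms_features(calls2, NULL, cg_fixture)
  expect_equal(unname(f2["correspondents_friends_on_campus"]), 2)
  expect_equal(unname(f2["correspondents_everyone"]), 2)
})

test_that("screen sessions pair unlocks with their terminators", {
  ev <- data.table::data.table(
    timestamp = ts_at("2017-02-01 10:00:00", "2017-02-01 10:05:00"),
    status = c("unlock", "off"))
  s <- screen_sessions(ev)
  expect_equal(nrow(s$interaction), 1)
  expect_equal(as.numeric(s$interaction$end - s$interaction$start, units = "mins"), 5)

  expect_equal(nrow(screen_sessions(ev[0])$interaction), 0)

  # trailing unlock truncated at the window end
  ev2 <- data.table::data.table(timestamp = ts_at("2017-02-01 23:58:00"),
                                status = "unlock")
  s2 <- screen_sessions(ev2, truncate_at = ts_at("2017-02-02 00:00:00"))
  expect_equal(as.numeric(s2$interaction$end - s2$interaction$start,
                          units = "mins"), 2)

  # unlock -> off -> lock: interaction ends at off, unlocked at lock
  ev3 <- data.table::data.table(
    timestamp = ts_at("2017-02-01 10:00:00", "2017-02-01 10:04:00",
                      "2017-02-01 10:06:00"),
    status = c("unlock", "off", "lock"))
  s3 <- screen_sessions(ev3)
  expect_equal(as.numeric(s3$interaction$end - s3$interaction$start, units = "mins"), 4)
  expect_equal(as.numeric(s3$unlocked$end - s3$unlocked$start, units = "mins"), 6)
})

test_that("screen features: unlock rate and first/last event hours", {
  ev <- data.table::data.table(
    timestamp = ts_seq("2017-02-01 10:00:00", 600, 6),
    status = "unlock")
  sess <- screen_sessions(ev, truncate_at = ts_at("2017-02-01 11:00:00"))
  f <- screen_features(ev, sess, window_minutes = 60, hourly_indicators = FALSE)
  expect_equal(unname(f["unlocks_per_min"]), 0.1)

  one <- data.table::data.table(timestamp = ts_at("2017-02-01 07:12:00"),
                                status = "unlock")
  f1 <- screen_features(one, screen_sessions(one, ts_at("2017-02-01 08:00:00")),
                        window_minutes = 60, hourly_indicators = TRUE)
  expect_equal(unname(floor(f1["first_unlock_h"])), 7)
  expect_equal(unname(f1["first_unlock_in_hour_07"]), 1)
  expect_equal(unname(f1["first_unlock_in_hour_08"]), 0)

  fe <- screen_features(ev[0], screen_sessions(ev[0]), window_minutes = 60,
                        hourly_indicators = FALSE)
  expect_true(is.na(fe["first_unlock_h"]))
})

test_that("bluetooth classification implements the score-and-cluster steps", {
  # planted inventory: A every day at high rate, B half the days moderate,
  # C once -- well-separated scores
  days <- seq(as.Date("2017-02-01"), by = "day", length.out = 20)
  mk_scans <- function(id, on_days, per_day) {
    data.table::rbindlist(lapply(on_days, function(d) data.table::data.table(
      timestamp = as.POSIXct(paste(d, "09:00:00"), tz = "UTC") +
        seq_len(per_day) * 600,
      device_id = id)))
  }
  scans <- data.table::rbindlist(list(
    mk_scans("A", days, 40), mk_scans("B", days[1:10], 8), mk_scans("C", days[3], 1)))
  cl <- classify_bluetooth_devices(scans)
  expect_identical(unname(cl$groups["A"]), "self")
  expect_identical(unname(cl$groups["B"]), "related")
  expect_identical(unname(cl$groups["C"]), "others")
  expect_equal(cl$k_chosen, 3L)
  # the chosen K has the smaller total within-cluster SSE, verified against
  # exhaustive contiguous-partition search in 1-D
  sc <- cl$profiles$score
  expect_lt(best_1d_partition_sse(sc, 3), best_1d_partition_sse(sc, 2))

  # scan-order invariance
  cl2 <- classify_bluetooth_devices(scans[sample.int(nrow(scans))])
  expect_identical(cl$groups[order(names(cl$groups))],
                   cl2$groups[order(names(cl2$groups))])

  # number_of_days / average_frequency definitions
  pa <- cl$profiles[device_id == "B"]
  expect_equal(pa$number_of_days, 10)
  expect_equal(pa$average_frequency, 8)
})

test_that("bluetooth classification degenerate and K=2 cases", {
  one <- data.table::data.table(timestamp = ts_seq("2017-02-01", 600, 5),
                                device_id = "solo")
  expect_identical(unname(classify_bluetooth_devices(one)$groups["solo"]), "self")

  # two strongly bimodal devices: only K=2 is fittable; higher score = self
  days <- seq(as.Date("2017-02-01"), by = "day", length.out = 10)
  mk <- function(id, nd, per) data.table::rbindlist(lapply(days[seq_len(nd)],
    function(d) data.table::data.table(
      timestamp = as.POSIXct(paste(d, "09:00:00"), tz = "UTC") + seq_len(per) * 60,
      device_id = id)))
  two <- data.table::rbindlist(list(mk("big", 10, 30), mk("small", 1, 1)))
  cl <- classify_bluetooth_devices(two)
  expect_equal(cl$k_chosen, 2L)
  expect_identical(unname(cl$groups["big"]), "self")
  expect_identical(unname(cl$groups["small"]), "others")
})

test_that("bluetooth features per scope from planted counts", {
  scans <- data.table::data.table(
    timestamp = ts_seq("2017-02-01 09:00:00", 600, 13),
    device_id = c(rep("A", 10), rep("B", 2), "C"))
  groups <- c(A = "self", B = "related", C = "others")
  f <- bluetooth_features(scans, groups)
  expect_equal(unname(f["bt_all_unique_devices"]), 3)
  expect_equal(unname(f["bt_all_most_frequent_scans"]), 10)
  expect_equal(unname(f["bt_all_least_frequent_scans"]), 1)
  expect_equal(unname(f["bt_all_scans_sum"]), 13)
  expect_equal(unname(f["bt_self_related_scans_sum"]), 12)
  expect_equal(unname(f["bt_others_unique_devices"]), 1)
  # empty window: missing markers
  fe <- bluetooth_features(scans[0], groups)
  expect_true(all(is.na(fe)))
  # scopes partition the devices
  expect_equal(unname(f["bt_self_related_unique_devices"] + f["bt_others_unique_devices"]),
               unname(f["bt_all_unique_devices"]))
})
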