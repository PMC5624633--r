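test_that("haversine distance matches closed-form references", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
})

test_that("split_days partitions by vessel and local (UTC+8) date", {
  ts <- as.POSIXct("2010-05-01 00:00:00", tz = "UTC") + (0:47) * 3600 -
    8 * 3600
  pts <- data.frame(vessel_id = "V1", timestamp = ts, lat = 22, lon = 121,
                    speed_kn = 5)
  days <- split_days(pts)
  expect_length(days, 2)
  expect_true(all(vapply(days, function(d) nrow(d$points), integer(1)) == 24))
  # two points straddling UTC midnight share a local date at offset 8
  pts2 <- data.frame(
    vessel_id = "V1",
    timestamp = as.POSIXct(c("2010-05-01 23:30:00", "2010-05-02 00:30:00"),
                           tz = "UTC"),
    lat = 22, lon = 121, speed_kn = 5)
  days2 <- split_days(pts2)
  expect_length(days2, 1)
  expect_false(days2[[1]]$classifiable) # < 3 points
})

test_that("resampling keeps the earliest fix and nearest points per interval", {
  day <- straight_day(hours = 24)
  rs <- resample_day(day, 5)
  hrs <- as.numeric(difftime(rs$points$timestamp, day$points$timestamp[1],
                             units = "hours"))
  expect_equal(hrs, c(0, 5, 10, 15, 20))
  expect_identical(resample_day(day, 1)$points, day$points)
  # irregular gaps: nearest selection, no duplicates
  irr <- day
  irr$points <- day$points[c(1, 2, 3, 10, 11, 24), ]
  rs2 <- resample_day(irr, 5)
  expect_false(any(duplicated(rs2$points$timestamp)))
  expect_true(!is.unsorted(rs2$points$timestamp))
})

test_that("speed criterion flags any slow instance", {
  d_fast <- make_day(lat = c(22, 22.1, 22.2), lon = 121,
                     speed = c(8, 9, 8))
  d_slow <- make_day(lat = c(22, 22.1, 22.2), lon = 121,
                     speed = c(8, 2, 7))
  expect_false(classify_speed(d_fast, 3))
  expect_true(classify_speed(d_slow, 3))
  d_na <- make_day(lat = c(22, 22.1, 22.2), lon = 121,
                   speed = rep(NA_real_, 3))
  expect_true(is.na(classify_speed(d_na, 3)))
})

test_that("distance criterion uses cumulative path length and is threshold-monotone", {
  stationary <- make_day(lat = rep(22, 5), lon = rep(121, 5), speed = 0)
  expect_true(classify_distance(stationary, 130))
  transit <- straight_day(hours = 24, speed_kn = 9)
  expect_false(classify_distance(transit, 130)) # ~ 380 km path
  # monotone: raising the threshold never flips fishing -> nonfishing
  set.seed(1)
  for (i in 1:20) {
    day <- straight_day(hours = 12, speed_kn = runif(1, 1, 10))
    prev <- FALSE
    for (thr in seq(70, 190, 10)) {
      cur <- classify_distance(day, thr)
      expect_false(prev && !cur)
      prev <- cur
    }
  }
})

test_that("direction criterion detects turn-arounds, not straight transits", {
  transit <- straight_day(hours = 24)
  expect_false(classify_direction(transit, 90, interval_h = 1))
  # out-and-back: 12 h north then 12 h back south
  out_back <- make_day(lat = c(22 + (0:11) * 0.08, 22.88 - (1:12) * 0.08),
                       lon = 121, speed = 5)
  expect_true(classify_direction(out_back, 90, interval_h = 1))
  # the literal "within x degrees" reading is available as a flipped rule
  expect_true(classify_direction(transit, 90, comparison = "at_most"))
  # sub-km jitter around a mooring gives no usable bearings
  moored <- make_day(lat = 22 + rnorm(10, 0, 1e-4),
                     lon = 121 + rnorm(10, 0, 1e-4), speed = 0.2)
  expect_true(is.na(classify_direction(moored, 90)))
})

test_that("confusion statistics reproduce all twelve derived values of the
           three printed criterion rows", {
  rows <- list(
    list(tp = 2731, fn = 96, fp = 1031, tn = 136,
         tpr = 0.966, tnr = 0.117, sss = 1.083, dss = 0.850),
    list(tp = 2482, fn = 343, fp = 690, tn = 474,
         tpr = 0.879, tnr = 0.407, sss = 1.286, dss = 0.471),
    list(tp = 2687, fn = 202, fp = 342, tn = 841,
         tpr = 0.930, tnr = 0.711, sss = 1.641, dss = 0.219)
  )
  for (r in rows) {
    cs <- confusion_from_counts(r$tp, r$fn, r$fp, r$tn)
    expect_equal(round(cs$TPR, 3), r$tpr)
    expect_equal(round(cs$TNR, 3), r$tnr)
    expect_equal(round(cs$SSS, 3), r$sss)
    expect_equal(round(cs$DSS, 3), r$dss)
  }
})

test_that("confusion identities hold for random count matrices", {
  set.seed(2)
  for (i in 1:50) {
    tp <- sample(0:500, 1); fn <- sample(1:500, 1)
    fp <- sample(0:500, 1); tn <- sample(1:500, 1)
    cs <- confusion_from_counts(tp, fn, fp, tn)
    expect_equal(cs$TPR, tp / (tp + fn))
    expect_equal(cs$TNR, tn / (tn + fp))
    expect_equal(cs$SSS, cs$TPR + cs$TNR)
    expect_equal(cs$DSS, abs(cs$TPR - cs$TNR))
    expect_true(cs$SSS >= 0 && cs$SSS <= 2)
    expect_true(cs$DSS >= 0 && cs$DSS <= 1)
  }
  expect_equal(confusion_stats(c(TRUE, FALSE), c(TRUE, FALSE))$SSS, 2)
  expect_error(confusion_stats(c(TRUE, TRUE), c(TRUE, TRUE)), "positive")
})

test_that("grid search ties break on the smaller DSS and the winner is undominated", {
  cfg <- sim_config(seed = 51, n_vessels = 10, n_days = 20)
  T <- gen_tracks(cfg)
  days <- split_days(T$points)
  gs <- grid_search(days, T$labels, "direction", intervals_h = c(1, 5))
  tab <- gs$table[!is.na(gs$table$SSS), ]
  dominated <- any(tab$SSS > gs$best$sss & tab$DSS < gs$best$dss)
  expect_false(dominated)
  # explicit tie: equal SSS, DSS 0.3 vs 0.1 -> pick DSS 0.1 (via table logic)
  best_sss <- max(tab$SSS)
  tied <- tab[tab$SSS >= best_sss - 0.01, ]
  expect_equal(gs$best$dss, min(tied$DSS))
})

test_that("speed-grid optimum sits near the generating retrieval speed", {
  cfg <- sim_config(seed = 52, n_vessels = 20, n_days = 25,
                    retrieval_speed_kn = 2.2)
  T <- gen_tracks(cfg)
  days <- split_days(T$points)
  gs <- grid_search(days, T$labels, "speed")
  expect_true(gs$best$threshold %in% 2:4)
})

test_that("apply_criterion is pure, handles empty input, and is sensitive on
           the synthetic fleet", {
  expect_equal(nrow(apply_criterion(list(),
                                    list(approach = "speed", threshold = 3))), 0)
  cfg <- sim_config(seed = 53, n_vessels = 10, n_days = 20)
  T <- gen_tracks(cfg)
  days <- split_days(T$points)
  spec <- list(approach = "direction", threshold = 90, interval_h = 5L)
  f1 <- apply_criterion(days, spec)
  f2 <- apply_criterion(days, spec)
  expect_identical(f1, f2)
  m <- merge(f1, T$labels, by = c("vessel_id", "date"))
  sens <- mean(m$fishing[m$is_fishing], na.rm = TRUE)
  expect_gte(sens, 0.9)
  expect_error(apply_criterion(days, list(approach = "sonar", threshold = 1)))
})
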