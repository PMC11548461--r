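mk_fixes <- function(n = 96, state = NULL, start = "2022-04-01") {
  ts <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 1800
  data.frame(animal_id = "A01", herd_type = "resident", timestamp = ts,
             state = state %||% rep(c("resting", "foraging"), length.out = n),
             diel = rep(c("night", "day"), each = n / 4),
             season = "warm_dry",
             step_m = rep(c(10, 200), length.out = n))
}

test_that("activity budgets conserve counts and normalise per cell", {
  surv <- small_survey()
  fx <- surv$truth
  fx$state <- factor(c("resting", "foraging", "travelling")[fx$true_state])
  fx$diel <- factor(ifelse(fx$night, "night", "day"))
  b <- activity_budget(fx, keys = c("herd_type", "diel"))
  expect_equal(sum(b$n), nrow(fx))
  cells <- split(b, interaction(b$herd_type, b$diel))
  for (cell in cells) {
    if (sum(cell$n) > 0) expect_equal(sum(cell$prop), 1, tolerance = 1e-12)
    else expect_true(all(is.na(cell$prop)))
  }
  # single-state input: proportion 1 everywhere it appears
  one <- mk_fixes(state = rep("resting", 96))
  b1 <- activity_budget(one, keys = "diel")
  expect_true(all(b1$prop[b1$n > 0] == 1))
})

test_that("empty budget cells carry count 0 and NA proportion", {
  fx <- mk_fixes()
  fx$unit <- factor("homefields", levels = c("homefields", "lowlands"))
  b <- activity_budget(fx, keys = "unit")
  low <- b[b$unit == "lowlands", ]
  expect_true(all(low$n == 0))
  expect_true(all(is.na(low$prop)))
  expect_error(activity_budget(fx, keys = "nonexistent"), "nonexistent")
})

test_that("daily metrics conserve time and sum distances by state", {
  fx <- mk_fixes()
  dm <- daily_metrics(fx, daytime_only = FALSE)
  day1 <- dm$daily[dm$daily$date == as.Date("2022-04-01"), ]
  # half-hour per fix: state times sum to the observed span
  expect_equal(sum(day1$time_h), 48 * 0.5)
  expect_equal(sum(day1$distance_m), sum(fx$step_m[1:48]))
  # distances credited to the step's originating state
  expect_equal(day1$distance_m[day1$state == "resting"],
               sum(fx$step_m[fx$state == "resting"][1:24]))
  # a resting-only day with zero steps: distance 0, time = fixes x 0.5 h
  still <- mk_fixes(state = rep("resting", 96))
  still$step_m <- 0
  dm2 <- daily_metrics(still, daytime_only = TRUE)
  expect_true(all(dm2$daily$distance_m == 0))
  expect_equal(sum(dm2$daily$time_h), sum(still$diel == "day") * 0.5)
  expect_true(all(c("herd_type", "state") %in% names(dm$means)))
})

test_that("1-D k-means groups the published-style duration multiset", {
  durations <- c(10, 11, 12, 28, 30, 32, 70, 80)
  cl <- cluster_durations(durations, n_clusters = 3, seed = 1)
  expect_equal(cl, c(1, 1, 1, 2, 2, 2, 3, 3))
  means <- as.numeric(tapply(durations, cl, mean))
  expect_equal(means, c(11, 30, 75))
  # degenerate: fewer distinct values than clusters
  expect_equal(cluster_durations(c(5, 5, 5), 3), rep(1L, 3))
})

test_that("transhumant phase detection recovers the schedule", {
  surv <- small_survey()
  sch <- surv$config$transhumance_schedule
  tr_ids <- unique(surv$truth$herd_id[surv$truth$herd_type == "transhumant"])
  gps <- surv$gps
  gps$timestamp <- as.POSIXct(gps$timestamp_utc, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%SZ")
  gps$herd_id <- surv$truth$herd_id
  home <- local_lonlat(
    cbind(3000 * cos(seq(0, 2 * pi, length.out = 61)),
          3000 * sin(seq(0, 2 * pi, length.out = 61))),
    surv$config$home_centre)
  tr <- gps[gps$herd_id == tr_ids[1], ]
  rec <- detect_stops_and_phases(tr, home, herd_id = tr_ids[1])
  dep_true <- surv$config$start_date + sch$start_day[1] - 1
  expect_false(is.na(rec$departure))
  expect_lte(abs(as.numeric(rec$departure - dep_true)), 1)
  expect_true(nrow(rec$stops) >= 1)
  expect_true(!is.unsorted(rec$phases$start))
  # resident herd: no departure
  res_ids <- unique(surv$truth$herd_id[surv$truth$herd_type == "resident"])
  rs <- gps[gps$herd_id == res_ids[1], ]
  rec0 <- detect_stops_and_phases(rs, home, herd_id = res_ids[1])
  expect_true(is.na(rec0$departure))
  expect_equal(rec0$phases$label, "home")
})

test_that("phase detection is invariant to a uniform time shift", {
  surv <- small_survey()
  gps <- surv$gps
  gps$timestamp <- as.POSIXct(gps$timestamp_utc, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%SZ")
  gps$herd_id <- surv$truth$herd_id
  tr_id <- unique(gps$herd_id[surv$truth$herd_type == "transhumant"])[1]
  home <- local_lonlat(
    cbind(3000 * cos(seq(0, 2 * pi, length.out = 61)),
          3000 * sin(seq(0, 2 * pi, length.out = 61))),
    surv$config$home_centre)
  tr <- gps[gps$herd_id == tr_id, ]
  r1 <- detect_stops_and_phases(tr, home)
  tr2 <- tr
  shift <- 365 * 86400
  tr2$timestamp <- tr2$timestamp + shift
  r2 <- detect_stops_and_phases(tr2, home)
  expect_equal(as.numeric(r2$departure - r1$departure), 365)
  expect_equal(r2$stops$duration_days, r1$stops$duration_days)
  expect_equal(r2$stops$duration_class, r1$stops$duration_class)
})
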