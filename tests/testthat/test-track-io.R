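write_gps_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("collar_id,timestamp_utc,lat,lon,dop,temperature_c", rows),
             path)
  path
}

regular_times <- function(n, start = "2022-04-01T06:00:00Z") {
  format(as.POSIXct(start, tz = "UTC",
                    format = "%Y-%m-%dT%H:%M:%SZ") + (seq_len(n) - 1) * 1800,
         "%Y-%m-%dT%H:%M:%SZ")
}

test_that("gps reader validates rows and reports malformed ones", {
  ts <- regular_times(5)
  good <- sprintf("C01,%s,14.5,-16.5,1.2,33.1", ts)
  p <- write_gps_fixture(good)
  g <- read_gps_table(p)
  expect_equal(nrow(g), 5)
  expect_s3_class(g$timestamp, "POSIXct")
  # lat out of range -> row-level error, not an exception
  p2 <- write_gps_fixture(c(good, "C01,2022-04-01T09:00:00Z,95,-16.5,1,33"))
  expect_warning(g2 <- read_gps_table(p2), "malformed")
  expect_equal(nrow(g2), 5)
  expect_match(attr(g2, "bad_rows")$reason, "latitude")
  # duplicate (collar, timestamp) deduplicated with a warning
  p3 <- write_gps_fixture(c(good, good[2]))
  expect_warning(g3 <- read_gps_table(p3), "duplicate")
  expect_equal(nrow(g3), 5)
  expect_equal(attr(g3, "n_duplicates"), 1L)
  # missing required column -> schema error
  p4 <- tempfile(fileext = ".csv")
  writeLines(c("collar_id,timestamp_utc,lat", "C01,2022-04-01T00:00:00Z,1"),
             p4)
  expect_error(read_gps_table(p4), "lon")
})

test_that("metadata reader enforces period validity", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("collar_id,animal_id,herd_id,herd_type,start_utc,end_utc",
               "C01,A01,H01,resident,2022-04-01T00:00:00Z,2022-05-01T00:00:00Z",
               "C01,A02,H02,transhumant,2022-05-01T00:00:00Z,2022-06-01T00:00:00Z"),
             p)
  m <- read_metadata(p)
  expect_equal(nrow(m), 2)
  writeLines(c("collar_id,animal_id,herd_id,herd_type,start_utc,end_utc",
               "C01,A01,H01,resident,2022-04-01T00:00:00Z,2022-05-01T00:00:00Z",
               "C01,A02,H02,resident,2022-04-15T00:00:00Z,2022-06-01T00:00:00Z"),
             p)
  expect_error(read_metadata(p), "overlapping")
  writeLines(c("collar_id,animal_id,herd_id,herd_type,start_utc,end_utc",
               "C01,A01,H01,nomadic,2022-04-01T00:00:00Z,2022-05-01T00:00:00Z"),
             p)
  expect_error(read_metadata(p), "herd_type")
})

make_meta <- function() {
  data.frame(collar_id = "C01", animal_id = "A01", herd_id = "H01",
             herd_type = "resident",
             start = as.POSIXct("2022-04-01", tz = "UTC"),
             end = as.POSIXct("2022-06-01", tz = "UTC"))
}

test_that("segmentation cuts at irregular gaps and drops short runs", {
  # 10 regular fixes with a 90-min gap after fix 4: two segments (4, 6)
  t0 <- as.POSIXct("2022-04-01 06:00:00", tz = "UTC")
  times <- t0 + c(0:3 * 1800, 3 * 1800 + 5400 + 0:5 * 1800)
  gps <- data.frame(collar_id = "C01", timestamp = times,
                    lat = 14.5, lon = -16.5, dop = 1, temperature_c = 30)
  res <- assign_and_segment(gps, make_meta(), min_len = 3)
  expect_equal(as.integer(table(res$segments$segment_id)[
    unique(res$segments$segment_id)]), c(4L, 6L))
  expect_equal(res$report$n_usable, 10L)
  # with min_len 5 the 4-run is removed and counted
  res5 <- assign_and_segment(gps, make_meta(), min_len = 5)
  expect_equal(res5$report$rules$short_segment, 4L)
  expect_equal(res5$report$n_usable, 6L)
})

test_that("filter accounting conserves fixes and is idempotent", {
  t0 <- as.POSIXct("2022-04-01 06:00:00", tz = "UTC")
  gps <- data.frame(collar_id = "C01", timestamp = t0 + 0:39 * 1800,
                    lat = 14.5, lon = -16.5, dop = 1, temperature_c = 30)
  gps$lat[5] <- NA                                   # incomplete
  gps$timestamp[30] <- gps$timestamp[30] + 600       # irregular
  gps2 <- gps
  gps2$collar_id[40] <- "C99"                        # unassigned
  res <- assign_and_segment(gps2, make_meta(), min_len = 3)
  rep <- res$report
  expect_equal(rep$n_collected,
               rep$n_usable + sum(unlist(rep$rules)))
  expect_equal(rep$pct_removed,
               100 * (rep$n_collected - rep$n_usable) / rep$n_collected)
  # perfectly regular stream: one segment, nothing removed
  clean <- assign_and_segment(gps[1:4 * 0 + 1:4, ][1:4, ], make_meta(),
                              min_len = 3)
  expect_equal(clean$report$pct_removed, 0)
  # idempotence: re-running on the cleaned output changes nothing
  seg <- res$segments
  again <- assign_and_segment(
    seg[c("collar_id", "timestamp", "lat", "lon", "dop", "temperature_c")],
    make_meta(), min_len = 3)
  expect_equal(again$segments$timestamp, seg$timestamp)
  expect_equal(again$report$pct_removed, 0)
  # every output fix belongs to exactly one segment and one animal
  expect_false(any(is.na(seg$segment_id)))
  expect_equal(length(unique(seg$animal_id)), 1L)
})

test_that("empty gps/metadata intersection returns an empty result", {
  t0 <- as.POSIXct("2023-01-01", tz = "UTC")
  gps <- data.frame(collar_id = "CXX", timestamp = t0 + 0:9 * 1800,
                    lat = 14.5, lon = -16.5, dop = 1, temperature_c = 30)
  res <- assign_and_segment(gps, make_meta())
  expect_equal(nrow(res$segments), 0)
  expect_equal(res$report$rules$unassigned, 10L)
})

test_that("season follows the calendar and diel follows the sun", {
  centre <- c(-16.5, 14.5)
  jan <- as.POSIXct("2023-01-15 12:00:00", tz = "UTC")
  apr <- as.POSIXct("2023-04-15 12:00:00", tz = "UTC")
  aug <- as.POSIXct("2023-08-15 12:00:00", tz = "UTC")
  lab <- label_time(c(jan, apr, aug), centre)
  expect_equal(as.character(lab$season), c("cold_dry", "warm_dry", "rainy"))
  # local solar noon is day; local solar midnight is night
  noonish <- as.POSIXct("2023-03-21 13:06:00", tz = "UTC") # ~solar noon
  expect_equal(as.character(label_time(noonish, centre)$diel), "day")
  expect_equal(as.character(label_time(noonish + 12 * 3600, centre)$diel),
               "night")
  expect_error(label_time(jan, c(0, 70)), "60")
})

test_that("equinox sunrise at 14.5 N is 06:00 apparent solar +- 6 min", {
  eq <- as.POSIXct("2023-03-20 12:00:00", tz = "UTC")
  st <- sun_times_apparent(eq, 14.5)
  expect_lt(abs(st$sunrise - 6), 0.1)       # 6 minutes = 0.1 h
  expect_lt(abs(st$sunset - 18), 0.1)
})
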