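test_that("CSV reader validates rows and reports drops", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- "mmsi,imo,name,timestamp_utc,lat,lon,course_deg,status,speed_kn,origin_port"
  writeLines(hdr, path)
  out <- read_ais_csv(path)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "dropped"), 0)

  writeLines(c(hdr,
    "1,9,A,2018-01-01T00:00:00Z,-54.0,-36.0,0,moored,0.1,",
    "1,9,A,2018-01-01T01:00:00Z,91,-36.0,0,moored,0.1,",      # lat out of range
    "1,9,A,not-a-time,-54.0,-36.0,0,moored,0.1,",             # bad timestamp
    "1,9,A,2018-01-01T03:00:00Z,-54.0,-36.0,0,moored,-2,"),   # negative speed
    path)
  out <- suppressMessages(read_ais_csv(path))
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "dropped"), 3)

  writeLines("mmsi,imo,name,lat,lon,course_deg,status,speed_kn,origin_port", path)
  expect_error(read_ais_csv(path), "timestamp_utc")
})

test_that("haversine matches an independent great-circle oracle", {
  expect_equal(haversine_m(-54, -36, -54, -36), 0)
  expect_equal(haversine_m(0, 0, 0, 180), pi * 6371000, tolerance = 1 / (pi * 6371000))
  expect_equal(
    haversine_m(-54, -36, -54, -35),
    slc_distance_m(-54, -36, -54, -35),
    tolerance = 0.1 / haversine_m(-54, -36, -54, -35))
  # symmetry + oracle agreement on 1,000 random pairs
  set.seed(2024)
  lat1 <- runif(1000, -89, 89); lon1 <- runif(1000, -180, 180)
  lat2 <- runif(1000, -89, 89); lon2 <- runif(1000, -180, 180)
  h <- haversine_m(lat1, lon1, lat2, lon2)
  expect_true(all(h >= 0))
  expect_equal(h, haversine_m(lat2, lon2, lat1, lon1))
  expect_lt(max(abs(h - slc_distance_m(lat1, lon1, lat2, lon2))), 0.1)
})

test_that("hourly resampling keeps the last report per hour and is idempotent", {
  t0 <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")
  rec <- tibble::tibble(
    mmsi = 1L, imo = NA_integer_, name = "t",
    timestamp = t0 + c(0, 600, 1200, 3000, 3600, 7200),
    lat = c(-54, -54, -54, -54.01, -54.01, -54.01),
    lon = -36, course = 0, status = "x",
    speed_kn = c(5, 5, 5, 5, 0.5, 0.5), origin_port = NA_character_)
  tp <- resample_hourly(rec)
  expect_equal(nrow(tp), 3)  # 4 reports in hour 0 collapse to 1
  expect_equal(tp$lat[1], -54.01)  # last report of the first hour retained
  expect_true(is.na(tp$displacement_m[1]))
  expect_equal(tp$displacement_m[3], 0)
  expect_equal(tp$dt_h, c(NA, 1, 1))

  again <- resample_hourly(tp |> dplyr::mutate(speed_kn = reported_speed,
                                               imo = NA, name = "t",
                                               course = 0, status = "x",
                                               origin_port = NA))
  expect_equal(again$timestamp, tp$timestamp)
  expect_equal(again$displacement_m, tp$displacement_m)

  one <- resample_hourly(rec[1, ])
  expect_equal(nrow(one), 1)
  expect_true(is.na(one$displacement_m))
})

test_that("displacements along a generated transit match the leg geometry", {
  sim <- small_sim()
  tr <- sim$truth$transits
  tr <- tr[tr$hours >= 3, ][1, ]
  rec <- sim$records[sim$records$mmsi == tr$mmsi &
                       sim$records$timestamp >= tr$start &
                       sim$records$timestamp <= tr$end, ]
  tp <- resample_hourly(rec)
  p <- small_cfg()$geography$ports
  leg <- haversine_m(p$lat[p$name == tr$from_port], p$lon[p$name == tr$from_port],
                     p$lat[p$name == tr$to_port], p$lon[p$name == tr$to_port])
  per_hour <- tp$displacement_m[-1]
  expect_true(all(abs(per_hour - leg / tr$hours) / (leg / tr$hours) < 0.01))
})

test_that("zone filtering keeps full tracks of vessels that ever enter", {
  study <- study_area(maritime_zone = synthetic_geography()$maritime_zone)
  t0 <- as.POSIXct("2018-01-01", tz = "UTC")
  mk <- function(mmsi, lat, lon) tibble::tibble(
    mmsi = mmsi, timestamp = t0 + seq_along(lat) * 3600, lat = lat, lon = lon,
    reported_speed = 5, displacement_m = NA, dt_h = NA)
  inside <- mk(1L, c(-54.3, -50.0), c(-36.5, -50.0))  # one point in zone
  outside <- mk(2L, c(-40, -41), c(-50, -51))          # never enters
  out <- filter_zone_vessels(dplyr::bind_rows(inside, outside), study)
  expect_equal(attr(out, "retained_mmsi"), 1L)
  expect_equal(nrow(out), 2)  # both points kept, incl. the one outside

  empty <- filter_zone_vessels(mk(1L, numeric(0), numeric(0)), study)
  expect_equal(nrow(empty), 0)

  # monotonicity: a larger zone never drops a retained vessel
  big <- study_area(maritime_zone = synthetic_geography(zone_radius_nm = 400)$maritime_zone)
  out_big <- filter_zone_vessels(dplyr::bind_rows(inside, outside), big)
  expect_true(all(attr(out, "retained_mmsi") %in% attr(out_big, "retained_mmsi")))
})

test_that("stationarity requires both the displacement and the speed condition", {
  t0 <- as.POSIXct("2018-01-01", tz = "UTC")
  tp <- tibble::tibble(
    mmsi = 1L, timestamp = t0 + (0:3) * 3600,
    lat = -54, lon = -36, reported_speed = c(0.1, 0.1, 0.1, 1.5),
    displacement_m = c(NA, 300, 400, 200), dt_h = c(NA, 1, 1, 1))
  out <- classify_stationary(tp)
  expect_equal(out$stationary, c(TRUE,   # first point: speed test alone
                                 TRUE,   # 300 m & 0.1 kn
                                 FALSE,  # 400 m not < 400 m (strict)
                                 FALSE)) # 200 m but 1.5 kn
})

test_that("across multi-hour gaps the speed condition alone decides, flagged gap", {
  t0 <- as.POSIXct("2018-01-01", tz = "UTC")
  tp <- tibble::tibble(
    mmsi = 1L, timestamp = t0 + c(0, 1, 7) * 3600,
    lat = -54, lon = -36, reported_speed = c(0.1, 0.1, 0.1),
    displacement_m = c(NA, 100, 5000), dt_h = c(NA, 1, 6))
  out <- classify_stationary(tp)
  expect_equal(out$gap, c(FALSE, FALSE, TRUE))
  expect_true(out$stationary[3])  # 5 km over 6 h, but speed < 1 kn
})

test_that("stationarity classification recovers the generator's stop spans exactly", {
  sim <- small_sim()
  res <- small_result()
  tp <- res$trackpoints
  truth <- sim$truth$stops
  # every point inside a true stop span is stationary; every other point is not
  in_stop <- rep(FALSE, nrow(tp))
  for (i in seq_len(nrow(truth))) {
    in_stop <- in_stop | (tp$mmsi == truth$mmsi[i] &
                            tp$timestamp >= truth$start[i] &
                            tp$timestamp <= truth$end[i])
  }
  expect_equal(tp$stationary, in_stop)
})

test_that("the 400 m per hour threshold is ~0.2 knots", {
  expect_equal(stationary_speed_equivalent_kn(400, 1), 400 / 1852)
  expect_equal(round(stationary_speed_equivalent_kn(), 1), 0.2)
})
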