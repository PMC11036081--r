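AIS_COLUMNS <- c("mmsi", "imo", "name", "timestamp_utc", "lat", "lon",
                 "course_deg", "status", "speed_kn", "origin_port")

#' Read an AIS position-record CSV
#'
#' Parses, validates and sorts AIS position reports. Rows with an
#' unparseable timestamp, out-of-range coordinates or negative speed are
#' dropped (the count is reported via a message and the `dropped`
#' attribute). Longitudes are normalised to (-180, 180].
#'
#' @param path CSV file with columns mmsi, imo, name, timestamp_utc
#'   (ISO 8601), lat, lon, course_deg, status, speed_kn, origin_port.
#' @return Tibble of records sorted by (mmsi, timestamp), with attribute
#'   `dropped` = number of malformed rows removed.
#' @export
read_ais_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               col_types = readr::cols(.default = "c")))
  missing_cols <- setdiff(AIS_COLUMNS, hdr)
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  raw <- readr::read_csv(path, col_types = readr::cols(
    mmsi = readr::col_integer(), imo = readr::col_integer(),
    name = readr::col_character(), timestamp_utc = readr::col_character(),
    lat = readr::col_double(), lon = readr::col_double(),
    course_deg = readr::col_double(), status = readr::col_character(),
    speed_kn = readr::col_double(), origin_port = readr::col_character()
  ), progress = FALSE)
  ts <- lubridate::ymd_hms(raw$timestamp_utc, tz = "UTC", quiet = TRUE)
  ok <- !is.na(raw$mmsi) & !is.na(ts) &
    !is.na(raw$lat) & raw$lat >= -90 & raw$lat <= 90 &
    !is.na(raw$lon) & raw$lon >= -360 & raw$lon <= 360 &
    !is.na(raw$speed_kn) & raw$speed_kn >= 0
  dropped <- sum(!ok)
  if (dropped > 0) message(dropped, " malformed AIS row(s) dropped")
  out <- raw[ok, ] |>
    dplyr::transmute(
      mmsi = .data$mmsi, imo = .data$imo, name = .data$name,
      timestamp = ts[ok],
      lat = .data$lat, lon = normalise_lon(.data$lon),
      course = .data$course_deg, status = .data$status,
      speed_kn = .data$speed_kn, origin_port = .data$origin_port) |>
    dplyr::arrange(.data$mmsi, .data$timestamp)
  attr(out, "dropped") <- dropped
  out
}

#' Resample AIS records to hourly track points
#'
#' Keeps at most one report per vessel per clock hour (the last report in
#' each hour bin, i.e. the position closest to the following displacement
#' interval), stamped to the bin hour so retained points are at least one
#' hour apart, and computes sequential point-to-point great-circle
#' displacements per vessel. Gaps longer than one hour are preserved as-is
#' (no interpolation); the hour gap to the previous retained point is
#' recorded in `dt_h`. Idempotent: resampling a resampled track is a no-op.
#'
#' @param records AIS record tibble (one or many vessels), time-sorted or
#'   not; must have mmsi, timestamp, lat, lon, speed_kn.
#' @return Tibble of track points: mmsi, timestamp, lat, lon,
#'   reported_speed, displacement_m (NA for each vessel's first point),
#'   dt_h (hours since previous retained point, NA for first).
#' @export
resample_hourly <- function(records) {
  if (!nrow(records)) {
    return(tibble(mmsi = integer(), timestamp = as.POSIXct(character(), tz = "UTC"),
                  lat = double(), lon = double(), reported_speed = double(),
                  displacement_m = double(), dt_h = double()))
  }
  records |>
    dplyr::arrange(.data$mmsi, .data$timestamp) |>
    dplyr::mutate(.hour = lubridate::floor_date(.data$timestamp, "hour")) |>
    dplyr::group_by(.data$mmsi, .data$.hour) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(timestamp = .data$.hour) |>
    dplyr::group_by(.data$mmsi) |>
    dplyr::mutate(
      displacement_m = haversine_m(dplyr::lag(.data$lat), dplyr::lag(.data$lon),
                                   .data$lat, .data$lon),
      dt_h = as.numeric(difftime(.data$timestamp, dplyr::lag(.data$timestamp),
                                 units = "hours"))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("mmsi", "timestamp", "lat", "lon",
                  reported_speed = "speed_kn", "displacement_m", "dt_h")
}

#' Keep only vessels that entered the maritime zone
#'
#' A vessel is retained if and only if at least one of its track points
#' falls inside the maritime-zone polygon; retained vessels keep their
#' whole track, including points outside the zone.
#'
#' @param trackpoints Track-point tibble (any per-vessel stage).
#' @param study A [study_area()] whose `maritime_zone` is set.
#' @return The track points of retained vessels; attribute
#'   `retained_mmsi` holds the vessel set.
#' @export
filter_zone_vessels <- function(trackpoints, study) {
  zone <- study$maritime_zone
  if (is.null(zone)) stop("study_area has no maritime_zone polygon")
  if (!nrow(trackpoints)) {
    out <- trackpoints
    attr(out, "retained_mmsi") <- integer(0)
    return(out)
  }
  inside <- point_in_polygon(trackpoints$lat, trackpoints$lon, zone)
  keep <- unique(trackpoints$mmsi[inside])
  out <- trackpoints |> dplyr::filter(.data$mmsi %in% keep)
  attr(out, "retained_mmsi") <- keep
  out
}

#' Classify track points as stationary or underway
#'
#' A point is stationary when it moved less than
#' `stationary_move_max_m` (default 400 m) over the preceding one-hour
#' interval AND its reported speed is below `stationary_speed_max_kn`
#' (default 1 kn); both conditions are required so that an error in either
#' the position or the speed attribute alone cannot misclassify a point.
#' Each vessel's first point, which has no displacement, is classified on
#' the speed condition alone. Across a reporting gap longer than one hour
#' the displacement is not comparable to the hourly threshold, so the
#' speed condition alone is used and the point is flagged `gap`.
#'
#' @param trackpoints Hourly track points from [resample_hourly()].
#' @param study A [study_area()] supplying the thresholds.
#' @return Input with logical columns `stationary` and `gap` added.
#' @export
classify_stationary <- function(trackpoints, study = study_area()) {
  if (!nrow(trackpoints)) {
    return(dplyr::mutate(trackpoints, stationary = logical(0), gap = logical(0)))
  }
  trackpoints |>
    dplyr::mutate(
      gap = !is.na(.data$dt_h) & .data$dt_h > 1,
      .speed_ok = .data$reported_speed < study$stationary_speed_max_kn,
      stationary = dplyr::case_when(
        is.na(.data$displacement_m) ~ .data$.speed_ok,   # first point of track
        gap ~ .data$.speed_ok,                           # unresolvable interval
        TRUE ~ .data$.speed_ok &
          .data$displacement_m < study$stationary_move_max_m
      )
    ) |>
    dplyr::select(-".speed_ok")
}

#' Share of zone-entering vessels that stopped inshore
#'
#' Worked-proportion helper for headline reporting: the percentage of
#' vessels that entered the maritime zone and went on to stop within the
#' coastal band.
#'
#' @param n_stopped Vessels with at least one coastal stop event.
#' @param n_total Vessels that entered the maritime zone.
#' @return Percentage (0-100).
#' @examples
#' coastal_stop_share(123, 143) # 86%
#' @export
coastal_stop_share <- function(n_stopped, n_total) {
  stopifnot(n_total > 0, n_stopped >= 0, n_stopped <= n_total)
  100 * n_stopped / n_total
}
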