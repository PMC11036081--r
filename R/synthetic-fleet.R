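#' Fleet simulation configuration
#'
#' Defines the statistical structure of a synthetic fleet: nine vessel
#' classes with class-specific abundance, hull-size distributions, journey
#' counts, stops per journey, stop-duration distributions, seasonal
#' activity windows and routing pools over a port catalog. Defaults emulate
#' a passenger/fishing-dominated sub-Antarctic fleet: ~100 vessels active
#' per year, a small number of extended multi-stop journeys per vessel per
#' year separated by >1 month rests in port, short passenger stops, long
#' fishing stops, spring-only tankers/cargo, and tenders tied to a
#' passenger mother ship.
#'
#' @param n_years Number of study years (years run July-June).
#' @param start Study start (UTC); coerced with [lubridate::ymd()].
#' @param vessels_per_class Optional named integer vector overriding the
#'   per-class vessel counts (names must be vessel classes).
#' @param classes Per-class parameter table; see `fleet_class_defaults()`.
#' @param geography A [synthetic_geography()] list.
#' @param rest_min_days,rest_max_days Bounds of the between-journey rest
#'   duration (days); rests always exceed the 30 d journey-segmentation
#'   threshold.
#' @param long_stop_step_h Reporting interval (hours) for position reports
#'   while moored longer than 48 h; shorter stops report hourly.
#' @param jitter_sd_m Gaussian positional noise while at anchor (metres);
#'   0 = noise-free, so pipeline recovery of the truth log is exact.
#' @param dropout Probability that any individual position report is lost.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `fleet_config` list.
#' @export
fleet_config <- function(n_years = 2,
                         start = "2017-07-01",
                         vessels_per_class = NULL,
                         classes = fleet_class_defaults(),
                         geography = synthetic_geography(),
                         rest_min_days = 35,
                         rest_max_days = 90,
                         long_stop_step_h = 6,
                         jitter_sd_m = 0,
                         dropout = 0,
                         seed = 42L) {
  stopifnot(n_years >= 1, rest_min_days > 30, rest_max_days >= rest_min_days,
            jitter_sd_m >= 0, dropout >= 0, dropout < 1)
  if (nrow(geography$ports) == 0) stop("port catalog is empty")
  if (!is.null(vessels_per_class)) {
    bad <- setdiff(names(vessels_per_class), classes$class)
    if (length(bad)) stop("unknown vessel class: ", paste(bad, collapse = ", "))
    idx <- match(names(vessels_per_class), classes$class)
    classes$n_vessels[idx] <- as.integer(vessels_per_class)
  }
  stopifnot(all(classes$n_vessels >= 0))
  structure(list(
    n_years = as.integer(n_years),
    start = lubridate::ymd(start, tz = "UTC"),
    classes = classes,
    geography = geography,
    rest_min_days = rest_min_days,
    rest_max_days = rest_max_days,
    long_stop_step_h = long_stop_step_h,
    jitter_sd_m = jitter_sd_m,
    dropout = dropout,
    seed = as.integer(seed)
  ), class = "fleet_config")
}

#' Default per-class fleet parameters
#'
#' Annual-mean movement parameters per vessel class (abundance, journeys
#' per year, stops per extended journey, mean stop duration) structured
#' like the study region's observed fleet, together with hull-dimension
#' distributions, cruise speeds, activity seasons (months) and routing
#' pools. All values are editable inputs, not fitted constants.
#'
#' @return Tibble with one row per vessel class.
#' @export
fleet_class_defaults <- function() {
  tibble::tribble(
    ~class,      ~n_vessels, ~journeys_per_year, ~stops_per_journey, ~stop_mean_h, ~cruise_kn, ~origin_prob, ~dwt_missing_prob,
    "Bulk",      1L,         2.0,                1.0,                6.5,          12,         0.5,          0,
    "Cargo",     5L,         1.8,                13.6,               45.1,         12,         0.5,          0,
    "Fishing",   20L,        2.3,                11.4,               71.4,         10,         0.4,          0.30,
    "Offshore",  10L,        1.9,                29.4,               19.4,         12,         0.4,          0.25,
    "Passenger", 26L,        2.0,                57.5,               4.0,          15,         0.4,          0.25,
    "Pilot",     2L,         2.5,                2.8,                15.3,         10,         0,            0.30,
    "Pleasure",  11L,        2.3,                20.6,               19.7,         8,          0.5,          0.50,
    "Tanker",    3L,         3.3,                8.6,                24.6,         12,         0.5,          0,
    "Tender",    25L,        2.0,                2.5,                1.4,          15,         0,            1.0
  ) |>
    dplyr::mutate(
      stop_sdlog = 0.6,
      season = list(
        10:12,            # Bulk: spring/early summer
        9:11,             # Cargo: spring only
        c(3:10),          # Fishing: year-round except summer
        c(12, 1:8),       # Offshore: all months except spring
        c(10:12, 1:3),    # Passenger: tourist season
        1:12,             # Pilot: resident
        c(11:12, 1:4),    # Pleasure: summer/autumn
        9:11,             # Tanker: spring only
        c(10:12, 1:3)     # Tender: follows passenger season
      ),
      pool = list(
        c("King Edward Point", "Stanley"),
        c("King Edward Point", "Stromness Bay", "Stanley", "Ushuaia"),
        c("King Edward Point", "Stromness Bay", "Bay of Isles",
          "St Andrews Bay", "Gold Harbour", "Cooper Bay"),
        c("King Edward Point", "Stromness Bay", "St Andrews Bay",
          "Saunders Island", "Port Lockroy", "Ushuaia"),
        c("King Edward Point", "Bay of Isles", "Gold Harbour",
          "St Andrews Bay", "Stromness Bay", "Cooper Bay",
          "Port Lockroy", "Ushuaia"),
        c("King Edward Point", "Stromness Bay", "St Andrews Bay"),
        c("King Edward Point", "Bay of Isles", "Gold Harbour",
          "Cooper Bay", "Ushuaia", "Punta Arenas"),
        c("King Edward Point", "Stanley", "Ushuaia"),
        character(0)      # Tender: derived from mother-ship itinerary
      ),
      home_port = c("Stanley", "Stanley", "Stanley", "Stanley", "Ushuaia",
                    "King Edward Point", "Stanley", "Stanley",
                    "King Edward Point"),
      # L_OA m, B_OA m, V (GT), DWT t, T (draft) m medians per class
      dims = list(
        c(180, 30, 35000, 60000, 12),
        c(120, 20, 9000, 12000, 8),
        c(55, 12, 1500, 1200, 6),
        c(75, 16, 3500, 2500, 6.5),
        c(150, 22, 30000, 5000, 7),
        c(20, 6, 90, 40, 2.5),
        c(30, 7, 150, 80, 3),
        c(140, 22, 12000, 18000, 9),
        c(5, 2, 2, 1, 0.8)
      )
    )
}

VESSEL_CLASSES <- c("Bulk", "Cargo", "Fishing", "Offshore", "Passenger",
                    "Pilot", "Pleasure", "Tanker", "Tender")

#' Study-year windows
#' @param config A [fleet_config()] (or any list with `start`, `n_years`).
#' @return Tibble with columns year, start, end (half-open windows).
#' @export
study_years <- function(config) {
  tibble(
    year = seq_len(config$n_years),
    start = config$start + lubridate::years(seq_len(config$n_years) - 1),
    end = config$start + lubridate::years(seq_len(config$n_years))
  )
}

year_of <- function(ts, config) {
  yrs <- study_years(config)
  idx <- findInterval(as.numeric(ts), as.numeric(yrs$start))
  idx[idx < 1 | ts >= yrs$end[config$n_years]] <- NA_integer_
  idx
}

# rounds x to an adjacent integer with expectation exactly x
stoch_round <- function(x) {
  floor(x) + stats::rbinom(length(x), 1L, x - floor(x))
}

resample1 <- function(x) x[sample.int(length(x), 1L)]

# route of m ports from `pool`, no adjacent repeats, never starting/ending at
# `home`, guaranteed to include at least one port in `require_country`
sample_route <- function(m, pool, ports, home, require_country = "SG") {
  route <- character(m)
  prev <- home
  for (i in seq_len(m)) {
    cand <- setdiff(pool, prev)
    if (i == m) cand <- setdiff(cand, home)
    if (!length(cand)) cand <- setdiff(pool, prev) # relax end rule if cornered
    route[i] <- resample1(cand)
    prev <- route[i]
  }
  cc <- ports$country[match(route, ports$name)]
  if (!any(cc == require_country)) {
    i0 <- sample.int(m, 1L)
    nb <- c(if (i0 > 1) route[i0 - 1], if (i0 < m) route[i0 + 1],
            if (i0 == 1 || i0 == m) home)
    cand <- setdiff(ports$name[ports$country == require_country], nb)
    if (length(cand)) route[i0] <- resample1(cand)
  }
  route
}

transit_hours <- function(dist_m, cruise_kn) {
  pmax(1, ceiling(dist_m / (cruise_kn * NM_M)))
}

draw_stop_h <- function(n, mean_h, sdlog, max_h = 672) {
  meanlog <- log(mean_h) - sdlog^2 / 2
  pmin(max_h, pmax(1, round(stats::rlnorm(n, meanlog, sdlog))))
}

HOUR <- 3600

# Schedules one (non-tender) vessel over all study years. Returns stops,
# transits and journeys tibbles with POSIXct times on the hour grid.
schedule_vessel <- function(mmsi, cls, config) {
  geo <- config$geography
  ports <- geo$ports
  yrs <- study_years(config)
  pcoord <- function(p) unname(unlist(ports[match(p, ports$name), c("lat", "lon")]))
  home <- cls$home_port
  rest_min_h <- config$rest_min_days * 24
  rest_max_h <- config$rest_max_days * 24

  stops <- list(); transits <- list(); journeys <- list()
  cursor <- NULL    # end time of last emitted event
  here <- NULL      # current port
  jid <- 0L
  add_transit <- function(from, to, e_prev) {
    d <- haversine_m(pcoord(from)[1], pcoord(from)[2],
                     pcoord(to)[1], pcoord(to)[2])
    tt <- transit_hours(d, cls$cruise_kn)
    transits[[length(transits) + 1L]] <<- tibble(
      mmsi = mmsi, from_port = from, to_port = to,
      start = e_prev + HOUR, end = e_prev + tt * HOUR, hours = tt
    )
    e_prev + (tt + 1) * HOUR  # start of the next stop
  }
  add_stop <- function(port, s, dur_h, kind) {
    stops[[length(stops) + 1L]] <<- tibble(
      mmsi = mmsi, port = port,
      lat = pcoord(port)[1], lon = pcoord(port)[2],
      start = s, end = s + dur_h * HOUR, duration_h = dur_h,
      kind = kind, journey_id = jid
    )
    s + dur_h * HOUR
  }

  for (y in seq_len(config$n_years)) {
    k <- max(1L, stoch_round(cls$journeys_per_year))
    season_days <- seq(yrs$start[y], yrs$end[y] - 86400, by = "day")
    season_days <- season_days[lubridate::month(season_days) %in% cls$season[[1]]]
    if (!length(season_days)) season_days <- seq(yrs$start[y], yrs$end[y] - 86400, by = "day")
    desired <- sort(season_days[sample.int(length(season_days), k, replace = TRUE)]) +
      sample(0:23, k, replace = TRUE) * HOUR
    for (j in seq_len(k)) {
      jid <- jid + 1L
      m <- max(1L, stoch_round(cls$stops_per_journey))
      route <- sample_route(m, cls$pool[[1]], ports, home)
      durs <- draw_stop_h(m, cls$stop_mean_h, cls$stop_sdlog)
      if (is.null(cursor)) {
        s <- lubridate::floor_date(desired[j], "hour")
      } else {
        # rest at home, then transit out to the first stop of this journey
        rest_start <- add_transit(here, home, cursor)
        t_out <- transit_hours(
          haversine_m(pcoord(home)[1], pcoord(home)[2],
                      pcoord(route[1])[1], pcoord(route[1])[2]), cls$cruise_kn)
        gap_h <- floor(as.numeric(difftime(desired[j], rest_start, units = "hours"))) -
          t_out - 1
        rest_h <- max(rest_min_h, min(gap_h, 1e5))
        if (gap_h < rest_min_h)
          rest_h <- round(stats::runif(1, rest_min_h, rest_max_h))
        cursor <- add_stop(home, rest_start, rest_h, "rest")
        here <- home
        s <- add_transit(here, route[1], cursor)
      }
      for (i in seq_len(m)) {
        if (i > 1) s <- add_transit(route[i - 1], route[i], cursor)
        cursor <- add_stop(route[i], s, durs[i], "stop")
        here <- route[i]
      }
      journeys[[length(journeys) + 1L]] <- tibble(
        mmsi = mmsi, journey_id = jid,
        year = year_of(stops[[length(stops) - m + 1L]]$start, config),
        n_stops = m, ports = list(route)
      )
    }
  }
  # trailing rest so the final journey is bounded like the others
  rest_start <- add_transit(here, home, cursor)
  add_stop(home, rest_start, round(stats::runif(1, rest_min_h, 60 * 24)), "rest")
  list(stops = dplyr::bind_rows(stops), transits = dplyr::bind_rows(transits),
       journeys = dplyr::bind_rows(journeys))
}

# Tender itinerary: shadows a mother ship, going ashore during a subset of
# the mother's longer stops; rests (stowed) at the tender home port between
# adopted journeys.
schedule_tender <- function(mmsi, cls, mother_stops, mother_journeys, config) {
  geo <- config$geography
  ports <- geo$ports
  pcoord <- function(p) unname(unlist(ports[match(p, ports$name), c("lat", "lon")]))
  home <- cls$home_port
  rest_min_h <- 31 * 24

  jids <- unique(mother_journeys$journey_id)
  k <- min(length(jids), max(1L, stoch_round(cls$journeys_per_year)))
  take <- sort(sample(jids, k))
  stops <- list(); transits <- list(); journeys <- list()
  cursor <- NULL; here <- NULL; jid <- 0L
  for (mj in take) {
    elig <- mother_stops[mother_stops$journey_id == mj &
                           mother_stops$kind == "stop" &
                           mother_stops$duration_h >= 4, , drop = FALSE]
    if (!nrow(elig)) next
    m <- min(nrow(elig), max(1L, stoch_round(cls$stops_per_journey)))
    pick <- sort(sample.int(nrow(elig), m))
    elig <- elig[pick, ]
    # no adjacent repeats; first stop after a rest must differ from home
    keep <- rep(TRUE, nrow(elig))
    prev <- home
    for (i in seq_len(nrow(elig))) {
      if (elig$port[i] == prev) keep[i] <- FALSE else prev <- elig$port[i]
    }
    elig <- elig[keep, , drop = FALSE]
    if (!nrow(elig)) next
    jid <- jid + 1L
    first <- TRUE
    for (i in seq_len(nrow(elig))) {
      s <- elig$start[i] + HOUR
      dur <- min(elig$duration_h[i] - 2, max(1, round(stats::rlnorm(1, log(1.4), 0.4))))
      if (dur < 1) next
      if (!is.null(cursor)) {
        if (first) {
          # rest stowed at home; must exceed the segmentation threshold
          d_home <- haversine_m(pcoord(here)[1], pcoord(here)[2],
                                pcoord(home)[1], pcoord(home)[2])
          t_in <- transit_hours(d_home, cls$cruise_kn)
          d_out <- haversine_m(pcoord(home)[1], pcoord(home)[2],
                               pcoord(elig$port[i])[1], pcoord(elig$port[i])[2])
          t_out <- transit_hours(d_out, cls$cruise_kn)
          rest_start <- cursor + (t_in + 1) * HOUR
          rest_h <- floor(as.numeric(difftime(s, rest_start, units = "hours"))) -
            t_out - 1
          if (rest_h < rest_min_h) { jid <- jid - 1L; break }
          transits[[length(transits) + 1L]] <- tibble(
            mmsi = mmsi, from_port = here, to_port = home,
            start = cursor + HOUR, end = cursor + t_in * HOUR, hours = t_in)
          stops[[length(stops) + 1L]] <- tibble(
            mmsi = mmsi, port = home, lat = pcoord(home)[1], lon = pcoord(home)[2],
            start = rest_start, end = rest_start + rest_h * HOUR,
            duration_h = rest_h, kind = "rest", journey_id = jid - 1L)
          cursor <- rest_start + rest_h * HOUR
          here <- home
        }
        d <- haversine_m(pcoord(here)[1], pcoord(here)[2],
                         pcoord(elig$port[i])[1], pcoord(elig$port[i])[2])
        tt <- transit_hours(d, cls$cruise_kn)
        if (cursor + (tt + 1) * HOUR > s) next  # cannot make this call in time
        # idle alongside until the scheduled departure keeps times exact
        transits[[length(transits) + 1L]] <- tibble(
          mmsi = mmsi, from_port = here, to_port = elig$port[i],
          start = s - tt * HOUR, end = s - HOUR, hours = tt)
      }
      stops[[length(stops) + 1L]] <- tibble(
        mmsi = mmsi, port = elig$port[i],
        lat = pcoord(elig$port[i])[1], lon = pcoord(elig$port[i])[2],
        start = s, end = s + dur * HOUR, duration_h = dur,
        kind = "stop", journey_id = jid)
      cursor <- s + dur * HOUR
      here <- elig$port[i]
      first <- FALSE
    }
    if (!first) {
      jj <- stops[[length(stops)]]
      journeys[[length(journeys) + 1L]] <- tibble(
        mmsi = mmsi, journey_id = jid,
        year = year_of(stops[[which.max(vapply(stops, function(x) x$journey_id[1] == jid, TRUE))]]$start, config),
        n_stops = sum(vapply(stops, function(x) x$journey_id[1] == jid && x$kind[1] == "stop", TRUE)),
        ports = list(vapply(stops[vapply(stops, function(x) x$journey_id[1] == jid && x$kind[1] == "stop", TRUE)],
                            function(x) x$port[1], "")))
    }
  }
  if (is.null(cursor)) return(NULL)
  # trailing stowed rest at home
  d_home <- haversine_m(pcoord(here)[1], pcoord(here)[2],
                        pcoord(home)[1], pcoord(home)[2])
  t_in <- transit_hours(d_home, cls$cruise_kn)
  transits[[length(transits) + 1L]] <- tibble(
    mmsi = mmsi, from_port = here, to_port = home,
    start = cursor + HOUR, end = cursor + t_in * HOUR, hours = t_in)
  rest_start <- cursor + (t_in + 1) * HOUR
  rest_h <- round(stats::runif(1, config$rest_min_days * 24, 60 * 24))
  stops[[length(stops) + 1L]] <- tibble(
    mmsi = mmsi, port = home, lat = pcoord(home)[1], lon = pcoord(home)[2],
    start = rest_start, end = rest_start + rest_h * HOUR,
    duration_h = rest_h, kind = "rest", journey_id = jid)
  list(stops = dplyr::bind_rows(stops), transits = dplyr::bind_rows(transits),
       journeys = dplyr::bind_rows(journeys))
}

draw_dims <- function(cls) {
  d <- cls$dims[[1]]
  if (cls$class == "Pleasure") {
    scale <- if (stats::runif(1) < 0.5) 0.55 else 1.2  # bimodal: small yachts vs large
    d <- d * c(scale, scale, scale^2, scale^2, scale)
  }
  v <- stats::rlnorm(5, log(d), 0.12)
  names(v) <- c("L_OA", "B_OA", "V", "DWT", "T")
  v
}

#' Generate a synthetic fleet with a ground-truth event log
#'
#' Draws vessel profiles and a full itinerary (stops, rests, transits,
#' journeys) for every vessel under the configured class parameters. The
#' returned truth log is the reference against which pipeline recovery is
#' tested. Deterministic under a fixed `config$seed`.
#'
#' @param config A [fleet_config()].
#' @return List with `profiles` (tibble: mmsi, imo, name, vessel_type,
#'   dimensions, declared_origin, cruise_kn, mother_mmsi) and `truth`
#'   (list of `stops`, `transits`, `journeys` tibbles).
#' @export
generate_fleet <- function(config) {
  stopifnot(inherits(config, "fleet_config"))
  if (nrow(config$geography$ports) == 0) stop("port catalog is empty")
  withr::with_seed(config$seed, {
    classes <- config$classes
    ext_ports <- config$geography$world_ports |>
      dplyr::filter(!.data$name %in% config$geography$ports$name)
    profiles <- list(); stops <- list(); transits <- list(); journeys <- list()
    idx <- 0L
    mothers <- list()  # candidate mother ships for tenders
    for (ci in seq_len(nrow(classes))) {
      cls <- classes[ci, ]
      if (cls$class == "Tender") next
      for (v in seq_len(cls$n_vessels)) {
        idx <- idx + 1L
        mmsi <- 200000000L + idx
        dims <- draw_dims(cls)
        if (stats::runif(1) < cls$dwt_missing_prob) dims["DWT"] <- NA
        origin <- if (stats::runif(1) < cls$origin_prob)
          resample1(ext_ports$name) else NA_character_
        profiles[[idx]] <- tibble(
          mmsi = mmsi, imo = 9000000L + idx,
          name = paste0(cls$class, " ", v),
          vessel_type = cls$class,
          L_OA = dims["L_OA"], B_OA = dims["B_OA"], V = dims["V"],
          DWT = dims["DWT"], T = dims["T"],
          declared_origin = origin, cruise_kn = cls$cruise_kn,
          mother_mmsi = NA_integer_
        )
        sched <- schedule_vessel(mmsi, cls, config)
        stops[[idx]] <- sched$stops
        transits[[idx]] <- sched$transits
        journeys[[idx]] <- sched$journeys
        if (cls$class %in% c("Passenger", "Fishing"))
          mothers[[length(mothers) + 1L]] <- list(mmsi = mmsi, sched = sched)
      }
    }
    tcls <- classes[classes$class == "Tender", ]
    if (nrow(tcls) == 1 && tcls$n_vessels > 0 && length(mothers) > 0) {
      for (v in seq_len(tcls$n_vessels)) {
        mother <- mothers[[resample1(seq_along(mothers))]]
        sched <- schedule_tender(200000000L + idx + 1L, tcls,
                                 mother$sched$stops, mother$sched$journeys, config)
        if (is.null(sched) || !nrow(sched$stops)) next
        idx <- idx + 1L
        mmsi <- 200000000L + idx
        dims <- draw_dims(tcls)
        dims["DWT"] <- NA
        profiles[[idx]] <- tibble(
          mmsi = mmsi, imo = NA_integer_, name = paste0("Tender ", v),
          vessel_type = "Tender",
          L_OA = dims["L_OA"], B_OA = dims["B_OA"], V = dims["V"],
          DWT = dims["DWT"], T = dims["T"],
          declared_origin = NA_character_, cruise_kn = tcls$cruise_kn,
          mother_mmsi = mother$mmsi
        )
        stops[[idx]] <- sched$stops
        transits[[idx]] <- sched$transits
        journeys[[idx]] <- sched$journeys
      }
    }
    empty_stops <- tibble(
      mmsi = integer(), port = character(), lat = double(), lon = double(),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC"),
      duration_h = double(), kind = character(), journey_id = integer())
    empty_transits <- tibble(
      mmsi = integer(), from_port = character(), to_port = character(),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC"), hours = double())
    empty_journeys <- tibble(mmsi = integer(), journey_id = integer(),
                             year = integer(), n_stops = integer(),
                             ports = list())
    truth <- list(
      stops = dplyr::bind_rows(empty_stops, stops) |>
        dplyr::arrange(.data$mmsi, .data$start),
      transits = dplyr::bind_rows(empty_transits, transits) |>
        dplyr::arrange(.data$mmsi, .data$start),
      journeys = dplyr::bind_rows(empty_journeys, journeys)
    )
    if (nrow(truth$stops)) truth$stops$year <- year_of(truth$stops$start, config)
    list(profiles = dplyr::bind_rows(profiles), truth = truth)
  })
}

#' Emit AIS position records for a simulated fleet
#'
#' Converts the truth itinerary into a time-sorted stream of position
#' reports: hourly reports while moored (thinned to
#' `config$long_stop_step_h` for stops longer than 48 h, emulating reduced
#' reporting at anchor), and hourly great-circle interpolated reports while
#' underway at the class cruise speed. With zero positional jitter,
#' consecutive moored reports are coincident and underway reports always
#' exceed the stationarity thresholds, so stationarity classification
#' recovers the truth log exactly.
#'
#' @param profiles Vessel profile tibble from [generate_fleet()].
#' @param truth Truth log from [generate_fleet()].
#' @param config The [fleet_config()] used to generate the fleet.
#' @param step_h Reporting interval while underway (hours).
#' @return Tibble of AIS records (schema of [read_ais_csv()]).
#' @export
simulate_tracks <- function(profiles, truth, config, step_h = 1) {
  stopifnot(step_h > 0)
  if (is.null(truth$stops) || !nrow(truth$stops)) {
    return(empty_ais_records())
  }
  st <- truth$stops
  steps <- ifelse(st$duration_h > 48, config$long_stop_step_h, step_h)
  s0 <- as.numeric(st$start); e0 <- as.numeric(st$end)
  tlist <- mapply(function(s, e, stp) {
    tt <- seq(s, e, by = stp * HOUR)
    if (tt[length(tt)] != e) tt <- c(tt, e)
    tt
  }, s0, e0, steps, SIMPLIFY = FALSE)
  nrep <- lengths(tlist)
  moored <- tibble(
    mmsi = rep(st$mmsi, nrep),
    timestamp = as.POSIXct(unlist(tlist), tz = "UTC",
                           origin = "1970-01-01"),
    lat = rep(st$lat, nrep), lon = rep(st$lon, nrep),
    speed_kn = 0.1, status = "moored", course = 0
  )

  ports <- config$geography$ports
  tr <- truth$transits
  underway <- NULL
  if (!is.null(tr) && nrow(tr)) {
    fi <- match(tr$from_port, ports$name)
    ti <- match(tr$to_port, ports$name)
    d <- haversine_m(ports$lat[fi], ports$lon[fi], ports$lat[ti], ports$lon[ti])
    i <- rep(seq_len(nrow(tr)), tr$hours)
    k <- sequence(tr$hours)
    f <- k / tr$hours[i]
    pos <- gc_interp(ports$lat[fi][i], ports$lon[fi][i],
                     ports$lat[ti][i], ports$lon[ti][i], f)
    crs <- geosphere::bearing(cbind(pos[, "lon"], pos[, "lat"]),
                              cbind(ports$lon[ti][i], ports$lat[ti][i]))
    crs[is.na(crs)] <- 0
    underway <- tibble(
      mmsi = tr$mmsi[i],
      timestamp = tr$start[i] + (k - 1) * HOUR,
      lat = pos[, "lat"], lon = pos[, "lon"],
      speed_kn = pmax(1.5, (d[i] / NM_M) / tr$hours[i]),
      status = "underway", course = (crs + 360) %% 360
    )
  }
  rec <- dplyr::bind_rows(moored, underway)
  if (config$jitter_sd_m > 0 || config$dropout > 0) {
    rec <- withr::with_seed(config$seed + 1L, {
      if (config$jitter_sd_m > 0) {
        dn <- stats::rnorm(nrow(rec), 0, config$jitter_sd_m)
        de <- stats::rnorm(nrow(rec), 0, config$jitter_sd_m)
        rec$lat <- rec$lat + dn / 111320
        rec$lon <- rec$lon + de / (111320 * cos(rec$lat * pi / 180))
      }
      if (config$dropout > 0) rec <- rec[stats::runif(nrow(rec)) >= config$dropout, ]
      rec
    })
  }
  rec |>
    dplyr::left_join(
      profiles |> dplyr::select("mmsi", "imo", "name", "declared_origin"),
      by = "mmsi") |>
    dplyr::transmute(
      mmsi = .data$mmsi, imo = .data$imo, name = .data$name,
      timestamp = .data$timestamp, lat = .data$lat, lon = .data$lon,
      course = .data$course, status = .data$status, speed_kn = .data$speed_kn,
      origin_port = .data$declared_origin) |>
    dplyr::arrange(.data$mmsi, .data$timestamp)
}

empty_ais_records <- function() {
  tibble(
    mmsi = integer(), imo = integer(), name = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    lat = double(), lon = double(), course = double(),
    status = character(), speed_kn = double(), origin_port = character()
  )
}

#' Simulate a complete fleet
#'
#' Convenience wrapper: [generate_fleet()] then [simulate_tracks()].
#' @inheritParams simulate_tracks
#' @param config A [fleet_config()].
#' @return List with `profiles`, `truth`, `records`.
#' @export
simulate_fleet <- function(config, step_h = 1) {
  fl <- generate_fleet(config)
  records <- simulate_tracks(fl$profiles, fl$truth, config, step_h = step_h)
  c(fl, list(records = records))
}

#' Write AIS records to CSV
#'
#' Column schema: mmsi, imo, name, timestamp_utc (ISO 8601), lat, lon,
#' course_deg, status, speed_kn, origin_port.
#' @param records Record tibble from [simulate_tracks()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ais_csv <- function(records, path) {
  out <- records |>
    dplyr::transmute(
      mmsi = .data$mmsi, imo = .data$imo, name = .data$name,
      timestamp_utc = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      lat = .data$lat, lon = .data$lon, course_deg = .data$course,
      status = .data$status, speed_kn = .data$speed_kn,
      origin_port = .data$origin_port)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write / read the truth log as JSON
#' @param truth Truth log from [generate_fleet()].
#' @param path File path.
#' @return `path` invisibly (write); truth list (read).
#' @export
write_truth_json <- function(truth, path) {
  fmt <- function(df) {
    df$start <- format(df$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    df$end <- format(df$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    df
  }
  obj <- list(
    stops = fmt(truth$stops),
    transits = fmt(truth$transits),
    journeys = truth$journeys |> dplyr::mutate(ports = lapply(.data$ports, as.list))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  obj$stops <- as_tibble(obj$stops) |>
    dplyr::mutate(start = parse_ts(.data$start), end = parse_ts(.data$end))
  obj$transits <- as_tibble(obj$transits) |>
    dplyr::mutate(start = parse_ts(.data$start), end = parse_ts(.data$end))
  obj$journeys <- as_tibble(obj$journeys)
  obj
}
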