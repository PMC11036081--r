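# Shared fixtures: a small 1-year fleet covering all nine classes, simulated
# once per test run, plus independent geometry oracles.

small_fleet_config <- function(seed = 7) {
  fleet_config(
    n_years = 1, seed = seed,
    vessels_per_class = c(Bulk = 1, Cargo = 1, Fishing = 2, Offshore = 1,
                          Passenger = 2, Pilot = 1, Pleasure = 2, Tanker = 1,
                          Tender = 2)
  )
}

.fixtures <- new.env()

small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$cfg <- small_fleet_config()
    .fixtures$sim <- simulate_fleet(.fixtures$cfg)
  }
  .fixtures$sim
}
small_cfg <- function() { small_sim(); .fixtures$cfg }
small_result <- function() {
  if (is.null(.fixtures$res)) {
    sim <- small_sim()
    .fixtures$res <- suppressMessages(
      run_pipeline(sim$records, sim$profiles, small_cfg()))
  }
  .fixtures$res
}

# independent great-circle oracle: spherical law of cosines
slc_distance_m <- function(lat1, lon1, lat2, lon2, r = 6371000) {
  to_rad <- pi / 180
  p1 <- lat1 * to_rad; p2 <- lat2 * to_rad
  dl <- (lon2 - lon1) * to_rad
  ang <- acos(pmin(1, pmax(-1,
    sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl))))
  r * ang
}

# hand-built hourly track points for classifier/event tests
make_track <- function(mmsi, hours, lat, lon, speed,
                       t0 = as.POSIXct("2018-01-01 00:00:00", tz = "UTC")) {
  tibble::tibble(
    mmsi = mmsi,
    timestamp = t0 + hours * 3600,
    lat = lat, lon = lon,
    course = 0, status = "x", speed_kn = speed,
    imo = NA_integer_, name = "t", origin_port = NA_character_
  )
}

# true directed transition counts from a truth log: consecutive stop pairs
# at distinct ports (re-anchoring at the same port is a visit, not a trip)
truth_transition_counts <- function(truth) {
  st <- truth$stops[order(truth$stops$mmsi, truth$stops$start), ]
  pairs <- do.call(rbind, lapply(split(st, st$mmsi), function(d) {
    if (nrow(d) < 2) return(NULL)
    data.frame(from = d$port[-nrow(d)], to = d$port[-1])
  }))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  stats::aggregate(cbind(weight = rep(1, nrow(pairs))) ~ from + to, pairs, sum)
}
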