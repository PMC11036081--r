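#' Run the full introduction-pathway pipeline
#'
#' Orchestrates every stage over a record stream: hourly resampling,
#' maritime-zone vessel filtering, stationarity classification, stop-event
#' construction, coastal anchorage clustering, declared-origin
#' augmentation, country assignment, journey segmentation, voyage-network
#' construction, hull WSA estimation, and the per-class / per-location /
#' monthly threat summaries.
#'
#' @param records AIS record tibble ([read_ais_csv()] or
#'   [simulate_tracks()]).
#' @param profiles Vessel profile tibble (mmsi, vessel_type, dimensions,
#'   declared_origin).
#' @param config A [fleet_config()]-like list providing `geography`,
#'   `start`, `n_years` (study-year windows).
#' @param study A [study_area()]; its maritime zone defaults to the
#'   configured geography's.
#' @param coefficients WSA coefficient table.
#' @param rest_threshold_days Journey segmentation threshold (days).
#' @return List: trackpoints, events, nodes, journeys, network,
#'   transnational, wsa, type_summary, monthly_profile, location_factors,
#'   entry_points, and run-level counts (`log`).
#' @export
run_pipeline <- function(records, profiles, config,
                         study = NULL,
                         coefficients = wsa_coefficients(),
                         rest_threshold_days = 30) {
  geo <- config$geography
  if (is.null(study)) study <- study_area(maritime_zone = geo$maritime_zone)
  if (is.null(study$maritime_zone)) study$maritime_zone <- geo$maritime_zone

  tp <- resample_hourly(records)
  n_vessels_seen <- dplyr::n_distinct(tp$mmsi)
  tp <- filter_zone_vessels(tp, study)
  n_vessels_zone <- length(attr(tp, "retained_mmsi"))
  tp <- classify_stationary(tp, study)

  events <- build_stop_events(tp)
  cl <- cluster_nodes(events, geo$coastline, study, gazetteer = geo$ports)
  ao <- attach_origin_ports(cl$events, cl$nodes, profiles, geo$world_ports, study)
  nodes <- assign_country(ao$nodes, geo$territories)
  events <- ao$events

  journeys <- segment_journeys(events, rest_threshold_days)
  network <- build_network(events, nodes)
  tn <- transnational_trips(events, nodes, config)
  wsa <- fleet_wsa(profiles |> dplyr::filter(.data$mmsi %in% unique(events$mmsi)),
                   coefficients)

  coastal_mmsi <- unique(events$mmsi[!events$is_origin & !is.na(events$node_id)])
  list(
    trackpoints = tp,
    events = events,
    nodes = nodes,
    journeys = journeys,
    network = network,
    transnational = tn,
    wsa = wsa,
    type_summary = summarise_types(events, journeys, wsa, profiles, nodes,
                                   tn, config, geo$world_ports),
    monthly_profile = monthly_visits(events, profiles, config),
    location_factors = location_factors(network, events, wsa, profiles),
    entry_points = entry_points(events, nodes, geo$home_territory,
                                rest_threshold_days),
    log = list(
      n_vessels_seen = n_vessels_seen,
      n_vessels_zone = n_vessels_zone,
      n_vessels_coastal_stop = length(coastal_mmsi),
      coastal_stop_share_pct =
        if (n_vessels_zone > 0)
          coastal_stop_share(length(coastal_mmsi), n_vessels_zone) else NA_real_,
      n_events = sum(!events$is_origin),
      n_records = nrow(records)
    )
  )
}

#' Write the pipeline's output bundle
#'
#' Writes type_summary.csv, monthly_profile.csv, location_factors.csv,
#' entry_points.csv, network edge list + GraphML, nodes GeoJSON and a
#' run.log with record/vessel counts and parameter echo.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$type_summary, file.path(out_dir, "type_summary.csv"))
  readr::write_csv(result$monthly_profile, file.path(out_dir, "monthly_profile.csv"))
  readr::write_csv(result$location_factors, file.path(out_dir, "location_factors.csv"))
  readr::write_csv(result$entry_points, file.path(out_dir, "entry_points.csv"))
  write_network(result$network,
                edge_csv = file.path(out_dir, "edges.csv"),
                graphml = file.path(out_dir, "network.graphml"))
  write_nodes_geojson(result$network, file.path(out_dir, "nodes.geojson"))
  writeLines(c(
    paste0("vessels seen: ", result$log$n_vessels_seen),
    paste0("vessels entering maritime zone: ", result$log$n_vessels_zone),
    paste0("vessels with coastal stops: ", result$log$n_vessels_coastal_stop),
    paste0("coastal stop share (%): ",
           format(result$log$coastal_stop_share_pct, digits = 4)),
    paste0("stop events: ", result$log$n_events),
    paste0("input records: ", result$log$n_records)
  ), file.path(out_dir, "run.log"))
  invisible(out_dir)
}
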