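#' Annual per-class movement and design summaries
#'
#' Computes the per-vessel-class annual metrics that drive relative
#' introduction threat, each calculated per study year and then averaged
#' across years, with SE = sd(yearly values) / sqrt(n_years) (for two
#' years this is |y1 - y2| / 2):
#' \itemize{
#'   \item vessel_number: distinct vessels active in the year;
#'   \item cumulative_wsa: summed WSA of those distinct hulls (m^2);
#'   \item n_journeys: extended journeys per vessel;
#'   \item stops_per_journey: mean ports of call per extended journey;
#'   \item stop_time_h: mean stop-event duration (hours, per event);
#'   \item n_origin_countries: distinct countries of origin across the
#'     class's vessels (declared origin if stated, else the country of the
#'     vessel's first stop that year);
#'   \item n_transnational_trips: border-crossing stop pairs per vessel.
#' }
#' Classes with no activity in any configured year are omitted, not
#' zero-filled.
#'
#' @param events Node-assigned events (with `is_origin`).
#' @param journeys Output of [segment_journeys()].
#' @param wsa Output of [fleet_wsa()].
#' @param profiles Vessel profiles.
#' @param nodes Node table with countries.
#' @param transnational Output of [transnational_trips()].
#' @param config List with `start` and `n_years` (e.g. a [fleet_config()]).
#' @param world_ports Optional world-port lookup used to resolve declared
#'   origin countries.
#' @return Long tibble: vessel_type, metric, mean, se.
#' @export
summarise_types <- function(events, journeys, wsa, profiles, nodes,
                            transnational, config, world_ports = NULL) {
  if (config$n_years < 1) stop("at least one study year must be configured")
  ev <- events |>
    dplyr::filter(!.data$is_origin) |>
    dplyr::mutate(
      year = year_of(.data$start, config),
      vessel_type = profiles$vessel_type[match(.data$mmsi, profiles$mmsi)],
      country = nodes$country[match(.data$node_id, nodes$node_id)]) |>
    dplyr::filter(!is.na(.data$year))
  if (!nrow(ev)) stop("no events fall inside the configured study years")

  active <- ev |> dplyr::distinct(.data$vessel_type, .data$year, .data$mmsi)
  vessel_number <- active |> dplyr::count(.data$vessel_type, .data$year,
                                          name = "vessel_number")
  cumulative_wsa <- active |>
    dplyr::left_join(wsa |> dplyr::select("mmsi", "wsa_m2"), by = "mmsi") |>
    dplyr::group_by(.data$vessel_type, .data$year) |>
    dplyr::summarise(cumulative_wsa = sum(.data$wsa_m2), .groups = "drop")

  jn <- journeys |>
    dplyr::mutate(year = year_of(.data$start, config),
                  vessel_type = profiles$vessel_type[match(.data$mmsi, profiles$mmsi)]) |>
    dplyr::filter(!is.na(.data$year))
  n_journeys <- jn |>
    dplyr::count(.data$vessel_type, .data$year, name = ".nj") |>
    dplyr::left_join(vessel_number, by = c("vessel_type", "year")) |>
    dplyr::mutate(n_journeys = .data$.nj / .data$vessel_number) |>
    dplyr::select("vessel_type", "year", "n_journeys")
  stops_per_journey <- jn |>
    dplyr::group_by(.data$vessel_type, .data$year) |>
    dplyr::summarise(stops_per_journey = mean(.data$n_stops), .groups = "drop")

  stop_time_h <- ev |>
    dplyr::group_by(.data$vessel_type, .data$year) |>
    dplyr::summarise(stop_time_h = mean(.data$duration_h), .groups = "drop")

  # origin country: declared (resolved) if available, else first-stop country
  first_stop <- ev |>
    dplyr::arrange(.data$mmsi, .data$start) |>
    dplyr::group_by(.data$vessel_type, .data$year, .data$mmsi) |>
    dplyr::summarise(first_country = dplyr::first(.data$country), .groups = "drop")
  decl <- profiles |>
    dplyr::select("mmsi", "declared_origin")
  if (!is.null(world_ports)) {
    decl <- decl |>
      dplyr::mutate(declared_country = world_ports$country[
        match(.data$declared_origin, world_ports$name)])
  } else decl$declared_country <- NA_character_
  n_origin_countries <- first_stop |>
    dplyr::left_join(decl, by = "mmsi") |>
    dplyr::mutate(origin_country = dplyr::coalesce(.data$declared_country,
                                                   .data$first_country)) |>
    dplyr::filter(!is.na(.data$origin_country), .data$origin_country != "UNKNOWN") |>
    dplyr::group_by(.data$vessel_type, .data$year) |>
    dplyr::summarise(n_origin_countries = dplyr::n_distinct(.data$origin_country),
                     .groups = "drop")

  n_transnational <- transnational |>
    dplyr::mutate(vessel_type = profiles$vessel_type[match(.data$mmsi, profiles$mmsi)]) |>
    dplyr::filter(!is.na(.data$year)) |>
    dplyr::group_by(.data$vessel_type, .data$year) |>
    dplyr::summarise(.nt = sum(.data$n_transnational), .groups = "drop") |>
    dplyr::left_join(vessel_number, by = c("vessel_type", "year")) |>
    dplyr::mutate(n_transnational_trips = .data$.nt / .data$vessel_number) |>
    dplyr::select("vessel_type", "year", "n_transnational_trips")

  yearly <- vessel_number |>
    dplyr::left_join(cumulative_wsa, by = c("vessel_type", "year")) |>
    dplyr::left_join(n_journeys, by = c("vessel_type", "year")) |>
    dplyr::left_join(stops_per_journey, by = c("vessel_type", "year")) |>
    dplyr::left_join(stop_time_h, by = c("vessel_type", "year")) |>
    dplyr::left_join(n_origin_countries, by = c("vessel_type", "year")) |>
    dplyr::left_join(n_transnational, by = c("vessel_type", "year")) |>
    dplyr::mutate(n_transnational_trips = dplyr::coalesce(.data$n_transnational_trips, 0))

  yearly |>
    tidyr::pivot_longer(-c("vessel_type", "year"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$vessel_type, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = if (config$n_years > 1)
        stats::sd(.data$value, na.rm = TRUE) / sqrt(config$n_years) else 0,
      .groups = "drop")
}

#' Monthly visit profiles per vessel class
#'
#' A visit is one stop event, attributed to the calendar month of its
#' start timestamp (events rarely straddle month boundaries at these
#' durations). Counts are zero-filled over all 12 months and all study
#' years for every class present in the data, then averaged across years
#' (SE across yearly values), with an "All" profile over classes.
#'
#' @inheritParams summarise_types
#' @return Tibble: vessel_type ("All" included), month (1-12), mean, se.
#' @export
monthly_visits <- function(events, profiles, config) {
  ev <- events |>
    dplyr::filter(!.data$is_origin) |>
    dplyr::mutate(
      year = year_of(.data$start, config),
      month = lubridate::month(.data$start),
      vessel_type = profiles$vessel_type[match(.data$mmsi, profiles$mmsi)]) |>
    dplyr::filter(!is.na(.data$year))
  counts <- ev |>
    dplyr::count(.data$vessel_type, .data$year, .data$month) |>
    tidyr::complete(.data$vessel_type, year = seq_len(config$n_years),
                    month = 1:12, fill = list(n = 0L))
  all_counts <- counts |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(vessel_type = "All")
  dplyr::bind_rows(counts, all_counts) |>
    dplyr::group_by(.data$vessel_type, .data$month) |>
    dplyr::summarise(
      mean = mean(.data$n),
      se = if (config$n_years > 1) stats::sd(.data$n) / sqrt(config$n_years) else 0,
      .groups = "drop")
}

#' Per-location introduction factors, ranked
#'
#' For every node: total visits, cumulative WSA of visiting hulls (each
#' vessel's WSA counted once per visit), total hours at anchor, in/out
#' link counts and the number of distinct vessel types using the
#' location — the location-side factors known to raise introduction
#' likelihood. Locations are ranked by a documented composite: the mean of
#' the per-factor ranks (each factor ranked descending), ties broken by
#' total visits then label.
#'
#' @param network A [build_network()] result.
#' @param events Node-assigned events.
#' @param wsa Output of [fleet_wsa()].
#' @param profiles Vessel profiles.
#' @return Tibble sorted by composite rank.
#' @export
location_factors <- function(network, events, wsa, profiles) {
  if (!"is_origin" %in% names(events)) events$is_origin <- FALSE
  ev <- events |> dplyr::filter(!is.na(.data$node_id))
  missing_nodes <- setdiff(unique(ev$node_id), network$nodes$node_id)
  if (length(missing_nodes))
    stop("events reference node(s) absent from the network: ",
         paste(missing_nodes, collapse = ", "))
  ev <- ev |>
    dplyr::filter(!.data$is_origin) |>
    dplyr::mutate(
      wsa_m2 = wsa$wsa_m2[match(.data$mmsi, wsa$mmsi)],
      vessel_type = profiles$vessel_type[match(.data$mmsi, profiles$mmsi)])
  per_node <- ev |>
    dplyr::group_by(.data$node_id) |>
    dplyr::summarise(
      total_visits = dplyr::n(),
      cumulative_wsa_m2 = sum(.data$wsa_m2),
      total_anchor_hours = sum(.data$duration_h),
      n_vessel_types = dplyr::n_distinct(.data$vessel_type),
      .groups = "drop")
  out <- network$nodes |>
    dplyr::select("node_id", "label", dplyr::any_of("country"),
                  "is_external", "in_links", "out_links") |>
    dplyr::left_join(per_node, by = "node_id") |>
    dplyr::mutate(dplyr::across(c("total_visits", "cumulative_wsa_m2",
                                  "total_anchor_hours", "n_vessel_types"),
                                \(x) dplyr::coalesce(x, 0)))
  factor_cols <- c("total_visits", "cumulative_wsa_m2", "total_anchor_hours",
                   "in_links", "out_links", "n_vessel_types")
  rk <- sapply(factor_cols, function(cn) rank(-out[[cn]], ties.method = "average"))
  out$composite_rank <- rowMeans(rk)
  out |>
    dplyr::arrange(.data$composite_rank, dplyr::desc(.data$total_visits),
                   .data$label)
}

#' Initial-entry stops per node
#'
#' An initial-entry stop is the first stop of an extended journey inside
#' the focal territory whose immediately preceding event (previous stop,
#' rest, or declared origin marker) was in a different country — the first
#' port of call into the territory from abroad. Counted per node.
#'
#' @param events Node-assigned events (with origin markers attached).
#' @param nodes Node table with countries.
#' @param home_territory Territory code of interest (default "SG").
#' @param rest_threshold_days Journey segmentation threshold.
#' @return Tibble: node_id, n_entries (nodes with zero entries omitted).
#' @export
entry_points <- function(events, nodes, home_territory = "SG",
                         rest_threshold_days = 30) {
  if (!"is_origin" %in% names(events)) events$is_origin <- FALSE
  ev <- events |>
    dplyr::filter(!is.na(.data$node_id)) |>
    dplyr::arrange(.data$mmsi, .data$start, .data$duration_h) |>
    dplyr::mutate(country = nodes$country[match(.data$node_id, nodes$node_id)]) |>
    dplyr::group_by(.data$mmsi) |>
    dplyr::mutate(prev_country = dplyr::lag(.data$country)) |>
    dplyr::ungroup()
  thr_h <- rest_threshold_days * 24
  ev <- ev |>
    dplyr::group_by(.data$mmsi) |>
    dplyr::mutate(
      .long = !.data$is_origin & .data$duration_h > thr_h,
      journey = 1L + cumsum(dplyr::lag(.data$.long, default = FALSE))) |>
    dplyr::ungroup()
  ev |>
    dplyr::filter(!.data$is_origin, !.data$.long,
                  .data$country == home_territory) |>
    dplyr::group_by(.data$mmsi, .data$journey) |>
    dplyr::slice_min(.data$start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_country),
                  .data$prev_country != home_territory,
                  .data$prev_country != "UNKNOWN") |>
    dplyr::count(.data$node_id, name = "n_entries") |>
    dplyr::arrange(dplyr::desc(.data$n_entries))
}
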