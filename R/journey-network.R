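#' Segment stop sequences into extended journeys
#'
#' An extended journey is a consecutive multi-stop voyage with no
#' prolonged intervening rest: any single stop longer than
#' `rest_threshold_days` (default 30 d, the ">1 month" convention)
#' terminates the journey in progress, and the next (short) stop opens the
#' next journey from that location. Rest stops and zero-duration origin
#' markers are excluded from `n_stops` and the node list, so "stops during
#' an extended journey" counts ports of call, not the rests bounding them.
#' Journeys are invariant to splitting the event stream at arbitrary time
#' seams and concatenating.
#'
#' @param events Node-assigned stop events (one or many vessels), with
#'   optional `is_origin` column.
#' @param rest_threshold_days Rest duration (days) above which a stop
#'   bounds journeys.
#' @return Tibble: mmsi, journey_id, start, end (span of counted stops),
#'   n_stops, nodes (list of node_ids in visit order).
#' @export
segment_journeys <- function(events, rest_threshold_days = 30) {
  empty <- tibble(mmsi = integer(),
                  journey_id = integer(),
                  start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  n_stops = integer(), nodes = list())
  if (!nrow(events)) return(empty)
  if (!"is_origin" %in% names(events)) events$is_origin <- FALSE
  ev <- events |>
    dplyr::filter(!.data$is_origin) |>
    dplyr::arrange(.data$mmsi, .data$start)
  if (!nrow(ev)) return(empty)
  thr_h <- rest_threshold_days * 24
  ev <- ev |>
    dplyr::group_by(.data$mmsi) |>
    dplyr::mutate(
      .long = .data$duration_h > thr_h,
      journey_id = 1L + cumsum(dplyr::lag(.data$.long, default = FALSE))) |>
    dplyr::ungroup()
  ev |>
    dplyr::filter(!.data$.long) |>
    dplyr::group_by(.data$mmsi, .data$journey_id) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_stops = dplyr::n(),
      nodes = list(.data$node_id), .groups = "drop") |>
    dplyr::group_by(.data$mmsi) |>
    dplyr::mutate(journey_id = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Build the directed voyage network
#'
#' Nodes are anchorages (plus external declared-origin ports); a directed
#' edge A -> B accrues one unit of weight each time any vessel's event
#' sequence moves from node A to a different node B, so edge weight is the
#' frequency of unique vessel trips along that port-to-port route.
#' Consecutive events at the same node (re-anchoring in place) add a visit
#' but no self-edge. Node size is `total_visits`, the number of stop
#' events at the node (origin markers excluded); `in_links` / `out_links`
#' count distinct neighbouring nodes, not edge weights.
#'
#' @param events Node-assigned events (with `is_origin` if origins were
#'   attached); events without a node are ignored.
#' @param nodes Node table (internal + external).
#' @return A `voyage_network`: list with `nodes` (node attributes +
#'   total_visits, in_links, out_links), `edges` (from, to, weight) and
#'   `graph` (igraph object with the same attributes).
#' @export
build_network <- function(events, nodes) {
  if (!"is_origin" %in% names(events)) events$is_origin <- FALSE
  ev <- events |>
    dplyr::filter(!is.na(.data$node_id)) |>
    dplyr::arrange(.data$mmsi, .data$start, .data$duration_h)
  visits <- ev |>
    dplyr::filter(!.data$is_origin) |>
    dplyr::count(.data$node_id, name = "total_visits")
  edges <- ev |>
    dplyr::group_by(.data$mmsi) |>
    dplyr::mutate(.next = dplyr::lead(.data$node_id)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$.next), .data$node_id != .data$.next) |>
    dplyr::count(from = .data$node_id, to = .data$.next, name = "weight") |>
    dplyr::arrange(.data$from, .data$to)
  nt <- nodes |>
    dplyr::left_join(visits, by = "node_id") |>
    dplyr::mutate(total_visits = dplyr::coalesce(.data$total_visits, 0L)) |>
    dplyr::left_join(
      edges |> dplyr::distinct(.data$from, .data$to) |>
        dplyr::count(node_id = .data$to, name = "in_links"),
      by = "node_id") |>
    dplyr::left_join(
      edges |> dplyr::distinct(.data$from, .data$to) |>
        dplyr::count(node_id = .data$from, name = "out_links"),
      by = "node_id") |>
    dplyr::mutate(in_links = dplyr::coalesce(.data$in_links, 0L),
                  out_links = dplyr::coalesce(.data$out_links, 0L))
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(from = character(), to = character(),
                                           weight = double()),
    directed = TRUE,
    vertices = as.data.frame(nt |> dplyr::select("node_id", dplyr::everything())))
  structure(list(nodes = nt, edges = edges, graph = g),
            class = "voyage_network")
}

#' @export
print.voyage_network <- function(x, ...) {
  cat("voyage_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$is_external), "external ),", nrow(x$edges),
      "directed edges, total visits", sum(x$nodes$total_visits), "\n")
  invisible(x)
}

#' Count trans-national trips
#'
#' A trans-national trip is a consecutive pair of stops whose country
#' codes differ (including the declared-origin marker to the first stop,
#' when present). Pairs with an UNKNOWN code on either side are skipped
#' (logged). Counts are attributed to the vessel and to the study year of
#' the arrival stop.
#'
#' @param events Node-assigned events.
#' @param nodes Node table with `country` filled.
#' @param config Optional [fleet_config()]-like list (`start`, `n_years`)
#'   used to attribute counts to study years; if NULL, `year` is NA.
#' @return Tibble: mmsi, year, n_transnational.
#' @export
transnational_trips <- function(events, nodes, config = NULL) {
  if (!"is_origin" %in% names(events)) events$is_origin <- FALSE
  ev <- events |>
    dplyr::filter(!is.na(.data$node_id)) |>
    dplyr::arrange(.data$mmsi, .data$start, .data$duration_h) |>
    dplyr::mutate(country = nodes$country[match(.data$node_id, nodes$node_id)]) |>
    dplyr::group_by(.data$mmsi) |>
    dplyr::mutate(.prev = dplyr::lag(.data$country)) |>
    dplyr::ungroup()
  pairs <- ev |> dplyr::filter(!is.na(.data$.prev))
  n_unknown <- sum(pairs$country == "UNKNOWN" | pairs$.prev == "UNKNOWN",
                   na.rm = TRUE)
  if (n_unknown > 0)
    message(n_unknown, " stop pair(s) skipped for UNKNOWN country")
  pairs <- pairs |>
    dplyr::filter(.data$country != "UNKNOWN", .data$.prev != "UNKNOWN")
  pairs$year <- if (!is.null(config)) year_of(pairs$start, config) else NA_integer_
  pairs |>
    dplyr::filter(.data$country != .data$.prev) |>
    dplyr::count(.data$mmsi, .data$year, name = "n_transnational")
}

#' Per-node degree and visit summary
#'
#' @param network A [build_network()] result.
#' @param top_n Optionally return only the busiest `top_n` nodes.
#' @return Tibble (node_id, label, country, is_external, total_visits,
#'   in_links, out_links) ordered by total visits (ties by label).
#' @export
degree_summary <- function(network, top_n = NULL) {
  out <- network$nodes |>
    dplyr::select("node_id", "label", dplyr::any_of(c("country", "is_external")),
                  "total_visits", "in_links", "out_links") |>
    dplyr::arrange(dplyr::desc(.data$total_visits), .data$label)
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Export the network
#'
#' Writes the edge list as CSV (from_id, to_id, weight) and the graph as
#' GraphML with node attributes (label, country, total_visits, in_links,
#' out_links).
#' @param network A `voyage_network`.
#' @param edge_csv,graphml Output paths (NULL to skip either).
#' @return Invisibly, the network.
#' @export
write_network <- function(network, edge_csv = NULL, graphml = NULL) {
  if (!is.null(edge_csv))
    readr::write_csv(network$edges |>
                       dplyr::rename(from_id = "from", to_id = "to"), edge_csv)
  if (!is.null(graphml))
    igraph::write_graph(network$graph, graphml, format = "graphml")
  invisible(network)
}

#' Write nodes as GeoJSON points
#' @param network A `voyage_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nodes_geojson <- function(network, path) {
  nt <- network$nodes
  features <- lapply(seq_len(nrow(nt)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(nt$lon[i], nt$lat[i])),
      properties = list(
        node_id = nt$node_id[i], label = nt$label[i],
        country = nt$country[i], is_external = nt$is_external[i],
        total_visits = nt$total_visits[i],
        in_links = nt$in_links[i], out_links = nt$out_links[i])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
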