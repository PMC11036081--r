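#' Collapse stationary runs into stop events
#'
#' A stop event is a maximal run of consecutive stationary track points of
#' one vessel: "cumulative time stopped at a location over a unique
#' continuous period of time". Event duration is the time span between the
#' first and last stationary point of the run; a single isolated stationary
#' point counts as one hour (one sampling interval), since hourly sampling
#' cannot resolve sub-hour stops.
#'
#' @param trackpoints Flagged track points from [classify_stationary()].
#' @return Tibble of events: mmsi, start, end, duration_h, lat, lon
#'   (mean position of the run), n_points.
#' @export
build_stop_events <- function(trackpoints) {
  empty <- tibble(
    mmsi = integer(), start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"), duration_h = double(),
    lat = double(), lon = double(), n_points = integer()
  )
  if (!nrow(trackpoints)) return(empty)
  tp <- trackpoints |> dplyr::arrange(.data$mmsi, .data$timestamp)
  run <- with(tp, cumsum(
    c(TRUE, mmsi[-1] != mmsi[-length(mmsi)] |
        stationary[-1] != stationary[-length(stationary)])))
  tp$.run <- run
  if (!any(tp$stationary)) return(empty)
  ev <- tp |>
    dplyr::filter(.data$stationary) |>
    dplyr::group_by(.data$mmsi, .data$.run) |>
    dplyr::summarise(
      start = min(.data$timestamp), end = max(.data$timestamp),
      lat = mean(.data$lat), lon = mean(.data$lon),
      n_points = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      duration_h = as.numeric(difftime(.data$end, .data$start, units = "hours")),
      duration_h = pmax(.data$duration_h, 1),
      end = .data$start + .data$duration_h * 3600) |>
    dplyr::arrange(.data$mmsi, .data$start) |>
    dplyr::select("mmsi", "start", "end", "duration_h", "lat", "lon", "n_points")
  ev
}

# single-linkage components at <= link_m; exact on the deduplicated
# coordinates, with a fine-grid collapse (cell diagonal < link) for very
# large inputs where the full distance matrix is impractical
single_linkage_clusters <- function(lat, lon, link_m, max_exact = 4000) {
  key <- paste(round(lat, 6), round(lon, 6))
  uk <- !duplicated(key)
  ulat <- lat[uk]; ulon <- lon[uk]
  if (length(ulat) > max_exact) {
    cell <- link_m / sqrt(2) / 111320 # degrees; diagonal < link_m
    gkey <- paste(floor(ulat / cell), floor(ulon / (cell / cos(mean(ulat) * pi / 180))))
    gu <- !duplicated(gkey)
    glat <- ulat[gu]; glon <- ulon[gu]
    gcl <- single_linkage_clusters(glat, glon, link_m, max_exact = Inf)
    ucl <- gcl[match(gkey, gkey[gu])]
  } else if (length(ulat) == 1) {
    ucl <- 1L
  } else {
    dm <- geosphere::distm(cbind(ulon, ulat), fun = function(p1, p2) {
      geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
    })
    hc <- stats::hclust(stats::as.dist(dm), method = "single")
    ucl <- stats::cutree(hc, h = link_m)
  }
  ucl[match(key, key[uk])]
}

#' Cluster coastal stop events into anchorage nodes
#'
#' Stops within the coastal band (default 12 nm of land) are clustered by
#' single linkage: stops whose buffers (default 5 km) overlap, i.e. whose
#' pairwise distance is at most twice the buffer radius, join one node.
#' The node centroid is the mean of member stop positions; the label is
#' the nearest gazetteer port if within the buffer radius of the centroid,
#' otherwise a synthetic identifier. Stops farther than the coastal band
#' from land are assigned no node (their count is messaged).
#'
#' Clustering is permutation-invariant: node membership and identifiers do
#' not depend on input row order (nodes are numbered by centroid
#' coordinates).
#'
#' @param events Stop events from [build_stop_events()].
#' @param coastline List of coastline rings (data frames with lat, lon).
#' @param study A [study_area()].
#' @param gazetteer Port gazetteer tibble (name, lat, lon, country);
#'   may be empty (all labels synthetic).
#' @return List: `nodes` (node_id, label, lat, lon, is_external, n_stops),
#'   `events` (input plus node_id; NA for stops outside the coastal band).
#' @export
cluster_nodes <- function(events, coastline, study = study_area(),
                          gazetteer = NULL) {
  if (!nrow(events)) {
    return(list(
      nodes = tibble(node_id = character(), label = character(),
                     lat = double(), lon = double(), is_external = logical(),
                     n_stops = integer()),
      events = dplyr::mutate(events, node_id = character(0))
    ))
  }
  band_m <- study$coastal_band_nm * NM_M
  key <- paste(round(events$lat, 6), round(events$lon, 6))
  uk <- !duplicated(key)
  udist <- dist_to_land_m(events$lat[uk], events$lon[uk], coastline)
  coastal <- (udist[match(key, key[uk])]) <= band_m
  n_off <- sum(!coastal)
  if (n_off > 0) message(n_off, " stop event(s) beyond the coastal band excluded from nodes")
  events$node_id <- NA_character_
  if (!any(coastal)) return(list(nodes = tibble(
    node_id = character(), label = character(), lat = double(), lon = double(),
    is_external = logical(), n_stops = integer()), events = events))

  ce <- events[coastal, ]
  cl <- single_linkage_clusters(ce$lat, ce$lon, 2 * study$node_buffer_km * 1000)
  cent <- tibble(cl = cl, lat = ce$lat, lon = ce$lon) |>
    dplyr::group_by(.data$cl) |>
    dplyr::summarise(lat = mean(.data$lat), lon = mean(.data$lon),
                     n_stops = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$lat, .data$lon) |>
    dplyr::mutate(node_id = sprintf("N%03d", dplyr::row_number()))
  # label: nearest gazetteer port within the buffer radius of the centroid;
  # ties broken alphabetically for determinism
  cent$label <- cent$node_id
  if (!is.null(gazetteer) && nrow(gazetteer)) {
    gz <- gazetteer |> dplyr::arrange(.data$name)
    for (i in seq_len(nrow(cent))) {
      dd <- haversine_m(cent$lat[i], cent$lon[i], gz$lat, gz$lon)
      j <- which(dd <= study$node_buffer_km * 1000)
      if (length(j)) cent$label[i] <- gz$name[j[which.min(dd[j])]]
    }
  }
  events$node_id[coastal] <- cent$node_id[match(cl, cent$cl)]
  nodes <- cent |>
    dplyr::mutate(is_external = FALSE) |>
    dplyr::select("node_id", "label", "lat", "lon", "is_external", "n_stops")
  list(nodes = nodes, events = events)
}

#' Attach declared origin ports outside the AOI
#'
#' When a vessel declares a port of origin that resolves against the world
#' port lookup and lies outside the area of interest, an external node is
#' created and a zero-duration origin event is prepended to that vessel's
#' event sequence, identifying the broader global link into the region.
#' Declared origins that are unresolvable (logged), blank, inside the AOI,
#' or identical to the vessel's first AIS-derived node leave the sequence
#' unchanged. Origin events carry `is_origin = TRUE` and never count as
#' visits or stop time.
#'
#' @param events Node-assigned events from [cluster_nodes()].
#' @param nodes Node table from [cluster_nodes()].
#' @param profiles Vessel profiles with `mmsi` and `declared_origin`.
#' @param world_ports Lookup tibble: name, lat, lon, country.
#' @param study A [study_area()] (for the AOI test).
#' @return List: `nodes` (with external nodes appended, carrying their
#'   country), `events` (with origin events prepended, `is_origin` column).
#' @export
attach_origin_ports <- function(events, nodes, profiles, world_ports,
                                study = study_area()) {
  events$is_origin <- FALSE
  if (!nrow(events)) return(list(nodes = nodes, events = events))
  decl <- profiles |>
    dplyr::filter(!is.na(.data$declared_origin), .data$declared_origin != "") |>
    dplyr::select("mmsi", "declared_origin")
  new_nodes <- list(); new_events <- list()
  unresolved <- 0L
  for (i in seq_len(nrow(decl))) {
    mm <- decl$mmsi[i]; pname <- decl$declared_origin[i]
    ev <- events[events$mmsi == mm & !is.na(events$node_id), ]
    if (!nrow(ev)) next
    wp <- world_ports[world_ports$name == pname, ]
    if (!nrow(wp)) { unresolved <- unresolved + 1L; next }
    if (in_aoi(wp$lat[1], wp$lon[1], study)) next
    first_ev <- ev[which.min(ev$start), ]
    first_label <- nodes$label[match(first_ev$node_id, nodes$node_id)]
    if (identical(first_label, pname)) next
    ext_id <- paste0("EXT_", gsub("[^A-Za-z0-9]+", "_", pname))
    if (!ext_id %in% c(nodes$node_id, vapply(new_nodes, function(x) x$node_id, "")))
      new_nodes[[length(new_nodes) + 1L]] <- tibble(
        node_id = ext_id, label = pname, lat = wp$lat[1], lon = wp$lon[1],
        is_external = TRUE, n_stops = 0L, country = wp$country[1])
    new_events[[length(new_events) + 1L]] <- tibble(
      mmsi = mm, start = first_ev$start, end = first_ev$start,
      duration_h = 0, lat = wp$lat[1], lon = wp$lon[1], n_points = 0L,
      node_id = ext_id, is_origin = TRUE)
  }
  if (unresolved > 0) message(unresolved, " declared origin port(s) unresolved")
  nodes_out <- dplyr::bind_rows(
    dplyr::mutate(nodes, country = NA_character_)[, union(names(nodes), "country")],
    dplyr::bind_rows(new_nodes))
  events_out <- dplyr::bind_rows(events, dplyr::bind_rows(new_events)) |>
    dplyr::arrange(.data$mmsi, .data$start, .data$duration_h)
  list(nodes = nodes_out, events = events_out)
}

#' Assign a country or territory code to every node
#'
#' Internal nodes are matched against territory polygons (first match in
#' table order); external nodes keep the country from the world-port
#' lookup. Unmatched internal nodes get code "UNKNOWN" (logged). Distinct
#' codes for jurisdictionally distinct island groups (e.g. South Georgia
#' vs the South Sandwich Islands) are respected by supplying them as
#' separate rows of the territory table.
#'
#' @param nodes Node table (with or without a `country` column).
#' @param territories Tibble with columns `code` and `polygon` (each a
#'   data frame of lat/lon ring vertices).
#' @return Nodes with a filled `country` column.
#' @export
assign_country <- function(nodes, territories) {
  if (!"country" %in% names(nodes)) nodes$country <- NA_character_
  for (i in seq_len(nrow(nodes))) {
    if (!is.na(nodes$country[i])) next
    code <- "UNKNOWN"
    for (j in seq_len(nrow(territories))) {
      if (point_in_polygon(nodes$lat[i], nodes$lon[i], territories$polygon[[j]])) {
        code <- territories$code[j]
        break
      }
    }
    nodes$country[i] <- code
  }
  n_unk <- sum(nodes$country == "UNKNOWN")
  if (n_unk > 0) message(n_unk, " node(s) with no territory match assigned UNKNOWN")
  nodes
}
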