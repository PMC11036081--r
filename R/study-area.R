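#' Study area definition
#'
#' Bundles the spatial filters and behavioural thresholds that drive data
#' cleaning: the area-of-interest bounding box, the maritime-zone polygon
#' used to select vessels, the coastal band within which anchorage nodes are
#' formed, and the stationarity thresholds.
#'
#' Defaults follow the South Atlantic / sub-Antarctic study region: AOI from
#' 68.5 to 45 S and 77 to 15 W, a 200 nm maritime zone, a 12 nm coastal
#' band, and the two-condition stationarity rule (< 400 m displacement over
#' 1 h AND reported speed < 1 kn).
#'
#' @param aoi_bbox Named numeric: lat_min, lat_max, lon_min, lon_max.
#' @param maritime_zone Polygon (data frame with lat, lon) or list of
#'   polygons; vessels never entering it are dropped.
#' @param coastal_band_nm Width of the band around land within which stops
#'   form nodes (nautical miles).
#' @param stationary_move_max_m Displacement threshold (metres per hour).
#' @param stationary_speed_max_kn Reported-speed threshold (knots).
#' @param underway_speed_min_kn Metadata: speed above which a vessel is
#'   considered underway (not used by the classifier, which applies the
#'   two-condition rule).
#' @param node_buffer_km Anchorage buffer radius; stops whose buffers
#'   overlap (centres within `2 * node_buffer_km`) join one node.
#' @return A `study_area` list.
#' @export
study_area <- function(aoi_bbox = c(lat_min = -68.5, lat_max = -45,
                                    lon_min = -77, lon_max = -15),
                       maritime_zone = NULL,
                       coastal_band_nm = 12,
                       stationary_move_max_m = 400,
                       stationary_speed_max_kn = 1,
                       underway_speed_min_kn = 0.2,
                       node_buffer_km = 5) {
  stopifnot(
    aoi_bbox["lat_min"] < aoi_bbox["lat_max"],
    aoi_bbox["lon_min"] < aoi_bbox["lon_max"],
    coastal_band_nm > 0, stationary_move_max_m > 0,
    stationary_speed_max_kn > 0, node_buffer_km > 0
  )
  structure(list(
    aoi_bbox = aoi_bbox,
    maritime_zone = maritime_zone,
    coastal_band_nm = coastal_band_nm,
    stationary_move_max_m = stationary_move_max_m,
    stationary_speed_max_kn = stationary_speed_max_kn,
    underway_speed_min_kn = underway_speed_min_kn,
    node_buffer_km = node_buffer_km
  ), class = "study_area")
}

#' Is a point inside the AOI bounding box?
#' @param lat,lon Coordinates, degrees.
#' @param study A [study_area()].
#' @return Logical vector.
#' @export
in_aoi <- function(lat, lon, study) {
  bb <- study$aoi_bbox
  lon <- normalise_lon(lon)
  lat >= bb["lat_min"] & lat <= bb["lat_max"] &
    lon >= bb["lon_min"] & lon <= bb["lon_max"]
}

circle_polygon <- function(lat, lon, radius_m, n = 72) {
  brg <- seq(0, 360, length.out = n + 1)[-(n + 1)]
  xy <- geosphere::destPoint(c(lon, lat), brg, radius_m, r = EARTH_RADIUS_M)
  tibble(lat = xy[, "lat"], lon = xy[, "lon"])
}

box_polygon <- function(lat_min, lat_max, lon_min, lon_max) {
  tibble(
    lat = c(lat_min, lat_min, lat_max, lat_max),
    lon = c(lon_min, lon_max, lon_max, lon_min)
  )
}

#' Synthetic study geography
#'
#' A self-contained geography for simulation and testing: a port catalog
#' (all ports >= 25 km apart so anchorage clusters are unambiguous), small
#' island coastline rings around each port, territory polygons, a 200 nm
#' maritime-zone polygon around the focal territory, and a world-port lookup
#' for declared origins outside the AOI. Coordinates are synthetic: they
#' approximate real South Atlantic anchorages but are nudged for spacing.
#'
#' @param zone_radius_nm Maritime-zone radius (nautical miles).
#' @return List with `ports`, `world_ports`, `coastline`, `territories`
#'   (tibble of code + polygon), `maritime_zone`, `home_territory`.
#' @export
synthetic_geography <- function(zone_radius_nm = 200) {
  ports <- tibble::tribble(
    ~name,               ~lat,    ~lon,    ~country,
    "King Edward Point", -54.28,  -36.49,  "SG",
    "Stromness Bay",     -54.15,  -36.90,  "SG",
    "Bay of Isles",      -54.02,  -37.30,  "SG",
    "St Andrews Bay",    -54.43,  -36.18,  "SG",
    "Gold Harbour",      -54.62,  -35.93,  "SG",
    "Cooper Bay",        -54.80,  -35.60,  "SG",
    "Saunders Island",   -57.80,  -26.45,  "SS",
    "Stanley",           -51.69,  -57.86,  "FK",
    "Ushuaia",           -54.80,  -68.30,  "AR",
    "Punta Arenas",      -53.16,  -70.91,  "CL",
    "Port Lockroy",      -64.82,  -63.50,  "AQ"
  )
  world_ports <- dplyr::bind_rows(
    ports,
    tibble::tribble(
      ~name,            ~lat,   ~lon,   ~country,
      "Montevideo",     -34.90, -56.21, "UY",
      "Mar del Plata",  -38.03, -57.53, "AR",
      "Cape Town",      -33.91,  18.42, "ZA",
      "Las Palmas",      28.13, -15.43, "ES"
    )
  )
  # one small island ring per port so every anchorage sits on the coast
  coastline <- lapply(seq_len(nrow(ports)), function(i) {
    box_polygon(ports$lat[i] - 0.04, ports$lat[i] + 0.04,
                ports$lon[i] - 0.07, ports$lon[i] + 0.07)
  })
  names(coastline) <- ports$name
  territories <- tibble(
    code = c("SG", "SS", "FK", "AR", "CL", "AQ"),
    polygon = list(
      box_polygon(-55.5, -53.5, -38.5, -35.0),
      box_polygon(-60.0, -56.0, -28.0, -25.0),
      box_polygon(-53.0, -50.9, -62.0, -57.0),
      box_polygon(-56.0, -45.0, -69.5, -62.5),
      box_polygon(-56.0, -45.0, -77.0, -69.6),
      box_polygon(-69.0, -60.0, -77.0, -44.0)
    )
  )
  maritime_zone <- list(
    circle_polygon(-54.4, -36.3, zone_radius_nm * NM_M),
    circle_polygon(-57.8, -26.4, zone_radius_nm * NM_M)
  )
  list(
    ports = ports,
    world_ports = world_ports,
    coastline = coastline,
    territories = territories,
    maritime_zone = maritime_zone,
    home_territory = "SG"
  )
}
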