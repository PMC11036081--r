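events_from_durations <- function(durations_h, nodes = NULL, mmsi = 1L,
                                  gap_h = 2) {
  t0 <- as.POSIXct("2018-01-01", tz = "UTC")
  start <- t0 + cumsum(c(0, head(durations_h, -1) + gap_h)) * 3600
  tibble::tibble(
    mmsi = mmsi, start = start, end = start + durations_h * 3600,
    duration_h = durations_h,
    lat = -54, lon = -36, n_points = 1L,
    node_id = if (is.null(nodes)) paste0("N", seq_along(durations_h)) else nodes,
    is_origin = FALSE)
}

test_that("a stop longer than the rest threshold splits journeys", {
  ev <- events_from_durations(c(5, 3, 35 * 24, 4))
  j <- segment_journeys(ev)
  expect_equal(nrow(j), 2)
  expect_equal(j$n_stops, c(2L, 1L))  # the 35 d rest bounds, and is not, a port call

  expect_equal(segment_journeys(ev[0, ]) |> nrow(), 0)
  single <- segment_journeys(events_from_durations(6))
  expect_equal(nrow(single), 1)
  expect_equal(single$n_stops, 1L)

  # threshold is configurable
  expect_equal(nrow(segment_journeys(ev, rest_threshold_days = 40)), 1)
})

test_that("journey segmentation is invariant to splitting at time seams", {
  ev <- events_from_durations(c(5, 3, 35 * 24, 4, 6, 40 * 24, 2))
  whole <- segment_journeys(ev)
  parts <- dplyr::bind_rows(ev[1:3, ], ev[4:7, ])  # seam mid-sequence
  expect_equal(segment_journeys(parts), whole)
})

test_that("synthetic journeys are recovered exactly from the event stream", {
  res <- small_result()
  truth <- small_sim()$truth
  tj <- truth$journeys |> dplyr::count(mmsi, name = "k")
  rj <- res$journeys |> dplyr::count(mmsi, name = "k")
  expect_equal(dplyr::arrange(rj, mmsi), dplyr::arrange(tj, mmsi))
  m <- dplyr::inner_join(truth$journeys, res$journeys,
                         by = c("mmsi", "journey_id"))
  expect_equal(nrow(m), nrow(truth$journeys))
  expect_equal(m$n_stops.x, m$n_stops.y)
})

test_that("edges accrue unique vessel trips between distinct nodes", {
  ev <- events_from_durations(c(2, 2, 2), nodes = c("A", "B", "A"))
  nodes <- tibble::tibble(node_id = c("A", "B"), label = c("A", "B"),
                          lat = 0, lon = 0, is_external = FALSE, n_stops = 0L,
                          country = "SG")
  net <- build_network(ev, nodes)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$weight, c(1, 1))
  expect_equal(net$nodes$total_visits[match(c("A", "B"), net$nodes$node_id)],
               c(2L, 1L))

  # two vessels on the same route: weight 2
  two <- dplyr::bind_rows(
    events_from_durations(c(2, 2), nodes = c("A", "B"), mmsi = 1L),
    events_from_durations(c(2, 2), nodes = c("A", "B"), mmsi = 2L))
  net2 <- build_network(two, nodes)
  expect_equal(net2$edges$weight, 2)

  # re-anchoring at the same node: a visit, not a self-edge
  re <- events_from_durations(c(2, 2, 2), nodes = c("A", "A", "B"))
  net3 <- build_network(re, nodes)
  expect_equal(nrow(net3$edges), 1)
  expect_equal(net3$nodes$total_visits[net3$nodes$node_id == "A"], 2L)

  empty <- build_network(ev[0, ], nodes)
  expect_equal(nrow(empty$edges), 0)
  expect_true(all(empty$nodes$total_visits == 0))
})

test_that("degree counts distinct neighbours, not edge weights", {
  nodes <- tibble::tibble(node_id = c("hub", paste0("S", 1:5)),
                          label = c("hub", paste0("S", 1:5)),
                          lat = 0, lon = 0, is_external = FALSE, n_stops = 0L,
                          country = "SG")
  star <- dplyr::bind_rows(lapply(1:5, function(i)
    events_from_durations(c(2, 2), nodes = c(paste0("S", i), "hub"),
                          mmsi = as.integer(i))))
  net <- build_network(star, nodes)
  hub <- net$nodes[net$nodes$node_id == "hub", ]
  expect_equal(hub$in_links, 5L)
  expect_equal(hub$out_links, 0L)

  # parallel trips from the same neighbour count once
  par <- events_from_durations(c(2, 2, 2, 2), nodes = c("S1", "hub", "S1", "hub"))
  netp <- build_network(par, nodes)
  expect_equal(netp$nodes$in_links[netp$nodes$node_id == "hub"], 1L)
  expect_equal(netp$edges$weight[netp$edges$from == "S1"], 2)

  # isolated node: visits without degree
  iso <- events_from_durations(2, nodes = "S1")
  neti <- build_network(iso, nodes)
  s1 <- neti$nodes[neti$nodes$node_id == "S1", ]
  expect_equal(s1$total_visits, 1L)
  expect_equal(s1$in_links + s1$out_links, 0L)

  ds <- degree_summary(net, top_n = 3)
  expect_equal(ds$node_id[1], "hub")  # busiest by visits
})

test_that("trans-national trips count border-crossing stop pairs", {
  nodes <- tibble::tibble(
    node_id = c("SG1", "SG2", "FK1", "AR1", "UNK"),
    label = node_id, lat = 0, lon = 0, is_external = FALSE, n_stops = 0L,
    country = c("SG", "SG", "FK", "AR", "UNKNOWN"))
  tn <- transnational_trips(
    events_from_durations(c(2, 2, 2), nodes = c("SG1", "SG2", "FK1")), nodes)
  expect_equal(tn$n_transnational, 1L)
  tn0 <- transnational_trips(
    events_from_durations(c(2, 2), nodes = c("SG1", "SG2")), nodes)
  expect_equal(nrow(tn0), 0)
  tn2 <- transnational_trips(
    events_from_durations(c(2, 2, 2), nodes = c("AR1", "SG1", "FK1")), nodes)
  expect_equal(tn2$n_transnational, 2L)
  # UNKNOWN on either side: pair skipped
  tnu <- suppressMessages(transnational_trips(
    events_from_durations(c(2, 2, 2), nodes = c("SG1", "UNK", "FK1")), nodes))
  expect_equal(nrow(tnu), 0)
})

test_that("edge weights conserve the number of distinct-node transitions", {
  res <- small_result()
  ev <- res$events[!is.na(res$events$node_id), ]
  ev <- ev[order(ev$mmsi, ev$start, ev$duration_h), ]
  n_trans <- sum(unlist(lapply(split(ev$node_id, ev$mmsi), function(x)
    if (length(x) > 1) sum(x[-1] != x[-length(x)]) else 0)))
  expect_equal(sum(res$network$edges$weight), n_trans)
  # visits conserve events
  expect_equal(sum(res$network$nodes$total_visits), sum(!res$events$is_origin))
})

test_that("deleting a node from the network never raises another node's degree", {
  res <- small_result()
  g0 <- res$network$graph
  for (victim in res$network$nodes$node_id[1:min(3, nrow(res$network$nodes))]) {
    g1 <- igraph::delete_vertices(g0, victim)
    keep <- setdiff(igraph::V(g0)$name, victim)
    expect_true(all(igraph::degree(g1, keep, mode = "in") <=
                      igraph::degree(g0, keep, mode = "in")))
    expect_true(all(igraph::degree(g1, keep, mode = "out") <=
                      igraph::degree(g0, keep, mode = "out")))
  }
})

test_that("network exports round-trip through GraphML and the edge CSV", {
  res <- small_result()
  gml <- withr::local_tempfile(fileext = ".graphml")
  ecsv <- withr::local_tempfile(fileext = ".csv")
  write_network(res$network, edge_csv = ecsv, graphml = gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(res$network$edges))
  expect_equal(sum(igraph::E(g)$weight), sum(res$network$edges$weight))
  back <- readr::read_csv(ecsv, show_col_types = FALSE)
  expect_equal(sum(back$weight), sum(res$network$edges$weight))
})
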