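---
title: "Quantifying marine introduction pathways from vessel-tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying marine introduction pathways from vessel-tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voyagenet)
library(dplyr)
```

## The problem

Hull biofouling is a leading vector for marine non-native species
introductions into remote, high-endemism coastal ecosystems. Absent direct
hull surveys, the introduction threat a fleet poses can be approximated from
vessel *behaviour* and *design*: how many vessels come, how much submerged
hull area (Wetted Surface Area, WSA) they carry, how long they sit at anchor
(settlement and release opportunity), how many distinct anchorages they
connect, and how often they cross jurisdictional and biogeographic
boundaries. `voyagenet` turns raw AIS-style position streams into exactly
these quantities: stationarity-classified hourly tracks, stop events,
clustered anchorage nodes, a directed voyage network, per-vessel WSA, and
per-class / per-location threat-factor tables.

Because real AIS feeds are commercially confidential, the package pairs the
pipeline with a synthetic fleet simulator that emits AIS streams from a known
ground-truth itinerary, so every stage can be verified by truth recovery
rather than by eyeballing maps.

## The processing model

**Hourly resolution.** Position reports are reduced to at most one point per
vessel per clock hour (the last report in each hour bin, stamped to the bin
hour), which bounds data volume while preserving movement structure.
Sequential point-to-point displacements are great-circle (haversine)
distances on a sphere of radius 6371 km.

**Stationarity.** A point is stationary when it moved less than 400 m over
the preceding hour (equivalent to ~0.2 kn, the conventional transit-
simplification threshold: `stationary_speed_equivalent_kn()` returns
400/1852 = 0.216 kn) *and* its reported speed is below 1 kn. Requiring both
conditions means a corrupt position or a corrupt speed field alone cannot
misclassify a point. Across reporting gaps longer than an hour the
displacement is not comparable against an hourly threshold, so the speed
condition decides alone and the point is flagged `gap`.

**Vessel selection.** Only vessels that enter the maritime-zone polygon
(200 nm limit by default) are analysed; retained vessels keep their entire
track, including points outside the zone.

**Stops and nodes.** Maximal runs of stationary points become stop events;
the duration is the span from first to last stationary point, and a single
isolated stationary point counts one sampling interval (1 h), since hourly
sampling cannot resolve shorter stops. Stops within 12 nm of land are
clustered into anchorage nodes by single linkage: stops whose 5 km buffers
overlap (pairwise distance at most 10 km) join one node. The published
method names the buffer but not the merge rule; transitive single linkage is
this package's documented choice (`node_buffer_km` is configurable) and is
permutation-invariant. Buffer geometry can equivalently be evaluated in a
local azimuthal equidistant projection; at anchorage scales planar and
great-circle distances agree within a metre (`aeq_project()` is tested
against the haversine path), so the great-circle form is used throughout.
Nodes take the nearest gazetteer port name within 5 km of the centroid, else
a synthetic identifier, and are assigned a country/territory code by polygon
lookup (with `UNKNOWN` fallback).

**Declared origins.** When a vessel declares a port of origin that lies
outside the area of interest, an external node is added and a zero-duration
origin marker is prepended to its event sequence. Origin markers create
network links into the region but never count as visits or stop time
(`origin_counts_as_visit = false` semantics); external nodes have no
out-edges because no track data exist for them.

**Journeys.** An extended journey is a consecutive multi-stop voyage bounded
by rests longer than one month (>30 days by convention; configurable). The
long rest terminates the journey in progress and its location seeds the
next. Rests are excluded from the stops-per-journey count: they are the
boundaries of voyages, not ports of call within them. This bookkeeping makes
the generator's stops-per-journey parameter exactly recoverable and keeps
"stops during an extended journey" aligned with its natural reading.

**Network.** Each ordered pair of consecutive distinct nodes in a vessel's
event sequence adds one trip to that directed edge's weight; re-anchoring at
the same node is a visit, not a self-edge ("port-to-port route" implies
distinct endpoints). Node size is total visits; `in_links`/`out_links` count
distinct neighbouring nodes, not edge weights.

**WSA.** Large-vessel hull area follows the power-law family
`WSA = a * DWT^b` per category, with breadth-overall regressions as the
fallback for fishing / tugs-and-supply / passenger categories when DWT is
missing, and length-overall for the "Other" (research vessel) category.
Pleasure craft under 26 m use the Denny-Mumford small-craft formula
`WSA = 1.7 * L_OA * T + V/T`; larger pleasure vessels use the fishing-vessel
regression; every tender takes the fixed 9.9 m² small-craft constant
regardless of recorded dimensions. Dispatch is total: a vessel either gets a
result with an audited `method`, or a typed error naming the missing
dimensions. The packaged coefficient CSV carries *synthetic illustrative*
(a, b) values in the published structure — the original regression constants
are not reprinted here — and all formula tests parameterise over the table,
so substituting a calibrated CSV changes results, not correctness.

**Summaries.** Per-class metrics (vessel number, cumulative WSA of distinct
hulls, journeys per vessel, stops per journey, mean stop time per event,
distinct countries of origin, trans-national trips per vessel) are computed
per study year and averaged across years, with SE = sd(yearly values)/√n;
for two years this is |y1−y2|/2. Stop time includes rest events — observed
fleets show multi-month stationary periods and these are real settlement
opportunity — while stops-per-journey excludes them, as above. Monthly visit
profiles attribute each stop event to its start month (events rarely span
month boundaries at these durations) and zero-fill all 12 months so the
month partition conserves yearly totals. Location factors aggregate visits,
anchor-hours, per-visit cumulative WSA, degree and vessel-type diversity per
node; the published presentation is a qualitative heat map, so the ranking
here is an explicit, documented composite — the mean of per-factor ranks,
ties broken by visits.

## The synthetic fleet: what it emulates, and what it does not

`fleet_config()` defaults encode a nine-class fleet with the observed
structure of sub-Antarctic traffic: ~100 vessels active per year, dominated
by passenger vessels (26/yr) and fishing vessels (20/yr) plus their tenders
(25), a handful of bulk/tanker/cargo/pilot vessels; about two extended
journeys per vessel per year separated by 35–90 day port rests; many short
stops per passenger journey (57.5 on average, ~4 h each) versus few long
fishing stops (11.4 per journey, 71.4 h mean); spring-only tankers and
cargo; and tenders tied to a mother ship, going ashore only during the
mother's longer calls. Journey and stop counts are drawn by stochastic
rounding (floor plus a Bernoulli on the fractional part), so integer-mean
parameters are hit exactly and fractional means are unbiased. Stop durations
are log-normal (sdlog 0.6) about the class mean — the published ranges give
no distributional form, so this is a free modelling choice — truncated below
the rest threshold, because an in-journey dwell longer than a month *is* a
rest by definition. Every journey calls at least once in the focal territory,
mirroring a fleet selected by zone entry.

Tracks are emitted on the hour: coincident moored reports (thinned to
6-hourly for stops longer than 48 h, emulating reduced reporting at anchor)
and great-circle-interpolated underway reports at the class cruise speed.
With the default zero positional jitter, stationarity classification
recovers the truth log *exactly* — every emitted stationary span maps to
exactly one truth stop — which is what makes 100% recovery a meaningful
test. Optional Gaussian jitter and record dropout exist for robustness
exploration but default to 0.

What the simulator does **not** emulate: weather and ice routing, port
congestion, hydrodynamics, AIS identity errors, mid-ocean loitering, or
seasonal *within-window* structure (journey starts are uniform over each
class's season months, and rest-duration constraints can push later
departures past the window, so the busiest synthetic month falls somewhere
inside or shortly after the dominant class's window rather than at any
particular calendar peak). Passing recovery tests
therefore demonstrates that the pipeline's bookkeeping is correct under the
stated statistical structure, not that real traffic looks like the
simulation.

The port catalog, coastline rings and territory boxes are synthetic: ports
approximate real South Atlantic anchorage locations but are nudged so all
pairs are at least 25 km apart, making the node-recovery comparison
unambiguous (clusters cannot straddle ports at a 10 km link distance).

## Numerical choices and degenerate inputs

* Longitudes are normalised to (−180, 180]; the area of interest does not
  cross the dateline, so the bounding-box test needs no wraparound logic.
* 12 nm = 22.224 km exactly (1 nm = 1852 m); distance to land is the
  great-circle distance to the nearest coastline ring edge, 0 inside a ring.
* Single-linkage clustering runs on exact-deduplicated coordinates via a
  full distance matrix; above 4000 unique positions it first collapses
  points onto a grid whose cell diagonal is below the link distance (cell
  co-members are provably co-clustered under single linkage, inter-cell
  linkage then uses representatives).
* Gazetteer label ties are broken alphabetically; node identifiers are
  ordered by centroid coordinates, so output is independent of input order.
* Zero-length transits (consecutive calls at identically-located ports)
  interpolate to a repeated position rather than erroring.
* Malformed AIS rows (unparseable time, |lat| > 90, negative speed) are
  dropped and counted, never silently fixed. A missing schema column is an
  error naming the column.
* Vessels with no usable hull dimension raise a typed error listing what was
  absent; there is no silent WSA default.

## Problem sizes

The default two-year, 103-vessel configuration emits ~650,000 position
records and ~10,000 stop events; generation plus the full pipeline completes
in a couple of minutes on a single core. The test suite exercises a 1-year
13-vessel fixture and a 1-year 22-vessel, nine-class acceptance fleet,
chosen to keep the whole suite under half a minute while still covering
every class and both recovery properties at 100%.

## Worked example

```{r example, eval = FALSE}
cfg <- fleet_config(n_years = 1, seed = 7,
  vessels_per_class = c(Bulk = 1, Cargo = 1, Fishing = 2, Offshore = 1,
                        Passenger = 2, Pilot = 1, Pleasure = 2, Tanker = 1,
                        Tender = 2))
sim <- simulate_fleet(cfg)
res <- run_pipeline(sim$records, sim$profiles, cfg)

res$log$n_events            # stop events recovered
degree_summary(res$network, top_n = 5)
res$type_summary |> dplyr::filter(metric == "cumulative_wsa")
```

## Known limitations

* The shipped WSA coefficients are placeholders with the correct structure;
  absolute WSA values are only meaningful after substituting calibrated
  regressions.
* Stop time per class mixes port calls and long rests; a per-journey or
  rest-excluded variant is a two-line filter on the event table if needed.
* The external-origin augmentation records only the declared port; true
  intermediate calls between that port and zone entry are invisible to the
  method, as they are to any single-feed AIS analysis.
* Country assignment is polygon-table-driven; overlapping or disputed
  jurisdiction polygons resolve to the first match in table order.
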