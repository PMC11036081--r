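# voyagenet

Vessel-movement network analysis for marine biological invasion pathways.

## What this package is for

Remote coastal ecosystems with high endemism face a growing threat from
non-native species carried on vessel hulls (biofouling). When hull condition
cannot be surveyed directly, introduction likelihood must be approximated
from vessel *behaviour* and *design*, measured from vessel-tracking (AIS)
position streams. `voyagenet` is a tested pipeline for exactly that,
aimed at biosecurity analysts and movement ecologists:

1. **Ingest & clean** — parse AIS-style CSV records, reduce to hourly
   resolution, keep only vessels that entered a maritime-zone polygon, and
   classify each hourly point as stationary or underway using a
   two-condition rule: displacement < 400 m over the hour (≈ 0.2 kn) **and**
   reported speed < 1 kn.
2. **Stops & anchorages** — collapse stationary runs into stop events;
   cluster stops within 12 nm of land into anchorage *nodes* (single
   linkage at a 5 km buffer, i.e. centres ≤ 10 km apart merge); label nodes
   from a port gazetteer and assign country/territory codes; add external
   nodes for declared ports of origin outside the area of interest.
3. **Journeys & network** — segment each vessel's stop sequence into
   extended journeys bounded by rests > 1 month; build a directed voyage
   network where node size is total visits and edge weight is the frequency
   of unique vessel trips per port-to-port route.
4. **Hull wetted surface area (WSA)** — per vessel, by class:
   `WSA = a·DWT^b` power laws (with B_OA / L_OA fallbacks when DWT is
   missing), the Denny–Mumford small-craft formula
   `WSA = 1.7·L_OA·T + V/T` for pleasure craft under 26 m, and a fixed
   9.9 m² constant for tenders.
5. **Threat surfaces** — annual per-class mean ± SE tables (vessel numbers,
   cumulative WSA, journeys, stops per journey, stop time, countries of
   origin, trans-national trips), monthly visit profiles, ranked
   per-location factor tables, and initial-entry ("first port of call from
   abroad") counts per node.

Because real AIS feeds are confidential, the package includes a **synthetic
fleet simulator** (`fleet_config()`, `simulate_fleet()`) that emits AIS
streams from a known ground-truth itinerary of nine vessel classes with
class-specific abundance, sizes, journey structure, stop durations and
seasonality. Every pipeline stage is verified by recovering that truth log
exactly (100% of stops, journeys and edge weights under noise-free
settings).

## Worked example

```r
library(voyagenet)
library(dplyr)

cfg <- fleet_config(n_years = 1, seed = 7,
  vessels_per_class = c(Bulk = 1, Cargo = 1, Fishing = 2, Offshore = 1,
                        Passenger = 2, Pilot = 1, Pleasure = 2, Tanker = 1,
                        Tender = 2))
sim <- simulate_fleet(cfg)             # profiles + truth log + AIS records
res <- run_pipeline(sim$records, sim$profiles, cfg)

res$log$n_events
#> [1] 533                              # stop events, equal to the truth log

degree_summary(res$network, top_n = 3)
#> # A tibble: 3 x 7
#>   node_id label             country is_external total_visits in_links out_links
#> 1 N007    King Edward Point SG      FALSE                 91       11         9
#> 2 N003    Ushuaia           AR      FALSE                 76       11        10
#> 3 N008    Stromness Bay     SG      FALSE                 67        9         9

res$entry_points |> head(3)
#> # A tibble: 3 x 2
#>   node_id n_entries
#> 1 N007           10                   # most first-ports-of-call from abroad
#> 2 N009            3
#> 3 N004            2
```

The busiest node (here the customs port King Edward Point) accumulates the
most visits, the most inward links and the most initial entries from other
territories — the profile of a dispersal hub that would be prioritised for
benthic and hull monitoring. `res$type_summary` holds the per-class annual
mean ± SE table, `res$location_factors` the ranked per-location factors, and
`write_pipeline_outputs(res, "out/")` writes the CSV/GraphML/GeoJSON bundle.
A thin CLI for both steps lives at `inst/cli/pathways.R`
(`simulate` / `run` subcommands).

Note the packaged WSA coefficient table
(`inst/extdata/wsa_coefficients_synthetic.csv`) carries illustrative values
in the published structure; substitute a calibrated CSV via
`wsa_coefficients(path)` for real absolute WSA figures.

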