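# pacsac

Parcel-level built-environment indices over adjacency-community moving
windows.

## What this package is for

Systematic social observation (SSO) audits record the condition of the
residential built environment — boarded windows, litter, security signage,
vacancy — one tax parcel at a time, across an entire urban study area.
Turning tens of thousands of parcel-level presence/absence observations
into neighborhood-scale measures that can be linked to health and
administrative data requires three things this package provides:

1. **A validated variable registry.** The audit instrument is a schema of
   79 variables: 53 assessed on every parcel and 26 assessed in public
   spaces, partitioned into disjoint domains — housing damage (13
   variables), property disorder (14), territoriality (6), vacancy (3),
   public-space nuisances (26), plus miscellaneous descriptors. Features
   assessed both on parcels and in public spaces (e.g. high weeds) are two
   distinct variables, one per applicability.

2. **Adjacency-community moving windows.** Census blocks are small and
   block groups ignore neighborhood boundaries, so indices are aggregated
   over *primary* and *secondary adjacency communities*. Blocks are
   adjacent under queen contiguity — they share a boundary segment and/or a
   corner vertex, detected with a snap tolerance for imperfect boundary
   files. The PAC of a block is the block plus all adjacent blocks (the
   graph ball of radius 1); the SAC adds every block adjacent to the PAC
   (radius 2). Unlike block groups, PACs and SACs overlap: each block gets
   its own window, a moving-window smoothing of the block lattice.

3. **Seven neighborhood indices at three scales.** For each block, PAC and
   SAC: counts of housing-damage, property-disorder and territoriality
   presences; vacant parcels (unoccupied or demolished parcels and vacant
   lots); public-space nuisances; renter-occupied parcels (tenure, called
   by scoring the match between each parcel's situs address and its owner's
   mailing address); and crime incidents assigned to blocks by
   point-in-polygon and classified into violent / property / vice / theft /
   vehicular / total. Window values are sums over member blocks, so
   block ≤ PAC ≤ SAC for every count index; per-parcel rates are emitted
   alongside for fair cross-scale comparison. Between-index correlation
   matrices are computed per level.

The package also implements one-way random-effects intraclass correlation
(single-rater and average-of-k forms, related by the Spearman–Brown
identity, with F-based confidence intervals) for multi-rater reliability
studies, and a seeded synthetic city generator with known ground truth for
every stage.

## Worked example

```r
library(pacsac)

reg <- default_registry()
reg
#> Built-environment variable registry (version be_variables.csv)
#> 79 variables: 53 parcel, 26 public-space
#>    housing_damage     13
#>    property_disorder  14
#>    territoriality     6
#>    vacancy            3
#>    nuisance           26
#>    miscellaneous      17

# a seeded synthetic city: 5 x 5 grid of blocks, 18 parcels per block
city <- generate_city(synth_config(grid_nx = 5, grid_ny = 5, seed = 42))

parcels   <- assign_parcels_to_blocks(city$parcels, city$blocks)
nuisances <- assign_parcels_to_blocks(city$nuisances, city$blocks)
tenure    <- classify_tenure(parcels)              # situs vs owner address
crime     <- aggregate_crime(city$crimes, city$blocks)

graph <- build_adjacency(city$blocks, tolerance = 1e-6)
graph
#> adjacency_graph: 25 blocks, 72 queen-contiguity edges (snap tolerance 1e-06)

community_window(graph, "B0303", 1)
#> PAC window of B0303: 9 member block(s)

idx <- build_index_table(parcels, nuisances, tenure, crime,
                         graph, reg, city$blocks)
subset(as.data.frame(idx), block_id == "B0303" & index == "housing_damage")
#>     block_id level          index value n_parcels      rate
#> 38     B0303 block housing_damage     6        18 0.3333333
#> 213    B0303   pac housing_damage    55       162 0.3395062
#> 388    B0303   sac housing_damage   132       450 0.2933333
```

The interior block `B0303` has 6 housing-damage presences among its own 18
parcels; its PAC (9 blocks, 162 parcels) accumulates 55 and its SAC (25
blocks, 450 parcels) 132. Counts grow mechanically with window size — the
`rate` column (presences per parcel) is the scale-comparable companion and
becomes *less* spatially variable as the window widens, which is the point
of the moving-window construction.

```r
round(correlate_indices(idx, level = "pac"), 2)   # 7 x 7, symmetric, unit diagonal
```

A full pipeline (read GeoJSON blocks and CSV inputs, write every stage and
a manifest) is available as `run_pipeline(run_config(...))` or from the
shell via the installed script:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "pacsac", package = "pacsac"))') \
  run --blocks blocks.geojson --parcels parcels.csv --out-dir out/
```

## Scope notes

The package computes indices and their correlation structure; it does not
geocode addresses, render maps, or link indices to health outcomes. The
offense-label-to-category mapping shipped as a default is illustrative and
should be replaced with the jurisdiction's own mapping in any real
deployment. Sidewalk segments are modeled as data (broken/obstructed
polylines) but no sidewalk index is defined.
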