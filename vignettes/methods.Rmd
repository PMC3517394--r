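---
title: "Methods: indices, adjacency communities, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indices, adjacency communities, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacsac)
```

This vignette is the package's own account of its methodology: what each
component computes, which parameters matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the design choices made where the design was genuinely open.

## The observation model

A parcel audit records, for every tax parcel visible from the public right
of way, the presence (1) or absence (0) of each instrument variable —
deliberately *not* an ordinal scale, because graded judgments are a known
source of inter-rater inconsistency in systematic social observation. The
registry (`default_registry()`) encodes this instrument: 53
parcel-applicable variables and 26 public-space nuisance variables, each
assigned to exactly one domain. The domains are disjoint by construction;
where the same physical feature is assessed on both private parcels and in
public space (high weeds, broken glass, litter, discarded items), the two
contexts are two distinct variables. Free-text "other condition"/"other
nuisance" entries are text-valued and count as present when non-empty.
Enumerative descriptors (property type and sub-type, front entry type,
fence material, fenced area) are categorical and contribute to no count
index. Unobserved variables default to absent, mirroring a field interface
whose drop-downs default to "0 = No": a zero can mean *observed absent* or
*not recorded*, an ambiguity inherent to the instrument and worth
remembering when interpreting low prevalences.

## Adjacency communities

Census blocks are the anchor geography. Two blocks are adjacent under
**queen contiguity**: their boundaries share a line segment or a single
corner vertex. Real boundary files are imperfect — block and parcel layers
are digitized separately and misalign by small offsets — so contact is
detected with a **snap tolerance** (default `1e-6` map units): boundaries
closer than the tolerance are deemed touching. The default is effectively
"exact contact plus floating-point slack" for clean data; for misaligned
real files a tolerance on the order of the digitizing error (e.g. 0.1–1 m
in a metric projection) is appropriate. The tolerance is a user parameter
everywhere it matters. Coordinates are assumed planar/projected; GeoJSON
declaring WGS84 longitude/latitude is rejected unless explicitly
overridden, because a tolerance in degrees is a trap.

The **PAC** (primary adjacency community) of a block is the block plus its
queen neighbors — the graph ball of radius 1. The **SAC** adds all blocks
adjacent to any PAC member — the ball of radius 2, equivalently the union
of the PAC's members' PACs (an identity the test suite checks). Orders
above 2 are rejected rather than silently computed: the construction is
defined at three scales, and an accidental `order = 5` is more likely a bug
than an intent. Windows overlap — every block is the focus of its own
window — which distinguishes this moving-window smoothing from a partition
into block groups: each block's score reflects its surroundings even when
those surroundings lie in a different administrative unit.

Geometry is handled by purpose-built planar primitives (ring validation,
segment distances, even-odd point-in-polygon): polygon rings must be
closed, non-self-intersecting and of positive area, and invalid input is
rejected with the offending block named, rather than repaired. Multipart
blocks are adjacent when any part touches any part. Graph operations
(neighborhoods, balls) are delegated to igraph; the test suite checks both
against independent oracles (a closed-form rectangle-distance formula and a
hand-rolled breadth-first search).

## The seven indices

Block-level values are sums: presences per domain (housing damage, property
disorder, territoriality, nuisances), vacant parcels (occupancy unoccupied
or demolished, or a vacant lot by property type), renter-occupied parcels,
and crime incidents. Window values are sums over member blocks, so every
count index is monotone in window order and block-level sums conserve the
raw totals — two invariants the suite asserts on every seeded replicate.
Counts are the primary output because summation is the construction;
because counts grow mechanically with window size, per-parcel rates are
emitted alongside (`rate = value / n_parcels`), and are reported as missing
— never zero — for windows without parcels. The tenure index counts
renters (a count, like every other index); the renter *proportion* is
recoverable from the rate column.

Correlations between indices are computed across blocks within one level,
Pearson by default (Spearman by flag). A zero-variance index has no defined
correlation; its row and column are `NA` and it is flagged, never coerced
to 0. At PAC/SAC levels, overlapping windows induce strong positive
correlations among all count indices even for spatially independent data —
a mechanical consequence of shared members worth keeping in mind when
reading multi-scale correlation tables.

## Tenure classification

The audit's tenure measure is administrative: a parcel whose situs
(geographic) address matches its owner's mailing address is owner-occupied,
otherwise renter-occupied. The matching algorithm here is an auditable
token model, chosen because the decision must be tunable and explainable:
addresses are canonicalized (uppercase, punctuation stripped, directionals
and street types mapped to USPS-style abbreviations, unit designators
split off; canonicalization is idempotent), then scored by weighted
component agreement — street name 0.5 (Jaccard token overlap), house
number 0.2, directional 0.15, street type 0.15 — with the total capped at
0.2 when house numbers disagree, since a different house number on the same
street is a different property. The owner call requires score ≥ 0.85: high
enough that only house number plus street name agreement (0.7 + partial)
with near-complete component agreement passes, i.e. effectively "same
address up to formatting". Both the weights and the threshold are exposed
parameters. A missing owner address yields a renter call with score 0 (the
binary scheme has no "unknown"); `strict = TRUE` emits `unknown` instead so
such parcels can be excluded from the tenure index. Raising the threshold
can only convert owner calls to renter calls — monotonicity the suite
sweeps explicitly.

## Crime

Incidents arrive as points with free-text offense labels. Classification is
an exact case-insensitive lookup in a label-to-category mapping; the
packaged mapping is illustrative (offense terminology is
jurisdiction-specific) and user-replaceable. Unmapped labels become
`unclassified` with a warning. The `total` column counts every incident in
the block including unclassified ones — total is its own category, not the
sum of the others. Points on shared boundaries are assigned to the
lexicographically smallest containing block id: an arbitrary but
deterministic tie-break, applied identically to parcels and nuisance
points. Incidents outside all blocks are returned in an `unassigned`
attribute, never dropped.

## Inter-rater reliability

Reliability of the binary instrument is summarized by mean pairwise percent
agreement and the one-way random-effects intraclass correlation. The
one-way model treats targets (parcels) as the random factor and the k
ratings per target as exchangeable replicates — appropriate when the rater
panel is not itself of interest. With between-target mean square MSB
(df n−1) and within-target MSW (df n(k−1)):

- single-rater form: ICC(1) = (MSB − MSW) / (MSB + (k−1) MSW)
- average-of-k form: ICC(k) = (MSB − MSW) / MSB

connected by the Spearman–Brown identity ICC(k) = k·ICC(1) / (1 +
(k−1)·ICC(1)); confidence limits come from the F distribution on (n−1,
n(k−1)) degrees of freedom. The one-way reading is a deliberate choice: a
reliability design with 7 raters reporting a single-rater consistency
around 0.70 alongside an average-form value around 0.95 is exactly the
Spearman–Brown pair under this model (7·0.7/(1+6·0.7) ≈ 0.94), whereas
two-way forms require rater-effect assumptions the design does not
motivate. Degenerate matrices (zero total variance) are an error — an ICC
of a constant is undefined, not 1. Long-format ratings are summarized
per-variable and pooled ("ALL") by stacking per-variable target rows into
one matrix.

## The synthetic-data generator

`generate_city()` draws a complete, internally consistent input set with
recorded ground truth, governed by one integer seed (identical seeds give
byte-identical files). Its defaults are the package's reference study
conditions:

- **Geometry**: a 10 × 10 grid of square blocks, 100 map units on a side.
  A grid is the simplest geometry with nontrivial queen structure (interior
  PAC 9, SAC 25).
- **Parcels**: 18 per block, placed strictly interior (2% margin), matching
  the per-block parcel density of a city-scale audit (~17.6 parcels/block).
- **Prevalences**: per-variable Bernoulli probabilities spanning the
  observed range of a real audit — common amenities (driveways 0.753,
  greenery 0.635), mid-frequency disorder (yard litter 0.307, security
  signage 0.243), rare damage (foundation damage 0.002, private graffiti
  0.0014); unlisted variables default to 0.02. An optional per-block latent
  factor shifts prevalences on the log-odds scale via per-domain loadings,
  planting cross-index correlation for correlation-structure tests.
- **Tenure**: exactly `round(0.3 · n)` parcels are renters; their owner
  addresses are drawn from a packaged synthetic street-name corpus on a
  different street, so the classifier's recovery of the planted set is
  exact by construction — the test validates the plumbing, not the
  difficulty of real-world matching.
- **Crime**: per-block Poisson counts by category (means 0.5/1.0/0.3/0.8/0.4
  for violent/property/vice/theft/vehicular — a low-crime regime with ~3
  incidents per block), labels sampled from the packaged mapping.
- **Nuisance points**: Poisson(5) per block with their own prevalence set.

What the generator does *not* emulate: real parcel geometry (parcels are
points, not polygons), irregular block shapes and multipart blocks beyond
what the rectangle-layout tests cover, geocoding error, address formats
beyond the simple `number [directional] street type [unit]` grammar,
temporal structure in crime, missing data, and rater drift. Tests passing
on synthetic cities therefore demonstrate the correctness of the
aggregation machinery under known truth — not robustness to dirty
real-world inputs, which must be assessed per deployment.

`generate_ratings()` plants a true one-way ICC ρ by construction (target
variance ρ, noise variance 1 − ρ); optional thresholding to binary
attenuates it.

## Numerical and degenerate-input choices

- Snap tolerance default `1e-6` map units; tolerance 0 means exact contact.
- Boundary containment epsilon `1e-9` for point-in-polygon; ties broken by
  smallest block id.
- Registry name uniqueness is case-insensitive per applicability (the same
  display name may appear once per side of the parcel/public-space split).
- Empty inputs are well-defined: zero incidents give all-zero counts; empty
  blocks get zero rows, not missing rows; an empty address scores 0 against
  anything.
- Windows whose members lack block values are an error (no silent 0s);
  correlation with fewer than 3 blocks is an error.

## Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which each property is sharply testable:
grid cities of 5 × 5 (aggregation laws, 20 seeds) and 10 × 10 (smoothing,
20 seeds); 100 random 4 × 4 rectangle layouts for the adjacency oracle; 200
replicates of 200 × 7 rating matrices for ICC recovery (tolerance ±0.05
around the planted 0.70); a 20 × 20 × 25-parcel city for prevalence
recovery at a 4σ binomial tolerance. The smoothing check compares the
across-block coefficient of variation of per-parcel rates at block, PAC and
SAC levels with an absolute slack of 0.02, small relative to the ~3-fold CV
reduction that window averaging produces on stationary data.

## Known limitations

Adjacency construction is all-pairs with bounding-box pruning — fine for
thousands of blocks, not engineered for national-scale lattices. The
address grammar is US-centric. The offense mapping is illustrative. Tenure
matching cannot distinguish an owner using a PO box from a landlord, a
known bias of administrative tenure measures. And the index table treats
every variable with unit weight; no weighting or standardization scheme is
imposed beyond counts and per-parcel rates.
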