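---
title: "Classifying pharmacy deserts from block-level access"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pharmacy deserts from block-level access}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desertmap)
```

## The classification model

A *pharmacy desert* is a census tract that is simultaneously **low income**
and has **low spatial access** to a community pharmacy. `desertmap`
implements this two-indicator definition at the tract level, with census
blocks as the unit of areal interpolation.

**Low income.** A tract meets the criterion when either

* at least 20% of its population lives below the Federal Poverty Level
  (`fpl_threshold = 0.20`, inclusive: a tract at exactly 20% qualifies), or
* its median household income is strictly below 80% of the median income of
  the nearest metropolitan area (`metro_income_ratio = 0.80`).

The two arms form an OR. When exactly one arm's input is missing the other
is evaluated alone — an OR with one unknown arm is true if the known arm is
true, and we treat "unknown OR false" as false for classification purposes
while flagging the tract (`income_partial`) so downstream users can see that
only one criterion was evaluated. When both income fields are missing the
tract is *unclassifiable* rather than assumed either way.

**Low access.** Each tract is assigned an urbanicity class from its
population density \(d = \text{population}/\text{land area}\):
urban when \(d \ge 5000\) persons/sq mi, rural when \(d < 1000\),
suburban between. The class fixes an access radius of 1, 5, or 10 miles;
tracts with fewer than 100 car-owning individuals use a 0.5-mile radius
instead (the override *replaces* the class radius; a `"min"` mode that takes
the smaller of the two is available in the policy). The density cut-offs are
policy fields because published work varies in where it places them; the 5000
persons/sq mi urban threshold is the conventional suburban boundary used by
pharmacy-network adequacy standards, and 1000 persons/sq mi is a common
rural ceiling. If you have authoritative thresholds for your study area,
set them in `threshold_policy()`.

Coverage is evaluated by **areal interpolation at the block level**: a block
counts as covered when its centroid lies strictly within the tract's radius
of *any* pharmacy in the dataset (pharmacies in neighbouring tracts count).
The covered population is the sum of covered blocks' populations, and the
tract is low-access when more than one-third of its population
(`access_fraction = 1/3`, strict) lives outside every radius.

**Verdicts.** Every tract receives exactly one of five verdicts:

| verdict | condition |
|---|---|
| `desert` | low income AND low access |
| `low_access_only` | low access, not low income |
| `not_desert` | everything else classified |
| `unclassified_no_income` | both income fields missing, population > 0 |
| `unclassified_zero_pop` | zero population |

Degenerate cases take precedence: zero population wins over everything,
and missing income wins over access. This keeps the unclassified categories
mutually exclusive and makes the verdict counts a partition of the tract
count.

## Numerical conventions

* **Distance** is the haversine great-circle distance on a sphere of radius
  3958.8 miles. A spherical model differs from an ellipsoidal geodesic by
  under 0.3%, far below the precision at which 1/5/10-mile policy radii are
  meaningful. Internally all coordinates are (lat, lon) WGS84 decimal
  degrees; GeoJSON I/O converts to and from the standard's (lon, lat) order
  at the boundary.
* **Boundary strictness.** "Covered" means distance strictly less than the
  radius — a household living exactly one mile from the pharmacy is far from
  it. Similarly "low access" means strictly more than the access fraction.
  Both conventions are pinned by unit tests; the access fraction and its
  strictness are policy fields because the definition is sometimes quoted as
  "at least 33%".
* **Zero-population blocks** contribute to neither the covered nor the
  uncovered population; their coverage status is irrelevant, mirroring
  population-weighted interpolation.
* **Nearest metro** is the metro minimising great-circle distance from the
  tract's population-weighted block-centroid mean (unweighted mean for
  zero-population tracts), with exact ties broken by lexicographic
  `metro_id`. How the original analysis assigned metros (distance,
  state containment, or a CBSA crosswalk) is not documented; nearest-by-
  distance is this package's documented stand-in, and it is deterministic.
* **Spatial index.** Coverage queries run through a latitude-sorted index
  with a conservative bounding-box prefilter followed by exact haversine
  tests, so indexed results are *identical* to a brute-force scan (verified
  exhaustively in tests on 200-block × 50-pharmacy geographies).
* The classifier stays agnostic about whether the supplied population field
  counts all persons or adults only; it classifies whatever population the
  tables carry.
* Tracts with population > 0 but no blocks on file cannot be interpolated;
  the readers flag them, and the classifier treats their population as
  uncovered with a warning rather than guessing.

## Group comparisons

`compare_groups()` reproduces the two descriptive tables: tract-population
characteristics and pharmacy characteristics, for deserts versus classified
non-deserts (the comparison group excludes unclassified tracts, so group
sizes sum to the classified count). Continuous characteristics use
*unweighted* tract-level means and SDs — each tract counts once regardless
of population — and a two-sample t test; Welch is the default since nothing
justifies assuming equal variances, with the pooled variant available.
Categorical families (urbanicity, pharmacies-per-tract binned 0/1/2+,
pharmacy ownership, each service flag) use Pearson chi-square tests of
independence without continuity correction (group sizes in this design make
the correction immaterial). Service flags may be unknown for a pharmacy;
unknowns are excluded from that flag's counts and denominators rather than
treated as "no".

P-values are Benjamini–Hochberg corrected. Each characteristic family
contributes one p-value to the BH family no matter how many levels it
displays. The default correction family spans *both* tables jointly —
the analysis's correction statement does not specify a family structure, and
the joint family is the conservative reading — with `bh_family =
"per_table"` available.

## What the synthetic generator emulates

`generate_region()` builds regions whose ground-truth verdicts are known by
construction, which is what makes every downstream stage testable without
any census download:

* Tracts sit on a grid with 30-mile spacing so no pharmacy radius can reach
  a neighbouring tract; each tract's truth is therefore local.
* Mile offsets become degree offsets via the local metric at the tract's
  latitude; latitudes stay below 60° so the distortion stays far inside the
  planted margins.
* Densities are drawn strictly inside the intended band (e.g. urban tracts
  at 1.1–2× the urban threshold), so urbanicity truth is forced.
* Coverage is planted with margin: covered blocks sit at ≤ 0.90 r from the
  tract-centre pharmacy, uncovered blocks at ≥ 1.05 r. No block is ever
  within 5% of a radius boundary, so classification is stable under
  coordinate round-tripping through CSV/GeoJSON.
* Partial coverage places a block subset holding a target fraction of the
  tract population outside the radius; the achieved fraction must land at
  least 0.02 from the access fraction on the intended side or generation
  fails. With equal block populations and a round target the fraction is
  exact. The defaults use 0.5 (above the one-third cut) and 0.25 (below).
* Income truth is planted at least 0.02 from the poverty threshold and 2
  percentage points of ratio from the relative-income threshold, against the
  metro the classifier itself will select.
* Block populations are log-normal (median 400 persons, log-sd 0.6) with
  4–10 blocks per tract, giving tract populations around the few-thousand
  scale of real census tracts.
* Tract demographics are drawn from the desert and non-desert mean/SD
  profiles reported in the published national tabulation, so planted deserts
  show the direction and rough magnitude of the published contrasts;
  pharmacy ownership and service-flag profiles likewise.

The generator deliberately does **not** emulate: real geography or
adjacency (tracts are isolated by construction, whereas real tracts share
pharmacies across boundaries — the classifier handles this, the generator
just doesn't exercise it at scale), spatial autocorrelation of demographics,
road networks or travel time (the access model is straight-line distance by
design, a named limitation of the underlying method), and realistic
pharmacy-per-tract count distributions. Passing the truth-recovery suite
therefore demonstrates that the pipeline implements the stated definition
exactly, not that the definition captures real-world access.

## Problem sizes used by the test and acceptance suites

The suites were sized to exercise every condition while staying quick:
truth recovery runs 20 regions of ~19–20 tracts spanning all three
urbanicity classes, partial-coverage fractions on both sides of 1/3,
low-vehicle overrides, zero-population and missing-income tracts; oracle
equivalence uses 200 query points × 50 pharmacies × 4 radii; monotonicity
runs 120 randomized trials; BH calibration runs 200 null replicates of a
15-row family (the empirical significant-row rate lands well under the
α = 0.01 target). The statistical cross-checks compare against
textbook-formula references at 1e-10 relative tolerance on 100 random
inputs each.

## Known limitations

* Straight-line distance, not travel time; urbanicity via density, not
  land-use classification.
* The relative-income arm depends on the metro table you supply and on the
  nearest-by-distance stand-in described above.
* National headline figures (total desert population and tract counts)
  require the full proprietary pharmacy file and census extracts; this
  package reproduces the *method* and the in-table arithmetic, not those
  inputs.
* GeoJSON export writes polygons only when you supply them; classification
  itself never uses polygon geometry, only block centroids.
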