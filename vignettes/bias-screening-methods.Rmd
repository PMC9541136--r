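---
title: "Screening occurrence records for sampling bias: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening occurrence records for sampling bias: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occbias)
```

## Why screen, and what a screen can say

Estimates of temporal biodiversity trends are statistical inferences from a
sample — the occurrence records in hand — to a target population: all the
places, times and taxa the study claims to speak about. When the sample is
opportunistic, its coverage of that population is uneven and, worse, the
unevenness changes over time, so a trend in the data can reflect a trend in
*recording* rather than in nature. `occbias` implements quantitative
*heuristics* for this risk. We use that word deliberately: without a
probability sample for comparison, the exact magnitude of bias is not
identifiable, so each statistic indicates *potential* for bias rather than
measuring it. Consequently the assessment document that the package builds
never converts a heuristic into a verdict; bias flags are booleans set by
the assessor, with the heuristics attached as evidence.

Everything is computed relative to a declared `target_population()`: a
geographic extent (bounding box or polygon), an inclusive year range, a
target taxon list, and the grain sizes — grid-cell edge in decimal degrees
and temporal bin width in years — at which both analysis and assessment
happen. Grain matters: data that look unbiased in decadal bins and 1° cells
may be badly biased at yearly/1-km grain, so `validate_assessment()` raises
a prominent warning whenever the assessment grain differs from the declared
inference grain.

## Gridding and temporal binning

Cells are half-open squares `[edge, edge + res)` anchored at a configurable
origin, default (−180, −90), so cell identifiers are reproducible and
independent of the data; a coordinate exactly on an edge belongs to the cell
whose lower edge it equals. Temporal bins partition the year range into
consecutive `width`-year bins labelled `p1, p2, …`; the final bin may be
truncated by the end year (1950–2019 in decades gives a full `p7` =
2010–2019; 1950–2020 would add a one-year `p8`). Records are excluded from
the population with a fixed precedence — geography, then time, then taxon —
so exclusion tallies are deterministic, and the invariant
`input = retained + Σ excluded` is enforced. Coordinates are treated as
planar degrees for binning; no CRS transformation is attempted beyond WGS84
degrees.

## The nearest-neighbour index

For one temporal bin with at least two records, the observed statistic is
the mean distance from each record to its nearest neighbouring record.
Distances are Euclidean in degrees by default — adequate for screening at
regional extents, though degrees compress east–west with latitude; a
haversine (km) option exists for extents where that distortion matters. The
reference value is the mean of the same statistic over `n_ref_sims`
(default 99) simulated datasets of the same size placed uniformly over the
declared extent, with rejection sampling inside polygons. Simulation, rather
than the closed form, defines the reference because it handles polygon
extents and edge effects implicitly; the closed-form Clark–Evans ratio
`R = 2 d̄ √(n/A)` (no edge correction) is kept as an independent oracle, and
the two routes agree within ±0.05 on rectangular CSR data in the test suite.
Duplicate coordinates are legitimate in aggregated data and contribute a
nearest-neighbour distance of 0; a bin of coincident points therefore has
index 0, and bins with fewer than two records yield an explicit undefined
result with a reason rather than being skipped — thin periods are exactly
what an assessment must report.

### Bootstrap uncertainty

The interval is a percentile bootstrap (default 199 resamples, level 0.95)
with the record as the resampling unit and the CSR reference held fixed per
bin. What is resampled is each record's nearest-neighbour distance as
computed on the full pattern, not the point set itself: recomputing
distances on a with-replacement resample manufactures exact duplicates
(about 37% of points), whose zero distances drag every resampled mean far
below the estimate and destroy the interval's calibration. Resampling the
per-record distances keeps the interval centred on the estimate; on CSR
data the intervals cover 1 at roughly the nominal rate (property-tested).
This bootstrap ignores the weak dependence among nearest-neighbour
distances, so coverage is approximate — acceptable for a screening band
whose job is to show whether departures from 1 are larger than sampling
noise.

Per-bin random streams are derived deterministically from one user seed, so
a fixed seed reproduces every number bit-for-bit.

## Map and coverage heuristics

The periods-sampled map counts, per cell, the distinct bins with at least
one record: a transient recording footprint shows up as a map dominated by
low counts. The density surface gives integer counts per cell per bin with
a log10 display transform (zero-count cells are absent, never −Inf).
Coverage overlap between two bins is the Jaccard similarity of their
sampled-cell sets; taxon turnover applies the same Jaccard (one shared
implementation, property-tested against brute-force set arithmetic) to
recorded taxon sets. Taxonomic coverage per bin is the fraction of the
declared taxon list with records; evenness of record shares is Pielou's
`H′/ln S`, 1 when recorded taxa are evenly represented and undefined below
two taxa. Records for taxa outside the declared list, and records in cells
without covariates, are tallied and reported, never silently dropped.

Environmental coverage is summarized at the cell level: the user supplies
one covariate vector per cell, each axis is cut into equal-width bins
(default 5; quantile binning optional) over the domain's realized range,
and coverage is occupied joint bins divided by the joint bins realized by
the domain's cells. The realized-bin reference was a deliberate choice:
climate combinations that nowhere exist in the domain should not count as
uncovered space. With equal-width binning on this reference, refining the
bins does not raise coverage on the fixture tables used in the tests,
though this is not a theorem for arbitrary configurations (a coarse bin can
split into several occupied fine bins); the default of 5 bins per axis is a
conventional compromise between resolution and sparsity.

## The assessment document

The document has a fixed schema asserted on every construction and parse:
17 questions — four on scope, inferential goal, provenance and cleaning;
one resolution statement; and representativeness / temporal-consistency /
mitigation triples for the geographic, environmental and taxonomic domains
plus an other-biases triple (ids 1.1–1.4, 2.1–2.13). Prompts live in an
editable text resource (`inst/extdata/question_prompts.csv`) with stable
ids, because checklist wording evolves; the prompts shipped here are
paraphrases, flagged as such in the resource. Validation is pure and
structural: it lists unanswered questions and subsections where a bias flag
is set but the mitigation answer is empty and no not-relevant justification
exists — assessors are not required to explain poor coverage that is
irrelevant to their inference, but they must say so explicitly.

Assessments iterate: screening often reveals that an extent should shrink
to its well-sampled portion, which changes the population and requires
re-assessment. `next_iteration()` therefore produces a new version with a
recorded reason, a field-level diff of any population change, and an
immutable snapshot of the prior version embedded in the chain. The on-disk
format is nested key–value plain text (YAML), chosen to be human-diffable
under ordinary version control, and serialization is canonicalized so that
serialize → parse → serialize is byte-identical. Rendering (Markdown or
HTML) uses one deterministic block structure — research statement,
resolutions, provenance, the four domain subsections in fixed order,
version history newest-first — with evidence artifacts listed, and images
embedded, under the questions they support.

## The bias simulator

The simulator is the package's validation instrument: it generates datasets
whose bias is known by construction, standing in for real aggregated
downloads. Three spatial modes cover the failure modes the heuristics
target. *CSR* places points uniformly — the null, with index ≈ 1.
*Clustered* is a Thomas-style process: Poisson parents over the domain,
records placed Gaussian around uniformly chosen parents; points falling
outside the domain are redrawn rather than clipped, keeping realized n
exact, which simplifies calibration tests at the cost of slightly inflating
density near edges. *Drifting window* confines each bin's points to a
sub-rectangle of fixed area fraction (aspect preserved) that translates by
a fixed offset per bin, clamped to the domain edge with a warning — the
cleanest generator of space–time confounding, since every bin looks locally
fine while endpoint coverage is disjoint. Per-bin counts are Poisson around
an expected count with optional effort multipliers (recording effort in
real schemes grows over decades); taxa are assigned independently of
location from normalized preference weights; years are uniform within each
bin. `scenario_expectations()` states, before data are drawn, the direction
each heuristic should move, and the test harness checks generated data
against those signatures.

What the simulator does not emulate — and what passing tests therefore do
not show about real data: road- and settlement-following observer
behaviour, list-length and effort-per-visit structure, detection
probability varying by taxon or habitat, taxon preferences that depend on
location, and coordinate error. Calibration on these mechanisms says the
heuristics detect the *kinds* of distortion they target, not that they
detect every distortion in a given real dataset.

## Numerical choices and problem sizes

Defaults: 99 CSR reference simulations and 199 bootstrap resamples per bin
at level 0.95 (odd counts make percentile quantiles land on order
statistics); 1° cells anchored at (−180, −90); decadal bins; 5
environmental bins per axis; Euclidean degrees. Undefined results (fewer
than two records; empty-vs-empty set comparisons) are explicit values with
reasons. The calibration experiments shipped with the package use 50
replicate CSR datasets of n = 500 on the unit square for the mean-index
check (tolerance ±0.05 around 1, a pre-registered Monte-Carlo band), n =
1000 for the analytic-oracle comparison, and 20 replicate seeds for
injected-bias recovery — sizes chosen so the full suite runs on a single
CPU in about a minute while keeping Monte-Carlo error well inside the
stated tolerances.

## Known limitations

Planar-degree distances distort at high latitudes and continental extents;
use the haversine option there. The nearest-neighbour index summarizes
small-scale clustering only — a perfectly even *but sparse* sample scores
≈ 1, and regular survey lattices score > 1, so the index must be read
alongside the maps. Environmental coverage inherits the cell grain: within-
cell environmental variation is invisible. The Jaccard overlap treats all
cells equally regardless of record counts. None of the heuristics corrects
bias; mitigation (thinning, bias covariates, extent restriction) is the
assessor's decision, recorded in the mitigation questions with its
justification.
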