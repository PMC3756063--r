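---
title: "Quantifying revertant fibers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying revertant fibers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revfiber)
```

This vignette is the package's account of its science: what is being
estimated, under which assumptions, which parameters matter, what the
synthetic cohorts do and do not emulate, and where we made judgment
calls.

## The measurement problem

Dystrophin-null muscle (DMD patients, the *mdx* mouse) shows sporadic
dystrophin-positive "revertant" fibers (RFs), thought to arise from
epigenetic splicing alterations in individual satellite cells whose
progeny then seed dystrophin-competent fibers. Two observations shape
the analysis. First, RF counts vary enormously — between muscles,
between age groups, and between animals of the same age (standard
deviations comparable to means). Second, a revertant segment extends
only 100–300 µm (occasionally up to 900 µm) along the fiber, so with
9-µm sections cut ~120 µm apart the *same* physical fiber can surface
in several neighbouring sections. Counts from sections of one muscle
are therefore strongly dependent, and any honest analysis must model
that dependence rather than pretend sections are independent samples.

## Per-section statistics

A section is a graph: fibers are vertices, membrane contact is an
edge. All downstream statistics are graph functionals:

* **Positivity.** A fiber is revertant when its whole membrane
  circumference is stained. Rasterized membranes rarely measure exactly
  1.0, so `call_revertant()` uses `stain_fraction >= 1 - tolerance`
  with `tolerance = 0.01` (bounded at 0.05); this preserves the
  whole-circumference intent without making the call trivially
  unattainable on discretized data.
* **Clusters.** RFs adjacent to each other count as a single cluster:
  connected components of the subgraph induced by revertant fibers.
  Size classes follow the reporting convention singleton / 2–4 / 5–8 /
  9–17 / >17.
* **Isolation.** An RF is "isolated" when separated from every other RF
  by at least two negative fibers. We formalize "separated by k fibers"
  as shortest-path distance ≥ k+1 on the *full* fiber graph (so k
  intervening fibers lie on the geodesic). Euclidean distance was
  rejected because the field counts intervening fibers, not
  micrometres; straight-line fiber counting was rejected as ill-defined
  on irregular packings. Unreachable RFs (disconnected tissue) count as
  infinitely separated. Singleton clusters that fail the isolation test
  form an implicit third category (non-isolated singletons), so
  singletons = isolated + non-isolated and totals reconcile.
* **Density.** RFs per mm² of section area. When the input is a label
  map, the area is the tissue mask (non-zero pixels), which excludes
  interstitium; a measured whole-section area can be supplied instead
  (`area_source = "provided"`). The two differ by the interstitial
  fraction, typically 10–20%.
* **Empty sections.** `pct_clustered` of a section with zero RFs is 0
  under the default policy (`empty_section_policy = "zero"`); `"drop"`
  records NA instead. Zero keeps every section in per-muscle averages
  (dropping would weight means toward RF-rich sections); but note that
  zero-policy percentages are *coupled to density* — a muscle with many
  empty sections gets its composition dragged toward 0. For questions
  about cluster composition (e.g. the age trend of the clustered
  percentage) the drop policy is the cleaner estimand, and that is what
  the calibration check in the acceptance suite uses.

Label-map adjacency defaults to 4-connectivity: under 8-connectivity
two fibers touching only at a pixel corner would count as adjacent,
overstating membrane contact. How much shared boundary constitutes
"adjacent" is genuinely under-determined at segmentation resolution, so
`min_shared_boundary` (default 1 pixel pair) is exposed rather than
guessed.

## The mixed model

Per-section trait values are analyzed with

```
value ~ muscle * age_group + (1 | mouse_id)
```

fitted by REML. Muscle (11 levels), age group (4 levels) and their
interaction are fixed; the animal is a random intercept, absorbing both
the between-animal variance and — in aggregate — the dependence among
the 10–12 sections of one muscle. Age-group contrasts within a muscle
are Wald tests on cell-mean differences. Degrees of freedom use the
between–within approximation with mice as the subject stratum: age
group is a between-subject factor, so contrasts carry
`df = n_mice − n_groups` (36 for the reference 40-mouse design). No
multiplicity correction is applied by default — the convention when
many pairwise muscle/age comparisons are reported descriptively — and
`adjust = "holm"` is available when a family-wise guarantee is wanted.

`screen_factors()` re-derives the usual preliminary ANOVA: nested
maximum-likelihood fits compare models with and without each fixed
factor, the mouse random intercept (boundary-corrected 50:50 mixture
p-value), and a per-section fixed effect. On data simulated from the
model, muscle and group are retained, the section index is not —
matching the rationale for leaving section out of the final model.
An optional square-root transform is available for count-like traits
but is off by default: the reference analysis operates on raw values,
and the contrasts of interest are on the raw scale.

Two caveats are deliberate. The exact denominator-degrees-of-freedom
method used in any particular historical analysis is unknowable;
p-values here are therefore comparable in pattern, not in digits, and
the tests assert directional significance structure on synthetic data
only. And section-level dependence beyond the mouse intercept gets no
variance component by default (the preliminary screen supports this);
an optional nested intercept would be the first thing to add if a
dataset showed otherwise.

## The synthetic cohort generator

`generate_cohort()` produces the full data structure the analysis
expects: 4 age groups × mice × muscles, each muscle a fixed planar
tessellation extruded along z, 10–12 sections ~120 µm apart.

**Geometry.** `make_tessellation()` jitters a triangular lattice of
seed points (a seeded point process) and partitions a pixel grid by
nearest seed — a discrete Voronoi tessellation. Adjacency is read off
the label map, so "adjacent" means shared region boundary; interior
fibers have ~6 neighbours, as in real fiber packings. Areas are
log-normal (default mean 2000 µm², σ_log 0.3 — typical adult mouse
fiber calibre); the modelled cross-section holds 600 fibers
(~1.4 mm²), a computational compromise: real mouse muscles range from
~1000 (EDL) to several thousand fibers, but density statistics only
require a representative neighbourhood, not the full organ.

**Reversion dynamics.** Founder clones appear at birth
(Poisson, mean `founder_rate` × muscle multiplier × mouse multiplier),
each on one fiber with a longitudinal extent drawn uniform on
[100, 300] µm with a 5% tail up to 900 µm. Each regeneration cycle,
every clone annexes each adjacent non-revertant fiber independently
with probability `expansion_prob` (annexed fibers inherit the clone's
interval, endpoints jittered ±50 µm — the model's stand-in for
longitudinal growth, on which data are silent), and new de-novo
founders arrive (Poisson, `denovo_rate` per cycle). Heart muscles run
with expansion suppressed and cardiomyocyte-length extents (80–120 µm):
revertant cardiomyocytes appear as singletons and rare chance-adjacent
pairs, never as expanded clusters.

**Variability.** Each mouse gets one log-normal multiplier
(σ = 0.6, mean 1) on both rates, shared across its muscles. This
reproduces the SD ≈ mean regime of real cohorts and the fact that a
"high-reverter" animal is high in many muscles at once.

**Calibration.** The defaults were calibrated once, against three
qualitative targets, and then frozen: (i) group-mean density clearly
higher in the oldest than in the youngest group for every skeletal
muscle, robustly so even in small (3 mice/group) cohorts, with
magnitudes in the observed range (a few RFs/mm² for limb muscles,
roughly half that for diaphragm/pectoralis, an order of magnitude less
for heart); (ii) the clustered share of RFs rising sharply from group
1 to group 2 and then plateauing (changing by well under 10 percentage
points between later groups); (iii) heart almost devoid of
medium-or-larger clusters. The chosen clock is
`cycles_per_group = c(2, 11, 12, 13)` with `expansion_prob = 0.010`,
`founder_rate = 11`, `denovo_rate = 2.8`, `muscle_length_um = 1500`:
degeneration/regeneration cycles concentrate early in life (as they do
in *mdx* mice, where necrosis peaks around 3–8 weeks), which is what
produces the clustering plateau — clusters are essentially formed by
6 months — while continued de-novo reversion keeps density rising into
old age. An evenly spaced clock (e.g. 1/3/6/10 cycles) cannot produce
both behaviours with any constant per-cycle expansion probability: the
clustered fraction then keeps climbing between every pair of adjacent
groups. The price of the compressed clock is that late-life density
growth is gentler than the near-doubling real cohorts show between 12
and 18+ months. Muscle multipliers scale founder and de-novo rates
proportionally to the observed density ordering (TA = SOL = 1.0 down
to D = PT = 0.55, heart 0.45 with heart mode).

When the calibration is *checked* (acceptance suite), the clustered
share per group is computed as total clustered RFs over total RFs
across the limb-muscle sections of a group — the ratio form of
"percentage of clustered RFs over the total RF number". Averaging
per-section percentages instead (the zero-policy default) couples the
statistic to density through empty and low-count sections and makes
the plateau unmeasurable at 3 mice/group; the ratio estimator measures
cluster composition directly.

**What a green test establishes — and what it does not.** The
generator reproduces the *statistical shape* of the reference data:
group structure, muscle ordering, age trends, between-animal scatter,
section-to-section dependence through shared z-extents, and exact
ground truth for cluster histograms. It does not emulate staining
artifacts, segmentation errors, fiber-calibre pathology (central
nucleation, splitting), immune infiltration, or any spatial preference
of reversion within the cross-section (founders are uniform). Passing
the pipeline tests on synthetic cohorts therefore validates the
counting and inference machinery, not any claim about real tissue; and
the simulator embodies the de-novo-reversion reading of late-appearing
isolated RFs — migration of pre-existing revertant satellite cells
would produce the same section-level signature and is deliberately not
modelled.

## Numerical and engineering choices

* Determinism: every stochastic function takes a seed; cohort
  generation derives per-(mouse, muscle) sub-seeds from the master seed
  with a fixed linear scheme, and simulator functions restore the
  caller's RNG state. CLI runs record a config-hash manifest.
* The generator's per-section ground truth is computed by a hand-rolled
  union-find, deliberately a different code path from the igraph-based
  `find_clusters()`, so the round-trip test compares two independent
  implementations.
* Cluster components and shortest paths use igraph; sections cut from
  one muscle share a cached graph. `include_isolated = FALSE` skips the
  distance computation in sweeps that do not need it (NA is reported).
* CSV dialect: comma-separated, UTF-8, header required; numeric fields
  accept decimal commas on input (European exports mix them in) and are
  written with points. Report densities print with one decimal.
* Degenerate inputs: empty label maps yield an empty graph whose zero
  area is flagged rather than silently propagated; a single-RF section
  counts that RF as isolated; designs with an empty muscle × group cell
  fail with the cell named, since the interaction is inestimable.

## Known limitations

* Physical fibers are not reconstructed across sections; counts are
  per-section by design, and the dependence is handled statistically —
  matching standard practice but meaning "n RFs" never refers to
  distinct physical fibers.
* Between–within df is one defensible convention; Satterthwaite or
  Kenward–Roger would shift borderline p-values.
* The tessellation is statistically homogeneous; real sections have
  fascicle boundaries and calibre gradients that could bias adjacency
  locally.
* Simulated section areas are constant per muscle (the tessellation's
  mask); real section areas taper toward the tendon.
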