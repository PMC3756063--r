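# revfiber

Quantification and statistical analysis of dystrophin **revertant fibers
(RFs)** in transverse muscle sections of dystrophic animals, plus a
stochastic clonal-expansion simulator that generates complete synthetic
cohorts for validating the whole pipeline.

## Who this is for

Muscles of Duchenne muscular dystrophy patients and of the *mdx* mouse
lack dystrophin, yet a small number of fibers spontaneously re-express
it ("revertant fibers"). Their background frequency confounds every
dystrophin-restoration study: a treated muscle must be read against the
age- and muscle-specific RF baseline. This package computes that
baseline from segmented histology (per-section fiber tables or integer
label maps) and analyzes it with the repeated-measures mixed models the
design requires (10–12 sections per muscle, 11 muscles per animal,
animals grouped by age).

## What it computes

Per transverse section, from the fiber adjacency graph:

* **RF density** — `n_rf / section_area_mm2` (RFs/mm²). A fiber is
  called revertant only when (essentially) its whole membrane
  circumference is dystrophin-positive: `stain_fraction >= 1 - tol`,
  `tol = 0.01` by default.
* **Clusters** — RFs adjacent to each other form a single cluster:
  connected components of the revertant-induced subgraph. Size classes:
  singleton (1), small (2–4), medium (5–8), large (9–17), very large
  (>17).
* **Percent clustered** — 100 × (RFs in clusters of ≥2) / total RFs.
* **Isolated RFs** — singletons separated from every other RF by at
  least 2 dystrophin-negative fibers (shortest-path graph distance ≥ 3);
  the operational signature of newly formed, rather than remnant, RFs.

Across the cohort: per-mouse → per-group mean ± SD grids, grand means,
and the repeated-measures mixed model

```
value ~ muscle * age_group + (1 | mouse_id)
```

fitted by REML (lme4), with Wald contrasts between age groups within a
muscle (between–within degrees of freedom, `df = n_mice − n_groups`)
and likelihood-ratio screening of the design factors.

The simulator implements the clonal model of reversion: Poisson founder
clones at birth, expansion into adjacent fibers at each
degeneration/regeneration cycle, continued de-novo reversion through
adult life, longitudinal extents of 100–300 µm (occasionally up to
900 µm) intersected with 9-µm sections cut ~120 µm apart — so the same
fiber reappears across neighbouring sections, reproducing the
within-muscle dependence the mixed model is there for.

## Worked example

```r
library(revfiber)

cfg    <- sim_config()                     # calibrated mdx-like defaults
cohort <- generate_cohort(cfg, cohort_design(10, c("TA", "D", "H")),
                          master_seed = 17)
traits <- trait_table(cohort$sections, cohort$design)

subset(aggregate_traits(traits)$grand, trait == "rf_per_mm2")
#>    muscle      trait grand_mean_groups grand_mean_sections
#> 10      D rf_per_mm2              3.15                3.09
#> 20      H rf_per_mm2              0.86                0.87
#> 30     TA rf_per_mm2              5.44                5.38

fit <- fit_repeated_measures(traits, "rf_per_mm2")
group_contrasts(fit, "TA", c("1-4", "1-3", "2-4"))
#>   muscle group_a group_b estimate    se statistic df  p_value significant
#> 1     TA       1       4     6.32 0.954      6.63 36 1.01e-07        TRUE
#> 2     TA       1       3     4.96 0.954      5.20 36 8.09e-06        TRUE
#> 3     TA       2       4     1.61 0.953      1.69 36 9.95e-02       FALSE

report_tables(traits)$density_grid
#>   muscle GROUP_1 GROUP_2 GROUP_3 GROUP_4
#> 1     TA 1.4±0.8 6.2±3.0 6.4±3.2 7.8±6.4
#> 2      D 1.0±0.5 3.3±1.8 3.9±2.0 4.5±3.2
#> 3      H 0.4±0.3 0.9±0.5 1.0±0.5 1.1±0.8
```

Reading: tibialis anterior carries several-fold more RFs/mm² than
diaphragm, with heart an order of magnitude below both; density rises
with age (groups 1→4 and 1→3 differ significantly, adjacent-ish
groups 2→4 do not),
with the large between-animal scatter (SD ≈ mean) these counts always
show. The same functions accept real data via
`read_fiber_tables(fibers.csv, edges.csv, design.csv)` or
`graph_from_labelmap()`.

## Command line

```sh
Rscript inst/cli/revfiber.R simulate --out-dir cohort --seed 17
Rscript inst/cli/revfiber.R quantify --fibers cohort/fibers.csv \
    --edges cohort/edges.csv --design cohort/design.csv --out traits.csv
Rscript inst/cli/revfiber.R analyze --traits traits.csv \
    --trait rf_per_mm2 --contrasts 1-4,1-3,2-4 --out results.csv
Rscript inst/cli/revfiber.R report --traits traits.csv \
    --contrasts results.csv --out-dir report
```

Every `simulate` run writes a JSON manifest (config hash, seed,
versions) for exact replay.

## File formats

* `fibers.csv`: `section_id,fiber_id,x_um,y_um,csa_um2,stain_fraction,revertant`
* `edges.csv`: `section_id,fiber_a,fiber_b` (unordered adjacency pairs)
* `design.csv`: `section_id,mouse_id,age_group,muscle,section_area_mm2,z_um`
* label maps: integer matrices (0 = background), or CSV grids via
  `read_label_map_csv()`

Numeric fields accept decimal comma or point on input; output always
uses the point.
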