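# hydroniche

Quantification toolkit for ex vivo **3D hydrogel bone-marrow-mimic
co-cultures** of acute lymphoblastic leukemia (ALL): patient-derived
leukemic blasts grown with primary mesenchymal stromal cells (MSC) and
endothelial cells (EC/HUVEC) in optically clear PEG hydrogels, where the
endothelial cells form vasculature-like networks and the blasts aggregate,
migrate into the gel and escape drug treatment.

The package is written for the computational side of such studies — image
analysts and bioinformaticians who need the quantification machinery of the
assay as tested, scriptable R rather than clicks in commercial high-content
software:

* **Segmentation & morphometry** — threshold/region segmentation and
  spot-style 3D nucleus detection in anisotropic confocal z-stacks
  (Gaussian smoothing → local-maxima seeding → seeded watershed), voxel
  volume and face-count surface area, centroid extraction
  (`segment_region()`, `segment_nuclei()`, `measure_volume_surface()`,
  `extract_positions()`).
* **Spatial statistics** — per-cell minimum 3D distances between
  populations (centroid and border-to-border, kd-tree backed, exact), the
  fraction of ALL cells within <10 µm of MSC/EC (`d_M`, `d_H`),
  bin-centered histograms, per-timepoint depth normalization with
  Δmedian/SD summaries, migration percentages referenced to the shallowest
  leukemic cell, and network-contact fractions at the 40% settling depth
  (`min_centroid_distances()`, `min_border_distances()`,
  `proximity_fraction()`, `z_profile()`, `migration_percent()`,
  `network_contact_fraction()`).
* **Motility kinetics** — mutual-nearest-neighbour track linking and the
  central-difference step-size/speed readout with windowed displacement
  (`link_tracks()`, `compute_kinetics()`, `track_displacement()`,
  `compare_distributions()`).
* **Dye-dilution proliferation** — generations from CellTrace-style
  halving and a reproducible trimodal non-/slow-/high-cycling
  classification anchored on the timepoint-0 sample
  (`generations_from_intensity()`, `classify_cycling()`,
  `compare_2d_3d_cycling()`).
* **Drug-response profiling** — counting-bead normalization to absolute
  counts, DMSO normalization, integrated two-concentration responses,
  decreased-sensitivity flags (>10 points at 100 nM), percentile ranking
  and the ratio paired t-test comparing 3D with 2D
  (`absolute_counts()`, `viability_table()`, `drp_response_summary()`).
* **Synthetic data, first class** — an agent-based tri-culture generator
  (diffusion + aggregation and stromal-attraction drifts, network geometry
  settling at a configurable depth), dye-dilution and cytometry event
  generators, and a voxel renderer, so every stage is testable with no
  microscopy or cytometry data (`sim_config()`, `simulate_culture()`,
  `render_cells()`, `simulate_drug_response()`, ...).

Results come back as tibbles and chain with the pipe; fitted/summary
objects have `tidy()`, `glance()` and `autoplot()` methods. A thin CLI
wrapper lives at `inst/cli/hydroniche.R`.

## A worked example

Simulate a desk-scale co-culture (300 ALL, 60 MSC, 100 EC agents, 4 h of
5-minute frames), quantify spatial phenotypes and motility, then score a
simulated 16-sample drug-response cohort with 5-fold 3D protection:

```r
library(hydroniche)
library(dplyr)

cfg <- sim_config_desk(n_all = 300, n_msc = 60, n_ec = 100, n_steps = 48,
                       seed = 1)
obs <- simulate_culture(cfg, mode = "co")

spatial <- run_spatial_pipeline(obs, gel_depth_um = cfg$gel_depth)
spatial$proximity
#> # A tibble: 2 × 3
#>   target fraction_lt_threshold threshold_um
#>   <chr>                  <dbl>        <dbl>
#> 1 MSC                   0.0533           10
#> 2 EC                    0                10
spatial$z_profile
#> # A tibble: 1 × 5
#>   delta_median_um sd_t0_um sd_tend_um t0_min tend_min
#>             <dbl>    <dbl>      <dbl>  <dbl>    <dbl>
#> 1            9.32     11.8       12.4      0      240

tracks <- link_tracks(filter(obs, cell_type == "ALL"), max_link_um = 25)
median(compute_kinetics(tracks)$speed_um_per_min, na.rm = TRUE)
#> [1] 0.4653
```

5.3% of leukemic cells sit within 10 µm of an MSC after 4 h, the ALL
population's median depth has moved 9.3 µm downward with a widening spread
(SD 11.8 → 12.4 µm), and the median in-plane speed is ~0.47 µm/min.

```r
drp <- run_drp_pipeline(sim_config(seed = 1, protection_factor_3d = 5),
                        sprintf("PDX%02d", 1:16), drugs = "venetoclax")
glance(drp$summary)
#> # A tibble: 1 × 10
#>   drug       statistic     p_value    df mean_log_ratio direction n_pairs flag
#>   <chr>          <dbl>       <dbl> <dbl>          <dbl> <chr>       <int> <chr>
#> 1 venetoclax      9.39 0.000000113    15          0.441 3D > 2D        16 <NA>
#> # ℹ 1 more variable: flagged_fraction <dbl>
```

With 5-fold 3D protection the ratio paired t-test detects significantly
higher normalized viability in 3D (p ≈ 1e-7, mean 3D/2D log-ratio 0.44).

## Acceptance script

`scripts/acceptance.R` re-runs the package's two headline workflows end to
end — simulate → render → segment → quantify spatial phenotypes and
kinetics, classify a dye-dilution mixture, and score a simulated 2D-vs-3D
drug-response cohort — from a caller-supplied seed, and writes its JSON
report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Conventions worth knowing

* Depth `z` is measured from the gel top surface, increasing downward (µm).
* Voxels are 0-based with centers at `(i + 0.5) * d`; anisotropic voxel
  sizes are carried through all computations.
* Proximity fractions use strict `<`; histogram bins are centered at
  multiples of the width, half-open on the right.
* Intensity thresholds are fluorophore-dependent and always explicit
  arguments.
* Undefined statistics are flagged `NA`s, never sentinels; all randomness
  derives from one config seed and reruns are byte-identical.

The methods vignette (`vignettes/hydroniche-methods.Rmd`) documents the
model assumptions, parameter defaults with units, numerical conventions and
known limitations in full.
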