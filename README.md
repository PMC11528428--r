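# smlmeq

Equilibrium constants for protein–protein interactions, measured in situ
from single-molecule localization microscopy (SMLM).

Most methods for measuring association constants need purified protein in
solution, and almost all of them work in 3D — a poor match for membrane
receptors, whose interactions happen in 2D at densities set by the cell.
`smlmeq` estimates association (K<sub>a</sub>) and dissociation
(K<sub>d</sub>) constants directly from super-resolution images by
counting associated and isolated molecules and measuring the area they
occupy:

```
K_a = n_pairs · A / (n_free_A · n_free_B)     [µm², in-membrane association]
K_d = c_free_ligand · n_free_receptor / n_pairs   [M, membrane–cytosol]
```

where `A` is the membrane area accessible to the molecules and the molar
free-ligand concentration comes from converting `A` into a volume via the
TIRF illumination depth (100–250 nm). It is aimed at microscopists and
quantitative cell biologists who already have localization tables
(DNA-PAINT, PALM/STORM) and want thermodynamics out of them.

The package provides:

* **qPAINT molecular counting** — dark-time extraction, qPAINT indexes
  (QPI = 1/mean dark time), a constrained Gaussian-mixture fit of the QPI
  histogram with peaks at integer multiples of a unit QPI, and conversion
  of localization clusters into counted molecule maps.
* **Three occupied-area estimators**, all parameterized by the mean first
  nearest-neighbour distance µ_NND: Delaunay tessellation (keep triangles
  ≤ (F_D·µ_NND)²), Voronoi tessellation (keep bounded cells ≤
  (F_V·µ_NND)²), and ks-density — a Gaussian kernel surface with
  σ = F_K·µ_NND thresholded at c/(2πσ²N), which needs no user-defined
  absolute parameters.
* **Pair counting against CSR** — greedy exclusive proximity matching,
  complete-spatial-randomness references inside the recovered pattern,
  threshold scans, K_a/K_d on surface and molar scales, extrapolation to
  infinite dilution, stepwise cluster constants
  K_a,j = N_j·A/(N_{j−1}·N_1), and Langmuir-type cluster occupancy.
* **A seeded simulation engine** — two species placed at equilibrium
  inside cell-shaped patterns with localization noise and optional
  DNA-PAINT blinking traces — used to validate the whole pipeline.

## Worked example

Simulate a cell-shaped field of two interacting species at a known
affinity, then recover that affinity blind:

```r
library(smlmeq)

poly <- make_cell_pattern(frame_size_um = c(13.3, 13.3),
                          target_area_um2 = 100, roughness = 0.1, seed = 1)
sim <- place_molecules(poly, total_density = 160, log_ka = -2,
                       mode = "hetero", seed = 2)
sim
#> Simulated hetero field: 16000 molecules (2753 bound pairs) in 100.0 um^2
#>   total density 160 um^-2, input log Ka = -2.00, seed 2

recover_log_ka(sim, method = "ksdensity")
#> # A tibble: 1 × 11
#>   method    factor mu_nnd_nm area_um2    f1 n_in_pattern n_pairs n_free_a
#>   <chr>      <dbl>     <dbl>    <dbl> <dbl>        <int>   <int>    <int>
#> 1 ksdensity      1      56.1     88.5 0.935        15921    2907     5053
#> # ... log_ka = -1.997, deviation = 0.0033
```

The estimator measured the occupied area (88.5 µm² of the true 100 µm²,
pattern-recovery F1 = 0.935), matched the 2907 in-pattern pairs at the
15 nm proximity criterion, and recovered log K_a = −1.997 against the −2
ground truth — well inside the ±0.3 band the method targets. `delaunay_pattern()`,
`voronoi_pattern()` and `ksdensity_pattern()` expose the area step alone;
`threshold_scan()` picks the proximity criterion from the data by
contrast with CSR; `extrapolate_to_infinite_dilution()` corrects the
density dependence caused by incomplete labeling.

For DNA-PAINT counting:

```r
qp <- qpaint_molecules(locs, radius_nm = 60, min_locs = 10,
                       frame_interval_s = 0.1)
qp$fit                    # unit QPI and mixture components
tidy(qp$fit)              # broom-style component table
qp$molecules              # counted molecule map
```

A thin command-line interface over the same functions lives at
`inst/cli/smlmeq.R` (subcommands `simulate`, `area`, `qpaint`,
`associate`, `extrapolate`, `clusters`, `validate-grid`; JSON reports).

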