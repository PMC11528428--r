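---
title: "Measuring protein-protein equilibrium constants from SMLM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein-protein equilibrium constants from SMLM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(smlmeq)
```

## The problem

Single-molecule localization microscopy (SMLM) resolves individual protein
molecules in their cellular environment. For a 1:1 interaction
A + B &harr; AB, the association constant on an area scale is

$$K_a = \frac{[AB]}{[A]\,[B]}
      = \frac{n_{\mathrm{pairs}} \cdot A}{n_{\mathrm{free},A}\; n_{\mathrm{free},B}}
      \quad (\mu m^2),$$

so an image in which associated and isolated molecules can be counted, and
in which the area $A$ accessible to the molecules can be measured, yields
$K_a$ directly in situ — no purified protein, no immobilization. For
membrane-cytosol dissociation (a receptor R releasing a cytosolic ligand
L), the same counts give a molar dissociation constant once the occupied
area is converted into an observation volume through the TIRF
evanescent-field depth (100–250 nm):

$$K_d = c_{\mathrm{free},L}\,\frac{n_{\mathrm{free},R}}{n_{\mathrm{pairs}}},
\qquad
c_{\mathrm{free},L} = \frac{n_{\mathrm{free},L}}{A \cdot d_{\mathrm{TIRF}} \cdot N_A}.$$

Four obstacles stand between raw localizations and those counts, and the
package addresses each one:

1. **Overcounting** — one molecule blinks many times. DNA-PAINT data are
   counted by qPAINT: the mean dark time of a localization cluster is
   inversely proportional to its number of docking sites, so the
   qPAINT index $QPI = 1/\bar\tau_{\mathrm{OFF}}$ falls on integer
   multiples of a unit QPI (module `qpaint`).
2. **Which area?** — association depends on the local density, so the
   denominator must be the area actually accessible to the molecules, not
   the camera field. Three estimators parameterized by the mean first
   nearest-neighbour distance $\mu_{NND}$ are provided (module `pattern`).
3. **Proximity is not binding** — localization precision exceeds
   molecular size, so pairing uses a proximity criterion benchmarked
   against complete spatial randomness (CSR) at the measured density
   (module `equilibrium`).
4. **Incomplete labeling** — unlabeled molecules bias the apparent
   constant with density; the corrected value is obtained by a linear
   extrapolation of log K versus total density to infinite dilution.

## Occupied-area estimators

All three estimators take the pooled molecular coordinates and the scale
$\mu_{NND}$:

* **Delaunay**: keep triangles with area $\le (F_D\,\mu_{NND})^2$,
  default $F_D = 3$. The estimate is the exact sum of accepted triangle
  areas; a molecule is in the pattern iff it is a vertex of an accepted
  triangle.
* **Voronoi**: keep bounded cells with area $\le (F_V\,\mu_{NND})^2$,
  default $F_V = 3$; unbounded cells (convex-hull sites) are always
  rejected so the estimator never credits area outside the data's
  support. Cell areas are computed exactly from the Delaunay circumcenter
  fan of each site.
* **ks-density**: a Gaussian kernel surface with
  $\sigma = F_K\,\mu_{NND}$ (default $F_K = 1$), normalized to unit mass,
  thresholded at $TH = c/(2\pi\sigma^2 N_T)$ with $c = 1.5$ — i.e. $c$
  times the peak height of a single kernel. With $c > 1$ an isolated
  molecule is rejected, which is what lets the surface exclude voids
  without any user-defined absolute threshold. Kernels are truncated at
  $4\sigma$ (relative error $< 3\times10^{-4}$) and evaluated by FFT
  convolution of binned counts.

The threshold formula has a second defensible reading
($c/(\sqrt{2\pi}\,\sigma N_T)$, a unit-dependent 1D-style normalization);
we adopt the peak-height reading because it is dimensionally consistent
on a 2D surface and makes the "isolated molecule rejected" property exact.
The constant is an argument (`th_constant`), so the alternative is one
call away.

**The $\mu_{NND}$ scale.** Nearest-neighbour distances are measured
within each species (each imaging channel) and pooled into one mean. The
pooled-across-channels alternative collapses to the intra-pair distance
(7–9 nm) once a large fraction of molecules is bound, which would shrink
the acceptance thresholds of all three estimators and fragment the
recovered pattern precisely in the high-affinity conditions of interest.
Within-channel distances track the inter-molecular spacing at any
affinity, and are what a two-channel experiment naturally measures.

Raster defaults: pixel $= \min(\mu_{NND}/4, \sigma/3)$, floored so grids
stay below ~2500 pixels per axis; tessellation areas are exact polygon
sums and do not depend on the raster, which only renders masks and scores
them (pixel-wise F1 against the true polygon, the optimization criterion
for the expansion factors; ties break toward the smaller, more
conservative factor).

## Pairing and CSR references

Candidate pairs are all cross-species (or within-species, for
homo-association) pairs within the proximity threshold; they are accepted
greedily in ascending distance with 1:1 exclusivity, ties broken by index,
so mass balance holds exactly and the result is deterministic. Greedy
matching is guaranteed within a factor 2 of the maximum matching and is
within one pair of it in almost all point configurations at these
densities; the exhaustive optimum is used as a test oracle, not in
production.

The CSR reference redraws one or both species uniformly inside the
recovered pattern mask at the experimentally measured counts (20 seeded
realizations by default). The proximity threshold is chosen where
$\log K - \log K_{CSR}$ peaks; for the simulation conditions below the
generator's noise makes 15 nm a sensible fixed criterion. For CSR data at
small radius $r$ the apparent hetero-association constant approaches
$\pi r^2$, an analytic oracle used in the tests
($\log_{10}(\pi \cdot 0.025^2) = -2.71$ at $r = 25$ nm).

With greedy exclusive matching the scan's contrast does not return
exactly to zero at very large thresholds (free counts approach zero and
log K is undefined in the saturated limit); the meaningful null is CSR
input versus CSR reference, which is calibrated to $|\Delta| < 0.1$.

## Cluster growth and occupancy

Single-linkage clustering at a linkage distance (exact connected
components, via grid bucketing with a star-union inside cells of side
$r/\sqrt2$) gives the cluster size distribution $N_j$. Stepwise
association constants for monomer addition are
$K_{a,j} = N_j A / (N_{j-1} N_1)$. An optional $1/j$-shaped overlay — the
qualitative expectation for size-independent association with a
dissociation rate growing linearly in size — is provided as a flagged
heuristic reference, not a fitted model. Ligand occupancy of receptor
clusters ($p_{\mathrm{bound},j}$, mean bound fraction per site in
$j$-clusters) is tabulated against a ligand-CSR null; the linear fit of
$1/p_{\mathrm{bound},j}$ versus $j$ is reported with its slope, and the
slope-to-$K_d$ conversion is left as an explicit user-supplied scale
because it requires the free-ligand concentration and a model choice.

## The simulation engine

The generator defines the validation conditions:

* **Cell-shaped patterns**: a circle radially perturbed by Fourier
  harmonics of orders 2–6 with random phases (total relative amplitude =
  `roughness`, default 0.1), rescaled to the target area exactly.
  The reference geometry is 692 µm² in a 35 × 35 µm² frame (area:frame
  ratio 0.565); scaled runs keep that ratio.
* **Equilibrium placement**: the bound-pair density $x$ solves
  $k_a(a-x)(b-x) = x$ (hetero, equal species amounts) or
  $k_a(\rho-2x)^2 = x$ (homo dimerization, the same quadratic with
  $a=b=\rho/2$, $4k_a$); the number of pairs is $\mathrm{round}(x A)$.
  Densities span 120–400 µm⁻² and $\log K_a$ −3 to 0 (µm² scale).
* **Geometry and noise**: bound partners at a fixed physical separation
  (default 0 nm) with random orientation; every molecule displaced by
  isotropic Gaussian position noise, default $\sigma = 3$ nm. The noise
  default is pinned by the proximity criterion rather than guessed: the
  15 nm limit is chosen "considering the average uncertainty in the
  location of pairs", i.e. it must capture essentially all bound pairs,
  which requires $15\,\mathrm{nm} \gtrsim 3\sigma_{\mathrm{pair}}$ with
  $\sigma_{\mathrm{pair}} = \sigma\sqrt2$ — hence $\sigma \le 3.5$ nm.
  That scale is also what qPAINT delivers in practice: a counted
  molecule's position is the centroid of many localizations, far more
  precise than a single 5–10 nm localization. With $\sigma = 3$ nm, pair
  distances are Rayleigh(4.2 nm) and 15 nm captures 99.8 % of pairs; at
  $\sigma = 5$ nm the same criterion misses ~10 % of pairs, which
  systematically destroys high-affinity recovery (the missed pairs
  inflate the small free-molecule counts quadratically) — a sensitivity
  worth knowing when applying the method to data with poor effective
  position precision. True positions are kept inside the polygon by
  rejection sampling; observed positions may exit it, as in a real
  measurement.
* **Blinking**: per molecule, alternating exponential OFF (mean
  $\tau_{OFF}/n_{\mathrm{sites}}$) and ON (mean $\tau_{ON}$) dwells,
  discretized by marking every frame overlapped by an ON interval; one
  localization per ON frame.

What the generator does *not* emulate: camera noise and PSF shape,
imager-concentration-dependent kinetics, labeling stoichiometry below 1,
drift, or 3D structure. Passing the validation grid therefore shows the
*estimators* are unbiased under known geometry and noise — it does not
certify performance on data whose localization precision or labeling
efficiency differ substantially from these settings.

## Validation problem sizes and numerical choices

The packaged validation grid simulates 100 µm² patterns (12 000–40 000
molecules per field at the grid densities) with one replicate per cell
and all three estimators; the pattern-recovery benchmark uses five seeds
at 160 µm⁻², $\log K_a = -2$. These sizes keep a full grid run in a few
minutes on one CPU while leaving counting error well below the effects
being measured; the original study's 692 µm² fields change the results
only through a smaller perimeter-to-area ratio (slightly higher F1).

Numerical notes:

* Delaunay/Voronoi use the `interp` triangulation; `deldir` serves as an
  independent oracle in the test suite. Duplicate coordinates are
  collapsed before triangulation and re-expanded for membership.
* The QPI histogram is fitted by Levenberg–Marquardt least squares
  (binned, Freedman–Diaconis widths) to $\sum_k a_k\,N(k q_1, \sigma_k)$
  with the shared unit $q_1$ — peak means are exact multiples by
  construction. $q_1$ is initialized at the histogram's first prominent
  mode and bounded to $[0.6, 1.6]\times$ that mode so the fit cannot
  slide to the $q_1/2$ relabelling; component weights are the fitted
  masses with data support, which zeroes spurious between-bin spikes.
* Sub-molecule placement for clusters counted as $n > 1$ molecules uses
  deterministic repeated 2-means (principal-axis extremes as seeds,
  widest subcluster split first).
* Degenerate inputs: collinear point sets raise a geometry error;
  a single isolated molecule yields an empty ks-density mask for
  $c > 1$; clusters with a single ON burst have undefined QPI and are
  excluded from the histogram; zero matched pairs flags log K as
  undefined rather than returning $-\infty$.

## Known limitations

* The expansion-factor optimum is flat: on simulated fields $F_D = 3$
  and $F_D = 4$ differ by $< 10^{-3}$ in F1. The recommended factors are
  those of the reference study; `optimize_expansion_factor()` re-derives
  them per data set when ground truth (or a trusted surrogate) exists.
* Under the peak-height threshold reading, ks-density pattern recovery
  on the simulated reference condition scores F1 ≈ 0.93, somewhat above
  the reference study's printed 0.87; the discrepancy is consistent with
  either the alternative threshold normalization or a different simulated
  localization precision, neither of which is published.
* Greedy matching slightly overestimates pairs at high density relative
  to the maximum matching; at 400 µm⁻² with $\log K_a = -3$ this, plus
  random coincidences, drives the documented up-to-±0.4 deviation in the
  worst grid cell.
* Molar $K_d$ scales inversely with the TIRF depth, which is an input
  (100–250 nm), not an estimate; report it alongside any $K_d$.
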