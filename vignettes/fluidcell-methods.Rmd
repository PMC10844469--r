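---
title: "Models and methods behind fluidcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluidcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidcell)
```

`fluidcell` analyzes how macrophage-like reporter cells activate NF-κB when
a TLR7/8 agonist is delivered at three spatial scales: onto one cell from a
FluidFM micropipette, onto a cluster of cells, or uniformly over a whole
culture. This vignette explains each model in the package, the defaults and
their units, the numerical choices, and what the synthetic data generator
does and does not emulate.

## The dispensing–diffusion model

A FluidFM probe dispenses agonist continuously at volumetric rate $Q$ from
an aperture held at height $h$ above the dish. We model the resulting field
as a continuous point source of strength $Q C_0$ above a reflecting plane
(the dish surface reflects all flux into the upper half space, the
image-source factor 2), evaluated at the plane:

$$C(r) = \frac{Q\,C_0}{2\pi D\, r_\mathrm{eff}}, \qquad
  r_\mathrm{eff} = \max\!\left(\sqrt{r^2 + h^2},\, a\right),$$

where $r$ is the in-plane distance from the point beneath the aperture, $D$
the agonist diffusivity, and $a$ the aperture radius, which floors
$r_\mathrm{eff}$ so the point-source singularity never enters (the real
concentration cannot exceed the reservoir-side value at the opening).
Build-up during dispensing follows the switched-on point source,

$$C(r,t) = C(r)\,\operatorname{erfc}\!\left(
   \frac{r_\mathrm{eff}}{2\sqrt{D t}}\right), \qquad t \le t_\mathrm{disp},$$

and after the probe stops the field is the superposition
$C(r,t) - C(r, t - t_\mathrm{disp})$ of a positive and a delayed negative
source, which decays below 10% of the steady value within five minutes over
the stimulated area. Both formulas are checked in the test suite against an
independent finite-volume radial diffusion solver (implicit Euler in time,
hemisphere-flux inner boundary) to within 5%, and the steady solution
conserves the source mass rate exactly.

Parameters and defaults:

| parameter | unit | single-cell | cluster | rationale |
|---|---|---|---|---|
| height $h$ | μm | 4 | 20 | probe retraction distances per mode |
| aperture radius $a$ | μm | 1 | 1 | half the 2 μm probe opening |
| diffusivity $D$ | m²/s | 5×10⁻¹⁰ | 5×10⁻¹⁰ | Stokes–Einstein scale for a ~314 Da molecule (R848) |
| flow $Q$ | m³/s | 2.28×10⁻¹⁶ | 1.98×10⁻¹⁴ | calibrated (below) |
| duration | s | 300 | 300 | 5-minute stimulation |

Absolute dispensing rates are not directly measurable, so $Q$ is a
*calibrated constant* per mode: it is pinned by requiring that the canonical
reservoir concentrations ($C_0 = 5.5$ μM single-cell at $h = 4$ μm,
$C_0 = 0.318$ μM cluster at $h = 20$ μm) each produce a peak surface
concentration $C_\mathrm{max} = 100$ nM. Those anchors give about 0.23 pL/s
and 20 pL/s. Because the field is linear in $C_0$, any other target
$C_\mathrm{max}$ is obtained by scaling $C_0$. The cell-height ambiguity in
single-cell mode (the probe sits one to two cell heights above the surface)
is quantified by `cmax_uncertainty()`: heights spanning 4–8 μm give a
factor-2 interval in $C_\mathrm{max}$, i.e. an uncertainty of about half the
nominal peak.

This closed form deliberately omits advection from the jet, media
convection, and full 3-D structure away from the dish; only the surface
concentration matters for adherent cells, and the calibrated anchors absorb
near-field details. The model form is configuration-swappable (all
parameters live in `dispense_conditions()`).

## The synthetic culture and response model

`generate_culture()` draws cell positions from a Thomas cluster process:
parent cluster centers from a homogeneous Poisson process (default rate =
density/8, i.e. a mean of 8 cells per cluster), offspring counts Poisson,
and offspring positions Gaussian with σ = 12 μm — roughly one cell diameter
— around each parent. Parents are drawn in a 4σ-buffered window so the
realized intensity inside the field equals the configured density without
edge deficits; offspring falling outside the field are discarded. This
emulates the clumped growth of RAW 264.7-like cells rather than an even
confluency. Density presets: sparse 400 cells/mm² (the tissue-resident
scale), moderate 1500, dense 2500 (confluent), dense whole-culture 3750.

Each cell's probability of activating is

$$p = b + (1-b)\,\sigma\!\big(k\,(\log_{10} C - \log_{10}
      \mathrm{EC50}_\mathrm{eff})\big),$$

with logistic $\sigma$, background $b$, slope $k$ per decade, and an
effective threshold that rises with culture density $\rho$ and relaxes with
stimulation time $t$:

$$\mathrm{EC50}_\mathrm{eff} = \mathrm{EC50}_0
  \left[1 + \beta \max\!\left(0, \tfrac{\rho}{\rho_\mathrm{ref}} - 1\right)
  h(t)\right],
  \qquad h(t) = \max\!\left(0,
  \tfrac{t_\mathrm{restore} - t}{t_\mathrm{restore} - t_\mathrm{min}}\right).$$

Below the minimum stimulation time ($t < t_\mathrm{min}$) the response stays
at background. Defaults: $\mathrm{EC50}_0 = 100$ nM (the single-cell
threshold at 5 min), $k = 4$, $b = 0.05$, $\rho_\mathrm{ref} = 1000$
cells/mm², $t_\mathrm{min} = 5$ min, $t_\mathrm{restore} = 15$ min, and
$\beta = 9/2.75 \approx 3.27$ so that the effective threshold at 3750
cells/mm² and 5-minute stimulation is exactly tenfold the sparse threshold.
This functional form is a *modeling choice of this package*: the density
effect is placed on the threshold (not the slope or the maximum) and decays
linearly in stimulation time, which is the simplest shape that reproduces
the observed orderings — single cells more sensitive than dense cultures at
5 min, suppression growing with density, and restoration by 15 min. Whether
the biological modulation acts on threshold, slope, or maximum is not
identified by the available observations.

Reporter ratios are log-normal: resting median 0.75, activated median 1.5,
both with log-sd 0.2. These place the resting population below ratio 1 and
the activated population above it with realistic overlap (≈5% of resting
cells above the activated population's lower decile); the true calibration
distributions behind the original measurements are not published, so these
are placeholders with the correct ordering and spread, and every parameter
is configurable through `response_params()`.

What the generator does **not** emulate: cell motility and division,
time-resolved translocation trajectories, secreted-factor
reaction–diffusion (the density effect is imposed phenomenologically, not
mechanistically), uneven illumination, or segmentation artifacts beyond
disk overlap. Passing tests therefore demonstrate that the *analysis
pipeline* is correct and internally consistent under the stated statistical
structure — not that the response model is the true biological mechanism.

## Imaging

`render_images()` draws each cell as a 9 μm-radius cytoplasm disk at its
cytoplasmic intensity with a 5 μm-radius nucleus overwritten at its nuclear
intensity (reporter channel), and a uniform bright nucleus disk (nuclear
channel), at 0.65 μm/px by default, with optional Poisson shot noise.
Because disks are piecewise constant, the rendered nuclear/cytoplasmic
ratio equals the record's ratio exactly in the noiseless case, which gives
the quantification stage a sharp round-trip oracle.

`segment_nuclei()` and `quantify_images()` replace an interactive
CellProfiler pipeline with the simplest defensible operators: global Otsu
threshold on the nuclear channel, connected components, a 25–400 μm² size
filter, nuclear intensity as the mean reporter signal in the nucleus mask,
and cytoplasmic intensity as the mean in a 3 μm annulus (nucleus dilated by
3 μm, minus *all* nuclear pixels, so abutting neighbors never contaminate
the annulus). Cells with an empty annulus are flagged and excluded from
ratio statistics rather than guessed. Mean (not median) intensities are
used; all of this is parameterized. No numeric equivalence with any
specific CellProfiler configuration is claimed.

## Activation calling and calibration

A cell is *called* activated when its ratio strictly exceeds the cutoff
fitted on a resting calibration population imaged under the same
conditions: the empirical 95th percentile (top 5% of the resting
population), computed with the linear-interpolation convention between
order statistics (`stats::quantile` type 7). Ties at the cutoff are
conservatively not called. Calibration requires at least 20 resting cells;
separate cutoffs per experimental setup are supported and the model
serializes to JSON with a content hash. By construction a fresh resting
sample is called at ≈5% — the false-positive floor of every downstream
fraction. Fractions activated carry bootstrap standard errors and
percentile 95% intervals from resampling cells with replacement.

One consequence worth stating explicitly: a null experiment (no stimulus)
reports a called fraction near $b + (1-b)\cdot 0.05 \approx 9.7\%$ — the
generator's spontaneous-activation background *plus* the calibration
false-positive rate. The two are distinct quantities and the pipeline keeps
ground-truth and called flags in separate columns.

## Resampling inference

- **Exceedance test** — the with-replacement null actually quoted for the
  single-cell comparison: pool both groups' calls, draw target-sized
  samples with replacement, count resamples whose fraction reaches the
  observed target fraction (inclusive ≥). This is a bootstrap-style null
  rather than a conventional permutation without replacement; it is
  implemented exactly as described, and on tiny pools it matches the exact
  binomial enumeration.
- **Permutation ANOVA** — statistic: size-weighted between-group sum of
  squares of group means about the grand mean, which orders permutations
  identically to the F statistic; labels are permuted without replacement.
- **Rank-sum test** — two-sided Wilcoxon with mid-ranks; exact enumeration
  of all $\binom{n_a+n_b}{n_a}$ assignments when both groups have ≤ 8
  values, otherwise the normal approximation with tie and continuity
  correction (checked against `stats::wilcox.test`).
- **Effect sizes** — differences in fraction activated (percentage points)
  and percent changes in median ratio, each with ±1 bootstrap SD from
  independent within-group resampling, matching the "x% ± y%" reporting
  style.

All resampling p-values use the add-one convention
$p = (\text{exceedances}+1)/(\text{resamples}+1)$, which keeps $p \in
(0,1]$ and makes the minimum attainable p-value $1/(N+1)$. Every operation
is deterministic given its seed.

## Dose–response fitting

`fit_dose_curve()` fits $p(C) = b + (1-b)\,\sigma(k(\log_{10}C -
\log_{10}\mathrm{EC50}))$ by binomial maximum likelihood with the
background *fixed* at the calibration false-positive rate (default 0.05):
with six or fewer dose points a free lower plateau is poorly identified and
trades off against the EC50. Optimization is multi-start — a 25-point
log-spaced EC50 grid crossed with three slope starts, the best five seeds
refined by Nelder–Mead — so the fit is deterministic and escapes local
optima; the fitted likelihood is never worse than any grid start. Panels
with no successes or all successes are refused (the threshold is
unidentifiable). `threshold_crossing()` inverts the fitted curve
analytically; note that the 50% crossing sits slightly below the EC50
whenever $b > 0$, since the EC50 is where $p = (1+b)/2$.

## Spatial statistics

Neighbor counts use a closed ball of radius 18 μm (about two cell lengths)
excluding the cell itself, with no edge correction — matching the empirical
neighbor definition — and are verified against an all-pairs brute-force
oracle. Activation maps bin cells into 100 μm squares on a grid anchored at
the dispensing point with half-open intervals, so each cell lands in
exactly one bin. The "center region" of a localized experiment is
operationalized as the disc where the *steady-state* concentration is at
least a threshold (30 nM for a 90 nM peak, 100 nM for a 900 nM peak — the
contours where activation drops below 50% for those conditions); this is an
interpretation, as the original center radii are not published. Density
classes: sparse < 1000 cells/mm² ≤ moderate < 2500 ≤ dense.

## The ligand budget

`free_ligand_count()` is $C \cdot V \cdot N_A$ over a 45 × 45 × 5 μm box
(≈10 pL; ≈6.1×10⁵ molecules at 100 nM); `bound_ligand_count()` is
$n_\mathrm{cells} \times \mathrm{receptors} \times C/(C+K_d)$. Receptor
count (5000/cell) and $K_d$ (100 nM) are order-of-magnitude placeholders
and deliberately configuration-mandatory for reported runs; the conclusion
only needs the order of magnitude — free ligand exceeds bound ligand by
tens to hundreds even with 9 cells per box, so uptake by neighbors cannot
deplete the local agonist.

## Virtual experiments and reproducibility

`run_virtual_experiment()` chains the stages: culture → field (or uniform
bath for whole-culture mode, where the dilution wash ends the stimulus) →
response simulation → calibration on an independent resting companion
culture → calling → neighbor counts → radial/binned/center summaries. In
single-cell mode the dispensing origin is placed *on* the cell nearest the
field center, as the probe is positioned over its target.
`replicate_panel()` runs independent seeds and pools target calls
(single-cell mode) or all calls. Stage seeds are derived deterministically
from the master seed; identical configs give byte-identical outputs, and
every CSV carries a provenance header (package version, seed, config hash
— computed over the scientific configuration, excluding the output path).

Problem sizes in the shipped tests are chosen to make the checks sharp but
cheap: 1 mm² fields at 400–3750 cells/mm², 8–20 replicates per panel,
500–5000 bootstrap resamples, 100-seed recovery studies, a 500-replicate
type-I-error study at 399 permutations each (with the add-one convention,
$p \le 0.05$ iff at most 19 permutations reach the observed statistic,
giving an exact 5% rejection rate under exchangeability), and a
finite-volume PDE oracle on a 4 μm radial grid out to 2.5 mm.

## Known limitations

- The diffusion model's accuracy within a few aperture radii of the probe
  is limited by the $r_\mathrm{eff}$ regularization; quantitative claims
  hold beyond ~5 μm.
- The density-dependent threshold shift is phenomenological; it reproduces
  orderings and fold-changes, not mechanism, and its parameters are only
  anchored at the tenfold 5-minute shift and the 15-minute restoration.
- The imaging stage assumes disk-shaped, moderately overlapping cells; at
  high confluency quantification degrades and flagged exclusions grow.
- Resting/activated ratio distributions are plausible placeholders; users
  with their own calibration images should fit cutoffs on those instead.
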