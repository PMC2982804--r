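---
title: "A stochastic microtubule model of cell length homeostasis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic microtubule model of cell length homeostasis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlength)
```

## The model

Animal cells spreading on adhesive micropatterned lines extend to a
reproducible steady-state length that is independent of cell volume and
pattern width. `mtlength` implements a one-dimensional stochastic half-cell
model in which this homeostasis emerges from the collective behaviour of a
fixed pool of dynamic microtubules:

* `N_m` microtubules nucleate at the cell centre and grow towards the cell
  tip at velocity `v_g` (um/min).
* Each microtubule is subject to catastrophe as a memoryless hazard:
  `c_I` per minute in the cell interior, rising to `c_B` once the plus end
  is within the cortex zone -- within `w_c` = 3 um of the boundary,
  inclusive. A catastrophe instantly returns the microtubule to length zero
  and frees its nucleation site, so the growing count is constant; there is
  no rescue and no explicit shrinkage phase.
* The half-cell boundary `L_B` moves at
  `v_g * exp(-alpha / n) - v_B`, where `n` is the number of plus ends in
  the cortex zone; `exp(-alpha / 0) := 0`, so with no contacts the margin
  retracts at the bare rate `v_B`. The cooperation constant `alpha`
  controls how strongly multiple contacts jointly drive extension.
* Reported cell length is `2 * L_B` (half-cell symmetry).

Time integration is fixed-step Euler with step `dt` = 0.001 min; each
microtubule draws one uniform number per step and catastrophes with
probability `dt * c`. Validation enforces `dt * max(c_I, c_B) <= 0.1` so
the Bernoulli discretisation of the exponential hazard stays accurate
(unit tests verify exponential waiting times per zone by Kolmogorov-
Smirnov). Tips are capped at the boundary; a capped tip rides with the
boundary and remains under the cortical hazard. The boundary is floored at
zero. The RNG draw order (microtubule 1..N_m, then the boundary update)
is fixed, so a seed reproduces a trajectory bit for bit.

Default rates are the experimentally derived reference values: `v_g` = 15,
`c_I` = 0.3, `c_B` = 4.8, `v_B` = 0.4, with the free parameters at
`N_m` = 11 and `alpha` = 8 and the initial half-length `L0` = 10 um
(half the length of a freshly attached, still-spreading cell; the model's
steady state does not depend on it).

## Why homeostasis, and the mean-field oracles

At steady state the boundary is stationary on average, which pins
`E[exp(-alpha/n)] = v_B / v_g`. Treating `n` as a constant gives the
flux-balance root `n* = alpha / ln(v_g / v_B)` (2.21 at defaults),
independent of `N_m` and of cell length -- the model's key prediction
that only a couple of pioneer microtubules maintain the length.

Two refinements matter in practice and are implemented in
`equilibrium_contact_count()` / `mean_contact_count()`:

* Because contacts arrive as a superposition of many renewal processes and
  reside for an exponential time of mean `1/c_B`, the instantaneous count
  `n` is approximately Poisson with a small mean. `exp(-alpha/n)` is
  convex over that range, so by Jensen's inequality the stationary mean
  count sits *below* the deterministic root: solving
  `E_Poisson(lambda)[exp(-alpha/k)] = v_B/v_g` gives 1.59 at defaults, and
  long simulations average about 1.66 -- "approximately two", but
  measurably less than 2.21. Tests of the simulator compare against the
  fluctuation-corrected value; the deterministic root is an upper bound.
* `predicted_steady_length()` closes the loop with a renewal
  approximation: a tip survives the interior traverse of length
  `L - w_c` with probability `p = exp(-c_I (L - w_c)/v_g)`, resides in
  the zone for `1/c_B` on average, and the expected contact count
  `N_m p tau_B / E[T]` is equated to the contact target. With the
  Poisson-corrected target the prediction lands within a few percent of
  simulation (37.6 vs 36.2 um cell length at defaults); with the
  deterministic root it is a coarser, ~30% approximation. The oracle
  deliberately ignores boundary motion during a microtubule lifetime
  (boundary speed is far below `v_g` at steady state).

The same convexity argument explains the regression of steady-state
length on growth velocity. The published line (`y = 1.7 x - 2`) is
reproduced by the model in the half-cell convention -- the boundary
position is the model's read-out of half cell length, and only that
convention is consistent with the published ~44 um default-parameter cell
(a full-length reading of the regression would put it at 23.5 um).
`length_vs_vg_fit()` therefore returns both fits; at the standard sweep
(`v_g` in 6..18) the half-length slope is about 1.35 with intercept
about -2.

## Analyses

* `summarize_steady_state()` computes post-burn-in mean/sd/CV of length
  and the mean contact count. Burn-in defaults to 500 min. A stationarity
  check fits an OLS trend to the retained window; the window is flagged
  non-stationary only if the slope CI excludes zero *and* the implied
  drift across the window exceeds one standard deviation of length -- on
  autocorrelated series of many thousands of samples a pure CI rule flags
  negligible slopes.
* `homeostasis_map()` sweeps (`N_m`, `alpha`) grids, one independently
  seeded run per cell (seeds derived deterministically from the master
  seed and the grid coordinates), recording sd of length: low sd is
  homeostasis, and the map shows control requires moderate cooperation
  (`alpha` above a low threshold) but is insensitive to `N_m`. Length
  distributions are read ergodically from a single long run per cell, not
  from replicate endpoints.
* `perturb_parameter()` scales chosen rates mid-run while continuing the
  same microtubule state and RNG stream: halving `v_g` settles to a lower
  plateau while the contact count re-equilibrates near the new balance
  point (2.73 deterministic, ~2.3 simulated); cutting `c_B` by orders of
  magnitude makes cortical contacts effectively immortal, piles them far
  above the balance value and drives runaway elongation.
* `density_profile()` time-averages tip positions on a 0-100% axis of the
  instantaneous half-length; occupancy is `N_m` at the centre and decays
  approximately linearly (straight-line R^2 > 0.9 at defaults) to roughly
  the contact count at the edge.

## Synthetic microscopy and its measurements

The generator (`render_patterned_cell()`, `simulate_comet_tracks()`)
emulates the statistical structure the measurement procedures assume, with
exact ground truth: a rectangular cell confined to a vertical adhesive
stripe; straight filaments with angles from a point-mass, uniform, or
axial von Mises model (the doubled angle is von Mises distributed -- the
standard treatment of orientation data); 1-px anti-aliased strokes
depositing a calibrated `intensity_unit` (100 grey levels) per pixel of
length; Gaussian optics (sigma 1 px by default) and additive Gaussian
noise; and plus-end comet tracks whose cortical fate follows the
contact-angle rule (bend at |angle| <= 25 degrees, catastrophe at
>= 32 degrees, a fair coin in the ambiguous band -- the band probability
is exposed as `mixed_bend_prob` since only "similar probability" is
established).

It does *not* emulate curved filaments, depth structure, photobleaching,
uneven illumination, or real segmentation difficulty, so passing round
trips validate the measurement implementations, not their robustness on
difficult real micrographs.

The measurements (`measure_pattern_width()`, `measure_cell_length()`,
`orientation_distribution()`, `classify_contact_fates()`,
`estimate_mt_count()`) implement the published procedures: horizontal-scan
averaging for pattern width; bounding extent along the line (patterned)
or convex-hull Feret diameter (non-patterned) with a mononucleate filter;
median filter + Otsu threshold + oriented straight-line kernels for the
angular distribution of linear polymer; rule-based fate classification
from pre-contact track direction; and background-subtracted integrated
intensity divided by the single-filament calibration for counts.

Orientation internals, where the published description leaves freedom:
kernels are 13 px long, stepped in 5 degree bins, sampled at subpixel
positions with bilinear interpolation; each polymer pixel goes to its
best-scoring bin, with bins within 0.25 samples of the maximum treated as
tied and resolved towards the axis (thick blurred strokes make nearby
angles exactly tie in coverage); pixels whose best kernel coverage is
below 0.85 of the kernel length (blob ends, stray noise) are excluded as
non-linear polymer, mirroring the normalisation by *linear* polymer.
Angular resolution is set by stroke width: a stroke of width `w` px ties
all angles within `asin((w-1)/2 / half-kernel)`, about 10 degrees for the
default 1 px optics and below one bin for 0.5 px optics, which is why
oblique-angle validation fixtures use the sharper point-spread setting.
Per-image recovered distributions are unbiased with a per-image scatter
of a few hundredths in circular variance, so distribution-level checks
pool several seeded images.

## Numerical choices and degenerate inputs

Tolerances: the renewal root is solved to |f| < 1e-9; orientation masses
sum to 1 to 1e-9; exact ties in orientation scoring resolve
deterministically (axis first, then bin order). Degenerate inputs are
first-class: `N_m = 0` (pure retraction), `alpha = 0` (no cooperative
brake; runaway), `c_B = c_I` (no cortical disadvantage; variability
grows), empty masks and multinucleate cells (errors or structured
rejections), `v_g <= v_B` (no equilibrium; refused by the oracles and the
velocity sweep).

Problem sizes: published sweeps use 10,000-min simulations; the package's
test suite uses 600-4,000 min runs and coarse grids, which this model's
short correlation time makes statistically equivalent for the properties
checked, and the acceptance script runs the full 10,000-min protocol.

## Known limitations

* The model is strictly one-dimensional and mechanics-free: no force
  balance, membrane tension, or actin, by design.
* The renewal oracle assumes a static boundary and Poisson contact
  counts; both are approximations, quantified above.
* The time-averaged contact count depends on the convention for what
  counts as "contact" (the 3 um zone, used here for both the hazard switch
  and the advance law, per the model's single definition of the cortex);
  steady-state *length* is sensitive to this choice even though the
  contact count is not.
* The orientation pipeline quantises angles to 5 degree bins and snaps
  near-axial plateaus to the axis; distribution statistics inherit a
  small but nonzero smoothing, which pooled comparisons absorb.
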