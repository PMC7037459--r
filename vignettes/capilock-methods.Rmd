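---
title: "Methods: cation-pi lock geometry and ion-binding descriptors"
author: "capilock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cation-pi lock geometry and ion-binding descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capilock)
```

## Scope and scientific background

Neuronal calcium sensors of the EF-hand family, such as the guanylate
cyclase activating protein GCAP1, switch between a target-activating and a
target-inhibiting conformation as calcium and magnesium exchange on their
functional EF-hands. Disease-associated substitutions can jam this switch.
One proposed jamming mechanism is a *double cation-pi lock*: an arginine
introduced in the hinge between the two EF-hand lobes (position 86) wedges
its guanidinium between two tryptophan side chains (positions 21 and 94),
forming two simultaneous, laterally oriented cation-pi contacts that pin
the hinge in the activator-like conformation.

`capilock` provides the quantitative layer needed to investigate this kind
of mechanism on desk scale:

* cation-pi geometry detection and axial/lateral classification on
  structures and multi-model ensembles (`cation_pi_geometry()`,
  `classify_cation_pi()`, `bridge_scan()`);
* trajectory descriptors: per-residue RMSF after rigid-body superposition
  (`rmsf()`), inter-residue distance series with running-average smoothing
  (`distance_series()`, `running_stats()`), and the hinge-opening
  descriptor `twisted_accordion()` (the D168-R178 C-alpha distance);
* multi-site ITC isotherm forward modelling and fitting
  (`predict_heats()`, `fit_itc()`) with the apparent-affinity summary
  `kd_apparent()`;
* CD spectral descriptors (`theta_ratio()`, `delta_theta()`,
  `normalize_near_uv()`), 4-parameter Hill melt fitting (`fit_melt()`) and
  fluorescence-titration normalisation (`normalize_fluorescence()`);
* seeded generators (`make_*`) producing every input class with planted
  ground truth, so each analysis can be validated against its exact
  inverse or a closed-form expectation.

MD simulation itself, homology modelling, secondary-structure
deconvolution and thermodynamic deconvolution of melts are out of scope.

## Cation-pi geometry

For a ring with at least three atoms, the centroid is the arithmetic mean
of the ring-atom positions and the plane normal is the direction of least
orthogonal variance (total least squares, smallest principal axis of the
centered coordinates). The descriptor triple for a cation point is:

* `d` — centroid-to-cation distance (Angstrom);
* `theta` — angle between the plane *normal* and the centroid-to-cation
  vector, folded to [0, 90] degrees. theta = 0 is the classical stacked,
  axial approach over the ring face; theta = 90 is an in-plane, lateral
  approach. This convention makes a reported "lateral" window of
  60-90 degrees self-consistent; the complementary plane-referenced angle
  is available via `theta_from_plane = TRUE`.
* `phi` — the minimum over the ring hydrogens of the angle
  cation-centroid-H. phi near zero means the cation points straight at a
  ring C-H edge, the hallmark of a lateral contact. Which hydrogen a study
  used is rarely stated, so the minimum (the hydrogen the cation aims at)
  is the default; when a heavy-atom-only model has no ring hydrogens, phi
  is reported missing and classification falls back to theta and d with a
  warning.

Classification defaults (`d_max` = 6.0 A, `phi_max` = 30 deg,
`theta_lateral_min` = 60 deg, `theta_axial_max` = 30 deg) are deliberate
package choices: only the 60-90 degree lateral theta window is a published
criterion, the rest bound what "near" and "aimed at a hydrogen" mean. All
four are arguments everywhere and echoed into report headers.

Ring definitions: tryptophan uses the six-membered benzo ring of the
indole by default (one well-defined plane, four ring hydrogens), with the
five-ring and all-nine-heavy-atoms alternatives available; Phe/Tyr use the
standard six-ring. The arginine reference point is CZ, which approximates
the guanidinium charge centroid and exists in every heavy-atom model; the
NH1/NH2/NE mean is available through the `atom` field of a cation
reference.

### The feasible (theta, phi) set and the exact-inverse generator

`make_ring_cation(theta, phi, d)` builds a hexagonal ring (radius 1.40 A)
with in-plane hydrogens (radius 2.48 A) and places the cation so the
analysis recovers the planted triple exactly. Because ring hydrogens lie
in the plane, a cation at polar angle theta can make an angle phi with an
in-plane direction only when |cos phi| <= sin theta, i.e.
phi in [90 - theta, 90 + theta]. Outside that set the construction raises
an infeasibility error rather than silently bending the geometry. Note the
lateral window (theta > 60, phi <= 30) lies inside the feasible set — the
physics and the classification criterion agree. With all six hydrogens
present the *reported* phi is a minimum and can undercut the planted value
once the cation azimuth passes halfway to the neighbouring hydrogen; the
single-reference-hydrogen variant (default) is therefore the exact inverse
used for round-trip validation, and `make_bridge_pdb()` fixtures restrict
planted phi to at most 90 degrees so the intended hydrogen stays the
minimizer.

## Trajectory descriptors

Superposition is a proper-rotation least-squares fit (SVD with determinant
correction). `rmsf()` fits every frame to the iteratively refined mean
structure (fit to the first frame, average, re-fit, re-average; two
refinement passes), then reports
sqrt(mean_t |r_i(t) - mean(r_i)|^2) per selected atom; `ref = "first"`
reproduces the fit-to-reference convention of common MD toolchains. The
two conventions differ negligibly for well-behaved trajectories but the
mean-structure reference is statistically cleaner.

`running_stats()` implements a centered moving window (window w keeps
floor((w-1)/2) frames before and floor(w/2) after the center); edges use
the truncated window rather than padding, so no data is fabricated at the
ends — smoothed traces differ from zero-padded implementations only within
half a window of the edges. The SD is the population SD computed in a
second pass about each window mean, which agrees exactly with a direct
windowed computation (a cumulative-sum-of-squares shortcut loses up to
eight digits to cancellation and was rejected). The default window of 100
frames corresponds to 1 ns of smoothing at a 10 ps frame spacing.

The two-state switch generator plants a deterministic jump of one atom's
mean position; with the default window the smoothed hinge distance crosses
the midpoint within half a window of the planted switch frame, which is
the resolution limit of centered smoothing.

## ITC: independent-site-class model

With site classes i = 1..n (one site per protein copy each), free ligand
X solves the monotone mass balance

    X_total = X + M_total * sum_i X / (K_Di + X),

bracketed by bisection and polished by Newton steps to 1e-12 relative
tolerance (vectorised over injections). Cumulative heat after injection k
is Q_k = V0 * M_k * sum_i dH_i * X / (K_Di + X) and the observed
per-injection heat carries the displaced-volume correction

    dQ_k = Q_k - Q_{k-1} + (dV_k / V0) * (Q_k + Q_{k-1}) / 2,

with sequential perfusion dilution (each injection displaces its own
volume: concentrations scale by 1 - dV/V0 per injection). At saturation
the correction term cancels the dilution loss exactly, so tail heats decay
to zero as they should. Schedule defaults are the published titration
conditions where stated (20 uM cell protein, 0.5 mM calcium or 10 mM
magnesium syringe, 5 uL injections, 25 C) and instrument-class values
where not: a 1.4 mL perfusion cell and 55 injections (275 uL, within a
standard syringe load). Units: K_D molar, dH kcal/mol, heats ucal.

`fit_itc()` minimises squared per-injection residuals over
(log10 K_D, dH) per class with Levenberg-Marquardt, 32 seeded random
starts (K_D log-uniform in [1e-9, 1e-2] M — also the hard box of the
optimiser — dH uniform in [-20, 25] kcal/mol), classes returned sorted
ascending by K_D to remove label switching, and uncertainties from the
local quadratic approximation. A class is flagged unidentifiable when it
sits at the K_D search bound or its interval overlaps a neighbouring
class; over-parameterised fits (more classes than the data support) are
flagged this way rather than silently reported.

`kd_apparent()` summarises a model as the geometric mean of its class
K_Ds. Published per-variant "overall apparent affinity" values are
reproduced by this definition in six of eight cases to within rounding of
the printed table (e.g. (16.3 nM * 36 nM * 0.25 uM)^(1/3) = 52.7 nM
against a printed ~52 nM); the remaining two printed values (~992 nM
where the geometric mean of the printed class constants gives 1.05 uM,
and ~73 nM where it gives 32.5 nM) cannot be reproduced from their own
table rows by this or any per-row summary we are aware of, and are
treated as probable rounding or transcription artefacts; they are
documented, not asserted, in the test suite.

### What ITC recovery can and cannot show

At c = [M]/K_D in the hundreds-to-thousands (20 uM protein against
nanomolar sites), a direct titration with 5 uL x 0.5 mM granularity
contains little information about the *absolute* K_D scale: each site's
saturation transition is rounded over less than one injection, so the
likelihood is nearly flat along a collective log-K_D shift while the K_D
ratios and enthalpies stay well determined. `fit_itc()`'s reported
`kd_se` for the tight classes of such data is of the same order as the
estimates themselves, which is the honest reading. Recovery of nanomolar
site constants from single noisy synthetic titrations therefore scatters
over roughly an order of magnitude seed to seed; recovery tests on such
conditions characterise the estimator, not a defect of the fitter, and
tight acceptance windows on the smallest recovered K_D should be expected
to fail for some seed sets. Weak sites titrated at c near or below 1
(e.g. hundreds-of-micromolar magnesium sites) are identifiable but their
precision is limited by the site's total heat relative to the noise.

## CD and melt descriptors

`theta_ratio()` reads ellipticity by linear interpolation at exactly
222.0 and 208.0 nm and returns their ratio — a shape descriptor of
all-alpha proteins insensitive to concentration and path length.
`delta_theta()` is the fractional 222 nm change of an ion-loaded form
relative to the ion-free (EGTA) form. `normalize_near_uv()` subtracts the
mean ellipticity over 310-320 nm, where a protein near-UV CD spectrum
carries no signal, removing cuvette-positioning offsets; it is idempotent
and commutes with constant offsets.

`fit_melt()` fits theta(T) = theta_f + (theta_u - theta_f) *
T^h / (T_m^h + T^h) with T in degrees C as scanned (20-96 C by default);
the Hill exponent absorbs the temperature scale, and theta(T_m) is the
baseline midpoint under any scale, so midpoint semantics do not depend on
the Celsius/Kelvin choice. Multi-start runs a grid of 8 T_m values
(spanning the scan and slightly beyond) by 4 exponents {5, 15, 30, 60}. A
fit is *censored* — reported as "> 96"-style, matching how melts without
a clear transition are tabulated — when any of: the fitted T_m exceeds the
scan maximum; the fitted in-scan amplitude is below 3x the residual SD
(no detectable transition); or the fitted transition fails to reach 90%
completion inside the scan (T_m * 9^(1/h) > T_max). The third condition
is needed because a transition truncated just beyond the scan can be
locally well fitted by a small-amplitude sigmoid whose nominal midpoint
falls inside the scan; requiring the unfolded baseline to be established
in-scan removes exactly those extrapolation-supported midpoints. With the
default scan and exponents of 15-40, genuine midpoints up to the
mid-80s C remain uncensored.

## Synthetic data: what it emulates and what it does not

Generators are bit-exact functions of their arguments including the seed,
and each has a consumer-side check: planted (theta, phi, d) round-trips
through `cation_pi_geometry()` to 1e-6; Gaussian trajectories use
per-coordinate sigma = amplitude/sqrt(3) so the expected RMSF equals the
planted amplitude exactly (chi closed form); noise-free thermograms and
melt curves equal the forward models exactly.

The emulation is deliberately minimal: trajectory noise is isotropic,
independent and uncorrelated in time (no Langevin memory, no anisotropy,
no concerted motions), the two-state switch is a clean step, ITC noise is
iid Gaussian on integrated heats (no baseline drift or peak-integration
error), and melt noise is iid on ellipticity (no scan-rate hysteresis or
aggregation artefacts). Passing recovery tests on these inputs
demonstrates correctness of the estimators under their own model
assumptions — not robustness to the correlated noise, baseline problems
and model misspecification of real instruments and force fields. Real
structure coordinates for the motivating sensor are not redistributed
here, so all geometry validation runs on synthetic fixtures with
GCAP1-like residue numbering (21/86/94/168/178).

## Problem sizes and numerical choices

Validation uses desk-scale sizes chosen to make closed-form comparisons
sharp: 5000-frame trajectories for the RMSF closed form (3-standard-error
agreement), 2000 frames for amplitude rank recovery (Spearman rho >
0.95), 500-draw geometry round trips, 55-injection thermograms and
153-point melt scans with 10-seed recovery batches. Free-ligand roots are
solved to 1e-12 relative tolerance; plane normals use SVD (collinear
rings rejected at a 1e-9 conditioning threshold); rigid fits enforce
det(R) = +1; degenerate inputs (coincident cation and centroid, windows
longer than a series, melts shorter than 8 points or 20 C span) raise
typed errors rather than producing numbers.

## Known limitations

* Binding is independent-sites with unit stoichiometry per class:
  cooperative, sequential and competition (mixed-ion) models are not
  fitted, and a floating stoichiometry is not offered.
* The apparent-K_D summary is a geometric mean; it is not an
  experimentally defined macroscopic constant and inherits the caveats
  above.
* phi requires ring hydrogens; heavy-atom structures classify on theta
  and d only.
* Absolute K_D recovery from very-high-c titrations is information-limited
  (see above), a property of the experiment design, not of the software.
* PDB output carries the format's 1e-3 A coordinate precision; round
  trips through files are exact only to that quantum.
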