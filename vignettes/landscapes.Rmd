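---
title: "Reconstructing aptamer binding and stability landscapes"
author: "aptascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing aptamer binding and stability landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptascan)
```

# Scope

`aptascan` reconstructs the thermodynamic binding and stability landscapes
of a fluorogenic RNA aptamer from chip-based saturation-mutagenesis
fluorescence data. A fluorogenic aptamer (the canonical example is Spinach
with its ligand DFHBI) emits fluorescence only as the aptamer–ligand
complex, so a microfluidic chip that transcribes every mutant in its own
unit cell, pulls the RNA down onto a spot, and images the spots across a
ligand titration and a temperature ramp measures — for each mutant — a
binding curve and a melting curve. From those the pipeline derives four
per-mutant parameters relative to wild type: relative saturation
fluorescence $S_m$, binding free energy change $\Delta\Delta G$, binding
enthalpy change $\Delta\Delta H$, and apparent melting temperature change
$\Delta T_m^{ap}$.

The package covers the chain end to end: mutant-library enumeration and
two-fragment assembly design, chip layout planning, spot segmentation and
signal extraction, isotherm and melt fitting, Van't Hoff regression,
landscape assembly with replicate error propagation, composite per-position
scoring, quantile-based candidate selection, compensatory double-mutant
rescue analysis, and a seeded synthetic-data generator that the test suite
uses to demonstrate parameter recovery.

# Models and assumptions

## Binding

Two-state binding $S + D \rightleftharpoons SD$ with
$K_d = [S][D]/[SD]$. The background-corrected, RNA-normalised spot signal
is proportional to the bound fraction, so a titration follows

$$ y(D) = A \cdot \frac{D/K_d}{1 + D/K_d}, $$

with free-ligand concentration $D$ (µM) and plateau amplitude $A$.
Assumptions: no ligand depletion (the perfused ligand concentration is the
free concentration), no cooperativity (a single site; no Hill exponent),
and signal linear in complex concentration. `fitBinding()` estimates
$(K_d, A)$ by bounded nonlinear least squares.

Fitting the plateau $A$ rather than dividing the curve by its
top-concentration point matters: with the default series ending at 43.5 µM
and $K_d$ near 1 µM the top point reaches only ~97% of saturation, and
normalising by it biases the apparent plateau and $K_d$ low. The
`normalizeAtMax = TRUE` compatibility mode reproduces the
normalise-by-top-point convention exactly for comparison with legacy
analyses.

## Temperature dependence and the Van't Hoff regression

Titrating at several temperatures (default 19, 23, 28 °C) gives $K_d(T)$,
and `vantHoff()` regresses $\ln K_d$ (converted to molar) on $1/T$. Under
the default `"binding"` convention the dissociation-direction identity

$$ \ln K_d = \frac{\Delta H}{RT} - \frac{\Delta S}{R} $$

is used, so $\Delta H = R \cdot \mathrm{slope}$ is the *binding*
(association) enthalpy with $\Delta H < 0$ meaning exothermic binding —
and, consequently, $K_d$ rising with temperature (weaker binding when
warm), which is what exothermic binders show experimentally. An
`"as_printed"` convention applying the association-form relation
$\ln K = -\Delta H/(RT) + \Delta S/R$ literally to $K_d$ is retained; the
two differ only by an overall sign on both coefficients. We made the
physically-signed convention the default because a sign-ambiguous "9
kcal/mol exothermic" is best resolved as $\Delta H = -9$ kcal/mol, and
because the generator and the fitter must agree on one convention for
recovery to be meaningful.

The standard-state unit of $K_d$ inside the logarithm affects only
$\Delta S$ (by $R \ln c$ under unit rescaling by $c$), never $\Delta H$;
molar is used, fixed.

## Mutant-vs-wild-type differences

$$ \Delta\Delta G(T) = RT \ln\!\left(K_d^m / K_d^{wt}\right), \qquad
   \Delta\Delta H = \Delta H_m - \Delta H_{wt}. $$

With the default `favorable_negative` convention a tighter binder has
negative $\Delta\Delta G$. The opposite (`as_printed`) sign is available
because the literature is inconsistent on this point; the package default
makes all four landscape parameters orientable as "larger oriented value =
more beneficial", which the composite score assumes.

## Stability

Melting of the complex at saturating ligand (default 43.5 µM, 23–49 °C in
2 °C steps) is modelled as a two-state folded/unfolded equilibrium with
folded fraction

$$ f(T) = \frac{1}{1 + \exp\!\big(\tfrac{\Delta H_T}{R}
   (1/T_m^{ap} - 1/T)\big)}, \qquad T_m^{ap} = \Delta H_T / \Delta S_T. $$

$f(T_m^{ap}) = 1/2$ exactly, and the hot-side asymptote is
$1/(1+e^{\Delta H_T/(R T_m^{ap})})$ — small but not zero, which the fitter
respects rather than forcing a zero baseline. No heat-capacity term
($\Delta C_p = 0$) and no sloped baselines are modelled. The measured
signal is $A \cdot f(T)$; by default $A$ is free (robust when the first
point is noisy), and `amplitudeMode = "anchor"` pins it to the
lowest-temperature signal, the chip assay's normalisation (the two
coincide for clean monotone melts).

Misfolding mutants can show a *bimodal* profile — no fluorescence at
either temperature extreme and a moderate maximum in between (the active
conformation is only reached at intermediate temperature).
`detectBimodal()` flags an interior maximum of the window-3-smoothed curve
whose prominence over both ends exceeds 3× a robust point-noise scale
(derived from second differences, so the smooth trend does not inflate
it). Three is the usual "clearly above noise" multiplier; the flag is
deliberately binary — multi-transition deconvolution is out of scope.

## Composite score

For the structural read-out the four parameters are combined per SPM:
each parameter is oriented so larger = more beneficial (higher $S_m$,
more favourable $\Delta\Delta G$ and $\Delta\Delta H$, higher
$\Delta T_m^{ap}$; configurable), min–max normalised over all fluorogenic
SPMs to $X_i \in [0,1]$, with non-fluorogenic SPMs set to $-1$ on every
parameter; the sum $S_j = \sum_{i=1}^4 X_i \in [-4, 4]$ is aggregated per
position and smoothed with a window-3 moving average,
$\mathrm{Score}(n) = \tfrac13\sum_{j=n-1}^{n+1} S_j$.

Two points were genuinely open and are package decisions:

* Each position carries three SPMs but the smoothing indexes positions;
  we average the three SPM scores per position before windowing (the mean
  is robust to one outlier substitution; `aggregate = "max"` is exposed
  for an optimistic read-out).
* At the two terminal positions the window is truncated to the available
  neighbours rather than padded or dropped, so the track has full length
  and stays inside the input range.

Paired stem positions carry the same structural burden, so their scores
mirror each other — the symmetry visible in score plots of real
landscapes. Note the mirror is exact (up to noise) only for positions
whose whole window lies inside the stem: stem-terminal windows mix in
unpaired flanking neighbours by construction.

## Error propagation

Replicates are fitted independently and combined afterwards (matching the
four-repeat error structure of the assay), never pooled into one fit. The
default per-parameter error is the recipe used with this assay family

$$ \sigma = \sqrt{\Big(\tfrac{\sum_j (X_j - \bar X)^2}{(N-1)N}\Big)^2 +
   \Big(\tfrac1N \sum_j \sigma_j^2\Big)^2 }, $$

which squares two already-squared terms and therefore carries units of
$\sigma^2$; it is implemented literally (`mode = "as_printed"`) so results
remain comparable with analyses that use it, and a conventional
$\sqrt{\mathrm{SEM}^2 + \overline{\sigma_j^2}}$ quadrature mode is
provided for users who want a dimensionally standard error.

## Candidate selection and rescue

`selectQuantiles()` takes the fluorogenic mutants strictly beyond the
empirical type-7 $1-q$ quantile of the oriented parameter (default
$q = 0.10$), intersecting across parameters when several are given —
mutants beneficial in fluorescence *and* binding *and* stability.
Quantiles are computed over fluorogenic mutants only: non-fluorogenic
mutants have no thermodynamic parameters and would only pad the tail.

The rescue index for a compensatory double mutant,
$(S_{dpm} - S_{spm})/(S_{wt} - S_{spm})$ against the more deleterious of
the two constituent SPMs, is a package-defined statistic (the experimental
read-out is usually shown as SPM-vs-DPM scatter plots without a named
index): 1 = full rescue to wild type, 0 = none, negative = aggravation,
clipped to $[-1, 2]$ for reporting with the raw value retained.

# Library design

The saturation scan emits, per position, the one transition and the two
transversions, in a fixed order (transition first, transversions
alphabetically) so enumerations are byte-reproducible; an $n$-nt reference
gives $3n$ SPMs (261 for 87 nt). The compensatory double-point scan emits
three DPMs per unordered position pair — the class-matched joint
substitution of both partners — for $3\binom{n}{2}$ in total (11223 for
87 nt); with a base-pairing map the partner substitution instead restores
Watson–Crick complementarity, the rescue set used in stem screens.
Coordinates are 1-based; deletions (single positions or named regions such
as a knob deletion) are applied after substitutions, and every
substitution is checked against the reference base so coordinate drift
fails loudly.

Fragment designs split a mutant into 5′/3′ fragments sharing a 19-nt
overlap centred on the sequence midpoint (the overlap length is the
assay's two-oligo stitch-PCR design; the centre split is a package choice
— the real oligo boundary is assay-specific and any split with the right
overlap reassembles identically). Mutations left of the overlap place the
mutant oligo 5′, right of it 3′, inside it (or straddling) both.
`stitchFragments()` is the exact inverse. Promoter/anchor/probe tags are
opaque configurable strings.

# Spot quantification

Spots are segmented on the anchor channel by least-squares fitting a
7-parameter generalized 2D Gaussian (amplitude, sub-pixel centre,
independent widths, rotation, constant offset), initialised from
intensity moments. The foreground disk radius is
$2\max(\sigma_x,\sigma_y)$ — capturing ≥95% of the Gaussian energy
deterministically — and the background annulus extends from the disk edge
to 1.5× the radius. Signals are medians (robust to ≤10% outlier pixels):
$S_m = (S_i - S_b)/S_p$ with complex-channel foreground $S_i$, annulus
background $S_b$, and the raw probe-channel foreground median $S_p$ (the
probe is not background-corrected; its spot sits on the same local
background that already cancels in the numerator, and correcting it would
couple the two channels' noise). Flat or amplitude-less images return a
flagged segmentation failure, never a silent drop. Images are optional
inputs throughout — the pipeline accepts pre-tabulated signals, since most
users will not have raw images.

# The synthetic generator

`makeTruth()` draws a ground-truth ensemble anchored at the assay's
wild-type values: $K_d = 1.18$ µM at 23 °C, binding enthalpy $-9$
kcal/mol, melt midpoint at 36 °C (mid scan window), unfolding enthalpy 60
kcal/mol. Per-SPM perturbations are normal — $\Delta\Delta G$ sd 0.3
kcal/mol, $\Delta\Delta H$ sd 1.5 kcal/mol, $\Delta T_m$ sd 2 °C — with a
lognormal amplitude (sd-log 0.1) and a 29% Bernoulli loss of
fluorogenicity, magnitudes chosen to bracket the extremes observed in real
landscapes (a ~1.3-fold maximal fluorescence gain, melting gains of a few
°C, $K_d$ spread over 1–2 orders of magnitude, 76 of 261 SPMs dark).
$K_d(T)$ follows the same Van't Hoff relation the fitter assumes, keeping
generator and fitter in one model family so recovery tests are exact in
the noiseless limit. Planted stems copy the class-matched perturbations to
partner positions and penalise both (default amplitude ×0.25), which
plants the score symmetry; `simulateCompensation()` emulates the rescue
screen (disrupting SPM ~0.2× wild type, pairing-restoring DPM ~0.9×,
mismatched control DPM unrescued).

Measurement noise is multiplicative (sd 2%) plus additive (sd 0.005),
calibrated so replicate CV sits comfortably inside the assay's <5% QC
bound. Defaults mirror the chip designs: 12-point titration 0.435–43.5 µM
(the titration point count is reported inconsistently as 12 or 13 in
assay descriptions; 12 is the default and both are accepted on input) at
19/23/28 °C (likewise 18 vs 19 °C; 19 is the default and the temperature
set is configurable), 23–49 °C melts in 2 °C steps, 4 replicates.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: ligand depletion, photobleaching and
other photophysics, spatial chip gradients and flat-field effects,
baseline slopes in melts, heat-capacity curvature of the Van't Hoff plot,
non-two-state (intermediate-state) unfolding, and correlated replicate
errors. Recovery results on synthetic data are a check of the estimation
machinery, not of the assay.

# Numerical choices

* Optimiser: Levenberg–Marquardt (`minpack.lm`) with box bounds, on
  log-parameters for positive quantities ($K_d$, amplitudes,
  $\Delta H_T$); tight tolerances (`ftol = ptol = 1e-15`) so noiseless
  recovery is exact to ~1e-9 relative.
* Multi-start: binding fits start from three log-spaced $K_d$ values
  across the concentration range; melt fits from three unfolding-enthalpy
  scales (20/60/150 kcal/mol) with the transition midpoint initialised at
  the half-range crossing. The best deviance wins; starts are
  deterministic, so there is no hidden RNG in fitting.
* Bounds: $K_d \in [0.01\,\min D,\ 100\,\max D]$ (outside that window the
  titration carries no information); $T_m$ within the scanned range ±30 K;
  $\Delta H_T \in [0.5, 1000]$ kcal/mol.
* Standard errors come from the residual-variance-scaled inverse Hessian,
  mapped through the delta method for log-parameters.
* Degenerate inputs are flags, not errors: all-zero curves are
  `non_fluorogenic`, rising melts `no_transition`, failed spot fits
  `converged = FALSE`; schema violations in files *are* errors, naming
  file, row and column.
* Non-fluorogenic threshold: 3× the standard deviation of the
  negative-control signals when controls are present (floored at 0.02),
  else the floor — the count of dark mutants is an observable, the cutoff
  is not, so it is derived from the controls.
* Quantile ties: selection is strictly-above-threshold on the type-7
  quantile, deterministic; candidate lists are ordered by decreasing
  benefit, ties by id.
* Seeds: every stochastic function takes an explicit seed and restores
  the caller's RNG state; identical (config, seed) gives byte-identical
  outputs.

# Test problem sizes

The suite exercises recovery at sizes chosen to keep the whole run fast
while leaving every statistic well-determined: full-length (87-nt)
enumeration for the combinatorial counts; 6–30-nt references for
end-to-end pipeline checks (noiseless runs reproduce the generating truth
to ~1e-6); 100 seeded Monte-Carlo repeats for noisy single-curve recovery;
a 103-mutant ensemble (34-nt reference, all fluorogenic) for the
noisy-chip recovery statistics; 50 random curves each for the
fitter-vs-grid-search (400×400) oracle comparisons; and an 8-bp planted
stem in a 30-nt reference for the symmetry and rescue properties.

# Known limitations

* Binding is strictly two-state and depletion-free: no Hill coefficients,
  two-site models or ITC-style heat fits.
* Melts have flat baselines and no $\Delta C_p$; strongly sloped real
  baselines will bias $T_m^{ap}$.
* The bimodal detector flags, it does not deconvolve; mutants flagged
  bimodal should have their $T_m^{ap}$ treated as unreliable.
* The score track is only as meaningful as the orientation assumption
  (each parameter monotonically beneficial); parameters with
  non-monotonic optima (e.g. fluorescence vs stability trade-offs) are
  better examined through `correlateLandscapes()`.
* Spot quantification assumes one dominant spot per image; gridding of
  whole-slide scans, flat-field correction and spectral unmixing are out
  of scope.
* The package does not map scores onto 3D structures and does not predict
  secondary structure; the stem-symmetry diagnostic is a correlation, not
  an inference engine.
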