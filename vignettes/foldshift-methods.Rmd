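---
title: "Models and methods in foldshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in foldshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldshift)
```

`foldshift` analyses alanine-scanning spectroscopy of a small (79-residue)
propeptide-like cysteine protease inhibitor whose inhibitory activity
requires a pH-driven molten globule-to-ordered structure transition. This
vignette is the package's account of its models, estimators, parameters and
numerical choices. Every empirical statement here is computed by the test
suite or the analysis scripts; nothing is asserted that the code does not
measure.

## Two-state thermal unfolding

A CD melt monitored at a single wavelength is modelled as a two-state
equilibrium N ⇌ D with linear baselines:

$$Y(T) \;=\; \frac{(Y_n + M_n T) + (Y_d + M_d T)\,K(T)}{1 + K(T)},
\qquad K(T) = \exp\!\left(-\frac{\Delta H\,(1 - T/T_m)}{R\,T}\right)$$

with $T$ in Kelvin, a van't Hoff enthalpy $\Delta H$ (kcal·mol⁻¹), melting
temperature $T_m$ (K), and $R = 1.987204\times10^{-3}$ kcal·mol⁻¹·K⁻¹.
Assumptions: two states only, $\Delta C_p = 0$ over the scanned range
(van't Hoff), and baselines linear in temperature. The model is
parameterised by $(\Delta H, T_m)$ rather than $(\Delta H, \Delta S)$: the
two are equivalent ($\Delta S = \Delta H/T_m$), but $T_m$ is directly
identified by the transition midpoint, which conditions the optimisation
much better. Derived quantities:
$\Delta G_u(T) = \Delta H (1 - T/T_m)$, fraction unfolded $= K/(1+K)$
(exactly 0.5 at $T_m$), and
$\Delta\Delta G_u = \Delta G_u(\text{mutant}) - \Delta G_u(\text{reference})$
at a shared reference temperature (negative = destabilising).

### Fitting

`fit_two_state()` minimises squared residuals by Levenberg–Marquardt
(`minpack.lm::nlsLM`, `ftol = ptol = 1e-12`, 500 iterations).
Initialisation: $T_m^{(0)}$ at the temperature of maximum $|dY/dT|$ by
central differences (clamped two grid points away from the scan edges so
the baselines keep leverage); baselines by ordinary least squares on the
first and last 15% of points; three restarts at
$\Delta H^{(0)} \in \{15, 30, 60\}$ kcal·mol⁻¹, keeping the attempt with
the lowest residual sum of squares. Bounds keep
$\Delta H \in [0.1, 500]$ and $T_m$ within the scan ± 50 K.

A fit is `converged` only when the optimiser met tolerance **and** the
fitted $T_m$ lies inside the scanned range — an extrapolated midpoint is
not a measured one. The qualitative `cooperative` label is
"non-cooperative" when the fit failed, $T_m$ left the scan, fitted
$\Delta H < 5$ kcal·mol⁻¹, or the transition amplitude at $T_m$ is below
3× the residual RMSE; this reproduces the usual qualitative
"progressive, non-cooperative unfolding" calls without inventing a test
statistic. An exactly linear trace makes the Jacobian singular; in that
degenerate case the function returns the least-squares line as both
baselines with `converged = FALSE` and a warning rather than erroring.

Measured performance (`analysis/03_parameter_recovery.R`, 50 fits per
level, truth $\Delta H = 50$, $T_m = 58$ °C on the 4–96 °C, 2 °C grid): at
noise 1/3/5% of the transition amplitude the median $|T_m|$ error is
≈0.12/0.25/0.37 °C and the median relative $\Delta H$ error
≈2/4/9%. Precision degrades roughly in proportion to $1/\Delta H$: the
broader the transition, the less sharply the midpoint is identified — at
$\Delta H = 30$ the median $T_m$ error at 3% noise is ≈0.7 °C. The
recovery test in the suite therefore uses the sharply cooperative regime
($\Delta H = 50$); a grid-search oracle (baselines solved linearly at each
$(\Delta H, T_m)$) independently confirms the optimiser reaches the global
residual floor within 5%.

### Reference temperatures and units

Temperatures are degrees Celsius at every I/O boundary (the acquisition
convention) and Kelvin inside all thermodynamics. Free energies default to
a 293.15 K (20 °C) reference, the temperature at which denatured-state
populations are compared across the panel; 277 K is the other conventional
choice and both are plain arguments. The CD signal may be converted to mean
residue ellipticity with `mdeg_to_mre()` —
$[\theta] = \theta_{\mathrm{mdeg}} / (10\, l\, c\, n)$ with path length $l$
in cm, molar concentration $c$ and residue count $n$ — but the melt fit is
invariant to this linear rescaling, so either unit may be fitted.

## Double-mutant cycles

For background (wt), single mutants (m1, m2) and double mutant (dm), the
coupling energy is the Horovitz–Fersht non-additivity

$$\Delta\Delta G_{\mathrm{int}} = \Delta G_{wt} - \Delta G_{m1} -
\Delta G_{m2} + \Delta G_{dm},$$

computed at a shared reference temperature from the four melt fits. The
sign convention makes an intact favourable side-chain interaction (e.g. a
salt bridge that both single mutations each break) positive. Algebraic
identities, all tested: exchanging the two single mutants leaves
$\Delta\Delta G_{\mathrm{int}}$ unchanged; traversing the cycle from the
double mutant (wt↔dm with the single mutants relabelled) also leaves it
unchanged — the expression is fully symmetric in that exchange, not
anti-symmetric; negation occurs when exchanging along one mutation edge
(wt↔m1 together with m2↔dm). No published coupling values are built into
the package: cycles are declared in the manifest and computed from the
panel's own fits.

## Emission maxima and MEWD

`find_peak()` locates the grid argmax and refines it; the result is
rounded to 0.5 nm, the conventional reporting resolution for tryptophan
emission maxima, while the peak intensity is left unrounded. Three
refinement methods:

* **parabolic** (default): a three-point parabola through the argmax and
  its neighbours. Exact on noiseless or replicate-averaged spectra, and
  what the reported ±0.5 nm uncertainties correspond to.
* **gauss**: least-squares fit of a Gaussian band plus constant offset to
  the whole spectrum, seeded from the argmax. This is the estimator for
  noisy single scans: a tryptophan band is ~25 nm wide, so with
  independent 2% per-point noise on a 0.5 nm grid the argmax wanders over
  several nanometres (measured: the parabolic rule lands within 0.5 nm in
  only ~20% of simulations, and even a 30 nm moving average only reaches
  ~88%), whereas pooling the whole band localises the centre to ~0.1 nm
  (100% within 0.5 nm over 200 simulations). No *local* three-point rule
  can do this; the design therefore keeps the parabolic default for clean
  spectra and exposes `method = "gauss"` where per-point noise matters.
* **argmax**: the plain grid maximum, for transparency.

Degenerate inputs: an argmax on the spectrum boundary is returned
unrefined with a warning (no neighbour to interpolate); an all-constant
spectrum is an error (no peak). Optional moving-average smoothing (odd
window, off by default) is available but not applied silently.

`mewd()` is simply $\lambda_{max}(\text{pH }4) - \lambda_{max}(\text{pH }6)$,
positive for a blue shift (tryptophan burial on folding, ~10 nm for a
complete transition); it refuses to pair spectra from different constructs
unless forced.

## Inhibition assay

Initial rates are ordinary least-squares slopes over the first 25% of the
progress curve by default — the early-phase window where substrate
depletion is negligible; the fraction is an argument and must cover ≥ 4
points. Negative slopes are clipped to zero with a warning (a release
assay cannot run backwards). Residual activity is
$100 \times v_i/v_0$; reduction is its complement, so the two always sum
to 100. Dose series are sorted by concentration (duplicates averaged with
a message) and an IC50 is interpolated linearly in
$\log_{10}$(concentration) across the 50% crossing, reported only when the
series actually brackets 50% — no sigmoidal model is imposed on data that
rarely constrain one. E-64 active-site titration fits rate vs inhibitor
concentration and returns the x-intercept as the active enzyme
concentration, flagged valid only when $r^2 \ge 0.95$ (an engineering
guard; the titration is only meaningful in the linear depletion regime,
and a non-negative slope is rejected outright). Tight-binding corrections
and $K_i$ estimation are deliberately out of scope: the assay design here
reports residual percentages, not inhibition constants.

## Motif scanning

The conserved propeptide aromatic motif is expressed in a PROSITE-like
grammar: dash-separated tokens, each a residue letter, a bracketed set, or
`x(n)` = exactly *n* arbitrary residues (fixed gaps, no ranges — the
subscript spacing of the consensus is exact). The bundled default,
`W-x(2)-[FYW]-x(3)-[FY]-x(3)-Y-x(12)-[FYW]`, spans 25 residues with five
constrained aromatic slots. The spacing between the conserved tyrosine and
the final aromatic varies among homologs (some propeptides place it
nearer); the pattern is a plain string precisely so callers can edit that
gap rather than the package silently "fixing" it. Scanning reports **all**
overlapping matches, 1-based and left to right (implemented as a
lookahead regular expression; an independent position-by-position checker
verifies it in the tests). `X` in a sequence is an unknown residue and
conservatively matches nothing — including wildcard gap positions.
Alignment input is degapped before scanning and hit coordinates are
remapped to the original alignment columns.

## Synthetic data

The generators emulate the acquisition settings of each experiment: melts
on a 4–96 °C grid in 2 °C increments (monitored wavelength 208 nm recorded
as metadata), emission spectra on 290–400 nm at 0.5 nm, and linear
early-phase AMC-release progress curves (default 300 s, 60 points). Noise
is i.i.d. Gaussian everywhere — melt noise parameterised as a fraction of
the transition amplitude so tests transfer across signal units, emission
and progress noise in signal units. Defaults chosen once as realistic for
the instruments emulated: melt baselines $Y_n = -28$, $M_n = 0.02$,
$Y_d = -4$, $M_d = 0.008$ (native signal more negative at 208 nm, gently
sloping baselines); emission bandwidth 25 nm; control assay rate such that
the curve spans a typical dynamic range. Every generator requires an
explicit seed whenever noise is requested, never wall-clock seeding, and
restores the caller's RNG state, so identical arguments give bit-identical
data. What the generators do **not** emulate — and what passing tests
therefore cannot show about real data: correlated (pink) instrument noise,
baseline drift and curvature, $\Delta C_p \ne 0$, aggregation or
irreversibility at high temperature, Raman/scatter bands in emission
spectra, and substrate depletion late in progress curves.

## Pipeline

`run_panel()` drives the whole analysis from a tab-separated manifest
(construct name, optional background, optional cycle membership, optional
qualitative folding-transition note, which is user-supplied and never
computed — calling a transition from HSQC dispersion is upstream of this
package). Any subset of the per-variant files may be present; missing
stages yield NA columns and per-variant failures are recorded without
aborting the run, because real panels are heterogeneous. Re-running the
same inputs gives byte-identical tables. Problem sizes throughout the
tests and scripts are deliberately modest — 47-point melts, 100-fit
recovery studies, 200-sequence scan comparisons — chosen so the full suite
re-runs in minutes while still measuring every stated property.

## Known limitations

* The two-state fit reports a van't Hoff enthalpy; calorimetric agreement
  (two-state validation) cannot be assessed from a single optical probe.
* $T_m$ standard errors are asymptotic fit errors, not replicate spreads.
* Broad or weakly cooperative transitions ($\Delta H \lesssim 30$
  kcal·mol⁻¹) near a scan edge are recovered with visibly larger $T_m$
  uncertainty; the `cooperative` label is a guard, not a hypothesis test.
* The IC50 interpolation is model-free and only defined when the series
  brackets 50%.
* Motif gaps are exact; variable-length gaps require editing the pattern.
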