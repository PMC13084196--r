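---
title: "Two-state unfolding and prolyl-isomerase kinetics with cyclofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state unfolding and prolyl-isomerase kinetics with cyclofit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclofit)
```

cyclofit quantifies two properties of a peptidyl-prolyl cis/trans
isomerase (PPIase) from optical spectroscopy: its conformational
stability, from urea-induced equilibrium unfolding followed by intrinsic
fluorescence, and its catalytic activity, from fluorescence relaxation
traces of a tetrapeptide isomerization assay. This vignette explains the
models, the assumptions behind them, the tunable parameters, and what the
synthetic-data generator does and does not emulate.

## The spectral layer

Far-UV circular dichroism verifies that a purified protein is folded.
Instrument exports arrive in millidegrees of ellipticity on a wavelength
grid; after subtraction of a buffer blank recorded on the identical grid
(`buffer_correct()`), the signal is normalized to mean residue
ellipticity,

$$[\Theta]_{MRE} = \frac{100\,\Theta_{obs}}{l\,c\,N}
\quad [\mathrm{deg\,cm^2\,dmol^{-1}}],$$

with pathlength $l$ in cm, molar protein concentration $c$, and $N$
residues (`mean_residue_ellipticity()`). Ellipticity is converted from
mdeg to degrees before the formula is applied, which yields values of the
conventional magnitude (around $-10^4$ deg cm$^2$ dmol$^{-1}$ at 222 nm
for a helical protein); normalizing the raw mdeg values — numerically
1000-fold larger — is available behind `mdeg_as_printed = TRUE` for
comparison against sources that tabulate it that way.

Two numerical policies matter here. Wavelength grids are compared after
rounding to 3 decimal places and never resampled: both members of a
correction pair come from the same acquisition program, so a mismatch
indicates a handling error and the functions fail loudly, naming the
first offending wavelength. Repeated scans of one sample are averaged
pointwise at ingest (`average_spectra()`); per-scan data are not carried
further. Protein concentrations come from absorbance at 280 nm via
Beer–Lambert (`concentration_from_a280()`); the cyclophilin constructs
this package was built around use $\varepsilon$ = 8730 and
16,960 M$^{-1}$cm$^{-1}$.

## Two-state unfolding by linear extrapolation

Equilibrium unfolding in urea is modeled as a two-state transition
N $\rightleftharpoons$ U whose free energy is linear in denaturant:
$\Delta G(D) = \Delta G - mD$. The observable with sloping native and
unfolded baselines is

$$y(D) = \frac{(y_N^0 + m_N D) + (y_U^0 + m_U D)\,
  e^{-\Delta G/RT + mD/RT}}{1 + e^{-\Delta G/RT + mD/RT}},$$

with $R$ = 8.314 × 10⁻³ kJ mol⁻¹ K⁻¹ (`two_state_signal()`). The
transition midpoint is the derived quantity $[urea]_{M} = \Delta G / m$;
it is always recomputed from the fitted $\Delta G$ and $m$, never stored
separately, so the two can never drift apart. `fraction_unfolded()` gives
the underlying population, exactly 0.5 at the midpoint.

Urea concentrations are calibrated from refractive-index differences
through the standard cubic (coefficients 117.66, 29.753, 185.56), exposed
as a configurable calibration record and valid to 11 M
(`urea_from_refractive_index()`). Protein-free blank titrations recorded
on a coarse 1 M grid are linearly interpolated at the sample's urea
values and subtracted before fitting (`blank_interpolate()`);
extrapolation beyond the blank range is refused.

### Fitting policy

`fit_two_state()` estimates all six parameters by unweighted
Levenberg–Marquardt least squares (no per-point uncertainties exist for
these recordings, so weighting would be arbitrary; free baselines avoid
biasing $\Delta G$ when baselines drift). Starting values are data-driven:
baselines from ordinary least squares on the lowest and highest 20% of
urea points, the midpoint guess at the steepest finite-difference slope
of the signal, $m$ at 5 kJ mol⁻¹ M⁻¹ — a typical cooperativity for an
18 kDa single domain — and $\Delta G = m \times$ midpoint guess. If a
start fails to converge, up to five further attempts are made from ±20%
jittered starts (seeded, reproducible) before a convergence error carries
the diagnosis. Convergence tolerances are tight (1e-14 on cost and
parameters) so that noiseless round trips recover generating parameters
to better than 1e-6 relative.

A fit is only *accepted* when it converged with $m > 0$, $\Delta G > 0$
and a midpoint inside the sampled urea range. This gate exists because a
baseline-only titration (no transition in window) can still converge to a
mathematically valid but thermodynamically meaningless optimum; such fits
are reported with `accepted = FALSE` and a machine-readable reason.
Datasets must have at least 8 points spanning at least 2 M urea to be
fitted at all. Replicates are combined by `summarize_replicates()`:
per-parameter mean and sample SD ($n-1$), with the midpoint summarized
from per-replicate midpoints rather than as a ratio of means — the ratio
of means is biased when $m$ varies across replicates.

All experiments this package models were performed at 15 °C, so
288.15 K is the default temperature everywhere; it is overridable per
dataset.

## Isomerization kinetics and the specificity constant

The activity assay follows fluorescence of Abz/pNA-labeled tetrapeptides
(Ala-Xaa-Pro-Phe) after a jump from LiCl/TFE, where the prolyl bond is
predominantly cis and the fluorophore quenched, into aqueous buffer,
where the equilibrium favors trans. The relaxation is (multi-)
exponential with observed rate

$$k_{app} = k_0 + [E]\,\frac{k_{cat}}{K_M},$$

so a linear regression of $k_{app}$ on enzyme concentration gives the
uncatalyzed rate $k_0$ as intercept and the specificity constant
$k_{cat}/K_M$ as slope. The assay operates far below $K_M$ by design
(micromolar peptide, nanomolar enzyme), which is why the second-order
regime holds and saturation analysis is out of scope.

`fit_exponential()` fits $I(t) = I_\infty - \sum_i A_i e^{-k_i t}$ with
rates parameterized on a log scale (positivity by construction) and
start values from the trace's $1 - 1/e$ crossing. The first 2 s of every
trace are excluded by default: peptide is added manually while the
instrument records at 1 s intervals, so the earliest samples contain the
mixing artifact. This exclusion is configurable (`dead_time_s`) and does
not bias the fit — the exponential model is valid from any origin, and
amplitudes are free parameters.

Some peptide syntheses leave a slow, PPIase-insensitive second phase
(plausibly residual salts or contaminants). `select_model()` therefore
compares 1- against 2-phase fits by corrected AIC, but a second phase is
only *accepted* when the rate ratio is at least 5 and the minor phase
carries at least 10% of the total amplitude. Both gates are needed: AICc
alone promotes noise into a phantom phase in a non-negligible fraction of
traces, and an unresolvable rate pair (ratio below ~5) makes the split
between amplitudes ill-conditioned. With the gates, simulations at 1%
noise call a spurious second phase in under 5% of single-phase traces and
recover a well-separated second phase (ratio 20, equal amplitudes) in
over 95%.

Which phase is the catalyzed isomerization is decided by
`identify_enzyme_sensitive_phase()` across the concentration series: the
fast phase must show a statistically positive slope of rate versus $[E]$
(one-sided test at $\alpha$ = 0.05) while the slow phase's slope must be
compatible with zero. If both phases track enzyme concentration the
assignment is ambiguous and the function raises an error rather than
guessing — in the pipeline this surfaces as a per-peptide failure, never
a silent choice. Replicate rates at each concentration are averaged
(`average_rates()`; at least four replicates per concentration in the
emulated design) and the regression (`fit_specificity()`) runs on those
averaged points, unweighted — matching how such plots are conventionally
analyzed; an inverse-variance weighted variant is available behind
`weighted = TRUE` for sensitivity analysis. A negative fitted slope is
reported but flagged not-accepted. Enzyme concentrations are carried in
molar internally; trace files store nM, and conversion happens at ingest.

The buffer condition tag (`reducing`, the DTT/cytosol mimic, versus
`er_mimicking`, the GSH/GSSG + Ca²⁺ mimic of the endoplasmic-reticulum
lumen) is metadata only: no numeric code path reads it. That design makes
the condition-independence of recovered activities provable in a test —
identical traces tagged differently yield identical numbers — mirroring
the biological finding the workflow was built to examine.

## The synthetic-data generator

No raw instrument recordings are distributed with this package, so every
stage is validated against seeded synthetic data with known ground truth
(`generate_unfolding()`, `generate_trace()`, `generate_assay()`).

The generators produce exactly what the fitters assume: titration
signals on the two-state curve, and relaxation traces of the
exponential form with rate $k_0 + [E]\,k_{cat}/K_M$, an optional
fixed-rate enzyme-insensitive slow phase, and Gaussian noise. Noise is
multiplicative on intensity by default (relative scale, matching
photon-flux-proportional instrument noise); an additive option is
retained. Default study conditions are the emulated design: titrations
of 30 points over 0–8 M urea at 1% relative noise and 288.15 K;
assays on a 0/2/6/10 nM concentration grid with four replicates,
1 s sampling for 300 s, 1% relative noise. The trace amplitude defaults
to 600 on a final fluorescence of 1000 — the relaxation covers 60% of
the plateau — because the peptides enter the assay predominantly cis
with the fluorophore quenched, so most of the final signal develops
during re-equilibration. Default uncatalyzed rates (0.02 s⁻¹ at 15 °C)
are order-of-magnitude choices for Xaa-Pro tetrapeptides and are labeled
as such in the truth manifests.

Presets cover the regimes of interest: `unfolding_preset()` provides
"cypa" ($\Delta G$ = 23 kJ/mol, $m$ = 5 kJ/mol/M, midpoint 4.6 M) and
"cypb" ($\Delta G$ = 18, midpoint 3.6 M); `assay_preset()` provides
cyclophilin-like enzymes with no sequence preference (one $k_{cat}/K_M$
across all five Xaa positions, 3 × 10⁶ or 8 × 10⁶ M⁻¹s⁻¹) and an
FKBP-like "slyd" preset whose $k_{cat}/K_M$ spans two orders of
magnitude across peptides, so both the "no preference" and the
"pronounced sequence specificity" analysis paths are exercised.

Determinism is part of the contract: identical (truth, seed) pairs
reproduce outputs bit-identically, and assays derive per-trace child
seeds from the master seed and the (peptide, concentration, replicate)
indices through a fixed integer mixing rule, so any single trace can be
regenerated in isolation.

What the generator does **not** emulate: solvent physics of the
TFE/LiCl jump, conformational-ensemble cis/trans populations,
photobleaching or lamp drift, correlated (non-white) noise, and
deviations from two-state behavior such as folding intermediates.
Passing recovery tests therefore demonstrate that the estimators are
correct and well-conditioned *under the stated observation model* — they
do not certify robustness to model violations in real recordings, which
is exactly why non-accepted fits, phase ambiguities and calibration
range violations are first-class, machine-readable outcomes rather than
silent repairs.

## Problem sizes and reproducibility

The validation suite works at the scale of the emulated experiments:
100-seed midpoint-recovery ensembles for each stability preset, 20-seed
noiseless round trips for both fitters, 200-seed operating-characteristic
runs for phase selection, and full 4 × 4 assay recoveries for specificity
constants spanning 10⁶–10⁷ M⁻¹s⁻¹ — sizes chosen so the whole suite runs
in well under a minute while keeping Monte-Carlo error far below the
tolerances being asserted. Pipeline reports echo their configuration,
seed and package version, and re-running a report from that echo
reproduces every number bit-identically on the same platform and
toolchain (floating-point determinism across platforms is explicitly not
claimed).

## Worked example

```{r example}
# stability: three simulated replicates of the less stable homolog
rep <- run_stability_pipeline(
  run_config(preset = unfolding_preset("cypb"), n_replicates = 3, seed = 1))
rep$summary

# activity: one peptide, full concentration series
truth <- assay_truth(peptides = "AAPF", k0_s = 0.02,
                     kcat_over_KM_M_s = 3e6)
act <- run_activity_pipeline(run_config(preset = truth, seed = 1))
act$specificity
```

## Known limitations

- Strictly two-state: no three-state or intermediate models, no thermal
  denaturation, no guanidinium calibration.
- At most two exponential phases; traces with more structure will fold
  extra phases into the residuals.
- The specificity regression assumes rate errors comparable across
  concentrations (unweighted default); strongly heteroscedastic designs
  should use the weighted variant.
- The slow-phase model (fixed-rate, enzyme-insensitive exponential) is
  one plausible form of an uncharacterized contaminant process.
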