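# cyclofit

Quantitative analysis of protein conformational stability and
peptidyl-prolyl cis/trans isomerase (PPIase) catalytic activity from
optical spectroscopy, built around the characterization of cyclophilin
enzymes. It is aimed at protein biophysicists who record circular
dichroism spectra, urea-titration fluorescence, and peptide-assay
relaxation traces, and want the full path from instrument export to
thermodynamic and kinetic parameters as tested, reproducible code.

Three models sit at the core:

- **Mean residue ellipticity.** CD spectra in mdeg are buffer-corrected
  and normalized as [Θ]_MRE = 100·Θ_obs/(l·c·N) in deg·cm²·dmol⁻¹, with
  Θ_obs in degrees, pathlength l (cm), molar concentration c, and N
  residues.
- **Two-state unfolding by linear extrapolation.** The titration signal
  with sloping baselines,
  y(D) = [(yN⁰ + mN·D) + (yU⁰ + mU·D)·e^(−ΔG/RT + mD/RT)] /
  [1 + e^(−ΔG/RT + mD/RT)],
  is fitted by unweighted Levenberg–Marquardt least squares; the
  transition midpoint is the derived [urea]_M = ΔG/m. Urea
  concentrations come from refractive-index differences via the
  standard cubic calibration.
- **Specificity constants from relaxation rates.** Fluorescence time
  courses of Abz/pNA tetrapeptide isomerization are decomposed into
  exponential phases (AICc model selection with resolvability gates),
  the PPIase-sensitive phase is identified across the enzyme series,
  and k_app = k0 + [E]·kcat/KM is fitted by linear regression: the
  slope is the specificity constant kcat/KM, the intercept the
  uncatalyzed rate k0.

No raw instrument data are distributed, so the package includes a
first-class synthetic-data generator (`generate_unfolding()`,
`generate_assay()`) with seeded, bit-reproducible output and ground-truth
manifests; every analysis stage is validated by parameter recovery. See
`vignettes/stability-and-ppiase-kinetics.Rmd` for the models,
assumptions, defaults and limitations.

## Worked example

Stability: three simulated replicate titrations of the less stable
cyclophilin homolog (generating ΔG = 18 kJ/mol, m = 5 kJ/mol/M), fitted
and aggregated:

```r
library(cyclofit)
rep <- run_stability_pipeline(
  run_config(preset = unfolding_preset("cypb"), n_replicates = 3, seed = 1))
rep$summary
#>    parameter        mean          sd
#> 1        yN0 1002.422626  3.95787910
#> 2         mN  -13.911389  7.79366876
#> 3        yU0 2972.959200 73.25874867
#> 4         mU   24.292163 10.13713368
#> 5  dG_kJ_mol   17.894675  0.84497984
#> 6 m_kJ_mol_M    4.984846  0.23865976
#> 7 midpoint_M    3.589888  0.00521871
```

The recovered midpoint (3.590 ± 0.005 M urea) matches the generating
ΔG/m = 3.6 M; baselines and thermodynamic parameters are recovered with
replicate scatter typical of 1% instrument noise.

Activity: a full single-peptide assay (0/2/6/10 nM enzyme, four
replicates per concentration, generating kcat/KM = 3 × 10⁶ M⁻¹s⁻¹ and
k0 = 0.02 s⁻¹):

```r
truth <- assay_truth(peptides = "AAPF", k0_s = 0.02, kcat_over_KM_M_s = 3e6)
act <- run_activity_pipeline(run_config(preset = truth, seed = 1))
act$specificity
#>   peptide_id condition       k0_s        k0_sd kcat_over_KM_M_s kcat_over_KM_sd
#> 1       AAPF  reducing 0.01993458 8.050786e-05          2991947        13608.31
#>   n_points accepted
#> 1        4     TRUE
```

The regression recovers the specificity constant to 0.3% and the
uncatalyzed rate to 0.3% under these conditions.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # synthetic titrations + assay traces + truth.json
Rscript analysis/02_stability.R  # two-state fits, replicate midpoint/dG/m tables
Rscript analysis/03_activity.R   # per-peptide kcat/KM under both buffer conditions
Rscript analysis/04_spectra.R    # MRE normalization and difference spectra
```

Stage 3 also checks that the reducing versus ER-mimicking condition tag
changes nothing numerically — condition is metadata by construction.

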