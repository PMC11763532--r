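# serorad

Label-free infrared serum profiling for monitoring autoimmune kidney
disease. **serorad** implements a time-resolved ATR-FTIR assay: a serum
droplet dries on a germanium crystal while consecutive spectra are acquired
(758 spectra at 0.791 s by default), and the temporal evolution of
characteristic absorption bands between the liquid phase and the dried film
is condensed into chemometric indices that track IgG glycosylation,
lactate, albumin and serum hydrophobicity — quantities that move with lupus
nephritis activity and treatment response.

The package is aimed at spectroscopists and translational researchers who
have (or want to simulate) dehydration series of biofluid spectra and need
a reproducible, scriptable implementation of the assay's full chain:
ingestion, ATR/baseline/lipid corrections, index computation, prognosis
scoring, clinical correlation and cohort statistics.

## The quantities

For a target band ν₁ and reference band ν₂ measured on the same spectrum at
dehydration time *t*:

    RAD(ν₁, ν₂, t) = (PH₁(ν₁, t) − PH₂(ν₂, t)) / PH₁(ν₁, t)

with PH the baseline-corrected window-maximum peak height. The **RAD gap**
of a run is Ψ = mean RAD over the first 100 spectra (liquid phase) minus
mean over the last 100 (dried film). Five canonical index band pairs are
tracked — Hp (2930/2960 cm⁻¹), Hph (1546/1650), Alb (1400/1450), Lact
(1121/1171), Gly (1030/1171) — and combine into the **prognosis prediction
function**

    Φ = Ψ_Lact + Ψ_Gly + Ψ_Hp − Ψ_Hph + Ψ_Alb

which is tracked against the combined normalized clinical biomarker score
UTP + UPCR + Scr − Albumin. The dried-film **hydrophobicity index**
HPI = PH(ν_as CH₂, ~2930) / PH(ν_as CH₃, ~2960), computed after
triglyceride-interference removal, reads out serum hydrophobicity changes
driven by IgG glycosylation.

Because no patient spectra are publicly deposited for this assay, the
package includes a first-class synthetic dehydration-series simulator with
named presets that encode the published cohort HPI values (healthy 0.94,
acute disease at 6/12 months 1.04/1.01, chronic 0.95, remission 0.94) in
their band amplitudes, plus analytic ground-truth RAD gaps; the validation
suite demonstrates that the full pipeline recovers those values end to end.

## Worked example

```r
library(serorad)

# a healthy-control run: 758 spectra, 0.791 s cadence, default noise
preset <- sim_preset("healthy")
series <- simulate_series(preset, seed = 1)
rec <- analyze_series(series)
rec
#> <followup_record> 'healthy_s1' T = NA d: Phi = 2.3327, HPI = 0.9407
#>   gaps: Hp=-0.1310  Hph=-1.8132  Alb=0.0772  Lact=0.3752  Gly=0.1981
```

The five Ψ values are the liquid-minus-dried RAD gaps of the canonical
indices: the large negative Hph gap reflects the water bending band under
the amide I reference in the liquid phase, and the positive Lact/Gly gaps
reflect analytes that stay spectroscopically active in solution. Φ sums
them (Hph negated). The HPI of 0.9407 recovers this preset's encoded
dried-film CH₂/CH₃ ratio of 0.94 through the complete correction chain.

Comparing simulated cohorts (4 acute vs 6 healthy controls):

```r
coh <- simulate_cohort(list(healthy = list(preset = sim_preset("healthy"), n = 6),
                            acute   = list(preset = sim_preset("acute_6m"), n = 4)),
                       seed = 42)
recs <- lapply(coh$series, analyze_series)
compare_cohorts(recs[coh$labels == "acute"], recs[coh$labels == "healthy"])[1, c(1,3,7,10:12)]
#>   label  median_a   median_b  U          p method
#> 1   hpi  1.039929  0.9408915 24 0.00952381  exact
```

Group summaries are median/IQR and the test is the exact two-sided
Mann–Whitney (full enumeration for these group sizes).

A thin command-line front end ships in `inst/cli/serorad.R`
(`simulate`, `analyze`, `gaps`, `compare`, `version` subcommands) for
driving the same pipeline from a shell.

## Package layout

* `R/spectrum.R`, `R/io.R` — spectrum/series containers, delimited-matrix
  and JCAMP-DX ingestion, clinical tables, reports
* `R/preprocess.R` — ATR penetration-depth correction, rubberband/ALS
  baseline, triglyceride subtraction
* `R/bandmetrics.R` — band windows and peak-height measurement
* `R/radcore.R` — RAD profiles, RAD gaps, HPI
* `R/scoring.R` — PPF, biomarker normalization and score, timelines,
  correlations
* `R/stats.R` — median/IQR, exact Mann–Whitney
* `R/synth.R` — the dehydration simulator and presets
* `R/pipeline.R` — configuration and end-to-end assembly
* `vignettes/serorad-methods.Rmd` — models, assumptions, design choices
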