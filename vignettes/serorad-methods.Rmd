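---
title: "Temporal RAD profiling of dehydrating serum films: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal RAD profiling of dehydrating serum films: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

serorad analyzes time-resolved ATR-FTIR absorbance spectra of a serum
droplet drying on a germanium crystal. During dehydration the water
background collapses and the solute film concentrates at the crystal
surface, so the relative heights of solute absorption bands evolve between a
liquid-phase regime and a dried-film regime. The package quantifies that
evolution with the **relative absorption difference**

$$\mathrm{RAD}(\nu_1, \nu_2, t) =
  \frac{PH_1(\nu_1, t) - PH_2(\nu_2, t)}{PH_1(\nu_1, t)},$$

where $PH_1$ is the baseline-corrected peak height of a target band and
$PH_2$ that of a nearby reference band measured on the same spectrum at
dehydration time $t$. Because RAD is a ratio of heights of one spectrum, it
is invariant to any global rescaling of that spectrum — the property that
makes the assay robust to loading volume and contact quality, and the reason
the quantitative path applies no normalization.

Five canonical index band pairs are tracked (target / reference, cm⁻¹):

| index | target $\nu_1$ | reference $\nu_2$ | TG-corrected | reads out |
|-------|------|------|----|----------------------------------------------|
| Hp    | 2930 | 2960 | yes | hydrophobicity: CH₂ stretch (IgG glycan methylenes) vs protein CH₃ |
| Hph   | 1546 | 1650 | no  | hydrophilicity: amide II vs amide I |
| Alb   | 1400 | 1450 | yes | albumin: carboxylate bend vs CH₂ scissoring |
| Lact  | 1121 | 1171 | no  | lactate C–O–H bend vs serine C–O–H reference |
| Gly   | 1030 | 1171 | yes | IgG glycosylation: glycosidic C–O–C vs the same reference |

Published center values for these vibrations drift by a few cm⁻¹ between
sera (and between reports); the package therefore measures heights as window
maxima within ±8 cm⁻¹ (two resolution elements at the instrument's 4 cm⁻¹
resolution) rather than at fixed wavenumbers, with argmax ties resolved
toward the nominal center for determinism. All centers, half-widths and
correction flags are overridable through the `indices:` config block.

The **RAD gap** of one dehydration run is

$$\Psi = \overline{\mathrm{RAD}}_{\text{first }100} -
         \overline{\mathrm{RAD}}_{\text{last }100},$$

the mean over the first 100 acquisitions (liquid phase) minus the mean over
the final 100 (dried film). The default window of 100 spectra matches the
acquisition protocol of 758 spectra at 0.791 s cadence; series shorter than
200 points require an explicit smaller window — there is no silent
adaptation. Whether the gap is plotted as initial−final or final−initial is
a convention; the package computes initial−final by default and offers
`gap.sign_convention` to flip it.

Per follow-up visit $T$ the five gaps combine into the **prognosis
prediction function**

$$\Phi(T) = \Psi_{Lact} + \Psi_{Gly} + \Psi_{Hp} - \Psi_{Hph} + \Psi_{Alb},$$

with unit weights (no weighting is fitted). The paired clinical quantity is
the combined normalized biomarker score
$\mathrm{UTP} + \mathrm{UPCR} + \mathrm{Scr} - \mathrm{Albumin}$.
Since those four quantities carry incompatible units, each is normalized
across the patient's own timeline first; the default is min–max scaling to
$[0,1]$ per biomarker, the only basis computable without population data
(z-scores and division by a supplied upper-limit-of-normal are available).
Consequently the score is comparable across a patient's follow-ups, not
across patients.

The **hydrophobicity index** of the dried film,

$$\mathrm{HPI} = \frac{PH_1(\nu_{as}(\mathrm{CH_2}),\ \sim 2930)}
                      {PH_2(\nu_{as}(\mathrm{CH_3}),\ \sim 2960)},$$

is computed on the triglyceride-corrected spectra as the mean per-spectrum
height ratio over the final 100 acquisitions. The dried film is the natural
stage for it: the reported cohort values come from dehydrated serum, and the
dried-film window is where the lipid correction is most reliable (no water
overlap at the anchor band).

## Preprocessing

The fixed chain is: interpolate to the canonical grid → ATR correction →
rubberband baseline → triglyceride subtraction (only for indices flagged
for it). Each step and its free choices:

**Canonical grid.** All quantitative work happens on one ascending linear
grid, 650–3998 cm⁻¹ at 2 cm⁻¹ spacing (comfortable for a 4 cm⁻¹ instrument
resolution), so band windows are index-stable. Readers keep the native grid
of a file; the coverage requirement (at least 900–3100 cm⁻¹) and the
interpolation are enforced at pipeline entry by `to_canonical_grid()`. This
split lets toy grids round-trip through the I/O layer unchanged while the
analysis path stays strict.

**ATR correction.** The evanescent-wave penetration depth
$d_p(\nu) = \left(2\pi \nu n_1 \sqrt{\sin^2\theta - (n_2/n_1)^2}\right)^{-1}$
scales as $1/\nu$, so raw ATR absorbance under-weights high wavenumbers.
The correction multiplies absorbance by $\nu/\nu_{ref}$
(defaults: germanium $n_1 = 4.0$, dried serum $n_2 = 1.5$,
$\theta = 45°$, $\nu_{ref} = 1000$ cm⁻¹; construction fails if the geometry
does not achieve total internal reflection). A metadata flag guards against
double application. For the defaults, $d_p(1000\,\mathrm{cm^{-1}}) =
0.664\ \mu m$.

**Baseline.** The default is the rubberband: subtract the lower convex hull
of the (wavenumber, absorbance) polyline. It is parameter-free and
idempotent, which keeps the invariant suite simple; an asymmetric
least-squares (Whittaker) alternative with $\lambda = 10^5$, $p = 0.01$, 10
iterations sits behind `baseline.method: als` for spectra whose broad real
features a hull would cut into. No smoothing is applied by default;
Savitzky–Golay (window 9, order 3) is available behind the config.

**Triglyceride correction.** Lipid-related species (triglycerides,
cholesterol, phospholipids) absorb at 2931, 2855 and 1456 cm⁻¹ and would
contaminate the Hp, Alb and Gly indices and the HPI. The correction
estimates the lipid amount $\alpha$ from the ester carbonyl band at 1737
cm⁻¹ — the one strong lipid band free of protein overlap — and subtracts
$\alpha$ times a unit-amplitude reference spectrum. The shipped reference is
a synthetic fixture (Gaussian bands at 2931, 2855, 1737, 1456 cm⁻¹ with
amplitude ratios 1.0 : 0.55 : 0.9 : 0.35, σ = 10 cm⁻¹, rescaled to unit
anchor height); real deployments should supply a measured standard via
`tg.reference_path`. Correction happens at spectrum level; `tg.enabled:
false` skips it for workflows that calibrate downstream instead.

The default $\alpha$ estimator is a least-squares fit of the spectrum on
the reference over a 1737 ± 25 cm⁻¹ window with a quartic local background
(the `"peak"` estimator implements the plain anchor-band peak-height
readout). The fit window is deliberately wider than the ± 15 cm⁻¹ anchor
band: over a narrow window a low-order polynomial cannot follow the
curvature of overlapping broad features (in the liquid phase, the tail of
the 1640 cm⁻¹ water bending band), while a high-order one becomes collinear
with the band shape itself and amplifies noise roughly 75-fold. The ± 25 /
quartic combination keeps the noiseless bias of $\alpha$ below $10^{-4}$
absorbance units at about 6.6 noise-standard-deviation amplification, and
the estimator is exactly right for noiseless multiples of the reference and
unbiased under zero-mean noise — unlike a peak-height readout, whose
argmax-of-noise bias propagates into the Hp numerator scaled by the
reference's CH₂/anchor height ratio (≈ 1.1). Negative estimates are clamped
to zero with a warning.

**Water.** Liquid-phase water absorbance is deliberately not compensated:
the temporal change of water-overlapped bands *is* the RAD signal. This is
why, e.g., the Hph gap is large and negative — its 1650 cm⁻¹ reference sits
under the water bending band in the liquid phase.

## Cohort statistics

Group results are summarized as median and IQR (type-7 interpolated
quantiles) and compared with the two-sided Mann–Whitney test. For the cohort
sizes this assay targets (4–8 per group), exact permutation inference is
feasible: with $m + n \le 12$ and untied data the exact distribution is
used; otherwise the normal approximation with tie and continuity
corrections. Only the two-sided alternative is exposed. Timeline
associations use Spearman rank correlation by default (a dozen follow-ups
do not support Pearson moments); p-values are reported raw and flagged
as uncorrected.

## The synthetic-data generator

No serum spectra are publicly deposited for this assay, so the package
ships a simulator whose defaults emulate the acquisition protocol (758
spectra at 0.791 s, 4 cm⁻¹ resolution) and whose presets encode the
published cohort index values as ground truth. The model absorbance is

$$A(\nu, t) = w(t)\, W(\nu) + \sum_b a_b(t)\, G_b(\nu)
            + \beta(t) R(\nu) + d(t) + \varepsilon,$$

with $w(t) = \left(1 + e^{r (t - t_{1/2})}\right)^{-1}$ the sigmoid water
fraction (midpoint 300 s, rate 0.03 s⁻¹, so the first 100 spectra are
water-dominated and the last 100 dried), $W$ a stylized water background
(broad Gaussians at 3350 and 1640 cm⁻¹), $G_b$ Gaussian solute bands at the
characteristic serum positions (σ = 10 cm⁻¹; 14 cm⁻¹ for the CH stretching
quartet), $R$ the triglyceride reference shape, $d$ a slow flat drift
(amplitude 0.001 AU) and $\varepsilon$ i.i.d. Gaussian noise (SD 0.002 AU,
about 0.2% of the amide I height). Solute amplitudes interpolate linearly
between a liquid-phase and a dried-film value in the solid fraction
$s(t) = 1 - w(t)$; the liquid amplitudes are sizable fractions (≈ 0.18–0.32)
of the dried ones rather than vanishing, because a liquid droplet's solutes
absorb measurably — and a generator whose liquid-phase bands vanish would
make the liquid-window RAD pure noise. The emitted raw spectrum is the model
times the $\nu_{ref}/\nu$ penetration-depth factor, so the pipeline's ATR
correction is exercised nontrivially and exactly undoes it.

**What the presets encode.** Each preset fixes a target dried-film CH₂/CH₃
peak-height ratio — healthy 0.94, acute disease at 6 months 1.04, at 12
months 1.01, chronic 0.95, remission 0.94 — and the 2931 cm⁻¹ amplitude is
solved (by root finding at construction) so the noiseless dried protein
film measures exactly that ratio. The solve is necessary because the CH₂
and CH₃ bands overlap: each bleeds roughly 16% of its height into the
other's window, so a naive amplitude ratio would not reproduce the target
peak-height ratio. Disease also shifts the dried amounts of the
glycosylation, lactate and albumin-related bands and their liquid:dried
ratios; for a target band with liquid fraction $f$ measured against a
reference with fraction $f_{ref}$, the encoded gap is approximately
$(\mathrm{ref}/\mathrm{amp})(1 - f_{ref}/f)$, so analytes that remain
spectroscopically active in the liquid phase carry larger gaps. The
resulting preset ordering (acute > chronic ≈ healthy in Φ; Hp, Gly, Lact
gaps up and Hph gap down in acute disease) mirrors the qualitative clinical
picture.

Ground truth stored with every preset/series consists of the target HPI and
the analytic window-averaged RAD gaps: the measurement definition applied
to the exact noiseless mixture with the lipid component removed exactly.
Recovery tests compare the estimating pipeline — which must find the
baseline, the lipid amount and the peaks on its own — against these values
(noiseless gaps to 10⁻³; noisy cohort HPI medians to ± 0.01).

**What the simulator does not emulate.** Scattering artifacts, coffee-ring
spatial heterogeneity, atmospheric lines, band-shape changes on drying,
instrument drift beyond a flat offset, and any pathology beyond the encoded
band-amplitude differences. Passing recovery tests therefore demonstrates
that the pipeline's corrections and estimators are consistent and unbiased
under the stated model — not that the published clinical separations would
be reproduced on real sera.

## Numerical choices and degenerate inputs

* Argmax ties resolve toward the nominal band center; an all-zero window
  reports height 0 at the center.
* RAD points with target height ≤ 10⁻⁶ AU become missing values; a profile
  with > 20% missing points carries a quality warning; each gap window must
  retain at least half its points valid.
* An all-equal (or affine) spectrum rubberbands to all zeros — not an
  error.
* Min–max normalization of a constant biomarker yields 0 with a warning.
* Identical pooled samples give $U = mn/2$, $p = 1$.
* Simulation is bit-reproducible for a given seed (the caller's RNG state
  is saved and restored); cohort series $i$ derives its seed as
  $\mathrm{seed} + i$.

## Problem sizes

The validation suite runs entirely on synthetic data generated at test
time: most unit tests use 220-frame series with a proportionally compressed
water-decay sigmoid, and the cohort-recovery checks use 50 full 758-frame
series per preset; the full five-preset recovery completes within a few
minutes on a single CPU.

## Known limitations

* JCAMP-DX ingestion covers single-spectrum AFFN `(X++(Y..Y))` blocks only;
  compressed encodings (SQZ/DIF) and binary vendor formats are out of
  scope.
* The combined biomarker score's units question (mg/day vs g/day UTP, and
  so on) is sidestepped by per-patient normalization; cross-patient score
  comparisons are undefined.
* No absolute concentration calibration is attempted: gaps correlate with,
  but do not measure, mg/dL quantities.
* The shipped triglyceride reference is synthetic; quantitative lipid
  correction on real spectra requires a measured standard.
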