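---
title: "Methods: occupational eye-lens dosimetry for CT-assisting staff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupational eye-lens dosimetry for CT-assisting staff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlensdose)
```

## The problem

Medical staff who stay inside the CT room to assist a patient during a
diagnostic scan — holding a mask for assisted ventilation, holding the head,
or simply observing — stand in the scatter field of a high-output X-ray
beam. Since the occupational equivalent-dose limit for the lens of the eye
was lowered to 20 mSv per year (averaged over five years, no single year
above 50 mSv), per-procedure eye-lens monitoring of such staff has become a
practical necessity. This package implements the full analysis chain for a
per-procedure monitoring campaign built on radio-photoluminescent glass
dosimeters (RPLDs) worn in and on radiation safety glasses:

1. **Beam quality**: characterise the 120 kVp CT beam by its aluminium
   half-value layer (HVL) and effective energy.
2. **Conversion**: turn each dosimeter's air-kerma reading into the personal
   dose equivalent at 3 mm depth, Hp(3), via the conversion coefficient
   K = Hp(3)/Ka at the beam's effective energy.
3. **Aggregation**: collapse the six readings per procedure (inside the
   glasses: left/right clips each holding a vertical and a horizontal RPLD;
   outside: one RPLD per side) to one outside and one inside Hp(3).
4. **Analysis**: ratio diagnostics, per-profession and per-area summaries
   with rank tests, protection-efficiency estimates for three measures and
   their multiplicative combination, and an annual compliance projection.

## Beam-quality model

The spectrum generator `simulate_spectrum()` is a semi-empirical
tungsten-anode model: a Kramers-type continuum $(T_0-E)/E$ weighted by
depth-integrated anode self-filtration. Electron penetration into the anode
follows a Thomson–Whiddington relation ($T_0^2-E^2$ proportional to mass
depth, constant `tw_constant` = 1.1e6 kV² cm²/g), and a photon born at
depth $x$ leaves through $x/\sin\theta$ of tungsten, with take-off angle
$\theta$ = 7° by default (a typical CT tube; exposed as a parameter).
Characteristic K lines (K$\alpha_1$, K$\alpha_2$, K$\beta_{1,3}$,
K$\beta_2$ at 59.32/57.98/67.1/69.07 keV, relative intensities
1.00/0.58/0.33/0.09) are added only when the tube potential exceeds the
tungsten K edge at 69.525 keV, with the conventional $(T_0/E_K-1)^{1.63}$
yield scaling; `char_fraction` = 0.135 puts roughly 8% of the unfiltered
120 kVp fluence into the lines.

The energy grid uses 0.5 keV bins from 10 keV up to the tube potential:
finer bins change the derived effective energy by well under 0.1 keV at
four times the cost.

Air kerma is the discrete integral $\sum_E \Phi(E)\,E\,(\mu_{en}/\rho)_{air}(E)$,
the HVL is found by bisection to 1e-4 mm, and the effective energy is the
monoenergetic energy whose Al attenuation reproduces that HVL (bisection on
the strictly monotone branch of the Al table, 1e-3 keV tolerance; invertible
HVL range corresponds to 10–150 keV).

**Calibration.** The measured per-configuration HVLs behind a scanner's
effective energies are rarely published, so the total Al-equivalent
filtration is treated as the calibration parameter: `ct_default_filtration`
holds the thickness per scanner/FOV configuration (13.8–18.9 mm Al) chosen
so the simulated 120 kVp beam reproduces the measured effective energies
55.74/57.97/54.87/57.30 keV (and 56.47 keV for the beam mean) to better
than 0.02 keV. These are calibration constants, not measured filtrations —
CT bow-tie plus inherent filtration is heavy, so an Al-equivalent in the
teens of millimetres is physically plausible. Because the filtration is
calibrated against the effective-energy anchors, constant-level differences
in the spectrum-model coefficients are absorbed; both the
measured-HVL path and the simulated-spectrum path through `beam_quality()`
agree under this calibration.

**Effective-energy summary.** `summarize_effective_energy()` reports the
mean and the *population* SD (divisor $n$): the canonical four-configuration
summary 56.47 ± 1.23 keV is only consistent with divisor $n$ (the sample SD
would be 1.42). Everywhere else the package uses the sample SD; the two
conventions are deliberately not mixed elsewhere.

## Reference data

Photon mass attenuation and mass energy-absorption coefficients for Al, air
and W are embedded from the standard published compilations at the standard
10–200 keV grid and interpolated log-log (exact for power-law segments; the
convention for cross-section data). The tungsten L-edge region below
12.5 keV is approximated smoothly: those photons are removed by any
realistic filtration and never influence a derived quantity. Conversion
coefficients Hp(3)/Ka are interpolated linearly (a smooth, peaked curve
where log-log has no advantage). Node queries return node values exactly.

The bundled Hp(3)/Ka table is a **synthetic** Behrens-type compilation for
photons at normal incidence on the cylinder head phantom (file
`hp3_ka_cylinder_0deg_synthetic.csv`): a smooth curve rising from
0.28 Sv/Gy at 10 keV to a peak of 1.67 near 70 keV with a slow falloff,
constructed to reproduce the beam-mean anchor K(56.47 keV) = 1.650. The
cylinder 0° geometry is chosen because that anchor value is consistent with
it. Users with access to the exact tabulation of their dosimetry service
can drop in their own table via `new_ref_table()`.

Densities: Al 2.699 g/cm³, air 1.205e-3 g/cm³ (20 °C), W 19.30 g/cm³.

## Aggregation conventions

Within each inside clip the *higher* of the vertical and horizontal reading
is used (`aggregate_orientation()`); the L-shaped mounting exists to offset
the directional dependence of the Sn-filtered RPLD, and the V/H ratio
diagnostic (median ≈ 1 in both the published data and the synthetic
generator) justifies treating the max as the best estimate rather than
averaging. The dose of record per placement is then the higher of the left
and right values (`aggregate_side()`). One beam-mean K converts kerma to
Hp(3) for both placements; the Sn filter's energy compensation is taken as
already folded into the reported kerma. `procedure_hp3()` validates the
exact six-slot layout and names any missing slot.

## Efficiency estimators and compliance

* **Glasses** (`glasses_efficiency()`): per-procedure outside/inside ratio,
  median over procedures, reduction $(R-1)/R \times 100$.
* **Extension tube** (`tube_efficiency()`): within assisted ventilation,
  Hp(3) is first normalised by the procedure's dose–length product
  (`dlp_normalize()`, reported ×10⁻⁴ mSv·mGy⁻¹·cm⁻¹) to remove the
  patient-dose scale, then stratum medians (with vs without tube) are
  compared with $\{1-b/a\}\times 100$ per placement.
* **Curtain** (`curtain_efficiency()`): phantom-experiment arm means (the
  usual replicate count is 5), same pair formula.
* **Combination** (`combine_measures()`): measures are treated as
  independent multiplicative transmissions, $\{1-\prod(1-r_i)\}\times100$;
  no interaction terms.
* **Compliance** (`max_procedures()`): $\lfloor L/\tilde{d} \rfloor$
  procedures per year at annual limit $L$ (default 20 mSv) and median dose
  per procedure $\tilde{d}$.

Printed percentages are rounded half away from zero (every published rate
uses commercial rounding); the raw fraction is always carried alongside so
chained computations never compound rounding. Zero denominators (inside
dose, DLP) are excluded with a logged warning and an exclusion count —
silently propagating infinities would be worse, and the choice is surfaced
in the report's warnings.

`group_summary()` uses type-7 linear-interpolation quantiles (the rule is a
documented choice; published tables rarely state theirs) and a t-based 95%
CI of the mean.

## Rank tests

`kruskal_wallis()` implements the tie-corrected statistic from the rank
formula (mid-ranks; $H$ divided by $1-\sum(t^3-t)/(N^3-N)$; chi-square
upper tail, $k-1$ df — the group sizes this package targets are large
enough that exact small-sample tables are unnecessary). `dunn_bonferroni()`
implements Dunn's z on pooled mid-ranks with the tie-corrected variance and
multiplies each two-sided p by the *full* number of pairs $k(k-1)/2$,
capped at 1, regardless of which pairs get reported. Two-sided p-values are
the conventional choice. All-tied data yields $H=0$, $p=1$ rather than an
error. The implementation is cross-checked in the test suite against the
independent base-R implementation on random tied datasets to 1e-9.

## The synthetic cohort generator

`generate_cohort()` emulates the stratified structure of a one-year
monitoring campaign (default 91 procedures): practices drawn 65/12/14
(assisted ventilation / head holding / observation), ventilation performed
exclusively by intensive-care physicians, head holding split 5/12
paediatricians vs 7/12 technologists, observation mixed 7/1/6; standing
areas concentrated next to the gantry for the hands-on practices. Latent
outside doses are lognormal with per-practice medians 0.51/0.36/0.19 mSv;
DLP is lognormal (ventilation median 1561 mGy·cm, GSD 1.6) and the dose is
generated *proportionally to DLP* times a residual lognormal sized so the
marginal dose GSD matches the configured value (2.0/1.8/2.4) — staff
scatter dose physically tracks DLP, and this is what makes the
DLP-normalised tube estimator efficient. Latent transmissions: glasses
0.49, extension tube 0.69 (used in 62/65 of ventilation procedures),
curtain 0.39 in the phantom-pair generator.

Two generator conventions deserve emphasis:

* The configured per-practice median is the *realized* outside dose under
  the prevailing (with-tube) condition; the rare without-tube ventilation
  procedures are divided by the tube transmission. Defining it the other
  way (base dose multiplied by transmission) would shift the realized
  ventilation median to ~0.35 mSv and make the configured 0.51 unrecoverable.
* Reading noise between competing dosimeters (V/H GSD 1.15, L/R GSD 1.15)
  is drawn *max-centred*: each pair is scaled so its maximum has median 1.
  The analysis aggregates by max, and uncentred symmetric noise would bias
  every recovered median upward by ~exp(0.545·σ) and the recovered glasses
  reduction downward by several points. With max-centring the configured
  medians and transmissions are recoverable truths.

Seeding is per-stream (assignment, DLP, dose, tube flags, side noise,
orientation noise, metadata each reseed from the root seed plus a stream
offset), so adding a stream never perturbs earlier draws and cohorts are
bit-reproducible.

**What the generator does not emulate**: room-specific scatter geometry
(dose does not vary by standing area beyond the practice stratification),
correlation of CTDIvol/tube current with dose beyond the practice stratum,
dosimeter energy-response and fading effects, and the heavy upper tail of
the observation stratum seen in practice (a lognormal cannot bracket a
0.07–1.46 mSv range around a 0.19 mSv median; the published campaign's
tail is area-mixture-driven). Passing recovery tests therefore demonstrates
estimator correctness under the assumed dose model, not robustness to every
feature of real campaign data.

## Problem sizes used by the test suite

The suite checks median convergence at n = 5000 draws per practice
(relative error < 5%), type-I error calibration of the Kruskal–Wallis test
under three equal lognormal groups of n = 30 over 2000 replicates
(rejection rate within [0.035, 0.065] at α = 0.05), and recovery of the
three latent transmissions as 51/31/61% reductions within ±4 percentage
points averaged over 20 seeds at n = 500 procedures. These sizes keep the
whole suite around half a minute while leaving the stochastic checks
well-powered.

## Known limitations

* The spectrum model is semi-empirical; absolute fluence is meaningless
  (only ratios of kermas are used) and per-configuration filtration is a
  calibration constant, not a measurement.
* The bundled conversion-coefficient table is a synthetic compilation
  anchored at one energy; for regulatory work substitute the tabulation
  your dosimetry service uses.
* One beam-mean K is applied to every reading; no per-reading energy or
  angular correction.
* The compliance projection divides the annual limit by a median; it is a
  planning aid, not a prediction for an individual with an atypical case
  mix.
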