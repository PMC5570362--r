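---
title: "Methods: photophysiology and proteomic differential expression under copper limitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photophysiology and proteomic differential expression under copper limitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuphyto)
```

`cuphyto` implements the quantitative chain used to characterise how an
oceanic diatom restructures its photosynthetic apparatus under chronic
copper limitation: active chlorophyll-fluorescence (FRRf) analysis,
photosynthesis–irradiance (PE) curve fitting, an electron:carbon
conversion factor, a ratio-based proteomic differential-expression
caller, growth and oxygen rates, and a factorial ANOVA contrast scheme.
This vignette explains the models, their assumptions, the tunable
parameters and the numerical choices; the README shows the worked
end-to-end example.

## Single-turnover fluorescence model

A fast-repetition-rate fluorometer delivers a train of sub-saturating
flashlets that closes PSII reaction centres (RCII) within a single
photochemical turnover. Fluorescence rises from the minimum yield (all
centres open; Fo dark-regulated, F′ under actinic light) to the maximum
(all closed; Fm or Fm′). The closure dynamics carry the functional
absorption cross-section of PSII, σ~PSII~ (Å² RCII⁻¹).

The package models the fraction of closed centres C(t) with cumulative
single-hit kinetics,

$$\frac{dC}{dt} = \sigma\, i(t)\,\frac{1 - C}{1 - pC}, \qquad
F(t) = F_0 + (F_\max - F_0)\, C(t),$$

where `i(t)` is the flashlet photon flux (quanta Å⁻² μs⁻¹, piecewise
constant over the interval ending at each sample) and `p` the Joliot
connectivity between PSII antennae. With `p = 0` (the default) the model
has the closed form `C = 1 − exp(−σ · dose)`; for `p > 0` the separable
ODE is solved through its implicit integral by root finding. The flux
unit is chosen so that σ·dose is dimensionless. `p = 0` keeps the model
identifiable on short transients; fitting `p` is available behind
`fit_connectivity = TRUE` for saturating, low-noise records.

`fit_st_transient()` estimates (F0, Fmax, σ) by bounded
Levenberg–Marquardt least squares with a deterministic initialisation:
F0 from the trace minimum, Fmax from its maximum, and σ from the
photon dose at half-rise (`σ ≈ ln 2 / dose_half`). A transient with zero
flux or a flat trace carries no information and is rejected. The fit is
scale-equivariant: rescaling the trace rescales F0 and Fmax and leaves σ
unchanged.

### Derived fluorescence parameters

From the five yields the package computes the standard parameters:
Fv/Fm = (Fm−Fo)/Fm; Fq′/Fv′ = (Fm′−F′)/(Fm′−Fo′) (fraction of open
centres); Fv′/Fm′ = (Fm′−Fo′)/Fm′; their product Fq′/Fm′ (the operating
PSII efficiency); and the normalised Stern–Volmer non-photochemical
quenching NPQ~NSV~ = Fo′/Fv′ = Fm′/Fv′ − 1. Fo′ is never taken from the
light-regulated fit baseline; it is always derived as
Fo′ = Fo / (Fv/Fm + Fo/Fm′), which collapses to Fo when Fm′ = Fm.
Noisy light steps can produce F′ slightly below Fo′; the quenching
ratios are then clamped to [0, 1] with a warning rather than failing,
since such steps occur routinely in real light-response ladders. The
light-regulated cross-section σ′ used at the growth irradiance is the
one fitted from the transient recorded at the nearest background light
step (155 μmol quanta m⁻² s⁻¹ here), not an interpolation across steps.

## ETR per reaction centre, PE curves and the conversion factor

The electron transport rate per RCII is

$$\mathrm{ETR}_{RCII} = E \times \sigma_{PSII}' \times F_q'/F_v'
  \times 6.022\times 10^{-3}
  \quad [\mathrm{mol\,e^-\,mol\,RCII^{-1}\,s^{-1}}],$$

where the constant is Avogadro's number × 10⁻⁶ (μmol→mol) × 10⁻²⁰
(Å²→m²), computed (not hard-coded) in `etr_unit_constant()`.

PE curves (rate vs irradiance, 11 levels spanning 2–700
μmol quanta m⁻² s⁻¹ in the study design) are fitted with the
Jassby–Platt saturating model `P(E) = P_max tanh(αE/P_max)` without an
intercept or an explicit photoinhibition term; E~k~ = P~max~/α by
construction. Photoinhibition is handled by exclusion instead:
depressed points form a suffix of the irradiance-sorted data, so
`fit_pe(..., exclude_photoinhibition = TRUE)` scans candidate suffixes
from the longest feasible down and excludes the first suffix whose
points all lie above the provisional E~k~ and fall below the fitted
curve by more than twice the residual RMS of the remaining points. The
rule is deterministic, excludes nothing on clean data (idempotence), and
refuses to leave fewer than four points. Duplicate curves per biological
replicate are fitted individually and the parameters averaged
(`fit_pe_table()`), rather than pooled into one fit.

The electron:carbon conversion factor is the ratio of ETR~RCII~ to
Chla-normalised C assimilation evaluated at the growth irradiance from
the *fitted* curves (robust to the sampling grid), after converting
g C g Chla⁻¹ h⁻¹ to mol C mol Chla⁻¹ s⁻¹ with the molar masses 893.5
(Chla) and 12 (C). It conflates the electron requirement per fixed
carbon (Φ~e:C~) and the Chla per RCII (1/n~PSII~); the two are not
separable from these data. 14C uptake rates themselves follow the
standard scintillation computation with the conventional 1.05 isotope
discrimination factor.

## Proteomic differential expression

Triplex dimethyl labelling tags the three growth conditions with
light/medium/heavy formaldehyde isotopologues mixed 1:1:1; relative
abundance is read from peptide channel-intensity ratios. The package
rolls peptides up to protein ratios per biological replicate by the
median over peptides observed in both channels (median resists single
outlier peptides; a mean option exists), then applies conjunctive
significance rules per protein:

1. a ratio observed in at least two of the three replicates,
2. arithmetic mean of the ratios > 2 (up) or < 0.5 (down),
3. two-sided one-sample z-test of the log₂ ratios against 0 with
   p < 0.05.

Independently, any single observed ratio > 10 or < 0.1 marks an
*all-or-nothing* response, and the protein is called regardless of the
other rules. All thresholds are strict inequalities. Design readings
that were genuinely open: the threshold test uses the arithmetic mean of
raw ratios (the criterion as printed) while the z-test operates in log₂
space (symmetric in r and 1/r); the z-test is one-sample against no
change, since a treatment/control ratio already encodes the
between-treatment contrast; and criterion 1 counts replicates with a
quantified ratio, not direction-consistent replicates. With three
replicates a normal-quantile test is anticonservative in isolation, but
the conjunction with the two-fold mean rule makes false calls rare (the
null-calibration test measures < 1% on 1000 null proteins). No
multiple-testing correction enters the calls — a Benjamini–Hochberg
column is emitted for reference only. Optional per-replicate median
centring (off by default) is available for runs with imperfect 1:1:1
mixing. Fold changes are reported signed: r when r ≥ 1, −1/r otherwise,
so a mean ratio of 0.227 prints as −4.41.

## Growth, oxygen and normalisations

Growth rate μ (d⁻¹) is the OLS slope of ln(signal) vs day. When no
window is supplied, the exponential phase is chosen deterministically as
the contiguous window (≥ 4 points) maximising the log-linear R², with
ties broken towards longer then earlier windows. Cultures count as
acclimated when rates over five successive transfers vary by less than
15%, read as (max−min)/mean < 0.15 strictly (a CV option exists; the
choice of statistic was open). Oxygen rates are hourly OLS slopes of the
electrode trace, positive in the light phase and negative in the dark.
Per-volume normalisations use the equivalent-sphere volume (π/6)d³ from
the Coulter diameter — diatom geometry is not exactly spherical, and
this convention is flagged wherever volumes are reported.

## Factorial ANOVA and simple main effects

Physiological parameters are analysed on a 2×2×2 design (Strain × Fe
level × Cu level, three biological replicates per cell).
`fit_factorial()` fits the full-factorial linear model, which for a
balanced design is the cell-means model: it supplies every cell mean,
the pooled within-cell variance (model MSE) and the residual degrees of
freedom. `simple_main_effect()` tests the difference between the two
cell means obtained by varying one factor with the others fixed, as an
F test against the pooled error — the standard post-hoc
interaction-contrast construction, equal to the squared pooled-variance
t-test. A Welch variant (per-cell variances, Satterthwaite df) is
available when variance homogeneity is doubtful. No multiplicity
adjustment is applied across contrasts, matching how such contrasts are
conventionally starred; adjusted p-values can be added downstream. For
unbalanced data the cell-means contrasts are unaffected by
sum-of-squares type; the packaged generators produce balanced designs.

## Synthetic data and what it does (not) show

Every input the chain consumes can be simulated (`gen_st_transient()`,
`gen_pe_dataset()`, `gen_proteomics_table()`, `gen_growth_curve()`,
`gen_physio_table()`), each deterministic given a seed and each an exact
round-trip partner of its fitter at zero noise. The scenario presets
encode the study conditions of the two strains (TO03 = CCMP1003,
TO05 = CCMP1005) under replete and low copper:

* Fv/Fm 0.6 (control) vs 0.3 (low Cu, TO03); σ~PSII~ +30% (500 → 650 Å²
  RCII⁻¹, absolute scale chosen as typical for a small centric diatom);
  NPQ~NSV~ ×4 (2/3 → 8/3, via Fv′/Fm′ 0.6 → 3/11); Fq′/Fv′ 0.7 → 0.6.
* μ 1.05 → 0.51 d⁻¹ (TO03) and 1.26 → 0.82 d⁻¹ (TO05); TO05's
  photophysiology and proteome do not respond to low Cu.
* marker protein ratios (low Cu/control): plastocyanin 0.227 (−4.41
  signed), ferredoxin 43.79, FNR 2.47.
* ETR PE: E~k~ 140 → 105 μmol quanta m⁻² s⁻¹ with α +18%. The measured
  percentage changes of α, P~max~ and E~k~ are not mutually consistent
  with E~k~ = P~max~/α, so the presets anchor E~k~ and α and let P~max~
  follow (×0.885).
* 14C PE: the low-Cu preset anchors the two headline outcomes — the
  conversion factor doubling at the growth irradiance and E~k~(14C)
  falling by about a third — giving α ×0.6 and P~max~ ×0.4. The
  separately measured per-chlorophyll declines (α −63%, P~max~ −75%)
  cannot hold simultaneously with a stable ETR and a two-fold factor,
  so the presets favour the derived contrasts over the component
  percentages.

Default noise levels are modest and realistic for the respective
instruments: Gaussian noise of a few instrument units on transients
(≲1% of Fm), 3–5% multiplicative noise on PE rates, 2% on growth
signals, log₂-sd 0.3 on peptide ratios with 5% channel dropout. The
test problem sizes (e.g. 200-seed recovery runs, 1000-protein null
tables, 2000 null ANOVA simulations) were chosen to estimate the
calibration quantities to the precision the assertions need.

The generators emulate the *statistical* structure the estimators
assume: single-hit closure with homoscedastic detector noise, tanh PE
shape with multiplicative error, lognormal peptide intensities with
independent channel dropout, exponential growth, Gaussian cell noise in
a balanced design. They do not emulate instrument baseline drift,
connectivity heterogeneity, saturating-detector nonlinearity, peptide
identification error, shared-peptide ambiguity between proteins, or
semi-continuous culture dynamics. Passing round-trip and calibration
tests therefore demonstrates correctness of the estimators under their
stated assumptions, not robustness to every artefact of real data.

One packaged dataset deserves emphasis: the stored low-Cu ETR PE
curves under `inst/extdata/` are **synthetic** replicates generated
from the low-Cu preset (E~k~ = 105), standing in for raw instrument
exports so that the refit pathway (CSV → per-replicate fits → averaged
E~k~) is exercised from a file on disk.

## Known limitations

* σ~PSII~ is fitted without spectral correction; values are
  instrument-spectrum specific.
* The plastoquinone-pool size per Q~B~ sometimes reported alongside
  these parameters has no documented derivation and is not computed.
* The ST model assumes negligible reopening during the flash train
  (true single turnover); transients longer than ~1 ms would need a
  reoxidation term.
* The DE caller is rule-based by design; it inherits the
  anticonservative small-n z-test and mitigates it only through the
  conjunction with the fold-change rule.
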