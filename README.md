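# cuphyto

Quantitative analysis of diatom copper-limitation experiments in R:
photophysiology from fast-repetition-rate fluorometry (FRRf),
photosynthesis–irradiance (PE) curves, an electron:carbon conversion
factor, a rule-based proteomic differential-expression caller for
triplex dimethyl labelling, growth and oxygen rates, and a 2×2×2
factorial ANOVA with simple-main-effect contrasts. A seeded
synthetic-data generator emulates every input, so the whole chain runs
and is tested without any external data.

The package is aimed at phytoplankton physiologists and quantitative
proteomics users who need the computations behind a two-strain
(*Thalassiosira oceanica* CCMP1003 "TO03" vs CCMP1005 "TO05")
copper-limitation study as reusable, tested functions.

## The core computations

**Single-turnover fluorescence.** A flashlet train closes PSII reaction
centres; fluorescence rises from Fo (or F′) to Fm (or Fm′) following
cumulative single-hit kinetics, `F(t) = F0 + (Fmax−F0)·C(t)` with
`dC/dτ = σ·i(τ)·(1−C)`. `fit_st_transient()` recovers F0, Fmax and the
functional absorption cross-section σ_PSII (Å² RCII⁻¹) by bounded
nonlinear least squares. From the five yields:
`Fv/Fm = (Fm−Fo)/Fm`, `Fo′ = Fo/(Fv/Fm + Fo/Fm′)`,
`Fq′/Fv′ = (Fm′−F′)/(Fm′−Fo′)`, `Fv′/Fm′ = (Fm′−Fo′)/Fm′`,
`Fq′/Fm′ = Fq′/Fv′ × Fv′/Fm′`, `NPQ_NSV = Fo′/Fv′`.

**ETR and PE curves.** `ETR_RCII = E·σ_PSII′·(Fq′/Fv′)·6.022×10⁻³`
(mol e⁻ mol RCII⁻¹ s⁻¹). PE curves are fitted with the Jassby–Platt
model `P(E) = Pmax·tanh(αE/Pmax)` (`Ek = Pmax/α`), with a deterministic
high-light photoinhibition exclusion rule. The conversion factor is
ETR_RCII over Chla-normalised C assimilation at growth irradiance
(155 μmol quanta m⁻² s⁻¹), units reconciled via the molar masses of
Chla (893.5) and C (12).

**Proteomic DE calls.** Peptide channel intensities → per-replicate
protein ratios (median roll-up) → calls: observed in ≥ 2 of 3
replicates, mean ratio > 2 (up) or < 0.5 (down), z-test of log₂ ratios
p < 0.05; plus an all-or-nothing rule for any single ratio > 10 or
< 0.1. Fold changes are signed (0.227 → −4.41).

**Growth, oxygen, factorial statistics.** μ from log-linear OLS with
automatic exponential-window selection; the <15% five-transfer
acclimation rule; hourly O₂ slopes; and full-factorial cell-means
models with pooled-error simple-main-effect F contrasts.

## Worked example

```r
library(cuphyto)

ctr <- run_scenario_contrast("TO03_control", "TO03_lowCu", seed = 1)
ctr
#> Contrast TO03_control vs TO03_lowCu
#>   Fv/Fm 0.60 -> 0.30 | sigma x1.29 | NPQ x4.04 | CF x1.86
#>   mu 1.05 -> 0.53 d-1 (50% of control)
#>   marker proteins:
#>     petE_plastocyanin  down signed FC -4.17
#>     petF_ferredoxin    up   signed FC 41.94 (all-or-nothing)
#>     petH_FNR           up   signed FC 2.30
```

Reading this: under low copper TO03 halves its maximum PSII quantum
yield (Fv/Fm 0.6 → 0.3), enlarges its PSII antenna cross-section ~30%,
quadruples non-photochemical quenching, and needs about twice as many
PSII charge separations per carbon fixed (conversion factor ×~2), while
growing at half its maximal rate; plastocyanin (the Cu-containing
electron carrier) is strongly down-regulated and ferredoxin shows an
extreme all-or-nothing induction.

The numbered scripts under `analysis/` run the same chain as a
file-based workflow (simulate raw CSV/TSV inputs, then fluorescence/PE,
proteomics, growth/oxygen, and factorial contrasts), writing tables
under `results/`.

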