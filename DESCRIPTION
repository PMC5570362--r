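Package: cuphyto
Title: Photophysiology and Proteomics of Copper-Limited Diatoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for two-strain diatom copper-limitation
    experiments: single-turnover chlorophyll-fluorescence (FRRf) induction
    fitting for Fo, Fm and the functional absorption cross-section of PSII;
    derived fluorescence parameters (Fv/Fm, Fq'/Fv', Fv'/Fm', Fq'/Fm',
    normalised Stern-Volmer NPQ); electron transport rate per PSII reaction
    centre; Jassby-Platt photosynthesis-irradiance curve fitting with
    photoinhibition exclusion; the electron-to-carbon conversion factor;
    a ratio-based differential-expression caller for triplex dimethyl-label
    proteomics; exponential growth-rate and oxygen-evolution rate fitting;
    and 2x2x2 factorial ANOVA with simple-main-effect contrasts. Includes a
    seeded synthetic-data generator so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    emmeans,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
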