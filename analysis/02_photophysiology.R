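#!/usr/bin/env Rscript
# Photophysiology of the TO03 control vs low-Cu conditions: fit the
# single-turnover transients for the five ChlF yields and sigma_PSII,
# derive the fluorescence parameters at growth irradiance, fit the PE
# curves (with photoinhibition screening) and form the electron:carbon
# conversion factor at the growth irradiance of 155 umol quanta m-2 s-1.

library(cuphyto)

data_dir <- "results/data"
out_dir <- "results"
growth_E <- 155

## ChlF yields and parameters from the ST transients
rows <- list()
for (preset in c("TO03_control", "TO03_lowCu")) {
  dark <- fit_st_transient(read_st_transient(
    file.path(data_dir, sprintf("st_%s_dark.csv", preset))))
  light <- fit_st_transient(read_st_transient(
    file.path(data_dir, sprintf("st_%s_light.csv", preset))))
  pars <- chlf_params(dark$F0, dark$Fmax, light$F0, light$Fmax,
                      background_E = growth_E)
  rows[[preset]] <- cbind(data.frame(sample_id = preset,
                                     sigma_PSII = dark$sigma_PSII,
                                     sigma_PSII_prime = light$sigma_PSII),
                          pars)
}
chlf <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
write.csv(chlf, file.path(out_dir, "chlf_parameters.csv"),
          row.names = FALSE)

message(sprintf("Fv/Fm: control %.2f -> low Cu %.2f", chlf$FvFm[1],
                chlf$FvFm[2]))
message(sprintf("sigma_PSII: %+.0f%%; NPQ_NSV: x%.1f",
                100 * (chlf$sigma_PSII[2] / chlf$sigma_PSII[1] - 1),
                chlf$NPQ_NSV[2] / chlf$NPQ_NSV[1]))

## PE fits per condition and rate type; conversion factor at growth E
pe <- read.csv(file.path(data_dir, "pe_curves.csv"))
fit_rows <- list()
cf <- c()
for (cond in unique(pe$condition)) {
  sub <- pe[pe$condition == cond, ]
  res <- fit_pe_table(
    data.frame(replicate_id = sub$replicate_id, rate_type = sub$rate_type,
               E = sub$E_umol_quanta_m2_s, rate = sub$rate),
    exclude_photoinhibition = TRUE)
  res$mean$condition <- cond
  fit_rows[[cond]] <- res$mean
  m <- res$mean
  etr155 <- jassby_platt(growth_E, m$alpha[m$rate_type == "ETR"],
                         m$Pmax[m$rate_type == "ETR"])
  c14155 <- jassby_platt(growth_E, m$alpha[m$rate_type == "C14"],
                         m$Pmax[m$rate_type == "C14"])
  cf[cond] <- conversion_factor(etr155, c14155)
}
pe_report <- do.call(rbind, c(fit_rows, list(make.row.names = FALSE)))
pe_report$conversion_factor_at_155 <- cf[pe_report$condition]
write.csv(pe_report, file.path(out_dir, "pe_fits.csv"), row.names = FALSE)

message(sprintf("Ek(ETR): %.0f -> %.0f; Ek(14C): %.0f -> %.0f",
                pe_report$Ek[pe_report$condition == "TO03_control" &
                               pe_report$rate_type == "ETR"],
                pe_report$Ek[pe_report$condition == "TO03_lowCu" &
                               pe_report$rate_type == "ETR"],
                pe_report$Ek[pe_report$condition == "TO03_control" &
                               pe_report$rate_type == "C14"],
                pe_report$Ek[pe_report$condition == "TO03_lowCu" &
                               pe_report$rate_type == "C14"]))
message(sprintf("Conversion factor at %d: x%.2f under low Cu", growth_E,
                cf["TO03_lowCu"] / cf["TO03_control"]))
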