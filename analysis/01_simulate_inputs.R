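#!/usr/bin/env Rscript
# Simulate one full set of raw inputs for the copper-limitation analysis:
# single-turnover FRRf transients (dark + light-regulated) for the TO03
# control and low-Cu conditions, ETR and 14C PE curves, a triplex peptide
# intensity table, growth series for all four strain x Cu conditions, and
# a tidy physiology table for the factorial ANOVA. Downstream scripts
# (02-05) consume only these files.

library(cuphyto)

seed <- 20260923
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

message("Simulating raw inputs into ", data_dir)

## FRRf single-turnover transients, one file per flash
for (preset in c("TO03_control", "TO03_lowCu")) {
  for (state in c("dark_regulated", "light_regulated")) {
    tr <- gen_st_transient(preset, state, noise_sd = 2,
                           seed = seed + match(state, c("dark_regulated",
                                                        "light_regulated")))
    write_st_transient(tr, file.path(
      data_dir, sprintf("st_%s_%s.csv", preset,
                        sub("_regulated", "", state))))
  }
  seed <- seed + 10
}

## PE curves: 3 replicates per condition and rate type
seed <- 20260923
pe_rows <- list()
for (preset in c("TO03_control", "TO03_lowCu")) {
  for (rt in c("ETR", "C14")) {
    pe <- gen_pe_dataset(preset, rt, noise_cv = 0.05, n_rep = 3,
                         seed = seed <- seed + 1)
    pe$condition <- preset
    pe_rows[[paste(preset, rt)]] <- pe
  }
}
pe_all <- do.call(rbind, pe_rows)
write.csv(data.frame(condition = pe_all$condition,
                     replicate_id = pe_all$replicate_id,
                     rate_type = pe_all$rate_type,
                     E_umol_quanta_m2_s = pe_all$E, rate = pe_all$rate),
          file.path(data_dir, "pe_curves.csv"), row.names = FALSE)

## Triplex proteome: low Cu (medium label) vs control (light label)
prot <- gen_proteomics_table(n_proteins = 300,
                             spikes = default_spikes("TO03_lowCu"),
                             seed = seed + 50)
write.table(prot, file.path(data_dir, "peptides_TO03.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

## Growth series for all four conditions
for (preset in c("TO03_control", "TO03_lowCu", "TO05_control",
                 "TO05_lowCu")) {
  g <- gen_growth_curve(preset, days = 0:5, noise_cv = 0.02,
                        seed = seed <- seed + 1)
  write.csv(g, file.path(data_dir, sprintf("growth_%s.csv", preset)),
            row.names = FALSE)
}

## Physiology table for the factorial model: Fv/Fm with a Cu effect
## confined to TO03 (low Cu drops Fv/Fm 0.6 -> 0.3 in TO03 only)
phys <- gen_physio_table("FvFm", baseline = 0.6, cu_effect = -0.3,
                         strain_cu_effect = 0.3, sd = 0.01,
                         seed = seed + 99)
write.csv(phys, file.path(data_dir, "physiology_FvFm.csv"),
          row.names = FALSE)

message("Done: ", length(list.files(data_dir)), " files.")
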