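#!/usr/bin/env Rscript
# Differential expression of the low-Cu (medium label) vs control (light
# label) proteome: aggregate peptide channel intensities to per-replicate
# protein ratios, apply the significance rules (>= 2 replicates observed,
# mean ratio > 2 or < 0.5, z-test p < 0.05, all-or-nothing single-replicate
# ratios > 10 or < 0.1) and report signed fold changes.

library(cuphyto)

peptides <- read_peptide_tsv("results/data/peptides_TO03.tsv")
ratios <- aggregate_protein_ratios(peptides, treatment = "medium",
                                   control = "light")
calls <- de_call_table(ratios)
write.table(calls, "results/de_calls_TO03.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sig <- calls[calls$call %in% c("up", "down"), ]
message(nrow(calls), " proteins quantified; ", nrow(sig),
        " significantly changed (", sum(sig$call == "up"), " up, ",
        sum(sig$call == "down"), " down, ",
        sum(sig$all_or_nothing), " all-or-nothing).")
markers <- calls[calls$protein_id %in%
                   c("petE_plastocyanin", "petF_ferredoxin", "petH_FNR"), ]
for (i in seq_len(nrow(markers)))
  message(sprintf("  %-18s %-4s signed FC %6.2f  p = %.2g%s",
                  markers$protein_id[i], markers$call[i],
                  markers$signed_fold_change[i], markers$p_value[i],
                  if (markers$all_or_nothing[i]) "  [all-or-nothing]" else ""))
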