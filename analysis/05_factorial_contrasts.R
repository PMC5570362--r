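#!/usr/bin/env Rscript
# Factorial analysis of a physiological parameter over the Strain x Fe x Cu
# design, followed by the simple-main-effect contrasts of interest: the
# low-Cu response within each strain (Fe fixed high), and the strain
# difference under low Cu.

library(cuphyto)

phys <- read_physio_csv("results/data/physiology_FvFm.csv")
fit <- fit_factorial(phys, parameter = "FvFm")
print(fit)

contrasts <- rbind(
  simple_main_effect(fit, vary = "cu_level",
                     fixed = c(strain = "TO03", fe_level = "high")),
  simple_main_effect(fit, vary = "cu_level",
                     fixed = c(strain = "TO05", fe_level = "high")),
  simple_main_effect(fit, vary = "strain",
                     fixed = c(fe_level = "high", cu_level = "low")))
write.csv(contrasts, "results/contrasts_FvFm.csv", row.names = FALSE)

for (i in seq_len(nrow(contrasts)))
  message(sprintf("%s @ %s: estimate %+.3f, F(1,%d) = %.1f, p = %.2g",
                  contrasts$vary[i], contrasts$fixed[i],
                  contrasts$estimate[i], contrasts$df2[i], contrasts$F[i],
                  contrasts$p_value[i]))
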