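#!/usr/bin/env Rscript
# Growth rates of both strains under replete and low Cu, relative growth
# (% of the strain's maximum), and oxygen evolution/respiration rates from
# electrode traces.

library(cuphyto)

data_dir <- "results/data"

mu <- sapply(c("TO03_control", "TO03_lowCu", "TO05_control", "TO05_lowCu"),
             function(p) {
               g <- read_growth_csv(file.path(data_dir,
                                              sprintf("growth_%s.csv", p)))
               fit_growth_rate(g$day, g$signal)$mu
             })
growth <- data.frame(
  condition = names(mu), mu = unname(mu),
  relative_pct = c(100, relative_growth(mu[["TO03_lowCu"]],
                                        mu[["TO03_control"]]),
                   100, relative_growth(mu[["TO05_lowCu"]],
                                        mu[["TO05_control"]])))
write.csv(growth, "results/growth_rates.csv", row.names = FALSE)
message(sprintf("TO03: mu %.2f -> %.2f d-1 (%.0f%% of max)",
                mu[["TO03_control"]], mu[["TO03_lowCu"]],
                growth$relative_pct[2]))
message(sprintf("TO05: mu %.2f -> %.2f d-1 (%.0f%% of max)",
                mu[["TO05_control"]], mu[["TO05_lowCu"]],
                growth$relative_pct[4]))

## Acclimation rule on a window of successive transfer rates
transfers <- c(1.04, 1.06, 1.05, 1.03, 1.07)
message("Acclimated (<15% variation over 5 transfers): ",
        acclimation_check(transfers))

## Oxygen rates: constructed light and dark phase traces at the per-cell
## rates measured for TO03 (123 -> 36 fmol O2 cell-1 h-1 gross production)
t_s <- seq(0, 300, by = 20)
o2 <- data.frame(
  condition = c("TO03_control", "TO03_lowCu"),
  gross_production = c(linear_rate(t_s, 200 + 123 / 3600 * t_s),
                       linear_rate(t_s, 200 + 36 / 3600 * t_s)),
  respiration = c(linear_rate(t_s, 200 - 30 / 3600 * t_s),
                  linear_rate(t_s, 200 - 28 / 3600 * t_s)))
o2$change_pct <- c(NA, percent_change(o2$gross_production[1],
                                      o2$gross_production[2]))
write.csv(o2, "results/o2_rates.csv", row.names = FALSE)
message(sprintf("Gross O2 production: %.0f -> %.0f (%.0f%%)",
                o2$gross_production[1], o2$gross_production[2],
                o2$change_pct[2]))
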