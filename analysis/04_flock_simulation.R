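#!/usr/bin/env Rscript
# Monte Carlo simulation of 1,000 virtual broilers under the registered
# single oral doses (25 mg/kg SDZ + 5 mg/kg TMP; 37.5 mg/kg SMX +
# 7.5 mg/kg TMP), protein-binding-corrected (SDZ 80%, TMP 77%, SMX 62%
# bound) free-concentration TMP:S ratio percentiles over 24 h and
# attainment of the 1:19 synergy target. Includes a sensitivity analysis
# on cross-drug random-effect correlations: the two drugs are
# co-formulated, and the published simulations included (unpublished)
# estimated correlations, to which the attainment fraction is highly
# sensitive.

library(sulfatrim)

pop <- boulanger2024()
regs <- list(TMP_SDZ = regimen_spec("SDZ", 25, 5, n = 1000, seed = 41),
             TMP_SMX = regimen_spec("SMX", 37.5, 7.5, n = 1000, seed = 42))

for (nm in names(regs)) {
  fs <- simulate_flock(pop, regs[[nm]])
  print(fs)
  q12 <- fs$percentiles[fs$percentiles$time == 12, ]
  cat(sprintf("  12 h free-ratio 5-95%%: 1:%0.f to 1:%0.f (median 1:%0.f)\n",
              1 / q12$p95, 1 / q12$p05, 1 / q12$p50))
  write_flock_csv(fs, sprintf("results/flock_%s_percentiles.csv", nm),
                  sprintf("results/flock_%s_attainment.csv", nm))
}

cat("\nsensitivity: attainment vs cross-drug correlation (TMP/SDZ)\n")
sens <- data.frame(cross = c(0, 0.5, 0.8, 0.95), attained_pct = NA_real_)
for (i in seq_len(nrow(sens))) {
  r <- sens$cross[i]
  fs <- simulate_flock(pop, regs$TMP_SDZ,
                       cross_corr = c(ka = r, Vd = r, CL = r))
  sens$attained_pct[i] <- 100 * fs$fraction_attained
  cat(sprintf("  cross-corr %.2f -> %.1f%% of birds ever reach 1:19\n",
              r, sens$attained_pct[i]))
}
write.csv(sens, "results/flock_cross_corr_sensitivity.csv", row.names = FALSE)
cat("wrote results/flock_*_percentiles.csv, *_attainment.csv, cross-corr sensitivity\n")
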