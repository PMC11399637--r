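#!/usr/bin/env Rscript
# Model validation for the fitted models: weighted residuals (PWRES /
# IWRES), normalized prediction distribution errors and the
# prediction-corrected visual predictive check per drug and route.

library(sulfatrim)

data <- read_dataset("results/study_dataset.csv")
ftj <- "results/estimates.json"
stopifnot(file.exists(ftj))
# rebuild a fit object (deterministic) to reuse its EBEs
ft <- fit(data, control = list(quiet = TRUE))

for (drug in names(ft$fits)) {
  wr <- weighted_residuals(ft, data, drug, nsim = 500, seed = 100 + match(drug, names(ft$fits)))
  write.csv(wr, sprintf("results/residuals_%s.csv", drug), row.names = FALSE)
  nd <- npde(ft, data, drug, nsim = 1000, seed = 200 + match(drug, names(ft$fits)))
  write.csv(nd, sprintf("results/npde_%s.csv", drug), row.names = FALSE)
  vpc <- pcvpc(ft, data, drug, nsim = 500, seed = 300 + match(drug, names(ft$fits)))
  write_vpc_csv(vpc, sprintf("results/vpc_%s.csv", drug))
  ks <- suppressWarnings(ks.test(nd$NPDE[!nd$censored], "pnorm"))
  p50 <- vpc[vpc$percentile == 50, ]
  cat(sprintf("%s: IWRES mean %+.3f sd %.3f | NPDE KS p = %.3f | pcVPC p50 in band %.0f%% of bins | %d censored obs excluded from residuals\n",
              drug, mean(wr$IWRES), sd(wr$IWRES), ks$p.value,
              100 * mean(p50$empirical >= p50$sim_lo & p50$empirical <= p50$sim_hi),
              attr(wr, "n_censored_excluded")))
}
cat("wrote results/residuals_*.csv, results/npde_*.csv, results/vpc_*.csv\n")
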