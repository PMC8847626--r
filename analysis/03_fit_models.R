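#!/usr/bin/env Rscript
# Stage 3: retention regressions.
# For each tracer form, exhaustively fits all 511 subsets of the nine
# candidate predictors to the loss fraction, organic-layer retention,
# plant:(plant+mineral) ratio and woody share, ranks them by AICc under the
# VIF <= 3 collinearity screen, and writes the winners plus the full ranked
# ledger for audit.

library(ndepsink)

sites <- read_site_csv("results/sites.csv")

for (form in c("NHx", "NOy")) {
  models <- fit_retention_models(sites, form, mode = "chained",
                                 selection = "subset")
  write_model_ledger(models, sprintf("results/models_%s.json", form))
  cat(sprintf("\n%s selected models (of 511 subsets each):\n", form))
  for (nm in names(models)) {
    m <- models[[nm]]
    cat(sprintf("  %-12s ~ %-30s R2 = %.2f, AICc = %7.2f, max VIF = %.2f\n",
                nm, paste(m$predictors, collapse = " + "), m$r2, m$aicc,
                max(m$vif)))
  }
}
cat("\nledgers -> results/models_NHx.json, results/models_NOy.json\n")
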