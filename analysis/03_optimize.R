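#!/usr/bin/env Rscript
# Stage 3 — maximize each fitted surface over the coded experimental cube
# [-1, 1]^4, decode the argmax to real medium concentrations, and compare
# the predictions against the verification culture (266.84 U/mL enzyme
# activity, 0.519 OD600 biomass at the fastigium).
#
# Finding: predicted optimum ~267.9 U/mL at ~1.76 g/L kappa-carrageenan,
# 20.0 g/L NaCl, 0.96 g/L yeast extract, 1.02 g/L FOS; both verification
# relative errors are well under 2%.

library(fermkin)
dir.create("results", showWarnings = FALSE)

bbd <- read_design_csv(fermkin_example("bbd_table4.csv"),
                       fermkin_example("bbd_table4.yaml"))

verified <- c(EA = 266.84, BM = 0.519)
summary_rows <- lapply(c("EA", "BM"), function(resp) {
  opt <- optimize_quadratic(fit_quadratic(bbd, resp), box = c(-1, 1))
  print(opt)
  write_report(opt, file.path("results", paste0("optimum_", resp, ".json")),
               format = "json")
  rel <- relative_error(opt$predicted_response, verified[[resp]])
  cat(sprintf("  verification %s = %g, relative error %.4f (%s 2%%)\n\n",
              resp, verified[[resp]], rel, if (rel < 0.02) "<" else ">="))
  data.frame(response = resp, predicted = opt$predicted_response,
             observed = verified[[resp]], relative_error = rel,
             on_boundary = opt$on_boundary)
})
verif <- do.call(rbind, summary_rows)
write_report(verif, "results/verification.tsv", format = "tsv")
cat("Optimization reports written to results/optimum_*.json and results/verification.tsv\n")
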