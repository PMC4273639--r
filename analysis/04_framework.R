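#!/usr/bin/env Rscript

# Step 4: the mobilization-potential calculus on the five measured transfer
# frequencies of the assay (conjugal plasmid into community and intrastrain,
# mobilizable plasmid into community by retromobilization, intrastrain
# retromobilization, and direct mobilization into the community).

library(mobipot)

freqs <- mating_frequency_set(
  conj_comm   = 1.16e-4,  # conjugal plasmid -> community
  conj_intra  = 1.76e-3,  # conjugal plasmid, isogenic mating
  retro_comm  = 1.16e-5,  # mobilizable plasmid -> community (retro)
  retro_intra = 8.34e-4,  # mobilizable plasmid -> isogenic mobilizer host
  direct_comm = 3.14e-3)  # mobilizable plasmid + co-resident conjugal -> community

report <- build_report(freqs)
print(report)

dir.create("results", showWarnings = FALSE)
write.csv(as.data.frame(report), "results/mobilization_report.csv",
          row.names = FALSE)

# how sensitive are the ratios to measurement error? assume 20% relative SEM
# on every frequency and propagate by the delta method
freqs_sem <- mating_frequency_set(
  conj_comm = list(mean = 1.16e-4, sem = 0.2 * 1.16e-4),
  conj_intra = list(mean = 1.76e-3, sem = 0.2 * 1.76e-3),
  retro_comm = list(mean = 1.16e-5, sem = 0.2 * 1.16e-5),
  retro_intra = list(mean = 8.34e-4, sem = 0.2 * 8.34e-4))
iv <- propagate_uncertainty(freqs_sem, method = "delta")
cat("\ndelta-method intervals under 20% relative SEM per frequency:\n")
print(iv, row.names = FALSE)
write.csv(iv, "results/mobilization_report_uncertainty.csv", row.names = FALSE)
cat("wrote results/mobilization_report.csv and _uncertainty.csv\n")
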