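#!/usr/bin/env Rscript
# Stage 2: available energy for anaerobic respiration in each well, the
# H2 threshold for anaerobic methane oxidation, and the sensitivity of
# the results to the assumed (unmeasured) sulfide activity.

library(mahomet)

dir.create("results", showWarnings = FALSE)

wells <- mahomet_wells()
classes <- sulfate_classes(wells)
et <- energy_table(wells)
write.table(et, "results/02_energy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (rxn in c("sulfate_reduction_h2", "methanogenesis_h2", "aom_reverse",
              "aom_sulfate_coupled")) {
  r <- et[et$reaction == rxn & et$computable, ]
  cat(sprintf("%-22s dG_A = %6.1f .. %6.1f kJ/mol  (%d wells, %d viable)\n",
              rxn, min(r$dG_A), max(r$dG_A), nrow(r), sum(r$viable)))
}
cat("Wells excluded for missing analytes:",
    paste(unique(et$well_id[!et$computable]), collapse = ", "), "\n")

cat("\nAOM (reverse methanogenesis) is endergonic at bulk H2 everywhere;\n")
cat("H2 thresholds at which it would become exergonic:\n")
ok <- wells$ch4_status != "missing" & wells$dic_status != "missing"
th <- do.call(rbind, lapply(which(ok), function(i) {
  t <- h2_threshold_aom(wells[i, ])
  data.frame(well_id = wells$well_id[i], sulfate_class = classes[i],
             h2_threshold_nM = t$h2_nM, closed_form_nM = t$closed_form_nM)
}))
write.table(th, "results/02_aom_thresholds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ls_th <- th$h2_threshold_nM[th$sulfate_class == "LS"]
cat(sprintf("  LS wells: %.2f .. %.2f nM (bulk H2 is 3-240 nM, so AOM\n",
            min(ls_th), max(ls_th)))
cat("  requires an H2-scavenging partner maintaining sub-nM H2 locally)\n")

sens <- assumption_sensitivity(reaction_catalog()$sulfate_reduction_h2,
                               wells[wells$well_id == "Chm94B", ])
cat(sprintf("\nSensitivity to assumed sulfide: %.2f kJ/mol per decade\n",
            abs(attr(sens, "slope_per_decade"))))
write.table(sens, "results/02_sulfide_sensitivity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/02_energy.tsv, results/02_aom_thresholds.tsv,",
    "results/02_sulfide_sensitivity.tsv\n")
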