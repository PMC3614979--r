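#!/usr/bin/env Rscript
# Stage 7 — back-translation: clinical signatures in the mouse time course.
#
# Compiles the per-direction unions of clinical DEGs (1.5-fold, q < 0.05)
# across the three comparisons and tests their enrichment against the
# composite-ranked mouse list of every time point.

library(phasesig)

SEED <- 1
mouse_de <- read.delim("results/de/mouse_de.tsv")
human_de <- read.delim("results/de/human_de.tsv")

clinical <- build_clinical_union_sets(split(human_de, human_de$contrast),
                                      fc_min = 1.5, q_max = 0.05)
message("clinical unions: ", length(clinical$up), " up / ",
        length(clinical$down), " down genes")

mouse_ranked <- lapply(split(mouse_de, mouse_de$time_days), composite_rank)
res <- back_translate(clinical, mouse_ranked,
                      gsea_params(n_permutations = 1000, seed = SEED))
write_enrichment_report(res, "results/enrichment/back_translation.tsv")

up <- res[res$set == "clinical_up", ]
message("clinical up-union enrichment across the time course:")
print(up[, c("time_days", "es", "nes", "p_value", "q_value")])
enr <- up$time_days[up$nes > 0 & up$p_value < 0.05 & up$q_value < 0.25]
message("positively enriched (p<0.05, FDR<0.25) at day(s): ",
        paste(enr, collapse = ", "))

bt <- cbind(contrast = paste0("day_", res$time_days), res)
export_enrichment_heatmap(bt, "results/enrichment/back_translation_heatmap.tsv",
                          p_max = 0.05, q_max = 0.25)
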