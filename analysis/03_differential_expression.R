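#!/usr/bin/env Rscript
# Stage 3 — differential expression.
#
# Mouse: per-gene ANOVA (treatment x time cell-means model) with the
# bleomycin-vs-saline contrast tested at each day on the pooled residual
# variance; BH correction within each contrast. Human: pooled two-sample
# t contrasts for stable IPF vs control, exacerbation vs control and
# exacerbation vs stable, with composite-ranked lists for enrichment.

library(phasesig)

mouse <- load_expression("results/processed/mouse_expression.tsv",
                         "results/processed/mouse_annotations.tsv")
human <- load_expression("results/data/human_expression.tsv",
                         "results/data/human_annotations.tsv")
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

mouse_de <- fit_contrasts(mouse, "bleomycin", "saline")
write.table(mouse_de, "results/de/mouse_de.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
degs <- filter_degs(mouse_de, fc_min = 2, q_max = 0.05)
for (ct in names(degs))
  message(ct, ": ", length(degs[[ct]]$up), " up / ",
          length(degs[[ct]]$down), " down DEGs (>= 2-fold, q < 0.05)")
union_size <- length(unique(unlist(lapply(degs, unlist))))
message("union of mouse DEGs across time points: ", union_size, " genes")

contrasts <- list(ipf_vs_control = c("stable", "control"),
                  exac_vs_control = c("exacerbation", "control"),
                  exac_vs_stable = c("exacerbation", "stable"))
human_de <- list()
for (nm in names(contrasts)) {
  pr <- contrasts[[nm]]
  de <- fit_contrasts(human, pr[1], pr[2], time_col = NULL)
  de$contrast <- nm
  human_de[[nm]] <- de
  write_rnk(composite_rank(de), sprintf("results/de/ranked_%s.rnk", nm))
  hits <- filter_degs(de, fc_min = 1.5, q_max = 0.05)
  message(nm, ": ", length(hits$up), " up / ", length(hits$down),
          " down DEGs (>= 1.5-fold, q < 0.05)")
}
write.table(do.call(rbind, human_de), "results/de/human_de.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
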