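#!/usr/bin/env Rscript
# Stage 6 — leading-edge union and canonical-pathway overlap.
#
# Pools the leading edges of signatures positively enriched in the
# IPF-vs-control analyses, tests the union for hypergeometric pathway
# over-representation against the ranked-list universe, and counts the
# top-k overlap between the mouse day-14 and clinical pathway tables.

library(phasesig)

forward <- read.delim("results/enrichment/forward_enrichment.tsv")
pathways <- read_gmt("results/data/pathways.gmt")
human_de <- read.delim("results/de/human_de.tsv")
universe <- names(read_rnk("results/de/ranked_ipf_vs_control.rnk"))

vs_control <- forward[forward$contrast %in% c("ipf_vs_control",
                                              "exac_vs_control") &
                        forward$p_value < 0.05 & forward$q_value < 0.25 &
                        forward$es > 0, ]
le_union <- leading_edge_union(vs_control)
message("leading-edge union: ", length(le_union), " genes from ",
        nrow(vs_control), " enrichment results")
writeLines(c("gene_id", le_union), "results/enrichment/leading_edge_union.tsv")

le_tab <- enrich_pathways(le_union, pathways, universe)
write.table(le_tab, "results/enrichment/leading_edge_pathways.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("top pathways for the leading-edge union:")
print(head(le_tab[, c("pathway", "overlap", "p_value", "q_value")], 5))

# top-k overlap between the two systems
mouse_de <- read.delim("results/de/mouse_de.tsv")
degs <- filter_degs(mouse_de, fc_min = 2, q_max = 0.05)
names(degs) <- as.character(sort(unique(mouse_de$time_days)))
clinical <- build_clinical_union_sets(
  split(human_de, human_de$contrast), fc_min = 1.5, q_max = 0.05)
mouse_tab <- significant_pathways(enrich_pathways(degs[["14"]]$up, pathways,
                                                  universe))
human_tab <- significant_pathways(enrich_pathways(clinical$up, pathways,
                                                  universe))
k <- min(25, nrow(mouse_tab), nrow(human_tab))
ov <- if (k > 0) topk_overlap(mouse_tab, human_tab, k) else
  list(count = 0, shared = character(0))
message("top-", k, " significant pathway overlap between day-14 mouse and ",
        "clinical up-DEGs: ", ov$count,
        if (ov$count) paste0(" (", paste(ov$shared, collapse = ", "), ")") else "")
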