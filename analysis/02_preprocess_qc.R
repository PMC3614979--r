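#!/usr/bin/env Rscript
# Stage 2 — preprocessing and quality control.
#
# Collapses probes to genes by maximum variance (the synthetic data is
# already gene-level, so the collapse runs with an identity probe map),
# maps mouse genes onto their human orthologs, and screens for outlier
# arrays with the PCA robust-z rule. The cleaned mouse study is written
# under results/processed/.

library(phasesig)

mouse <- load_expression("results/data/mouse_expression.tsv",
                         "results/data/mouse_annotations.tsv")
omap <- read_gene_map("results/data/ortholog_map.tsv")

probe_map <- data.frame(source = rownames(mouse$values),
                        target = rownames(mouse$values))
mouse <- collapse_probes_by_variance(mouse, probe_map)
mouse <- map_orthologs(mouse, omap)
message("after ortholog mapping: ", nrow(mouse$values), " genes")

flagged <- flag_outlier_samples(mouse, n_components = 2, threshold = 4)
message("PCA outlier screen flagged: ",
        if (length(flagged)) paste(flagged, collapse = ", ") else "none")
if (length(flagged))
  mouse <- subset_samples(mouse, setdiff(colnames(mouse$values), flagged))

dir.create("results/processed", showWarnings = FALSE, recursive = TRUE)
write_expression(mouse, "results/processed/mouse_expression.tsv",
                 "results/processed/mouse_annotations.tsv")
writeLines(c("sample_id", flagged), "results/processed/dropped_samples.tsv")
message("kept ", ncol(mouse$values), " mouse samples")
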