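#!/usr/bin/env Rscript
# Stage 4 — phase signatures and clustering.
#
# Builds one up-regulated signature per time point, takes per-phase unions
# and intersections (inflammation days 1-2, active fibrosis days 7-14,
# late fibrosis days 21-35), and clusters the DEG union across all mouse
# samples with correlation distance and average linkage.

library(phasesig)

mouse <- load_expression("results/processed/mouse_expression.tsv",
                         "results/processed/mouse_annotations.tsv")
mouse_de <- read.delim("results/de/mouse_de.tsv")
dir.create("results/signatures", showWarnings = FALSE, recursive = TRUE)

degs <- filter_degs(mouse_de, fc_min = 2, q_max = 0.05)
names(degs) <- as.character(sort(unique(mouse_de$time_days)))

signatures <- build_timepoint_signatures(degs, direction = "up")
write_gmt(signatures, "results/signatures/signatures_up.gmt")
message("signature sets: ", paste(names(signatures), collapse = ", "))

both <- lapply(degs, function(s) sort(unique(c(s$up, s$down))))
phases <- phase_union_intersection(both, default_phases())
for (ph in names(phases))
  message(ph, ": union ", length(phases[[ph]]$union), " genes, intersection ",
          length(phases[[ph]]$intersection))

union_genes <- sort(unique(unlist(both)))
cl <- hierarchical_cluster(mouse, union_genes, mode = "unsupervised", k = 3)
write_clustered_matrix(mouse, cl, "results/signatures/deg_union_clustered.tsv")
as_newick(cl$gene_tree, "results/signatures/deg_union_gene_tree.nwk")
message("clustered ", length(union_genes), " DEG-union genes into ",
        length(unique(cl$gene_clusters)), " flat clusters")

# supervised view (genes clustered, samples ordered by arm and day)
sup <- hierarchical_cluster(mouse, union_genes, mode = "supervised", k = 3)
write_clustered_matrix(mouse, sup, "results/signatures/deg_union_supervised.tsv")
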