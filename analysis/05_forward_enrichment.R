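#!/usr/bin/env Rscript
# Stage 5 — forward enrichment: mouse signatures in the clinical contrasts.
#
# Runs the weighted running-sum enrichment of each per-day bleomycin
# signature against the composite-ranked clinical lists, with a
# gene-permutation null (1000 draws), NES, nominal p, across-set FDR and
# leading edges. Exports the masked heatmap (p < 0.05 and FDR < 0.25).

library(phasesig)

SEED <- 1
signatures <- read_gmt("results/signatures/signatures_up.gmt")
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)

gp <- gsea_params(n_permutations = 1000, seed = SEED)
forward <- list()
for (nm in c("ipf_vs_control", "exac_vs_control", "exac_vs_stable")) {
  ranked <- read_rnk(sprintf("results/de/ranked_%s.rnk", nm))
  res <- run_gsea(ranked, signatures, gp)
  forward[[nm]] <- cbind(contrast = nm, res)
  sig <- res[res$p_value < 0.05 & res$q_value < 0.25 & res$es > 0, "set"]
  message(nm, ": positively enriched at p<0.05, FDR<0.25: ",
          if (length(sig)) paste(sig, collapse = ", ") else "none")
}
forward <- do.call(rbind, forward)
write_enrichment_report(forward, "results/enrichment/forward_enrichment.tsv")

png_path <- if (requireNamespace("pheatmap", quietly = TRUE))
  "results/enrichment/forward_enrichment_heatmap.png" else NULL
export_enrichment_heatmap(forward,
                          "results/enrichment/forward_enrichment_heatmap.tsv",
                          png_path, p_max = 0.05, q_max = 0.25)
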