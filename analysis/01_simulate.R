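#!/usr/bin/env Rscript
# Stage 1 — simulate the study materials.
#
# Generates the synthetic mouse bleomycin time course (2 arms x 7 days x
# n = 8, one planted outlier array), the human IPF cohort
# (control / stable / exacerbation), the mouse-to-human ortholog map and a
# synthetic canonical-pathway collection, and writes everything under
# results/data/.

library(phasesig)

SEED <- 1
params <- sim_params(seed = SEED)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

mouse <- generate_mouse_timecourse(params)
human <- generate_human_cohort(params)
omap <- generate_ortholog_map(params)
pathways <- generate_pathway_collection(params)

write_expression(mouse$study, "results/data/mouse_expression.tsv",
                 "results/data/mouse_annotations.tsv")
write_expression(human$study, "results/data/human_expression.tsv",
                 "results/data/human_annotations.tsv")
write_gene_map(omap, "results/data/ortholog_map.tsv")
write_gmt(pathways, "results/data/pathways.gmt")
write_truth(mouse$truth, "results/data")

message("mouse study: ", nrow(mouse$study$values), " genes x ",
        ncol(mouse$study$values), " samples; planted outlier = ",
        mouse$truth$outlier_sample_id)
message("human cohort: ", ncol(human$study$values), " samples (",
        paste(capture.output(print(table(human$study$annotations$group))),
              collapse = " "), ")")
message("ortholog map: ", nrow(omap), " pairs; pathway collection: ",
        length(pathways), " sets")
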