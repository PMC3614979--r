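#' Configuration for a full synthetic pipeline run
#'
#' Collects everything a pipeline run depends on: simulation parameters,
#' DEG thresholds per species, enrichment parameters, phase definition and
#' heatmap masking thresholds. All randomness fans out deterministically
#' from `seed`.
#'
#' @param seed Top-level integer seed.
#' @param sim A [sim_params()] object (defaults to `sim_params(seed = seed)`).
#' @param gsea A [gsea_params()] object (defaults to
#'   `gsea_params(seed = seed)`).
#' @param mouse_fc_min,clinical_fc_min Fold-change thresholds (2 for the
#'   mouse arm, 1.5 for clinical contrasts).
#' @param q_max Strict DEG q threshold (0.05, both species).
#' @param phases Phase definition, see [default_phases()].
#' @param heatmap_p_max,heatmap_q_max Masking thresholds for the enrichment
#'   heatmap (nominal p < 0.05 and FDR q < 0.25).
#' @param n_random_pathways,random_pathway_size Synthetic canonical-pathway
#'   collection shape (see [generate_pathway_collection()]).
#' @param outlier_threshold Robust z cutoff for the PCA sample screen.
#' @return Object of class `RunConfig`.
#' @export
run_config <- function(seed = 1,
                       sim = sim_params(seed = seed),
                       gsea = gsea_params(seed = seed),
                       mouse_fc_min = 2, clinical_fc_min = 1.5, q_max = 0.05,
                       phases = default_phases(),
                       heatmap_p_max = 0.05, heatmap_q_max = 0.25,
                       n_random_pathways = 30, random_pathway_size = 50,
                       outlier_threshold = 4) {
  stopifnot(inherits(sim, "SimulationParams"), inherits(gsea, "GseaParams"),
            mouse_fc_min > 0, clinical_fc_min > 0, q_max > 0)
  structure(list(seed = as.integer(seed), sim = sim, gsea = gsea,
                 mouse_fc_min = mouse_fc_min,
                 clinical_fc_min = clinical_fc_min, q_max = q_max,
                 phases = phases, heatmap_p_max = heatmap_p_max,
                 heatmap_q_max = heatmap_q_max,
                 n_random_pathways = n_random_pathways,
                 random_pathway_size = random_pathway_size,
                 outlier_threshold = outlier_threshold),
            class = "RunConfig")
}

#' Mask an enrichment score matrix at significance thresholds
#'
#' Cells failing (nominal p < `p_max` AND FDR q < `q_max`) are set to 0;
#' passing cells keep their signed score, so positive values mark sets
#' enriched in cases ("red" channel) and negative values sets enriched in
#' controls ("blue" channel).
#'
#' @param es,p,q Numeric matrices of identical shape (sets x contrasts).
#' @param p_max,q_max Strict thresholds (defaults 0.05 and 0.25).
#' @return The masked numeric matrix.
#' @export
mask_enrichment_scores <- function(es, p, q, p_max = 0.05, q_max = 0.25) {
  stopifnot(all(dim(es) == dim(p)), all(dim(es) == dim(q)))
  out <- es
  out[!(p < p_max & q < q_max)] <- 0
  out
}

#' Export a masked enrichment heatmap
#'
#' Reshapes a stacked enrichment table (several contrasts) into a sets x
#' contrasts score matrix, masks it at the significance thresholds, writes
#' the numeric matrix as TSV and optionally renders a red/blue heatmap
#' through pheatmap.
#'
#' @param results Data frame with columns `set`, `contrast`, `es` (or
#'   `nes`), `p_value`, `q_value`.
#' @param path_tsv Output TSV path for the masked matrix.
#' @param path_png Optional PNG path; rendered only if the pheatmap package
#'   is available.
#' @param score Which score fills the cells, `"es"` (default) or `"nes"`.
#' @param p_max,q_max Masking thresholds (defaults 0.05 and 0.25).
#' @return Invisibly, the masked matrix.
#' @export
export_enrichment_heatmap <- function(results, path_tsv, path_png = NULL,
                                      score = c("es", "nes"),
                                      p_max = 0.05, q_max = 0.25) {
  score <- match.arg(score)
  sets <- unique(results$set)
  contrasts <- unique(results$contrast)
  shape <- function(col) {
    m <- matrix(NA_real_, length(sets), length(contrasts),
                dimnames = list(sets, contrasts))
    m[cbind(match(results$set, sets), match(results$contrast, contrasts))] <-
      results[[col]]
    m
  }
  masked <- mask_enrichment_scores(shape(score), shape("p_value"),
                                   shape("q_value"), p_max, q_max)
  out <- data.frame(set = rownames(masked), masked, check.names = FALSE)
  utils::write.table(out, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_png) && requireNamespace("pheatmap", quietly = TRUE)) {
    lim <- max(abs(masked), 1e-9)
    pheatmap::pheatmap(masked, cluster_rows = FALSE, cluster_cols = FALSE,
                       breaks = seq(-lim, lim, length.out = 101),
                       color = grDevices::colorRampPalette(
                         c("blue", "white", "red"))(100),
                       filename = path_png)
  }
  invisible(masked)
}

#' Run the full synthetic translational pipeline
#'
#' Executes every stage in order: simulate mouse and human studies ->
#' probe collapse (identity at gene level) -> ortholog mapping -> PCA
#' outlier screen -> per-time-point mouse contrasts -> DEG signatures,
#' phase unions and clustering -> forward enrichment of the mouse
#' signatures in the human contrasts -> leading-edge union -> hypergeometric
#' pathway enrichment and top-k overlap -> clinical union sets ->
#' back-translation onto the mouse time course -> masked heatmap exports.
#' Every stage result is written as TSV/GMT/RNK under `out_dir`, along with
#' a machine-readable `manifest.json` (seeds, thresholds, cardinalities,
#' dropped samples/sets). Re-running with the same config yields
#' byte-identical outputs.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with all intermediate objects (`mouse`,
#'   `human`, `mouse_de`, `signatures`, `forward`, `pathway_tables`, ...).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  manifest <- list(seed = config$seed,
                   thresholds = list(mouse_fc_min = config$mouse_fc_min,
                                     clinical_fc_min = config$clinical_fc_min,
                                     q_max = config$q_max,
                                     heatmap_p_max = config$heatmap_p_max,
                                     heatmap_q_max = config$heatmap_q_max),
                   gsea = unclass(config$gsea),
                   sim = unclass(config$sim),
                   stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message("[", name, "] ", paste(names(list(...)), unlist(list(...)),
                                   sep = "=", collapse = " "))
  }

  # -- simulate ---------------------------------------------------------
  mouse <- generate_mouse_timecourse(config$sim)
  human <- generate_human_cohort(config$sim)
  omap <- generate_ortholog_map(config$sim)
  write_expression(mouse$study, pth("mouse_expression.tsv"),
                   pth("mouse_annotations.tsv"))
  write_expression(human$study, pth("human_expression.tsv"),
                   pth("human_annotations.tsv"))
  write_gene_map(omap, pth("ortholog_map.tsv"))
  write_truth(mouse$truth, out_dir)
  log_stage("simulate", mouse_genes = nrow(mouse$study$values),
            mouse_samples = ncol(mouse$study$values),
            human_samples = ncol(human$study$values))

  # -- collapse + ortholog mapping --------------------------------------
  probe_map <- data.frame(source = rownames(mouse$study$values),
                          target = rownames(mouse$study$values))
  mouse_study <- collapse_probes_by_variance(mouse$study, probe_map)
  mouse_study <- map_orthologs(mouse_study, omap)
  log_stage("map_orthologs", genes_mapped = nrow(mouse_study$values))

  # -- outlier QC -------------------------------------------------------
  flagged <- flag_outlier_samples(mouse_study, threshold = config$outlier_threshold)
  if (length(flagged))
    mouse_study <- subset_samples(mouse_study,
                                  setdiff(colnames(mouse_study$values), flagged))
  writeLines(c("sample_id", flagged), pth("dropped_samples.tsv"))
  log_stage("qc_outliers", flagged = length(flagged),
            samples_kept = ncol(mouse_study$values))

  # -- mouse differential expression ------------------------------------
  mouse_de <- fit_contrasts(mouse_study, "bleomycin", "saline")
  utils::write.table(mouse_de, pth("mouse_de.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  deg_sets <- filter_degs(mouse_de, fc_min = config$mouse_fc_min,
                          q_max = config$q_max)
  days <- sort(unique(mouse_de$time_days))
  names(deg_sets) <- as.character(days)
  both_by_day <- lapply(deg_sets, function(s) sort(unique(c(s$up, s$down))))
  mouse_union <- sort(unique(unlist(both_by_day)))
  writeLines(c("gene_id", mouse_union), pth("mouse_deg_union.tsv"))
  log_stage("mouse_de", contrasts = length(days),
            deg_union = length(mouse_union))

  # -- signatures, phases, clustering -----------------------------------
  signatures <- build_timepoint_signatures(deg_sets, direction = "up")
  write_gmt(signatures, pth("signatures_up.gmt"))
  phase_sets <- phase_union_intersection(both_by_day, config$phases)
  phase_rows <- lapply(names(phase_sets), function(ph) {
    data.frame(phase = ph,
               union_size = length(phase_sets[[ph]]$union),
               intersection_size = length(phase_sets[[ph]]$intersection),
               union = paste(phase_sets[[ph]]$union, collapse = ","),
               intersection = paste(phase_sets[[ph]]$intersection, collapse = ","))
  })
  utils::write.table(do.call(rbind, phase_rows), pth("phase_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clustering <- NULL
  if (length(mouse_union) >= 2) {
    clustering <- hierarchical_cluster(mouse_study, mouse_union,
                                       mode = "unsupervised")
    write_clustered_matrix(mouse_study, clustering, pth("deg_union_clustered.tsv"))
    as_newick(clustering$gene_tree, pth("deg_union_gene_tree.nwk"))
  }
  log_stage("signatures", n_sets = length(signatures),
            phases = length(phase_sets))

  # -- human differential expression + ranked lists ---------------------
  contrast_pairs <- list(ipf_vs_control = c("stable", "control"),
                         exac_vs_control = c("exacerbation", "control"),
                         exac_vs_stable = c("exacerbation", "stable"))
  grp <- human$study$annotations$group
  contrast_pairs <- Filter(function(pr) all(pr %in% grp), contrast_pairs)
  human_de <- list()
  ranked <- list()
  for (nm in names(contrast_pairs)) {
    pr <- contrast_pairs[[nm]]
    de <- fit_contrasts(human$study, pr[1], pr[2], time_col = NULL)
    de$contrast <- nm
    human_de[[nm]] <- de
    ranked[[nm]] <- composite_rank(de)
    write_rnk(ranked[[nm]], pth(paste0("ranked_", nm, ".rnk")))
  }
  utils::write.table(do.call(rbind, human_de), pth("human_de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("human_de", contrasts = length(human_de))

  # -- forward enrichment (mouse signatures in human contrasts) ---------
  forward <- lapply(names(ranked), function(nm) {
    res <- run_gsea(ranked[[nm]], signatures, config$gsea)
    cbind(contrast = nm, res)
  })
  forward <- do.call(rbind, forward)
  write_enrichment_report(forward, pth("forward_enrichment.tsv"))
  export_enrichment_heatmap(forward, pth("forward_enrichment_heatmap.tsv"),
                            p_max = config$heatmap_p_max,
                            q_max = config$heatmap_q_max)
  log_stage("forward_gsea", results = nrow(forward),
            enriched = sum(forward$p_value < config$heatmap_p_max &
                             forward$q_value < config$heatmap_q_max &
                             forward$es > 0))

  # -- leading-edge union + pathway enrichment --------------------------
  vs_control <- forward[forward$contrast %in%
                          c("ipf_vs_control", "exac_vs_control") &
                          forward$p_value < config$heatmap_p_max &
                          forward$q_value < config$heatmap_q_max &
                          forward$es > 0, , drop = FALSE]
  le_union <- leading_edge_union(vs_control)
  writeLines(c("gene_id", le_union), pth("leading_edge_union.tsv"))
  pathways <- generate_pathway_collection(config$sim,
                                          n_random = config$n_random_pathways,
                                          size_random = config$random_pathway_size)
  write_gmt(pathways, pth("pathways.gmt"))
  universe <- names(ranked[[1]])
  le_pathways <- enrich_pathways(le_union, pathways, universe)
  utils::write.table(le_pathways, pth("leading_edge_pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("pathway_enrichment", le_union = length(le_union),
            pathways_tested = nrow(le_pathways))

  # -- top-k overlap between systems (day-14 mouse vs clinical) ---------
  day14 <- if ("14" %in% names(deg_sets)) deg_sets[["14"]]$up else character(0)
  clinical_sets <- build_clinical_union_sets(human_de,
                                             fc_min = config$clinical_fc_min,
                                             q_max = config$q_max)
  mouse_pw <- enrich_pathways(day14, pathways, universe)
  human_pw <- enrich_pathways(clinical_sets$up, pathways, universe)
  utils::write.table(mouse_pw, pth("mouse_day14_pathways.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(human_pw, pth("clinical_up_pathways.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  k_cmp <- min(25, nrow(significant_pathways(mouse_pw)),
               nrow(significant_pathways(human_pw)))
  overlap <- if (k_cmp > 0) {
    topk_overlap(significant_pathways(mouse_pw),
                 significant_pathways(human_pw), k = k_cmp)
  } else list(count = 0L, shared = character(0))
  log_stage("topk_overlap", k = k_cmp, shared = overlap$count)

  # -- back-translation -------------------------------------------------
  # the mouse study was ortholog-mapped upstream, so its ranked lists and
  # the clinical union sets already share the human ID space
  mouse_ranked <- lapply(split(mouse_de, mouse_de$time_days), composite_rank)
  backtrans <- back_translate(clinical_sets, mouse_ranked, config$gsea)
  write_enrichment_report(backtrans, pth("back_translation.tsv"))
  bt <- cbind(contrast = paste0("day_", backtrans$time_days), backtrans)
  export_enrichment_heatmap(bt, pth("back_translation_heatmap.tsv"),
                            p_max = config$heatmap_p_max,
                            q_max = config$heatmap_q_max)
  log_stage("back_translation",
            up_set = length(clinical_sets$up),
            down_set = length(clinical_sets$down),
            results = nrow(backtrans))

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(config = config, mouse = mouse, human = human,
                 ortholog_map = omap, mouse_study = mouse_study,
                 flagged_samples = flagged, mouse_de = mouse_de,
                 deg_sets = deg_sets, mouse_union = mouse_union,
                 signatures = signatures, phase_sets = phase_sets,
                 clustering = clustering, human_de = human_de,
                 ranked = ranked, forward = forward, le_union = le_union,
                 pathways = pathways, le_pathways = le_pathways,
                 mouse_pathways = mouse_pw, clinical_pathways = human_pw,
                 overlap = overlap, clinical_sets = clinical_sets,
                 back_translation = backtrans))
}
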