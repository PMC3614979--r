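#' Union DEG sets across clinical comparisons
#'
#' Derives the clinical signature pair: per-direction unions of DEGs
#' (default 1.5-fold, q < 0.05) across several case/control comparisons. A
#' gene that is up-regulated in one comparison and down-regulated in
#' another is kept in both unions (one message per run reports how many).
#'
#' @param de_tables A [fit_contrasts()] table spanning one or more
#'   contrasts, or a list of such tables.
#' @param fc_min,q_max DEG thresholds (defaults 1.5 and 0.05; fold change
#'   inclusive, q strict).
#' @param drop_conflicts If `TRUE`, genes with conflicting directions are
#'   removed from both unions instead.
#' @return List with sorted character vectors `up` and `down`; a warning is
#'   emitted when both are empty.
#' @export
build_clinical_union_sets <- function(de_tables, fc_min = 1.5, q_max = 0.05,
                                      drop_conflicts = FALSE) {
  if (is.data.frame(de_tables)) de_tables <- list(de_tables)
  if (length(de_tables) == 0) stop("need at least one comparison", call. = FALSE)
  up <- character(0)
  down <- character(0)
  for (de in de_tables) {
    sets <- filter_degs(de, fc_min = fc_min, q_max = q_max)
    if (!is.null(sets$up)) sets <- list(sets)  # single contrast
    for (s in sets) {
      up <- union(up, s$up)
      down <- union(down, s$down)
    }
  }
  conflicted <- intersect(up, down)
  if (length(conflicted)) {
    message("build_clinical_union_sets: ", length(conflicted),
            " gene(s) up in one comparison and down in another",
            if (drop_conflicts) " (dropped)" else " (kept in both unions)")
    if (drop_conflicts) {
      up <- setdiff(up, conflicted)
      down <- setdiff(down, conflicted)
    }
  }
  if (length(up) + length(down) == 0)
    warning("no gene passed the clinical DEG thresholds", call. = FALSE)
  list(up = sort(up), down = sort(down))
}

#' Back-translate clinical signatures onto the mouse time course
#'
#' Runs set enrichment of the clinical up/down union sets against the
#' composite-ranked mouse bleomycin-vs-saline list of every time point —
#' the reverse of the forward mouse-to-human analysis. Sets falling below
#' the minimum size after intersection with a ranked list are skipped with
#' a warning.
#'
#' @param union_sets List with `up` and/or `down` character vectors (mouse
#'   ID space; map with [map_gene_sets()] first if needed).
#' @param mouse_ranked Named list of ranked lists (one per time point, names
#'   like `"7"`), each from [composite_rank()].
#' @param params A [gsea_params()] object.
#' @return Combined [run_gsea()] data frame with a leading `time_days`
#'   column; up to `2 x length(mouse_ranked)` rows.
#' @export
back_translate <- function(union_sets, mouse_ranked, params = gsea_params()) {
  sets <- Filter(length, union_sets[intersect(c("up", "down"), names(union_sets))])
  if (length(sets) == 0) stop("both union sets are empty", call. = FALSE)
  names(sets) <- paste0("clinical_", names(sets))
  out <- lapply(names(mouse_ranked), function(day) {
    scores <- mouse_ranked[[day]]
    keep <- vapply(sets, function(s) {
      sz <- length(intersect(s, names(scores)))
      sz >= params$min_set_size && sz < length(scores)
    }, logical(1))
    if (any(!keep))
      warning("day ", day, ": set(s) below min_set_size skipped: ",
              paste(names(sets)[!keep], collapse = ", "), call. = FALSE)
    if (!any(keep)) return(NULL)
    res <- run_gsea(scores, sets[keep], params)
    cbind(time_days = as.integer(day), res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
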