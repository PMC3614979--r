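#' Default response phases of the bleomycin time course
#'
#' Inflammation (days 1-2), active fibrosis (days 7-14) and late fibrosis
#' (days 21-35): the three temporal phases of the transcriptional response
#' to a single bleomycin challenge.
#'
#' @return Named list mapping phase label to a vector of days.
#' @export
default_phases <- function() {
  list(inflammation = c(1, 2),
       active_fibrosis = c(7, 14),
       late_fibrosis = c(21, 28, 35))
}

#' Build per-time-point signature gene sets
#'
#' Turns per-time-point DEG sets into a named gene-set collection, one set
#' per time point and direction. Sets that are empty at a time point are
#' omitted with a warning.
#'
#' @param deg_sets Named list, one element per time point (names are days,
#'   e.g. `"7"`), each a list with `up` and `down` character vectors (as
#'   returned by [filter_degs()] per contrast).
#' @param direction `"up"`, `"down"` or `"both"` (default `"up"`, the
#'   convention for forward enrichment of bleomycin-induced genes).
#' @param prefix Name prefix for the sets (default `"bleo"`).
#' @return Named list of character vectors; names are
#'   `<prefix>_d<day>_<direction>` and carry a `time_days` attribute giving
#'   each set's day.
#' @export
build_timepoint_signatures <- function(deg_sets, direction = c("up", "down", "both"),
                                       prefix = "bleo") {
  direction <- match.arg(direction)
  dirs <- if (direction == "both") c("up", "down") else direction
  sets <- list()
  days <- integer(0)
  for (day in names(deg_sets)) {
    for (d in dirs) {
      members <- unique(deg_sets[[day]][[d]])
      nm <- sprintf("%s_d%02d_%s", prefix, as.integer(day), d)
      if (length(members) == 0) {
        warning("empty ", d, "-regulated DEG set at day ", day,
                "; signature omitted", call. = FALSE)
        next
      }
      sets[[nm]] <- members
      days <- c(days, as.integer(day))
    }
  }
  attr(sets, "time_days") <- days
  sets
}

#' Per-phase union and intersection of time-point sets
#'
#' @param sets_by_day Named list of gene vectors, names the day (e.g. `"7"`).
#' @param phases Named list mapping phase label to days; phases must be
#'   disjoint over time points. Defaults to [default_phases()].
#' @return Named list per phase, each a list with `union` and
#'   `intersection` (sorted character vectors). Phase days with no set are
#'   skipped with a warning.
#' @export
phase_union_intersection <- function(sets_by_day, phases = default_phases()) {
  all_days <- unlist(phases)
  if (anyDuplicated(all_days))
    stop("phases must be disjoint over time points", call. = FALSE)
  out <- list()
  for (ph in names(phases)) {
    avail <- intersect(as.character(phases[[ph]]), names(sets_by_day))
    missing <- setdiff(as.character(phases[[ph]]), names(sets_by_day))
    if (length(missing))
      warning("phase ", ph, ": no gene set at day(s) ",
              paste(missing, collapse = ", "), call. = FALSE)
    if (length(avail) == 0) next
    member_lists <- sets_by_day[avail]
    out[[ph]] <- list(union = sort(unique(unlist(member_lists))),
                      intersection = sort(Reduce(intersect, member_lists)))
  }
  out
}

# Correlation distance between rows of x after per-row standardization.
# Zero-variance rows get distance 1 to everything (correlation defined as 0).
.cor_dist_rows <- function(x) {
  z <- x - rowMeans(x)
  sdv <- sqrt(rowSums(z^2))
  zero <- sdv == 0
  if (any(zero)) {
    message(sum(zero), " zero-variance row(s): correlation distance set to 1")
    sdv[zero] <- 1
  }
  z <- z / sdv
  co <- tcrossprod(z)
  co[zero, ] <- 0
  co[, zero] <- 0
  d <- 1 - co
  diag(d) <- 0
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Hierarchical clustering of an expression signature
#'
#' Clusters genes (and, in unsupervised mode, samples) of a study restricted
#' to a gene set, using one minus the Pearson correlation of the per-gene
#' standardized profiles as distance and average linkage — the standard
#' convention for expression heatmaps. Flat gene clusters are obtained by
#' cutting the gene tree into `k` groups (default 3, matching the three
#' temporal response phases).
#'
#' @param study An [expression_study()].
#' @param genes Character vector of genes to cluster (>= 2 present in the
#'   study).
#' @param mode `"unsupervised"` clusters genes and samples; `"supervised"`
#'   clusters genes only and orders samples by (group, time, sample ID).
#' @param k Number of flat gene clusters (default 3).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List with `gene_tree` (hclust), `gene_order`, `gene_clusters`
#'   (named integer vector from [stats::cutree()]), `sample_tree` (hclust or
#'   NULL), and `sample_order`.
#' @export
hierarchical_cluster <- function(study, genes,
                                 mode = c("unsupervised", "supervised"),
                                 k = 3, linkage = "average") {
  stopifnot(inherits(study, "ExpressionStudy"))
  mode <- match.arg(mode)
  genes <- intersect(genes, rownames(study$values))
  if (length(genes) < 2) stop("need >= 2 genes present in the study", call. = FALSE)
  if (ncol(study$values) < 2) stop("need >= 2 samples", call. = FALSE)
  x <- study$values[genes, , drop = FALSE]
  gene_tree <- stats::hclust(.cor_dist_rows(x), method = linkage)
  gene_clusters <- stats::cutree(gene_tree, k = min(k, length(genes)))
  sample_tree <- NULL
  if (mode == "unsupervised") {
    z <- t(scale(t(x)))      # standardize each gene profile
    z[is.na(z)] <- 0         # zero-variance genes contribute nothing
    sample_tree <- stats::hclust(.cor_dist_rows(t(z)), method = linkage)
    sample_order <- colnames(x)[sample_tree$order]
  } else {
    ann <- study$annotations
    tcol <- if ("time_days" %in% names(ann)) ann$time_days else 0
    sample_order <- ann$sample_id[order(ann$group, tcol, ann$sample_id)]
  }
  list(gene_tree = gene_tree,
       gene_order = genes[gene_tree$order],
       gene_clusters = gene_clusters,
       sample_tree = sample_tree,
       sample_order = sample_order)
}

#' Export a dendrogram as a Newick string
#'
#' @param tree An `hclust` object.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly if `path` given).
#' @export
as_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a clustered matrix with leaf order
#'
#' Writes the study values restricted to the clustering's genes and ordered
#' by the gene/sample leaf orders, with the flat cluster label as a column —
#' a plot-ready TSV.
#'
#' @param study An [expression_study()].
#' @param clustering Result of [hierarchical_cluster()].
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_clustered_matrix <- function(study, clustering, path) {
  x <- study$values[clustering$gene_order, clustering$sample_order, drop = FALSE]
  out <- data.frame(gene_id = rownames(x),
                    cluster = clustering$gene_clusters[rownames(x)],
                    x, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read / write gene-set collections in GMT format
#'
#' GMT: one set per line, `name<TAB>description<TAB>member1<TAB>member2...`.
#' Reading goes through [fgsea::gmtPathways()]; descriptions are not
#' retained (written back as `"na"`).
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
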