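#' Union of leading-edge genes across enrichment analyses
#'
#' @param results A [run_gsea()] result data frame, or a list of them (one
#'   per analysis). All leading-edge columns are pooled.
#' @return Sorted character vector of distinct leading-edge genes; empty
#'   with a warning when every leading edge is empty.
#' @export
leading_edge_union <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  if (length(results) == 0) stop("need at least one analysis", call. = FALSE)
  genes <- unlist(lapply(results, function(r) {
    unlist(strsplit(r$leading_edge[nzchar(r$leading_edge)], ",", fixed = TRUE))
  }), use.names = FALSE)
  if (length(genes) == 0) {
    warning("all leading edges are empty", call. = FALSE)
    return(character(0))
  }
  sort(unique(genes))
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance that a random
#' query of `n` genes from a universe of `N` overlaps a pathway of `K` genes
#' in at least `k` members. Computed through [stats::phyper()], which works
#' on log probabilities internally and is stable for large `N`.
#'
#' @param k Observed overlap.
#' @param n Query size.
#' @param K Pathway size within the universe.
#' @param N Universe size.
#' @return The p-value in `(0, 1]`.
#' @export
hypergeom_p <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 1 || k > min(n, K) || n > N || K > N)
    stop("invalid hypergeometric bounds: k=", k, " n=", n, " K=", K, " N=", N,
         call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric pathway over-representation
#'
#' Tests each pathway for over-representation of the query set within the
#' universe. Query genes outside the universe are dropped with a warning;
#' pathway memberships are intersected with the universe. Duplicate pathway
#' names collapse to their first entry.
#'
#' @param query Character vector of genes (e.g. a leading-edge union).
#' @param pathways Named list of character vectors.
#' @param universe Character vector of all testable genes (non-empty).
#' @return Data frame sorted by p ascending (ties: larger overlap, then
#'   name): `pathway`, `overlap` (k), `query_size` (n), `pathway_size` (K),
#'   `universe_size` (N), `p_value`, `q_value` (BH across pathways),
#'   `overlap_genes` (comma-joined).
#' @export
enrich_pathways <- function(query, pathways, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  dropped <- setdiff(query, universe)
  if (length(dropped))
    warning(length(dropped), " query gene(s) outside the universe dropped",
            call. = FALSE)
  query <- intersect(unique(query), universe)
  pathways <- pathways[!duplicated(names(pathways))]
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(pathways[[nm]]), universe)
    ov <- intersect(query, pw)
    data.frame(pathway = nm, overlap = length(ov),
               query_size = length(query), pathway_size = length(pw),
               universe_size = length(universe),
               p_value = if (length(pw)) hypergeom_p(length(ov), length(query),
                                                     length(pw), length(universe))
                         else 1,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- adjust_bh(out$p_value)
  out <- out[order(out$p_value, -out$overlap, out$pathway, method = "radix"), ]
  rownames(out) <- NULL
  out[, c("pathway", "overlap", "query_size", "pathway_size", "universe_size",
          "p_value", "q_value", "overlap_genes")]
}

#' Filter to significantly enriched pathways
#'
#' Applies the conventional significance filter (p < 0.05 and FDR < 0.05)
#' before a top-k comparison.
#'
#' @param table An [enrich_pathways()] table.
#' @param p_max,q_max Strict thresholds (defaults 0.05 / 0.05).
#' @return The filtered table (original order preserved).
#' @export
significant_pathways <- function(table, p_max = 0.05, q_max = 0.05) {
  table[table$p_value < p_max & table$q_value < q_max, , drop = FALSE]
}

#' Top-k pathway overlap between two systems
#'
#' Counts the pathways shared between the top `k` rows of two enrichment
#' tables (already sorted by their documented order, typically best p
#' first). Tables shorter than `k` are truncated with a warning.
#'
#' @param table_a,table_b [enrich_pathways()] tables (or any data frames
#'   with a `pathway` column in ranked order).
#' @param k Number of top pathways to compare (default 25).
#' @return List with `count` and `shared` (sorted pathway names).
#' @export
topk_overlap <- function(table_a, table_b, k = 25) {
  take <- function(tab, label) {
    if (nrow(tab) < k)
      warning(label, " has only ", nrow(tab), " rows; truncating k",
              call. = FALSE)
    utils::head(tab$pathway, k)
  }
  shared <- sort(intersect(take(table_a, "table_a"), take(table_b, "table_b")))
  list(count = length(shared), shared = shared)
}
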