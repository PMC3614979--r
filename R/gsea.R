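#' Parameters for set-enrichment analysis
#'
#' @param weight_exponent Exponent `p >= 0` on `|score|` when weighting hit
#'   increments (default 1, the weighted statistic; 0 gives the classic
#'   unweighted Kolmogorov-Smirnov-style statistic).
#' @param n_permutations Gene permutations per null (default 1000; at least
#'   100, required for a usable FDR estimate).
#' @param seed Integer seed for the permutation null.
#' @param min_set_size,max_set_size Size bounds applied after intersecting
#'   each set with the ranked list (defaults 5 and 500).
#' @return Object of class `GseaParams`.
#' @export
gsea_params <- function(weight_exponent = 1, n_permutations = 1000, seed = 1,
                        min_set_size = 5, max_set_size = 500) {
  p <- list(weight_exponent = weight_exponent,
            n_permutations = as.integer(n_permutations),
            seed = as.integer(seed),
            min_set_size = as.integer(min_set_size),
            max_set_size = as.integer(max_set_size))
  if (p$weight_exponent < 0) stop("weight_exponent must be >= 0", call. = FALSE)
  if (p$n_permutations < 100)
    stop("n_permutations must be >= 100 for FDR estimation", call. = FALSE)
  if (p$min_set_size <= 0 || p$max_set_size < p$min_set_size)
    stop("invalid set size bounds", call. = FALSE)
  class(p) <- "GseaParams"
  p
}

# The ranked-list contract: a named numeric vector with unique names and
# non-increasing scores (ties in value are permitted; the *order* of the
# vector is the ranking).
.check_ranked <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("ranked list must have unique gene names", call. = FALSE)
  if (is.unsorted(-scores))
    stop("ranked list scores must be non-increasing; rank with composite_rank()",
         call. = FALSE)
  invisible(scores)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list accumulating `P_hit(i)`, the `|score|^p`-weighted
#' fraction of set members seen so far, against `P_miss(i)`, the fraction of
#' non-members seen so far. The enrichment score is the deviation
#' `P_hit - P_miss` of maximum absolute value, signed; when a positive and a
#' negative extreme tie in magnitude, the one at the earlier rank position
#' is taken.
#'
#' @param scores Ranked list: named numeric vector, non-increasing.
#' @param set Character vector of member genes; members absent from the
#'   ranked list are dropped first. After dropping, the set must be
#'   non-empty and not the whole list.
#' @param weight_exponent Hit-weight exponent `p` (default 1).
#' @return List with `es` (in `[-1, 1]`), `peak_index` (rank position of the
#'   extreme), `running` (the full deviation profile), and `hit_index`
#'   (positions of set members).
#' @export
running_es <- function(scores, set, weight_exponent = 1) {
  .check_ranked(scores)
  n <- length(scores)
  hits <- names(scores) %in% set
  m <- sum(hits)
  if (m == 0 || m == n)
    stop("degenerate set: ", m, " of ", n, " ranked genes are members",
         call. = FALSE)
  wh <- abs(scores)^weight_exponent * hits
  w_total <- sum(wh)
  if (w_total == 0)
    stop("degenerate weights: all hit scores are zero at weight_exponent > 0",
         call. = FALSE)
  dev <- cumsum(wh) / w_total - cumsum(!hits) / (n - m)
  peak <- as.integer(which.max(abs(dev)))
  list(es = dev[[peak]], peak_index = peak, running = unname(dev),
       hit_index = which(hits))
}

# Enrichment score from sorted hit positions only (O(m) instead of O(N)).
# The deviation profile rises only at hits and falls linearly between them,
# so its maxima sit immediately after a hit and its minima immediately
# before one; evaluating those candidates reproduces running_es bit for bit
# (adding zero weight between hits leaves the long-double cumsum
# accumulator unchanged). Used for the permutation null.
.es_from_positions <- function(pos, w_all, n) {
  m <- length(pos)
  nm <- n - m
  wh <- unname(w_all[pos])
  w_total <- sum(wh)
  if (w_total == 0) return(list(es = 0, peak_index = pos[1]))
  j <- seq_len(m)
  cum <- cumsum(wh) / w_total
  dev_after <- cum - (pos - j) / nm        # deviation at position pos_j
  dev_before <- c(0, cum[-m]) - (pos - j) / nm  # at position pos_j - 1
  i_max <- which.max(dev_after)
  i_min <- which.min(dev_before)
  hi <- dev_after[i_max]
  lo <- dev_before[i_min]
  if (abs(hi) > abs(lo)) {
    list(es = hi, peak_index = pos[i_max])
  } else if (abs(lo) > abs(hi)) {
    list(es = lo, peak_index = pos[i_min] - 1L)
  } else {
    # magnitude tie between a positive and a negative extreme: earlier rank
    if (pos[i_max] <= pos[i_min] - 1L) list(es = hi, peak_index = pos[i_max])
    else list(es = lo, peak_index = pos[i_min] - 1L)
  }
}

#' Gene-permutation null distribution of the enrichment score
#'
#' Draws `n_permutations` uniform random gene subsets of the given size
#' (without replacement) from the ranked list and computes each one's
#' enrichment score with the same weight exponent — the gene-permutation
#' null against which observed scores are calibrated.
#'
#' @param scores Ranked list (named numeric, non-increasing).
#' @param set_size Size of the random sets; must be `< length(scores)`.
#' @param params A [gsea_params()] object (permutation count, seed, weight).
#' @return Numeric vector of null enrichment scores, reproducible given the
#'   seed.
#' @export
permutation_null <- function(scores, set_size, params = gsea_params()) {
  .check_ranked(scores)
  n <- length(scores)
  if (set_size >= n || set_size < 1)
    stop("set_size must be in [1, ", n - 1, "]", call. = FALSE)
  w_all <- abs(scores)^params$weight_exponent
  set.seed(.stage_seed(params$seed, set_size))
  vapply(seq_len(params$n_permutations), function(b) {
    pos <- sort.int(sample.int(n, set_size))
    .es_from_positions(pos, w_all, n)$es
  }, numeric(1))
}

#' Normalized enrichment score and nominal p from a null sample
#'
#' Same-sign convention: a non-negative observed ES is compared against the
#' non-negative null values only, `p = (1 + #\{null >= ES\}) / (1 + #null)`
#' (the plus-one estimator, so p is never 0), and `NES = ES / mean` of those
#' null values; symmetrically (on absolute values) for a negative ES.
#'
#' @param es_obs Observed enrichment score.
#' @param null_es Numeric vector of null enrichment scores (non-empty).
#' @return List with `nes`, `p_value`, and `flagged` (TRUE when no same-sign
#'   null values exist, in which case `nes` is NA and p is 1).
#' @export
enrichment_stats <- function(es_obs, null_es) {
  if (length(null_es) == 0) stop("empty null sample", call. = FALSE)
  same <- if (es_obs >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same) == 0)
    return(list(nes = NA_real_, p_value = 1, flagged = TRUE))
  p <- (1 + sum(abs(same) >= abs(es_obs))) / (1 + length(same))
  nes <- sign(es_obs) * abs(es_obs) / mean(abs(same))
  list(nes = nes, p_value = p, flagged = FALSE)
}

# Normalize a null ES sample to null NES values using its own same-sign
# means (the same means that normalize the observed ES of that set size).
.null_nes <- function(null_es) {
  pos <- null_es >= 0
  out <- numeric(length(null_es))
  if (any(pos)) out[pos] <- null_es[pos] / mean(null_es[pos])
  if (any(!pos)) out[!pos] <- -(abs(null_es[!pos]) / mean(abs(null_es[!pos])))
  out
}

#' Across-set FDR from pooled permutation NES values
#'
#' For each observed NES\*, q is the ratio of (fraction of pooled same-sign
#' null NES values at least as extreme as NES\*) to (fraction of observed
#' same-sign NES values at least as extreme), clipped to `[0, 1]` and made
#' monotone non-increasing in `|NES|` within each sign.
#'
#' @param nes_obs Numeric vector of observed NES values (one per set).
#' @param null_nes Pooled numeric vector of null NES values (non-empty).
#' @return Numeric vector of q-values aligned with `nes_obs`.
#' @export
fdr_across_sets <- function(nes_obs, null_nes) {
  if (length(null_nes) == 0) stop("empty pooled null", call. = FALSE)
  if (length(nes_obs) == 0) return(numeric(0))
  q <- vapply(nes_obs, function(v) {
    if (is.na(v)) return(NA_real_)
    same_null <- if (v >= 0) null_nes[null_nes >= 0] else null_nes[null_nes < 0]
    same_obs <- if (v >= 0) nes_obs[nes_obs >= 0] else nes_obs[nes_obs < 0]
    if (length(same_null) == 0) return(1)
    num <- mean(abs(same_null) >= abs(v))
    den <- mean(abs(same_obs) >= abs(v), na.rm = TRUE)
    min(1, max(0, num / den))
  }, numeric(1))
  # enforce monotonicity: within each sign, a more extreme NES never gets a
  # larger q than a less extreme one (step-up: each set takes the minimum
  # ratio over itself and all less extreme sets)
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes_obs) & (if (sgn > 0) nes_obs >= 0 else nes_obs < 0))
    if (length(idx) > 1) {
      ord <- idx[order(-abs(nes_obs[idx]))]
      q[ord] <- rev(cummin(rev(q[ord])))
    }
  }
  q
}

#' Leading-edge genes of an enrichment result
#'
#' For a positive enrichment score, the set members at ranks up to and
#' including the running-sum peak; for a negative score, the members at
#' ranks at or after the peak. Order follows the ranked list.
#'
#' @param scores Ranked list used for the enrichment.
#' @param set Member genes.
#' @param peak_index,es Peak position and score from [running_es()].
#' @return Character vector of leading-edge genes.
#' @export
leading_edge <- function(scores, set, peak_index, es) {
  nm <- names(scores)
  idx <- if (es >= 0) seq_len(peak_index) else peak_index:length(scores)
  nm[idx][nm[idx] %in% set]
}

#' Run set enrichment over a collection
#'
#' Intersects each set with the ranked list, applies the size filters,
#' computes the weighted running-sum enrichment score, a gene-permutation
#' null shared across sets of equal size, the normalized score, nominal p,
#' across-set FDR, and the leading edge.
#'
#' @param scores Ranked list (named numeric, non-increasing), e.g. from
#'   [composite_rank()].
#' @param collection Named list of character vectors.
#' @param params A [gsea_params()] object.
#' @return Data frame with one row per retained set: `set`, `size`, `es`,
#'   `nes`, `p_value`, `q_value`, `peak_rank`, `direction` (`"top"` /
#'   `"bottom"`), `leading_edge` (comma-joined), `leading_edge_size`.
#'   Dropped sets are reported via `message()`.
#' @export
run_gsea <- function(scores, collection, params = gsea_params()) {
  .check_ranked(scores)
  stopifnot(inherits(params, "GseaParams"))
  if (length(collection) == 0 || is.null(names(collection)))
    stop("collection must be a non-empty named list", call. = FALSE)
  sizes <- vapply(collection, function(s)
    length(intersect(unique(s), names(scores))), integer(1))
  keep <- sizes >= params$min_set_size & sizes <= params$max_set_size &
    sizes < length(scores)
  if (any(!keep))
    message("run_gsea: dropped ", sum(!keep), " set(s) by size filter: ",
            paste(names(collection)[!keep], collapse = ", "))
  if (!any(keep)) stop("no sets retained after size filtering", call. = FALSE)
  collection <- collection[keep]
  sizes <- sizes[keep]

  nulls <- lapply(unique(sizes), function(sz)
    permutation_null(scores, sz, params))
  names(nulls) <- as.character(unique(sizes))

  rows <- lapply(seq_along(collection), function(i) {
    res <- running_es(scores, collection[[i]], params$weight_exponent)
    null_es <- nulls[[as.character(sizes[i])]]
    st <- enrichment_stats(res$es, null_es)
    le <- leading_edge(scores, collection[[i]], res$peak_index, res$es)
    data.frame(set = names(collection)[i], size = sizes[[i]],
               es = res$es, nes = st$nes, p_value = st$p_value,
               q_value = NA_real_, peak_rank = res$peak_index,
               direction = if (res$es >= 0) "top" else "bottom",
               leading_edge = paste(le, collapse = ","),
               leading_edge_size = length(le),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled <- unlist(lapply(as.character(sizes), function(sz)
    .null_nes(nulls[[sz]])), use.names = FALSE)
  out$q_value <- fdr_across_sets(out$nes, pooled)
  rownames(out) <- NULL
  out
}

#' Write an enrichment report TSV
#'
#' @param results Data frame from [run_gsea()] (possibly with extra
#'   columns, e.g. the contrast).
#' @param path Output path.
#' @return Invisibly, `results`.
#' @export
write_enrichment_report <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(results)
}
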