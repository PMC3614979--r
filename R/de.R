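#' Per-gene treatment contrasts with ANOVA pooled variance
#'
#' Fits, per gene, a two-way fixed-effects cell-means model (treatment x
#' time, with interaction) on the log2 values and tests the
#' treatment-vs-reference contrast at each time point with a t statistic on
#' the pooled residual variance (residual df = samples - cells). For a
#' single-factor two-group design (`time_col = NULL`) this reduces exactly
#' to the pooled two-sample t-test. `variance = "within"` instead pools only
#' the two cells of each contrast (a per-time-point two-sample t-test).
#'
#' @param study An [expression_study()].
#' @param treatment,reference Levels of `group_col` to contrast; `log2_fc`
#'   is treatment minus reference.
#' @param group_col Annotation column holding the arm/cohort label (default
#'   `"group"`).
#' @param time_col Annotation column holding the time point, or `NULL` for a
#'   single two-group contrast.
#' @param variance `"pooled"` (residual variance across all design cells) or
#'   `"within"` (only the two cells under contrast).
#' @return Data frame with one row per gene and contrast: `gene`, `contrast`,
#'   `time_days` (NA for two-group designs), `log2_fc`, `fold_change`
#'   (`2^|log2_fc|`), `direction` (`"up"`/`"down"`), `p_value`, `q_value`
#'   (Benjamini-Hochberg within contrast), `mean_treatment`,
#'   `mean_reference`, `n_treatment`, `n_reference`.
#' @details Degenerate genes with zero residual variance get p = 1 when the
#'   contrast is 0 and p = 0 otherwise; a message reports how many occurred.
#'   Two-sided p-values throughout.
#' @export
fit_contrasts <- function(study, treatment, reference, group_col = "group",
                          time_col = "time_days",
                          variance = c("pooled", "within")) {
  stopifnot(inherits(study, "ExpressionStudy"))
  variance <- match.arg(variance)
  ann <- study$annotations
  if (!group_col %in% names(ann))
    stop("annotation column not found: ", group_col, call. = FALSE)
  if (!is.null(time_col) && !time_col %in% names(ann))
    stop("annotation column not found: ", time_col, call. = FALSE)
  grp <- ann[[group_col]]
  if (!all(c(treatment, reference) %in% grp))
    stop("treatment/reference levels absent from ", group_col, call. = FALSE)

  keep <- grp %in% c(treatment, reference)
  x <- study$values[, keep, drop = FALSE]
  grp <- grp[keep]
  tim <- if (is.null(time_col)) rep(NA_integer_, sum(keep)) else ann[[time_col]][keep]
  cell <- if (is.null(time_col)) factor(grp) else
    interaction(grp, tim, drop = TRUE, lex.order = TRUE)
  tab <- table(cell)
  if (any(tab < 2))
    stop("design cells with < 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)

  # per-gene cell means and pooled residual variance, fully vectorized
  ind <- stats::model.matrix(~ 0 + cell)
  counts <- stats::setNames(colSums(ind), levels(cell))
  means <- x %*% ind %*% diag(1 / counts, length(counts))
  colnames(means) <- levels(cell)
  resid2 <- rowSums((x - means[, as.integer(cell), drop = FALSE])^2)

  times <- if (is.null(time_col)) NA_integer_ else sort(unique(tim))
  out <- vector("list", length(times))
  degenerate <- 0L
  for (ti in seq_along(times)) {
    tt <- times[ti]
    lev_t <- if (is.null(time_col)) treatment else paste(treatment, tt, sep = ".")
    lev_r <- if (is.null(time_col)) reference else paste(reference, tt, sep = ".")
    n1 <- counts[[lev_t]]; n2 <- counts[[lev_r]]
    d <- means[, lev_t] - means[, lev_r]
    if (variance == "pooled") {
      df <- ncol(x) - nlevels(cell)
      s2 <- resid2 / df
    } else {
      in_cells <- cell %in% c(lev_t, lev_r)
      sub <- x[, in_cells, drop = FALSE]
      subcell <- droplevels(cell[in_cells])
      df <- sum(in_cells) - 2L
      s2 <- rowSums((sub - means[, levels(subcell), drop = FALSE][
        , as.integer(subcell), drop = FALSE])^2) / df
    }
    if (df <= 0) stop("zero residual degrees of freedom", call. = FALSE)
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    tstat <- d / se
    p <- 2 * stats::pt(-abs(tstat), df)
    zero_var <- s2 == 0
    if (any(zero_var)) {
      degenerate <- degenerate + sum(zero_var)
      p[zero_var] <- ifelse(d[zero_var] == 0, 1, 0)
    }
    contrast <- if (is.null(time_col)) {
      paste0(treatment, "_vs_", reference)
    } else {
      sprintf("%s_vs_%s_d%02d", treatment, reference, tt)
    }
    out[[ti]] <- data.frame(gene = rownames(x), contrast = contrast,
                            time_days = tt, log2_fc = unname(d),
                            fold_change = 2^abs(unname(d)),
                            direction = ifelse(d >= 0, "up", "down"),
                            p_value = unname(p),
                            q_value = adjust_bh(unname(p)),
                            mean_treatment = unname(means[, lev_t]),
                            mean_reference = unname(means[, lev_r]),
                            n_treatment = n1, n_reference = n2,
                            stringsAsFactors = FALSE)
  }
  if (degenerate > 0)
    message("fit_contrasts: ", degenerate,
            " gene x contrast cell(s) with zero residual variance ",
            "(p set to 0/1 by contrast value)")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate control, applied within one
#' contrast at a time. Thin wrapper around [stats::p.adjust()] so the
#' adjustment used across the package is defined in exactly one place.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (may be empty).
#' @return Vector of q-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Filter differentially expressed genes
#'
#' Retains genes with `fold_change >= fc_min` (inclusive, "at least
#' fc_min-fold") and `q_value < q_max` (strict), split by direction of
#' change. Thresholds of 2-fold / q < 0.05 are conventional for the mouse
#' arm; 1.5-fold / q < 0.05 for clinical contrasts.
#'
#' @param de A [fit_contrasts()] table (one or several contrasts).
#' @param fc_min Minimum linear fold change, inclusive (default 2).
#' @param q_max Strict upper bound on the BH q-value (default 0.05).
#' @return If `de` holds one contrast, a list with character vectors `up`
#'   and `down`; otherwise a named list of such lists, one per contrast (in
#'   order of first appearance).
#' @export
filter_degs <- function(de, fc_min = 2, q_max = 0.05) {
  stopifnot(fc_min > 0, q_max > 0)
  split_one <- function(d) {
    hit <- d$fold_change >= fc_min & d$q_value < q_max
    list(up = d$gene[hit & d$direction == "up"],
         down = d$gene[hit & d$direction == "down"])
  }
  contrasts <- unique(de$contrast)
  if (length(contrasts) == 1) return(split_one(de))
  sets <- lapply(contrasts, function(ct) split_one(de[de$contrast == ct, ]))
  names(sets) <- contrasts
  sets
}

#' Composite fold-change/FDR ranking of one contrast
#'
#' Each gene scores `sign(log2_fc) * -log10(max(q, q_floor))`, where
#' `q_floor` is the smallest nonzero q-value in the contrast divided by 10
#' (so q = 0 stays finite). Genes are ordered by score descending, then
#' `|log2_fc|` descending, then gene ID ascending — a strict total order, as
#' the enrichment engine requires.
#'
#' @param de A [fit_contrasts()] table restricted to a single contrast.
#' @return Named numeric vector of scores, ordered by the documented total
#'   order (scores non-increasing).
#' @export
composite_rank <- function(de) {
  if (length(unique(de$contrast)) != 1)
    stop("composite_rank expects exactly one contrast; got ",
         length(unique(de$contrast)), call. = FALSE)
  if (anyDuplicated(de$gene))
    stop("duplicate genes in contrast table", call. = FALSE)
  nz <- de$q_value[de$q_value > 0]
  q_floor <- if (length(nz)) min(nz) / 10 else 1e-300
  s <- sign(de$log2_fc) * -log10(pmax(de$q_value, q_floor))
  ord <- order(-s, -abs(de$log2_fc), de$gene, method = "radix")
  stats::setNames(s[ord], de$gene[ord])
}

#' Read / write ranked lists in RNK format
#'
#' RNK is the two-column tab-separated interchange format (gene, score), no
#' header, ordered by score.
#'
#' @param ranked Named numeric vector as produced by [composite_rank()].
#' @param path File path.
#' @return `write_rnk` invisibly returns `ranked`; `read_rnk` returns the
#'   named vector in file order.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(data.frame(names(ranked), sprintf("%.17g", ranked)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ranked)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  d <- utils::read.delim(path, header = FALSE, colClasses = c("character", "numeric"))
  stats::setNames(d[[2]], d[[1]])
}
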