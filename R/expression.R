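#' Construct an expression study
#'
#' An `ExpressionStudy` bundles a log2 expression matrix (genes in rows,
#' samples in columns) with a per-sample annotation table. It is the common
#' container passed between preprocessing, differential expression and
#' enrichment stages.
#'
#' @param values Numeric matrix of log2 intensities with unique rownames
#'   (gene or probe IDs) and unique colnames (sample IDs). All values must be
#'   finite.
#' @param annotations Data frame with one row per sample. Must contain a
#'   `sample_id` column covering every column of `values`; typical additional
#'   columns are `group` (arm or cohort) and `time_days`.
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `values` and `annotations` (reordered to match the sample order of
#'   `values`).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ann <- data.frame(sample_id = c("s1", "s2"), group = c("a", "b"))
#' study <- expression_study(m, ann)
#' @export
expression_study <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("non-finite expression values at ",
         sum(!is.finite(values)), " cell(s)", call. = FALSE)
  if (!is.data.frame(annotations) || !"sample_id" %in% names(annotations))
    stop("`annotations` must be a data.frame with a sample_id column", call. = FALSE)
  missing_ann <- setdiff(colnames(values), annotations$sample_id)
  if (length(missing_ann))
    stop("samples missing from annotations: ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(values = values, annotations = annotations),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("annotation columns:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' Expects a tab-separated matrix whose first column is `gene_id` and whose
#' header names the samples, plus an annotation TSV with a `sample_id`
#' column. Input is assumed to be on the log2 scale; apparently linear-scale
#' matrices are rejected unless `linear = TRUE`, in which case values are
#' floored at 1.0 and log2-transformed.
#'
#' @param matrix_path Path to the expression TSV.
#' @param annotation_path Path to the sample annotation TSV.
#' @param linear If `TRUE`, treat input as linear intensities and take
#'   `log2(pmax(x, 1))`.
#' @return An [expression_study()].
#' @export
load_expression <- function(matrix_path, annotation_path, linear = FALSE) {
  if (!file.exists(matrix_path))
    stop("expression matrix file not found: ", matrix_path, call. = FALSE)
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path, call. = FALSE)
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2 || names(raw)[1] != "gene_id")
    stop("matrix TSV must start with a gene_id column", call. = FALSE)
  genes <- raw[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene IDs in ", matrix_path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value '%s' at gene %s, sample %s",
                 vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  ann <- utils::read.delim(annotation_path, check.names = FALSE)
  if (linear) {
    num <- log2(pmax(num, 1))
  } else if (max(num) > 30) {
    stop("matrix looks linear-scale (max value ", round(max(num), 1),
         " > 30); pass linear = TRUE to log2-transform", call. = FALSE)
  }
  expression_study(num, ann)
}

#' Write an expression study to TSV files
#'
#' Values are serialized with 17 significant digits so that
#' `load_expression(write_expression(study))` round-trips to full double
#' precision.
#'
#' @param study An [expression_study()].
#' @param matrix_path,annotation_path Output paths.
#' @return Invisibly, the study.
#' @export
write_expression <- function(study, matrix_path, annotation_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  vals <- study$values
  chr <- matrix(sprintf("%.17g", vals), nrow = nrow(vals))
  out <- data.frame(gene_id = rownames(vals), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("gene_id", colnames(vals))
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$annotations, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(study)
}

# Validate a two-column gene map (probe->gene or mouse->human ortholog).
# Each source may appear at most once; extra columns (e.g. a collision flag)
# are preserved.
validate_gene_map <- function(map) {
  if (!is.data.frame(map) || !all(c("source", "target") %in% names(map)))
    stop("gene map must be a data.frame with source and target columns",
         call. = FALSE)
  if (anyDuplicated(map$source))
    stop("gene map has duplicated source genes: ",
         paste(unique(map$source[duplicated(map$source)]), collapse = ", "),
         call. = FALSE)
  map
}

#' Read / write a two-column gene map TSV
#'
#' @param path File path. The file has a header `source<TAB>target`.
#' @return A data.frame with columns `source` and `target`.
#' @export
read_gene_map <- function(path) {
  validate_gene_map(utils::read.delim(path, check.names = FALSE,
                                      colClasses = "character"))
}

#' @rdname read_gene_map
#' @param map A validated gene map data.frame.
#' @export
write_gene_map <- function(map, path) {
  utils::write.table(validate_gene_map(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(map)
}

# Pick, per target gene, the source row of maximal variance across samples.
# Ties are broken toward the lexicographically smallest source ID so the
# result is deterministic. Returns the retained matrix with rows renamed to
# targets and sorted by target ID.
.collapse_max_variance <- function(values, map) {
  map <- map[map$source %in% rownames(values), , drop = FALSE]
  if (nrow(map) == 0)
    return(values[integer(0), , drop = FALSE])
  v <- apply(values[map$source, , drop = FALSE], 1, stats::var)
  # order by target, then variance (descending), then source ID: the first
  # row per target is the winner under the documented tie-break
  ord <- order(map$target, -v[map$source], map$source, method = "radix")
  map <- map[ord, , drop = FALSE]
  keep <- map[!duplicated(map$target), , drop = FALSE]
  out <- values[keep$source, , drop = FALSE]
  rownames(out) <- keep$target
  out[order(rownames(out)), , drop = FALSE]
}

#' Collapse probes to genes by maximum variance
#'
#' For each gene, the row of its maximum-variance probe (variance taken
#' across all samples) is retained verbatim; remaining probes are dropped.
#' Variance ties are broken toward the lexicographically smallest probe ID.
#' Probes without a mapping, and genes with no mapped probe, are silently
#' absent from the output. Output rows are sorted by gene ID.
#'
#' @param study Probe-level [expression_study()].
#' @param probe2gene Data frame with columns `source` (probe) and `target`
#'   (gene); each probe appears at most once.
#' @return Gene-level `ExpressionStudy`.
#' @export
collapse_probes_by_variance <- function(study, probe2gene) {
  stopifnot(inherits(study, "ExpressionStudy"))
  probe2gene <- validate_gene_map(probe2gene)
  out <- .collapse_max_variance(study$values, probe2gene)
  study$values <- out
  study
}

#' Map study genes to orthologs
#'
#' Rows are renamed from source-species to target-species gene IDs. Source
#' genes without a mapping are dropped. When several source genes map to one
#' target, the maximum-variance source row is retained (same rule and
#' tie-break as [collapse_probes_by_variance()]).
#'
#' @param study An [expression_study()] keyed by source-species IDs.
#' @param map Ortholog map data.frame with columns `source`, `target`.
#' @return `ExpressionStudy` keyed by target-species IDs, rows sorted by ID.
#' @export
map_orthologs <- function(study, map) {
  collapse_probes_by_variance(study, map)
}

#' Map gene sets through an ortholog map
#'
#' @param sets Named list of character vectors (source-species IDs).
#' @param map Ortholog map data.frame (`source`, `target`).
#' @return Named list with members translated to target IDs (unmapped genes
#'   dropped, duplicates removed, order preserved by first occurrence).
#' @export
map_gene_sets <- function(sets, map) {
  map <- validate_gene_map(map)
  lut <- stats::setNames(map$target, map$source)
  lapply(sets, function(g) unique(unname(lut[g[g %in% names(lut)]])))
}

#' Flag outlier samples by PCA
#'
#' Principal components are computed over samples (genes centred); a sample
#' is flagged when its score on any of the first `n_components` components
#' lies more than `threshold` robust z-units (median/MAD across samples) from
#' the centre. This mirrors the PCA screen used to drop aberrant arrays
#' before differential expression.
#'
#' @param study An [expression_study()] with at least 3 samples.
#' @param n_components Number of leading components to screen (default 2).
#' @param threshold Robust z cutoff (default 4).
#' @return Sorted character vector of flagged sample IDs (possibly empty).
#' @export
flag_outlier_samples <- function(study, n_components = 2, threshold = 4) {
  stopifnot(inherits(study, "ExpressionStudy"))
  x <- t(study$values)
  if (nrow(x) < 3)
    stop("outlier screening needs at least 3 samples", call. = FALSE)
  if (all(apply(x, 2, stats::var) == 0))
    return(character(0))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  flagged <- rep(FALSE, nrow(x))
  for (j in seq_len(k)) {
    s <- pc$x[, j]
    md <- stats::mad(s)
    if (md == 0) next
    flagged <- flagged | abs(s - stats::median(s)) / md > threshold
  }
  sort(rownames(x)[flagged])
}

#' Drop genes below a background expression percentile
#'
#' Optional background filter: genes whose mean log2 expression falls below
#' the given percentile of all gene means are removed. No default claim is
#' made about any particular platform's background level; the cutoff is
#' entirely user-chosen.
#'
#' @param study An [expression_study()].
#' @param percentile Percentile of gene mean expression in `[0, 100)` below
#'   which genes are dropped.
#' @return Filtered `ExpressionStudy`.
#' @export
filter_low_expression <- function(study, percentile) {
  stopifnot(inherits(study, "ExpressionStudy"),
            percentile >= 0, percentile < 100)
  mu <- rowMeans(study$values)
  cut <- stats::quantile(mu, percentile / 100)
  study$values <- study$values[mu >= cut, , drop = FALSE]
  study
}

#' Subset a study by samples
#'
#' @param study An [expression_study()].
#' @param sample_ids Character vector of samples to keep (order preserved as
#'   given).
#' @return `ExpressionStudy` restricted to those samples.
#' @export
subset_samples <- function(study, sample_ids) {
  stopifnot(inherits(study, "ExpressionStudy"))
  missing <- setdiff(sample_ids, colnames(study$values))
  if (length(missing))
    stop("unknown samples: ", paste(missing, collapse = ", "), call. = FALSE)
  expression_study(study$values[, sample_ids, drop = FALSE], study$annotations)
}
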