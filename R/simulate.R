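#' Simulation parameters for synthetic studies
#'
#' Defines the study conditions for the synthetic mouse bleomycin time course
#' and human IPF cohort: a 2-arm x 7-time-point mouse design (n = 8 per
#' group, one planted outlier array) and a human cohort with control,
#' stable-IPF and exacerbation-IPF groups. Three gene programs are planted:
#' `inflammation` (shifted in the bleomycin arm at days 1-2 only),
#' `active_fibrosis` (shifted at days 7-14, decaying at days 21-35, and
#' shifted in both human IPF groups, more strongly under exacerbation) and
#' `late_fibrosis` (shifted at days 21-35 only, not shifted in humans).
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_per_group Mouse replicates per arm x time-point cell (default 8).
#' @param time_points_days Mouse sampling days (default 1, 2, 7, 14, 21, 28,
#'   35).
#' @param human_group_sizes Named counts for `control`, `stable`,
#'   `exacerbation` (defaults 10/10/8, typical clinical cohort sizes).
#' @param program_sizes Named gene counts for `inflammation`,
#'   `active_fibrosis`, `late_fibrosis` (default 100 each); programs are
#'   disjoint.
#' @param effect_size Planted log2 shift per program in its active condition
#'   (default 1.5, comfortably above the 2-fold DEG threshold at n = 8).
#' @param exacerbation_multiplier Factor applied to `effect_size` for the
#'   active-fibrosis program in the exacerbation group (default 1.75; must be
#'   > 1 so the exacerbation shift is strictly larger than the stable shift).
#' @param late_decay Multiplier on the active-fibrosis shift during days
#'   21-35 (default 0.4, a moderate residual up-regulation in the late
#'   phase).
#' @param noise_sd Gaussian noise SD on the log2 scale (default 0.5).
#' @param baseline_mean,baseline_sd Per-gene baseline intensities are drawn
#'   once per study from N(baseline_mean, baseline_sd) on the log2 scale
#'   (defaults 7 and 1.5, typical of RMA-normalized arrays).
#' @param outlier_shift Log2 shift added to the designated outlier sample
#'   (default 6) on a random `outlier_gene_fraction` of genes (default 0.5).
#'   Set `outlier_shift = 0` to disable the outlier.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   studies.
#' @return A validated object of class `SimulationParams`.
#' @export
sim_params <- function(n_genes = 2000,
                       n_per_group = 8,
                       time_points_days = c(1, 2, 7, 14, 21, 28, 35),
                       human_group_sizes = c(control = 10, stable = 10,
                                             exacerbation = 8),
                       program_sizes = c(inflammation = 100,
                                         active_fibrosis = 100,
                                         late_fibrosis = 100),
                       effect_size = 1.5,
                       exacerbation_multiplier = 1.75,
                       late_decay = 0.4,
                       noise_sd = 0.5,
                       baseline_mean = 7,
                       baseline_sd = 1.5,
                       outlier_shift = 6,
                       outlier_gene_fraction = 0.5,
                       seed = 1) {
  p <- list(n_genes = as.integer(n_genes),
            n_per_group = as.integer(n_per_group),
            time_points_days = as.integer(time_points_days),
            human_group_sizes = human_group_sizes,
            program_sizes = program_sizes,
            effect_size = effect_size,
            exacerbation_multiplier = exacerbation_multiplier,
            late_decay = late_decay,
            noise_sd = noise_sd,
            baseline_mean = baseline_mean,
            baseline_sd = baseline_sd,
            outlier_shift = outlier_shift,
            outlier_gene_fraction = outlier_gene_fraction,
            seed = as.integer(seed))
  if (p$n_genes <= 0 || p$n_per_group <= 0)
    stop("n_genes and n_per_group must be positive", call. = FALSE)
  if (length(p$time_points_days) < 1 || anyDuplicated(p$time_points_days))
    stop("time_points_days must be non-empty and distinct", call. = FALSE)
  req <- c("control", "stable", "exacerbation")
  if (!all(req %in% names(p$human_group_sizes)) ||
      any(p$human_group_sizes < 0))
    stop("human_group_sizes needs non-negative control/stable/exacerbation",
         call. = FALSE)
  if (!all(names(p$program_sizes) %in%
           c("inflammation", "active_fibrosis", "late_fibrosis")) ||
      any(p$program_sizes < 0))
    stop("program_sizes must name inflammation/active_fibrosis/late_fibrosis",
         call. = FALSE)
  if (sum(p$program_sizes) > p$n_genes)
    stop("program sizes sum (", sum(p$program_sizes),
         ") exceeds n_genes (", p$n_genes, ")", call. = FALSE)
  if (p$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (p$exacerbation_multiplier <= 1)
    stop("exacerbation_multiplier must be > 1", call. = FALSE)
  class(p) <- "SimulationParams"
  p
}

# Deterministic fan-out of the top-level seed to independent stages.
.stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647L)
}

# Gene programs are assigned to seeded, disjoint index blocks; membership is
# shared between the mouse and human studies via the index (ortholog) pairing.
.assign_programs <- function(params) {
  set.seed(.stage_seed(params$seed, 7))
  idx <- sample.int(params$n_genes)
  membership <- rep("none", params$n_genes)
  at <- 0
  for (prog in names(params$program_sizes)) {
    sz <- params$program_sizes[[prog]]
    if (sz > 0) membership[idx[at + seq_len(sz)]] <- prog
    at <- at + sz
  }
  membership
}

.gene_ids <- function(n, prefix) sprintf("%s_g%05d", prefix, seq_len(n))

# Phase of a mouse time point: days <= 2 inflammation, days 3-20 active
# fibrosis, days > 20 late fibrosis.
.phase_of_day <- function(day) {
  ifelse(day <= 2, "inflammation", ifelse(day <= 20, "active", "late"))
}

# Planted log2 shift for one (program, arm, day) cell of the mouse design.
.mouse_shift <- function(program, arm, day, params) {
  if (arm != "bleomycin" || program == "none") return(0)
  phase <- .phase_of_day(day)
  e <- params$effect_size
  if (program == "inflammation" && phase == "inflammation") return(e)
  if (program == "active_fibrosis" && phase == "active") return(e)
  if (program == "active_fibrosis" && phase == "late") return(e * params$late_decay)
  if (program == "late_fibrosis" && phase == "late") return(e)
  0
}

.human_shift <- function(program, cohort, params) {
  if (program != "active_fibrosis" || cohort == "control") return(0)
  if (cohort == "stable") return(params$effect_size)
  params$effect_size * params$exacerbation_multiplier
}

#' Generate a synthetic mouse bleomycin time course
#'
#' Simulates a 2-arm (bleomycin vs saline) x time-point design with
#' `n_per_group` replicates per cell. Per-gene baselines are drawn once;
#' noise is i.i.d. Gaussian on the log2 scale. Program genes receive their
#' phase-dependent planted shifts in the bleomycin arm only, and exactly one
#' sample (first saline replicate at day 14, or the first sample if day 14 is
#' absent) is perturbed by `outlier_shift` on a random half of the genes.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `study` (an [expression_study()], genes
#'   `mmu_g*`) and `truth` (a `SyntheticTruth` list: `program_membership`
#'   data.frame, `shifts` data.frame of every nonzero planted shift,
#'   `outlier_sample_id`, `outlier_genes`).
#' @export
generate_mouse_timecourse <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  membership <- .assign_programs(params)
  genes <- .gene_ids(params$n_genes, "mmu")
  arms <- c("bleomycin", "saline")
  days <- params$time_points_days
  n <- params$n_per_group
  ann <- expand.grid(replicate = seq_len(n), time_days = days, group = arms,
                     stringsAsFactors = FALSE)
  ann$sample_id <- sprintf("%s_d%02d_r%d", substr(ann$group, 1, 4),
                           ann$time_days, ann$replicate)
  ann <- ann[, c("sample_id", "group", "time_days")]

  set.seed(.stage_seed(params$seed, 1))
  baseline <- stats::rnorm(params$n_genes, params$baseline_mean,
                           params$baseline_sd)
  shift_mat <- matrix(0, params$n_genes, nrow(ann))
  for (j in seq_len(nrow(ann))) {
    for (prog in names(params$program_sizes)) {
      s <- .mouse_shift(prog, ann$group[j], ann$time_days[j], params)
      if (s != 0) shift_mat[membership == prog, j] <- s
    }
  }
  vals <- baseline + shift_mat +
    matrix(stats::rnorm(params$n_genes * nrow(ann), 0, params$noise_sd),
           params$n_genes, nrow(ann))

  outlier_id <- NA_character_
  outlier_genes <- character(0)
  if (params$outlier_shift != 0) {
    cand <- which(ann$group == "saline" & ann$time_days == 14)
    j <- if (length(cand)) cand[1] else 1L
    outlier_id <- ann$sample_id[j]
    pick <- sample.int(params$n_genes,
                       round(params$outlier_gene_fraction * params$n_genes))
    vals[pick, j] <- vals[pick, j] + params$outlier_shift
    outlier_genes <- genes[sort(pick)]
  }
  dimnames(vals) <- list(genes, ann$sample_id)

  shifts <- expand.grid(program = setdiff(unique(membership), "none"),
                        group = arms, time_days = days,
                        stringsAsFactors = FALSE)
  shifts$shift <- if (nrow(shifts)) {
    mapply(function(p, a, d) .mouse_shift(p, a, d, params),
           shifts$program, shifts$group, shifts$time_days)
  } else numeric(0)
  truth <- list(program_membership = data.frame(gene = genes,
                                                program = membership,
                                                stringsAsFactors = FALSE),
                shifts = shifts[shifts$shift != 0, , drop = FALSE],
                outlier_sample_id = outlier_id,
                outlier_genes = outlier_genes)
  list(study = expression_study(vals, ann), truth = truth)
}

#' Generate a synthetic human IPF cohort
#'
#' Simulates control, stable-IPF and exacerbation-IPF groups. The
#' active-fibrosis program is shifted upward in both IPF groups relative to
#' control, with a strictly larger shift in the exacerbation group; the
#' inflammation and late-fibrosis programs are not shifted in any human
#' group. Gene index i of the human study is the ortholog partner of mouse
#' gene index i, so planted program membership carries across species.
#'
#' @param params A [sim_params()] object.
#' @return A list with `study` (genes `hsa_g*`; annotation column `group`
#'   holds the cohort) and `truth` (as in [generate_mouse_timecourse()], with
#'   per-cohort shifts and no outlier).
#' @export
generate_human_cohort <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  membership <- .assign_programs(params)
  genes <- .gene_ids(params$n_genes, "hsa")
  sizes <- params$human_group_sizes
  cohorts <- c("control", "stable", "exacerbation")
  grp <- rep(cohorts, times = sizes[cohorts])
  if (length(grp) == 0) stop("all human group sizes are zero", call. = FALSE)
  ann <- data.frame(sample_id = sprintf("%s_s%02d", substr(grp, 1, 4),
                                        unlist(lapply(sizes[cohorts], seq_len))),
                    group = grp, stringsAsFactors = FALSE)

  set.seed(.stage_seed(params$seed, 2))
  baseline <- stats::rnorm(params$n_genes, params$baseline_mean,
                           params$baseline_sd)
  shift_mat <- matrix(0, params$n_genes, nrow(ann))
  for (j in seq_len(nrow(ann))) {
    for (prog in names(params$program_sizes)) {
      s <- .human_shift(prog, ann$group[j], params)
      if (s != 0) shift_mat[membership == prog, j] <- s
    }
  }
  vals <- baseline + shift_mat +
    matrix(stats::rnorm(params$n_genes * nrow(ann), 0, params$noise_sd),
           params$n_genes, nrow(ann))
  dimnames(vals) <- list(genes, ann$sample_id)

  shifts <- expand.grid(program = setdiff(unique(membership), "none"),
                        group = intersect(cohorts, unique(grp)),
                        stringsAsFactors = FALSE)
  shifts$shift <- if (nrow(shifts)) {
    mapply(function(p, g) .human_shift(p, g, params),
           shifts$program, shifts$group)
  } else numeric(0)
  truth <- list(program_membership = data.frame(gene = genes,
                                                program = membership,
                                                stringsAsFactors = FALSE),
                shifts = shifts[shifts$shift != 0, , drop = FALSE],
                outlier_sample_id = NA_character_,
                outlier_genes = character(0))
  list(study = expression_study(vals, ann), truth = truth)
}

#' Generate a mouse-to-human ortholog map
#'
#' By default the map is the identity pairing `mmu_gNNNNN -> hsa_gNNNNN`
#' over all genes. A fraction of mouse genes can be left unmapped, and a
#' fraction of the mapped genes can be redirected onto another gene's human
#' target to create many-to-one collisions (flagged in the `collision`
#' column).
#'
#' @param params A [sim_params()] object (supplies `n_genes` and the seed).
#' @param fraction_unmapped Fraction of mouse genes with no ortholog
#'   (default 0); exactly `round(fraction * n_genes)` genes are removed.
#' @param collision_fraction Fraction of mapped genes redirected to an
#'   already-used human target (default 0).
#' @return Data frame with columns `source`, `target`, `collision`; each
#'   source appears at most once.
#' @export
generate_ortholog_map <- function(params, fraction_unmapped = 0,
                                  collision_fraction = 0) {
  stopifnot(inherits(params, "SimulationParams"),
            fraction_unmapped >= 0, fraction_unmapped < 1,
            collision_fraction >= 0, collision_fraction < 1)
  n <- params$n_genes
  map <- data.frame(source = .gene_ids(n, "mmu"),
                    target = .gene_ids(n, "hsa"),
                    collision = FALSE, stringsAsFactors = FALSE)
  set.seed(.stage_seed(params$seed, 3))
  n_drop <- round(fraction_unmapped * n)
  if (n_drop > 0)
    map <- map[-sample.int(n, n_drop), , drop = FALSE]
  n_coll <- round(collision_fraction * nrow(map))
  if (n_coll > 0 && nrow(map) >= 2) {
    who <- sample.int(nrow(map), n_coll)
    onto <- sample(setdiff(seq_len(nrow(map)), who), n_coll, replace = TRUE)
    map$target[who] <- map$target[onto]
    map$collision[who] <- TRUE
  }
  rownames(map) <- NULL
  map
}

#' Generate a synthetic canonical-pathway collection
#'
#' Builds a GMT-style named list in the human ID space: one pathway per
#' planted program (its exact member genes) plus `n_random` pathways of
#' `size_random` genes drawn uniformly. This gives the pathway-enrichment
#' stage a collection with known positives.
#'
#' @param params A [sim_params()] object.
#' @param n_random Number of random background pathways (default 30).
#' @param size_random Genes per random pathway (default 50).
#' @return Named list of character vectors of `hsa_g*` IDs.
#' @export
generate_pathway_collection <- function(params, n_random = 30,
                                        size_random = 50) {
  stopifnot(inherits(params, "SimulationParams"))
  membership <- .assign_programs(params)
  genes <- .gene_ids(params$n_genes, "hsa")
  sets <- lapply(setdiff(unique(membership), "none"),
                 function(p) genes[membership == p])
  names(sets) <- paste0("pathway_", setdiff(unique(membership), "none"))
  set.seed(.stage_seed(params$seed, 4))
  for (i in seq_len(n_random)) {
    sets[[sprintf("pathway_random_%02d", i)]] <-
      genes[sort(sample.int(params$n_genes, min(size_random, params$n_genes)))]
  }
  sets
}

#' Write simulation truth tables to TSV
#'
#' @param truth A `SyntheticTruth` list from the generators.
#' @param dir Output directory; writes `truth_programs.tsv` and
#'   `truth_shifts.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  p1 <- file.path(dir, "truth_programs.tsv")
  p2 <- file.path(dir, "truth_shifts.tsv")
  utils::write.table(truth$program_membership, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sh <- truth$shifts
  sh$outlier_sample_id <- truth$outlier_sample_id
  utils::write.table(sh, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
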