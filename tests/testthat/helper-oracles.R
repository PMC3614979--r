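# Independent oracles and fixture builders shared across the test files.
# Each oracle is a literal, unoptimized transcription of the defining
# formula, kept deliberately separate from the package implementation.

# Literal evaluation of the running-sum deviation definition: walk every
# rank position, accumulate weighted hit mass and miss counts, return the
# deviation of maximum absolute value (earlier position wins ties).
brute_force_es <- function(scores, set, weight_exponent = 1) {
  n <- length(scores)
  is_hit <- names(scores) %in% set
  m <- sum(is_hit)
  w <- abs(unname(scores))^weight_exponent
  w_total <- sum(w[is_hit])
  idx <- seq_len(n)
  best <- 0
  best_i <- NA_integer_
  for (i in idx) {
    p_hit <- sum(w[is_hit & idx <= i]) / w_total
    p_miss <- sum(!is_hit & idx <= i) / (n - m)
    dev <- p_hit - p_miss
    if (is.na(best_i) || abs(dev) > abs(best)) {
      best <- dev
      best_i <- i
    }
  }
  list(es = best, peak_index = best_i)
}

# Unweighted two-sample KS-style statistic: the signed supremum difference
# between the empirical CDF of hit positions and that of miss positions,
# evaluated independently of any running-sum bookkeeping.
direct_ks_es <- function(scores, set) {
  n <- length(scores)
  hit_pos <- which(names(scores) %in% set)
  miss_pos <- setdiff(seq_len(n), hit_pos)
  devs <- vapply(seq_len(n), function(i) {
    mean(hit_pos <= i) - mean(miss_pos <= i)
  }, numeric(1))
  i <- which.max(abs(devs))
  devs[i]
}

# Step-up Benjamini-Hochberg from its definition: q_(i) = min_{j >= i}
# p_(j) * m / j, capped at 1.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws from a universe with K marked elements.
enumerate_hypergeom <- function(k, n, K, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# A strictly ranked list of n random scores with unique gene names.
random_ranked <- function(n, prefix = "g") {
  s <- sort(stats::rnorm(n), decreasing = TRUE)
  names(s) <- sprintf("%s%03d", prefix, seq_len(n))
  s
}

# A tiny annotated study from an explicit matrix.
toy_study <- function(values, group = rep("a", ncol(values)),
                      time_days = NULL) {
  ann <- data.frame(sample_id = colnames(values), group = group)
  if (!is.null(time_days)) ann$time_days <- time_days
  expression_study(values, ann)
}

# Shared small simulation for integration-flavored module tests.
small_sim <- function(seed, n_genes = 500, n_per_group = 4,
                      program = c(inflammation = 40, active_fibrosis = 40,
                                  late_fibrosis = 40), ...) {
  sim_params(n_genes = n_genes, n_per_group = n_per_group,
             program_sizes = program, seed = seed, ...)
}

# Mouse study -> per-day DEG sets (names are days) and up signatures.
mouse_signature_run <- function(sp) {
  mouse <- generate_mouse_timecourse(sp)
  omap <- generate_ortholog_map(sp)
  ms <- map_orthologs(mouse$study, omap)
  fl <- flag_outlier_samples(ms)
  if (length(fl))
    ms <- subset_samples(ms, setdiff(colnames(ms$values), fl))
  de <- suppressMessages(fit_contrasts(ms, "bleomycin", "saline"))
  degs <- filter_degs(de)
  names(degs) <- as.character(sort(unique(de$time_days)))
  list(study = ms, de = de, degs = degs, truth = mouse$truth, map = omap,
       signatures = suppressWarnings(build_timepoint_signatures(degs)))
}
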