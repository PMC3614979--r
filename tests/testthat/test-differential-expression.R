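test_that("two-group contrast matches the closed-form pooled t-test", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  colnames(m) <- paste0("s", 1:6)
  study <- toy_study(m, group = rep(c("A", "B"), each = 3))
  de <- fit_contrasts(study, "A", "B", time_col = NULL)
  expect_equal(de$log2_fc, -3)
  expect_equal(de$fold_change, 8)
  expect_equal(de$direction, "down")
  # textbook pooled two-sample t: sp2 = 1, se = sqrt(2/3)
  t_exp <- -3 / sqrt(1 * (2 / 3))
  expect_equal(de$p_value, 2 * pt(-abs(t_exp), 4))
  expect_equal(round(de$p_value, 4), 0.0213)

  # identical group means, nonzero variance -> t = 0, p = 1 exactly
  m2 <- rbind(g1 = c(1, 3, 2, 1, 3, 2))
  colnames(m2) <- paste0("s", 1:6)
  de2 <- fit_contrasts(toy_study(m2, group = rep(c("A", "B"), each = 3)),
                       "A", "B", time_col = NULL)
  expect_equal(de2$p_value, 1)
})

test_that("fit_contrasts agrees with t.test on random two-group data", {
  set.seed(13)
  m <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
  grp <- rep(c("case", "ctrl"), each = 6)
  de <- fit_contrasts(toy_study(m, group = grp), "case", "ctrl",
                      time_col = NULL)
  for (g in sample(rownames(m), 10)) {
    tt <- t.test(m[g, grp == "case"], m[g, grp == "ctrl"], var.equal = TRUE)
    row <- de[de$gene == g, ]
    expect_equal(row$p_value, tt$p.value)
    expect_equal(row$log2_fc, unname(diff(rev(tt$estimate))))
  }
})

test_that("outputs are invariant to sample order within groups", {
  set.seed(17)
  m <- matrix(rnorm(30 * 16), 30, 16,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:16)))
  grp <- rep(c("bleomycin", "saline"), each = 8)
  day <- rep(c(1, 7), times = 8)
  st <- toy_study(m, group = grp, time_days = day)
  de1 <- fit_contrasts(st, "bleomycin", "saline")
  perm <- sample(ncol(m))
  st2 <- expression_study(m[, perm], st$annotations)
  de2 <- fit_contrasts(st2, "bleomycin", "saline")
  de2 <- de2[order(de2$contrast, de2$gene), ]
  de1 <- de1[order(de1$contrast, de1$gene), ]
  rownames(de1) <- rownames(de2) <- NULL
  expect_equal(de1, de2)
})

test_that("time-course ANOVA uses pooled residual variance across cells", {
  set.seed(19)
  m <- matrix(rnorm(20 * 24), 20, 24,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:24)))
  grp <- rep(c("bleomycin", "saline"), each = 12)
  day <- rep(rep(c(1, 7, 14), each = 4), 2)
  st <- toy_study(m, group = grp, time_days = day)
  de <- fit_contrasts(st, "bleomycin", "saline")
  expect_equal(sort(unique(de$time_days)), c(1, 7, 14))
  # oracle: per-gene lm on the cell-means model, contrast at day 7
  g <- "g05"
  fit <- lm(m[g, ] ~ 0 + interaction(grp, day))
  s2 <- sum(residuals(fit)^2) / df.residual(fit)
  d <- mean(m[g, grp == "bleomycin" & day == 7]) -
    mean(m[g, grp == "saline" & day == 7])
  t_exp <- d / sqrt(s2 * (1 / 4 + 1 / 4))
  p_exp <- 2 * pt(-abs(t_exp), df.residual(fit))
  row <- de[de$gene == g & de$time_days == 7, ]
  expect_equal(row$p_value, p_exp)
  expect_equal(row$log2_fc, d)
  # the within-cell variant reduces to a per-day two-sample t-test
  dew <- fit_contrasts(st, "bleomycin", "saline", variance = "within")
  tt <- t.test(m[g, grp == "bleomycin" & day == 7],
               m[g, grp == "saline" & day == 7], var.equal = TRUE)
  expect_equal(dew[dew$gene == g & dew$time_days == 7, "p_value"], tt$p.value)
})

test_that("BH adjustment matches the step-up definition and is idempotent", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.03), 0.03)
  expect_identical(adjust_bh(numeric(0)), numeric(0))
  set.seed(29)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    q <- adjust_bh(p)
    expect_equal(q, brute_force_bh(p))
    perm <- sample(length(p))
    expect_equal(adjust_bh(p[perm]), q[perm])  # permutation-equivariant
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("DEG filter is inclusive on fold change and strict on q", {
  de <- data.frame(gene = c("a", "b", "c", "d"), contrast = "x",
                   log2_fc = c(log2(2.5), 1, log2(3), -2),
                   fold_change = c(2.5, 2, 3, 4),
                   direction = c("up", "up", "up", "down"),
                   p_value = 0.01, q_value = c(0.01, 0.049, 0.05, 0.001))
  sets <- filter_degs(de, fc_min = 2, q_max = 0.05)
  expect_true("a" %in% sets$up)
  expect_true("b" %in% sets$up)       # exactly 2-fold: "at least" is inclusive
  expect_false("c" %in% sets$up)      # q exactly 0.05: strict
  expect_equal(sets$down, "d")
})

test_that("composite rank applies the signed -log10(q) with documented ties", {
  de <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"), contrast = "c",
                   log2_fc = c(1, -0.5, 2, 1, 0.2),
                   fold_change = 2^abs(c(1, -0.5, 2, 1, 0.2)),
                   direction = c("up", "down", "up", "up", "up"),
                   p_value = 0.01,
                   q_value = c(0.01, 0.01, 0.1, 0.1, 1))
  r <- composite_rank(de)
  expect_equal(unname(r["g1"]), 2)
  expect_equal(unname(r["g5"]), 0)    # q = 1 scores 0 regardless of fold
  # exhaustive check of the total order on the 5-gene fixture
  score <- sign(de$log2_fc) * -log10(pmax(de$q_value, min(de$q_value) / 10))
  ord <- order(-score, -abs(de$log2_fc), de$gene)
  expect_equal(names(r), de$gene[ord])
  # equal scores: the larger |log2_fc| gene ranks higher
  expect_lt(match("g3", names(r)), match("g4", names(r)))

  # q = 0 is floored at min nonzero q / 10
  de0 <- de
  de0$q_value[1] <- 0
  r0 <- composite_rank(de0)
  expect_equal(unname(r0["g1"]), -log10(0.01 / 10))
  expect_error(composite_rank(rbind(de, transform(de, contrast = "c2"))),
               "one contrast")
})

test_that("zero residual variance is degenerate, not an error", {
  m <- rbind(flat = c(1, 1, 1, 2, 2, 2), same = rep(3, 6))
  colnames(m) <- paste0("s", 1:6)
  st <- toy_study(m, group = rep(c("A", "B"), each = 3))
  expect_message(de <- fit_contrasts(st, "A", "B", time_col = NULL),
                 "zero residual variance")
  expect_equal(de$p_value[de$gene == "flat"], 0)  # nonzero contrast, no noise
  expect_equal(de$p_value[de$gene == "same"], 1)  # zero contrast
})

test_that("planted program genes are recovered at days 7/14 with high
           sensitivity and low FDR", {
  sens <- fdr <- numeric(0)
  for (seed in 1:20) {
    run <- mouse_signature_run(small_sim(seed, n_per_group = 8))
    prog <- run$truth$program_membership
    act <- sub("mmu_", "hsa_", prog$gene[prog$program == "active_fibrosis"])
    up714 <- unique(c(run$degs[["7"]]$up, run$degs[["14"]]$up))
    sens <- c(sens, mean(act %in% up714))
    fdr <- c(fdr, if (length(up714)) mean(!up714 %in% act) else 0)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr), 0.1)
})

test_that("RNK files round-trip ranked lists", {
  r <- random_ranked(20)
  p <- tempfile(fileext = ".rnk")
  write_rnk(r, p)
  expect_identical(read_rnk(p), r)
})
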