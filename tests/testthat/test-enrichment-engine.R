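test_that("running score reproduces the worked single-hit and two-hit cases", {
  r5 <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  top <- running_es(r5, "g1")
  expect_equal(top$es, 1)
  expect_equal(top$peak_index, 1)
  bottom <- running_es(r5, "g5")
  expect_equal(bottom$es, -1)
  expect_equal(bottom$peak_index, 4)

  r6 <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  two <- running_es(r6, c("g1", "g2"), weight_exponent = 1)
  expect_equal(two$es, 1)
  expect_equal(two$peak_index, 2)
  expect_equal(leading_edge(r6, c("g1", "g2"), two$peak_index, two$es),
               c("g1", "g2"))
})

test_that("degenerate sets and unordered input are refused", {
  r <- random_ranked(10)
  expect_error(running_es(r, "absent"), "degenerate set")
  expect_error(running_es(r, names(r)), "degenerate set")
  expect_error(running_es(rev(r), names(r)[1]), "non-increasing")
  rz <- setNames(c(1, 0, 0, 0), paste0("g", 1:4))
  expect_error(running_es(rz, c("g2", "g3")), "degenerate weights")
})

test_that("running score equals the brute-force deviation definition", {
  set.seed(61)
  for (i in 1:500) {
    n <- sample(3:12, 1)
    r <- random_ranked(n)
    m <- sample(seq_len(min(4, n - 1)), 1)
    set <- sample(names(r), m)
    p <- sample(c(0, 1, 2), 1)
    got <- running_es(r, set, weight_exponent = p)
    exp <- brute_force_es(r, set, weight_exponent = p)
    expect_identical(got$es, exp$es)
    expect_identical(got$peak_index, exp$peak_index)
  }
})

test_that("position-based scorer is bit-identical to the full profile", {
  set.seed(67)
  for (i in 1:300) {
    n <- sample(5:60, 1)
    r <- random_ranked(n)
    m <- sample(seq_len(n - 1), 1)
    pos <- sort(sample.int(n, m))
    p <- sample(c(0, 0.5, 1, 2), 1)
    full <- running_es(r, names(r)[pos], weight_exponent = p)
    fast <- phasesig:::.es_from_positions(pos, abs(r)^p, n)
    expect_identical(fast$es, full$es)
    expect_identical(as.integer(fast$peak_index), as.integer(full$peak_index))
  }
})

test_that("score agrees with the fgsea reference implementation", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(10:100, 1)
    r <- random_ranked(n)
    m <- sample(2:min(10, n - 1), 1)
    pos <- sort(sample.int(n, m))
    for (p in c(0, 1)) {
      mine <- running_es(r, names(r)[pos], weight_exponent = p)$es
      ref <- fgsea::calcGseaStat(r, pos, gseaParam = p)
      expect_equal(mine, ref, tolerance = 1e-12)
    }
  }
})

test_that("reversing the list and negating scores negates the score", {
  set.seed(73)
  for (i in 1:50) {
    r <- random_ranked(sample(6:40, 1))
    set <- sample(names(r), sample(2:4, 1))
    a <- running_es(r, set)$es
    b <- running_es(rev(-r), set)$es
    expect_equal(b, -a, tolerance = 1e-12)
  }
})

test_that("permutation null is seeded, bounded and centred", {
  r <- random_ranked(100)
  gp <- gsea_params(n_permutations = 200, seed = 99)
  null1 <- permutation_null(r, 10, gp)
  expect_identical(null1, permutation_null(r, 10, gp))
  expect_length(null1, 200)
  expect_true(all(null1 >= -1 & null1 <= 1))

  # symmetric score vector: null mean ~ 0 within 3 SE over 1e4 permutations
  sym <- setNames(seq(2, -2, length.out = 101), sprintf("g%03d", 1:101))
  gp2 <- gsea_params(n_permutations = 10000, seed = 7)
  null2 <- permutation_null(sym, 8, gp2)
  expect_lt(abs(mean(null2)), 3 * sd(null2) / sqrt(length(null2)))
  expect_error(permutation_null(r, 100, gp), "set_size")
})

test_that("NES and nominal p follow the same-sign plus-one convention", {
  null <- c(0.5, 0.4, 0.3, 0.2, 0.1, -0.1, -0.2, -0.3)
  st <- enrichment_stats(0.9, null)
  expect_equal(st$p_value, 1 / (1 + 5))
  expect_equal(st$nes, 0.9 / mean(c(0.5, 0.4, 0.3, 0.2, 0.1)))
  expect_equal(enrichment_stats(0.3, null)$p_value, (1 + 3) / (1 + 5))
  neg <- enrichment_stats(-0.25, null)
  expect_equal(neg$p_value, (1 + 1) / (1 + 3))  # only |-0.3| >= 0.25
  expect_equal(neg$nes, -0.25 / mean(c(0.1, 0.2, 0.3)))
  expect_lt(neg$nes, 0)
  flagged <- enrichment_stats(-0.5, c(0.1, 0.2))
  expect_true(flagged$flagged)
  expect_equal(flagged$p_value, 1)
  expect_error(enrichment_stats(0.5, numeric(0)), "empty null")
})

test_that("across-set FDR matches an independent ratio estimator", {
  # extremes
  expect_equal(fdr_across_sets(3, c(0.5, 1, 1.5)), 0)
  pool <- c(seq(0.1, 2, by = 0.1), -seq(0.1, 1, by = 0.1))
  self <- fdr_across_sets(pool, pool)
  expect_true(all(self >= 0.999))  # self-comparison: equal tail fractions

  set.seed(77)
  nes <- c(runif(6, 0.5, 3), -runif(4, 0.5, 3))
  null <- c(rnorm(300, 1, 0.3), -rnorm(200, 1, 0.3))
  got <- fdr_across_sets(nes, null)
  # recompute raw ratios independently and apply the same monotone rule
  raw <- sapply(nes, function(v) {
    sn <- if (v >= 0) null[null >= 0] else null[null < 0]
    so <- if (v >= 0) nes[nes >= 0] else nes[nes < 0]
    min(1, mean(abs(sn) >= abs(v)) / mean(abs(so) >= abs(v)))
  })
  for (s in c(TRUE, FALSE)) {
    idx <- which(if (s) nes >= 0 else nes < 0)
    idx <- idx[order(abs(nes[idx]))]
    raw[idx] <- cummin(raw[idx])
  }
  expect_equal(got, raw)
  # monotonicity: within sign, larger |NES| never has larger q
  pos <- order(abs(nes[nes >= 0]))
  expect_true(all(diff(got[nes >= 0][pos]) <= 0))
})

test_that("planted enrichments take the smallest FDR among 20 sets", {
  set.seed(83)
  n <- 400
  scores <- sort(c(rnorm(50, 3, 0.5), rnorm(350, 0, 0.5)), decreasing = TRUE)
  names(scores) <- sprintf("g%03d", seq_len(n))
  top_genes <- names(scores)[1:50]
  sets <- c(lapply(1:5, function(i) sample(top_genes, 15)),
            lapply(1:15, function(i) sample(names(scores), 15)))
  names(sets) <- c(paste0("planted", 1:5), paste0("null", 1:15))
  res <- run_gsea(scores, sets, gsea_params(n_permutations = 200, seed = 5))
  best5 <- res$set[order(res$q_value, -abs(res$nes))][1:5]
  expect_true(all(grepl("planted", best5)))
})

test_that("leading edge obeys the sign rule", {
  r <- random_ranked(30)
  res <- running_es(r, names(r)[c(2, 4, 25)])
  le <- leading_edge(r, names(r)[c(2, 4, 25)], res$peak_index, res$es)
  if (res$es >= 0) expect_true(all(match(le, names(r)) <= res$peak_index))
  # bottom-enriched set draws only from the tail
  bot <- running_es(r, names(r)[27:30])
  le_b <- leading_edge(r, names(r)[27:30], bot$peak_index, bot$es)
  expect_lt(bot$es, 0)
  expect_true(all(match(le_b, names(r)) >= bot$peak_index))
  expect_equal(le_b, names(r)[27:30])
})

test_that("run_gsea is deterministic, shares nulls by size, filters by size", {
  r <- random_ranked(60)
  sets <- list(a = names(r)[1:8], a_dup = names(r)[1:8],
               tiny = names(r)[1:2], big = names(r))
  gp <- gsea_params(n_permutations = 150, seed = 11, min_set_size = 5)
  expect_message(res <- run_gsea(r, sets, gp), "dropped 2")
  expect_equal(nrow(res), 2)
  expect_equal(res$es[1], res$es[2])
  expect_equal(res$p_value[1], res$p_value[2])
  expect_equal(res$nes[1], res$nes[2])
  res2 <- suppressMessages(run_gsea(r, sets, gp))
  expect_identical(res, res2)
  expect_error(suppressMessages(run_gsea(r, list(tiny = names(r)[1:2]), gp)),
               "no sets retained")
})

test_that("weight zero reduces to the unweighted KS-style statistic", {
  set.seed(89)
  for (i in 1:100) {
    n <- sample(8:60, 1)
    r <- random_ranked(n)
    set <- sample(names(r), sample(2:6, 1))
    expect_equal(running_es(r, set, weight_exponent = 0)$es,
                 direct_ks_es(r, set), tolerance = 1e-12)
  }
})
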