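test_that("mouse time course has the full 2-arm x 7-day x n design", {
  sp <- sim_params(n_genes = 2000, n_per_group = 8, seed = 11)
  out <- generate_mouse_timecourse(sp)
  expect_equal(dim(out$study$values), c(2000, 2 * 7 * 8))
  expect_equal(nrow(out$study$annotations), 112)
  expect_setequal(unique(out$study$annotations$group), c("bleomycin", "saline"))
  expect_setequal(unique(out$study$annotations$time_days),
                  c(1, 2, 7, 14, 21, 28, 35))
  # the designated outlier sits in the saline day-14 cell
  ann <- out$study$annotations
  j <- match(out$truth$outlier_sample_id, ann$sample_id)
  expect_equal(ann$group[j], "saline")
  expect_equal(ann$time_days[j], 14)
  # planted programs are disjoint and of the configured sizes
  tab <- table(out$truth$program_membership$program)
  expect_equal(tab[["inflammation"]], 100)
  expect_equal(tab[["active_fibrosis"]], 100)
  expect_equal(tab[["late_fibrosis"]], 100)
})

test_that("planted shifts follow the phase structure", {
  sp <- sim_params(seed = 5)
  out <- generate_mouse_timecourse(sp)
  sh <- out$truth$shifts
  expect_true(all(sh$group == "bleomycin"))
  infl <- sh[sh$program == "inflammation", ]
  expect_setequal(infl$time_days, c(1, 2))
  expect_true(all(infl$shift == 1.5))
  act <- sh[sh$program == "active_fibrosis", ]
  expect_equal(act$shift[act$time_days %in% c(7, 14)], rep(1.5, 2))
  expect_equal(act$shift[act$time_days %in% c(21, 28, 35)], rep(0.6, 3))
  late <- sh[sh$program == "late_fibrosis", ]
  expect_setequal(late$time_days, c(21, 28, 35))
})

test_that("null configuration plants nothing and arms differ only by noise", {
  sp <- sim_params(n_genes = 300, n_per_group = 6, effect_size = 0,
                   outlier_shift = 0, seed = 21,
                   program_sizes = c(inflammation = 30,
                                     active_fibrosis = 30, late_fibrosis = 30))
  out <- generate_mouse_timecourse(sp)
  expect_equal(nrow(out$truth$shifts), 0)
  expect_true(is.na(out$truth$outlier_sample_id))
  ann <- out$study$annotations
  d <- rowMeans(out$study$values[, ann$group == "bleomycin"]) -
    rowMeans(out$study$values[, ann$group == "saline"])
  # per-gene noise-only difference: sd = noise_sd * sqrt(2/42)
  expect_lt(max(abs(d)), 0.5 * sqrt(2 / 42) * 6)
})

test_that("identical seeds give bit-identical studies, different seeds differ", {
  sp17 <- sim_params(n_genes = 100, n_per_group = 2, seed = 17,
                     program_sizes = c(inflammation = 10,
                                       active_fibrosis = 10, late_fibrosis = 10))
  a <- generate_mouse_timecourse(sp17)
  b <- generate_mouse_timecourse(sp17)
  expect_identical(a$study$values, b$study$values)
  expect_identical(a$truth, b$truth)
  sp18 <- sim_params(n_genes = 100, n_per_group = 2, seed = 18,
                     program_sizes = c(inflammation = 10,
                                       active_fibrosis = 10, late_fibrosis = 10))
  expect_false(identical(a$study$values,
                         generate_mouse_timecourse(sp18)$study$values))
  h1 <- generate_human_cohort(sp17)
  expect_identical(h1$study$values, generate_human_cohort(sp17)$study$values)
})

test_that("human cohort shape, shifts and planted-effect recovery", {
  sp <- sim_params(n_genes = 2000,
                   human_group_sizes = c(control = 10, stable = 10,
                                         exacerbation = 10), seed = 9)
  out <- generate_human_cohort(sp)
  expect_equal(dim(out$study$values), c(2000, 30))
  sh <- out$truth$shifts
  expect_true(all(sh$program == "active_fibrosis"))
  s_stable <- sh$shift[sh$group == "stable"]
  s_exac <- sh$shift[sh$group == "exacerbation"]
  expect_gt(s_exac, s_stable)

  # empirical program shift converges to the planted value (3 SE at n = 50)
  sp2 <- sim_params(n_genes = 1000, effect_size = 1,
                    human_group_sizes = c(control = 50, stable = 50,
                                          exacerbation = 0),
                    program_sizes = c(inflammation = 50,
                                      active_fibrosis = 100,
                                      late_fibrosis = 50), seed = 41)
  h <- generate_human_cohort(sp2)
  prog <- h$truth$program_membership
  act <- prog$gene[prog$program == "active_fibrosis"]
  grp <- h$study$annotations$group
  d <- rowMeans(h$study$values[act, grp == "stable"]) -
    rowMeans(h$study$values[act, grp == "control"])
  se <- 0.5 * sqrt(2 / 50) / sqrt(length(act))
  expect_lt(abs(mean(d) - 1), 3 * se)
  # inflammation program is never shifted in humans
  infl <- prog$gene[prog$program == "inflammation"]
  d0 <- rowMeans(h$study$values[infl, grp == "stable"]) -
    rowMeans(h$study$values[infl, grp == "control"])
  expect_lt(abs(mean(d0)), 3 * se * sqrt(2))
})

test_that("control-only cohorts and invalid configurations", {
  sp <- sim_params(n_genes = 100,
                   human_group_sizes = c(control = 5, stable = 0,
                                         exacerbation = 0),
                   program_sizes = c(inflammation = 10,
                                     active_fibrosis = 10, late_fibrosis = 10),
                   seed = 2)
  h <- generate_human_cohort(sp)
  expect_equal(dim(h$study$values), c(100, 5))
  expect_equal(nrow(h$truth$shifts), 0)
  expect_error(sim_params(n_genes = 20,
                          program_sizes = c(inflammation = 10,
                                            active_fibrosis = 10,
                                            late_fibrosis = 10)),
               "exceeds n_genes")
  expect_error(sim_params(noise_sd = 0), "noise_sd")
  expect_error(sim_params(exacerbation_multiplier = 1), "multiplier")
})

test_that("ortholog map: bijection, unmapped counts, collisions", {
  sp <- sim_params(n_genes = 1000, seed = 31,
                   program_sizes = c(inflammation = 10,
                                     active_fibrosis = 10, late_fibrosis = 10))
  full <- generate_ortholog_map(sp)
  expect_equal(nrow(full), 1000)
  expect_false(anyDuplicated(full$source) > 0)
  expect_false(anyDuplicated(full$target) > 0)
  expect_equal(full$target, sub("mmu_", "hsa_", full$source))

  dropped <- generate_ortholog_map(sp, fraction_unmapped = 0.1)
  expect_equal(nrow(dropped), 900)
  expect_false(anyDuplicated(dropped$source) > 0)

  coll <- generate_ortholog_map(sp, collision_fraction = 0.05)
  expect_false(anyDuplicated(coll$source) > 0)
  expect_gte(max(table(coll$target)), 2)
  expect_true(all(coll$target[coll$collision] %in%
                    coll$target[duplicated(coll$target) |
                                  duplicated(coll$target, fromLast = TRUE)]))
})
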