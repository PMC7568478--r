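test_that("offspring-parent weights follow the one/both-parent rule", {
  ped <- toy_pedigree(list(list(k = 1), list(k = 2)))
  # family 1: both parents phenotyped; family 2: father only
  adj <- toy_adjusted(c("f01_fa", "f01_mo", "f01_o1",
                        "f02_fa", "f02_o1", "f02_o2"),
                      c(1, 2, 3, 4, 5, 6))
  ps <- build_offspring_parent(ped, adj)
  expect_equal(nrow(ps$pairs), 4)                     # 2 + 2 pairs
  w1 <- ps$pairs$weight[ps$pairs$family_id == "f01"]
  w2 <- ps$pairs$weight[ps$pairs$family_id == "f02"]
  expect_equal(sort(w1), c(0.5, 0.5))
  expect_equal(w2, c(1, 1))
  # weight sum equals number of offspring with >= 1 phenotyped parent
  expect_equal(sum(ps$pairs$weight), 3)
  # df = sum(k_i) - 2 = (1 + 2) - 2
  expect_equal(ps$df, 1L)
})

test_that("offspring-parent df follows sum(k) - 2", {
  ped <- toy_pedigree(list(list(k = 1), list(k = 2), list(k = 3)))
  ids <- ped$individual_id
  adj <- toy_adjusted(ids, seq_along(ids))
  ps <- build_offspring_parent(ped, adj)
  expect_equal(ps$df, 6L - 2L)
  expect_equal(ps$n_families, 3L)
})

test_that("offspring without phenotyped parents are excluded, not fatal", {
  ped <- toy_pedigree(list(list(k = 1), list(k = 1)))
  adj <- toy_adjusted(c("f01_fa", "f01_o1", "f02_o1"), c(1, 2, 3))
  ps <- build_offspring_parent(ped, adj)
  expect_equal(nrow(ps$pairs), 1)
  expect_equal(ps$n_excluded, 1L)
})

test_that("self-parenting is a pedigree-integrity error", {
  ped <- toy_pedigree(list(list(k = 1)))
  ped$father_id[ped$individual_id == "f01_o1"] <- "f01_o1"
  adj <- toy_adjusted(ped$individual_id, seq_len(nrow(ped)))
  expect_error(build_offspring_parent(ped, adj), "own parent")
})

test_that("midparent pairs need both parents and share the predictor", {
  ped <- toy_pedigree(list(list(k = 2), list(k = 1)))
  adj <- toy_adjusted(c("f01_fa", "f01_mo", "f01_o1", "f01_o2",
                        "f02_fa", "f02_o1"),
                      c(2, 4, 1, 7, 9, 3))
  ps <- build_midparent(ped, adj)
  expect_equal(nrow(ps$pairs), 2)                # f02 contributes nothing
  expect_equal(unique(ps$pairs$predictor_value), 3)   # (2 + 4) / 2
  expect_equal(ps$pairs$weight, c(1, 1))
  expect_equal(ps$df, 2L - 2L)
})

test_that("full-sib double entry produces all ordered pairs and sum(k-1) df", {
  ped <- toy_pedigree(list(list(k = 2), list(k = 3), list(k = 1)))
  ids <- ped$individual_id
  adj <- toy_adjusted(ids, seq_along(ids))
  ps <- build_full_sib(ped, adj)
  expect_equal(nrow(ps$pairs), 2 + 6)            # k(k-1) per sibship
  expect_equal(ps$df, 1L + 2L + 0L)
  # mirror symmetry: (a, b) and (b, a) both present
  key <- paste(ps$pairs$dependent_value, ps$pairs$predictor_value)
  rev_key <- paste(ps$pairs$predictor_value, ps$pairs$dependent_value)
  expect_setequal(key, rev_key)
})

test_that("double entry makes the sib slope equal the sib correlation", {
  set.seed(12)
  co <- small_cohort(n_families = 300, seed = 12)
  adj <- adjust_phenotypes(co$pedigree, co$phenotypes)
  ps <- build_full_sib(co$pedigree, adj)
  x <- ps$pairs$predictor_value
  y <- ps$pairs$dependent_value
  slope <- cov(x, y) / var(x)
  expect_equal(slope, cor(x, y), tolerance = 1e-10)
})

test_that("half-sibs are excluded from full-sib pairs", {
  ped <- toy_pedigree(list(list(k = 3)))
  ped$mother_id[ped$individual_id == "f01_o3"] <- "f01_mo2"
  ped <- rbind(ped, data.frame(individual_id = "f01_mo2", family_id = "f01",
                               father_id = NA, mother_id = NA, sex = "F",
                               age = 50, generation = "parent"))
  adj <- toy_adjusted(ped$individual_id, seq_len(nrow(ped)))
  ps <- build_full_sib(ped, adj)
  expect_equal(nrow(ps$pairs), 2)                # only o1-o2 remain full sibs
})

test_that("spouse correlation is symmetric and validated", {
  ped <- toy_pedigree(list(list(k = 1), list(k = 1), list(k = 1)))
  adj <- toy_adjusted(c("f01_fa", "f01_mo", "f02_fa", "f02_mo",
                        "f03_fa", "f03_mo"),
                      c(1, 1, 5, 5, -2, -2))
  expect_equal(spouse_correlation(ped, adj), 1.0)

  ped2 <- toy_pedigree(list(list(k = 1), list(k = 1)))
  adj2 <- toy_adjusted(ped2$individual_id, seq_len(nrow(ped2)))
  expect_error(spouse_correlation(ped2, adj2), "at least 3")

  set.seed(3)
  co <- generate_cohort(cohort_config(n_families = 2000, seed = 33,
                                      r_spouse_target = 0,
                                      p_both_parents = 1))
  adjc <- adjust_phenotypes(co$pedigree, co$phenotypes)
  expect_lt(abs(spouse_correlation(co$pedigree, adjc)), 3 / sqrt(2000))
})
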