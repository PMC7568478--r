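test_that("configuration invariants are enforced", {
  expect_error(cohort_config(h2_latent = 0.7, c2_shared = 0.5),
               "variance decomposition")
  expect_error(cohort_config(transform = "cube"), "unknown transform")
  expect_error(cohort_config(transform = function(z) -z), "monotone")
  expect_error(cohort_config(sibship_size_dist = c(0.5, 0.4)), "sum to 1")
  expect_error(cohort_config(n_families = 0), "integer")
  expect_s3_class(cohort_config(transform = function(z) z^3 + z), "qh_config")
})

test_that("regeneration with the same seed is bit-for-bit identical", {
  cfg <- cohort_config(n_families = 50, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$phenotypes, b$phenotypes)
  c <- generate_cohort(cohort_config(n_families = 50, seed = 78))
  expect_false(identical(a$phenotypes, c$phenotypes))
})

test_that("latent additive model matches closed-form expectations", {
  # h2 = 0: no offspring-parent covariance
  co0 <- small_cohort(n_families = 2000, seed = 301, h2_latent = 0)
  ped <- co0$pedigree
  off <- ped[ped$generation == "offspring", ]
  pf <- ped$latent[match(off$father_id, ped$individual_id)]
  n <- nrow(off)
  expect_lt(abs(cor(off$latent, pf)), 3 / sqrt(n))

  # h2 = 0.5, r = 0, c2 = 0: offspring-parent slope h2/2, sib corr h2/2
  co <- generate_cohort(cohort_config(n_families = 3000, h2_latent = 0.5,
                                      r_spouse_target = 0, c2_shared = 0,
                                      seed = 302))
  ped <- co$pedigree
  off <- ped[ped$generation == "offspring", ]
  pf <- ped$latent[match(off$father_id, ped$individual_id)]
  pm <- ped$latent[match(off$mother_id, ped$individual_id)]
  slope_f <- cov(off$latent, pf) / var(pf)
  slope_m <- cov(off$latent, pm) / var(pm)
  n <- nrow(off)
  expect_lt(abs(slope_f - 0.25), 3 / sqrt(n))
  expect_lt(abs(slope_m - 0.25), 3 / sqrt(n))
  sib <- merge(off[, c("family_id", "individual_id", "latent")],
               off[, c("family_id", "individual_id", "latent")],
               by = "family_id")
  sib <- sib[sib$individual_id.x != sib$individual_id.y, ]
  expect_lt(abs(cor(sib$latent.x, sib$latent.y) - 0.25),
            3 / sqrt(nrow(sib) / 2))
})

test_that("spouse correlation round-trips through adjustment", {
  co <- generate_cohort(cohort_config(n_families = 3000, seed = 303,
                                      p_both_parents = 1))
  adj <- adjust_phenotypes(co$pedigree, co$phenotypes)
  r <- spouse_correlation(co$pedigree, adj)
  expect_lt(abs(r - 0.04), 3 / sqrt(3000))
})

test_that("adjusted values are free of age and sex effects", {
  co <- small_cohort(n_families = 1500, seed = 304, transform = "exp")
  adj <- adjust_phenotypes(co$pedigree, co$phenotypes)
  ped <- co$pedigree[match(adj$individual_id, co$pedigree$individual_id), ]
  n <- nrow(adj)
  expect_lt(abs(cor(adj$adjusted_value, ped$age)), 3 / sqrt(n))
  expect_lt(abs(cor(adj$adjusted_value, as.numeric(ped$sex == "F"))),
            3 / sqrt(n))
})

test_that("quantile-slope oracle reproduces bivariate-normal theory", {
  # identity transform: conditional quantile slope is rho at every tau
  s50 <- expected_quantile_slope_oracle(0.5, "identity", 0.5,
                                        n_oracle = 2e5, seed = 31)
  s90 <- expected_quantile_slope_oracle(0.5, "identity", 0.9,
                                        n_oracle = 2e5, seed = 31)
  expect_lt(abs(s50 - 0.5), 0.02)
  expect_lt(abs(s90 - 0.5), 0.02)
  # exp transform: slopes increase with tau
  e10 <- expected_quantile_slope_oracle(0.5, "exp", 0.1,
                                        n_oracle = 2e5, seed = 32)
  e90 <- expected_quantile_slope_oracle(0.5, "exp", 0.9,
                                        n_oracle = 2e5, seed = 32)
  expect_gt(e90, e10)
  # deterministic given seed
  expect_identical(e10, expected_quantile_slope_oracle(0.5, "exp", 0.1,
                                                       n_oracle = 2e5,
                                                       seed = 32))
})

test_that("cohort files round-trip through disk", {
  co <- small_cohort(n_families = 20, seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("pedigree.csv",
                                               "phenotypes.csv",
                                               "config.yaml")))))
  back <- read_cohort(dir)
  expect_equal(nrow(back$pedigree), nrow(co$pedigree))
  expect_equal(back$phenotypes$value, co$phenotypes$value)
  expect_false("latent" %in% names(back$pedigree))
  expect_equal(yaml::read_yaml(file.path(dir, "config.yaml"))$seed, 5)
})
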