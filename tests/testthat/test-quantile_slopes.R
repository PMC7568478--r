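pairs_df <- function(x, y, w = rep(1, length(x)),
                     fam = as.character(seq_along(x))) {
  data.frame(family_id = fam, dependent_value = y, predictor_value = x,
             weight = w, stringsAsFactors = FALSE)
}

test_that("exact linear data give a zero-loss fit at any tau", {
  x <- seq(-3, 5, length.out = 40)
  d <- pairs_df(x, 2 * x)
  for (tau in c(0.1, 0.5, 0.9)) {
    f <- qreg_fit(d, tau)
    expect_equal(f$slope, 2, tolerance = 1e-9)
    expect_equal(f$intercept, 0, tolerance = 1e-9)
    expect_equal(f$objective, 0, tolerance = 1e-12)
  }
})

test_that("the three-point fit matches brute-force enumeration", {
  d <- pairs_df(c(0, 1, 2), c(0, 1, 4))
  f <- qreg_fit(d, 0.5)
  o <- brute_rq(c(0, 1, 2), c(0, 1, 4), rep(1, 3), 0.5)
  expect_equal(f$objective, o$objective, tolerance = 1e-12)
  # the minimizing line passes through two of the points
  r <- abs(c(0, 1, 4) - f$intercept - f$slope * c(0, 1, 2))
  expect_equal(sum(r < 1e-9), 2)
})

test_that("duplication and weight doubling leave the fit unchanged", {
  set.seed(4)
  x <- rnorm(25)
  y <- 1 + x + rt(25, df = 3)
  d <- pairs_df(x, y)
  f <- qreg_fit(d, 0.25)
  f_dup <- qreg_fit(pairs_df(c(x, x), c(y, y)), 0.25)
  f_w <- qreg_fit(pairs_df(x, y, w = rep(2, 25)), 0.25)
  expect_equal(f_dup$slope, f$slope, tolerance = 1e-9)
  expect_equal(f_w$slope, f$slope, tolerance = 1e-9)
  expect_equal(f_w$objective, 2 * f$objective, tolerance = 1e-9)
})

test_that("fits are equivariant to scaling and shifts", {
  set.seed(5)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  f <- qreg_fit(pairs_df(x, y), 0.7)
  fy <- qreg_fit(pairs_df(x, 3 * y), 0.7)
  fx <- qreg_fit(pairs_df(2 * x, y), 0.7)
  fs <- qreg_fit(pairs_df(x + 10, y - 4), 0.7)
  expect_equal(fy$slope, 3 * f$slope, tolerance = 1e-8)
  expect_equal(fx$slope, f$slope / 2, tolerance = 1e-8)
  expect_equal(fs$slope, f$slope, tolerance = 1e-8)
  expect_equal(fs$intercept, f$intercept - 4 - 10 * f$slope, tolerance = 1e-7)
})

test_that("objective optimality holds on random small datasets", {
  set.seed(6)
  for (rep in 1:25) {
    n <- sample(5:15, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    w <- sample(c(0.5, 1), n, replace = TRUE)
    tau <- runif(1, 0.1, 0.9)
    f <- qreg_fit(pairs_df(x, y, w), tau)
    o <- brute_rq(x, y, w, tau)
    expect_lte(f$objective, o$objective * (1 + 1e-9) + 1e-12)
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- pairs_df(rep(1, 10), rnorm(10))
  expect_error(qreg_fit(d, 0.5), "constant")
  expect_error(qreg_fit(pairs_df(1:2, 1:2), 0.5), "at least 3")
  expect_error(qreg_fit(pairs_df(1:10, 1:10), 1.5), "tau")
  expect_error(sqreg(pairs_df(rep(0, 20), rnorm(20)),
                     taus = acceptance_taus, B = 50), "constant")
  expect_error(sqreg(pairs_df(rnorm(20), rnorm(20)),
                     taus = c(0.25, 0.5, 0.75), B = 50),
               "must include")
  expect_error(sqreg(pairs_df(rnorm(20), rnorm(20)),
                     taus = acceptance_taus, B = 10), "B must be")
})

test_that("sqreg is well-posed and deterministic given a seed", {
  set.seed(7)
  n <- 300
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n)
  fam <- as.character(rep(1:100, 3))
  d <- pairs_df(x, y, fam = fam)
  s1 <- sqreg(d, taus = acceptance_taus, B = 60, seed = 42)
  s2 <- sqreg(d, taus = acceptance_taus, B = 60, seed = 42)
  s3 <- sqreg(d, taus = acceptance_taus, B = 60, seed = 43)
  expect_identical(s1$boot_slopes, s2$boot_slopes)
  expect_false(identical(s1$boot_slopes, s3$boot_slopes))
  expect_true(all(diag(s1$vcov) > 0))
  expect_equal(dim(s1$boot_slopes), c(60L, length(acceptance_taus)))
  # vcov is symmetric PSD
  expect_equal(s1$vcov, t(s1$vcov))
  expect_gte(min(eigen(s1$vcov, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
  # observation-unit bootstrap also runs
  s4 <- sqreg(d, taus = acceptance_taus, B = 60, seed = 42,
              boot_unit = "observation")
  expect_false(identical(s4$boot_slopes, s1$boot_slopes))
})

test_that("slope curves match bivariate normal and lognormal theory", {
  set.seed(9)
  n <- 4000
  zx <- rnorm(n)
  zy <- 0.5 * zx + sqrt(0.75) * rnorm(n)
  # bivariate normal: all conditional-quantile slopes equal rho
  s <- sqreg(pairs_df(zx, zy), taus = acceptance_taus, B = 200, seed = 14)
  se <- sqrt(diag(s$vcov))
  mid <- which(s$taus == 0.5)
  expect_true(all(abs(s$slopes - s$slopes[mid]) <=
                    3 * sqrt(se^2 + se[mid]^2) + 1e-12))
  # bivariate lognormal: upper-tail slope exceeds lower-tail slope
  sl <- sqreg(pairs_df(exp(zx), exp(zy)), taus = acceptance_taus,
              B = 200, seed = 15)
  c_diff <- as.numeric(sl$taus == 0.9) - as.numeric(sl$taus == 0.1)
  out <- slope_contrast(sl, c_diff)
  expect_gt(out$estimate, 3 * out$se)
})

test_that("slope_contrast reproduces single slopes and rejects bad input", {
  set.seed(8)
  d <- pairs_df(rnorm(200), rnorm(200))
  s <- sqreg(d, taus = acceptance_taus, B = 60, seed = 1)
  K <- length(s$taus)
  e5 <- as.numeric(s$taus == 0.5)
  out <- slope_contrast(s, e5)
  expect_equal(out$estimate, s$slopes[s$taus == 0.5])
  expect_equal(out$se, sqrt(diag(s$vcov))[s$taus == 0.5])
  expect_equal(out$df, s$df)
  # 90th minus 10th difference contrast
  c90 <- as.numeric(s$taus == 0.9) - as.numeric(s$taus == 0.1)
  out2 <- slope_contrast(s, c90)
  expect_equal(out2$estimate,
               s$slopes[s$taus == 0.9] - s$slopes[s$taus == 0.1])
  # null contrast
  out0 <- slope_contrast(s, rep(0, K))
  expect_equal(out0$estimate, 0)
  expect_equal(out0$se, 0)
  expect_error(slope_contrast(s, rep(1, K + 1)), "length")
})
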