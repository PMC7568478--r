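# Independent oracles and fixture builders.  These deliberately avoid the
# package's solver path: the quantile-regression oracle enumerates every
# line through two data points and scores the exact check loss.

check_loss_r <- function(x, y, w, tau, a, b) {
  r <- y - a - b * x
  sum(w * r * (tau - (r < 0)))
}

# brute-force weighted quantile regression: an optimal basic solution of the
# check-loss LP passes through two data points
brute_rq <- function(x, y, w, tau) {
  n <- length(x)
  best <- Inf
  ab <- c(NA_real_, NA_real_)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      o <- check_loss_r(x, y, w, tau, a, b)
      if (o < best) {
        best <- o
        ab <- c(a, b)
      }
    }
  }
  list(intercept = ab[1], slope = ab[2], objective = best)
}

# explicit normal-equations least squares, as an oracle for the adjustment
normal_eq_resid <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  drop(y - X %*% beta)
}

# hand-built pedigree: fams = list(list(k = <offspring>, parents = <1|2>))
toy_pedigree <- function(fams) {
  rows <- list()
  for (f in seq_along(fams)) {
    fam <- sprintf("f%02d", f)
    fa <- paste0(fam, "_fa"); mo <- paste0(fam, "_mo")
    rows[[length(rows) + 1]] <- data.frame(
      individual_id = c(fa, mo), family_id = fam,
      father_id = NA_character_, mother_id = NA_character_,
      sex = c("M", "F"), age = c(60, 58), generation = "parent",
      stringsAsFactors = FALSE)
    k <- fams[[f]]$k
    rows[[length(rows) + 1]] <- data.frame(
      individual_id = paste0(fam, "_o", seq_len(k)), family_id = fam,
      father_id = fa, mother_id = mo,
      sex = rep_len(c("M", "F"), k), age = 30 + seq_len(k),
      generation = "offspring", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# adjusted-value table for given ids
toy_adjusted <- function(ids, values) {
  data.frame(individual_id = ids, adjusted_value = values,
             n_exams_used = 1L, stringsAsFactors = FALSE)
}

# a synthetic qh_sqreg object with normal replicate noise around a given
# slope curve, for testing downstream transforms without refitting
fake_sqreg <- function(taus, slopes, se = 0.01, B = 400, df = 1000,
                       seed = 1) {
  set.seed(seed)
  K <- length(taus)
  reps <- matrix(rnorm(B * K, mean = rep(slopes, each = B),
                       sd = rep(se, length.out = K)[rep(seq_len(K), each = B)]),
                 nrow = B)
  obj <- list(taus = taus, slopes = slopes, intercepts = rep(0, K),
              objectives = rep(0, K), boot_slopes = reps,
              vcov = stats::cov(reps), df = as.integer(df), B = B,
              seed = as.integer(seed), boot_unit = "family",
              n_pairs = 1000L, n_families = 500L, n_redraws = 0L,
              pair_kind = "synthetic")
  class(obj) <- "qh_sqreg"
  obj
}

# compact cohort for cross-module tests
small_cohort <- function(n_families = 400, transform = "identity", seed = 42,
                         ...) {
  generate_cohort(cohort_config(n_families = n_families,
                                transform = transform, seed = seed, ...))
}

acceptance_taus <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)
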