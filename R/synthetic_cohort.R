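#' Configuration for the synthetic nuclear-family cohort generator
#'
#' Describes a cohort of nuclear families with a fully additive latent
#' phenotype model: parent latent values are standard bivariate normal with
#' the target spouse correlation, offspring receive the mid-parental genetic
#' value plus segregation, shared-sibship and unique environmental noise, and
#' the observed phenotype applies a strictly monotone transform to the latent
#' value, then adds age/sex effects and per-examination measurement noise.
#' With the identity transform quantile-specific familial slopes are flat in
#' the percentile; a convex transform such as `exp` makes the raw-scale
#' slopes rise with the percentile while leaving the latent model unchanged.
#'
#' Defaults emulate a Framingham-like design: sibships of 1-5 (truncated
#' geometric), both parents phenotyped in 42% of families, weak spouse
#' correlation (0.04), latent narrow-sense heritability 0.5, parents about 20
#' years older than offspring, a female excess in the phenotype mean, and two
#' examinations with small measurement noise (assay CV of a few percent).
#'
#' @param n_families number of nuclear families.
#' @param sibship_size_dist probability vector over sibship sizes `1:k_max`;
#'   must be nonnegative and sum to 1.
#' @param p_both_parents probability that both parents are phenotyped
#'   (otherwise one parent, chosen at random, has no phenotype rows).
#' @param r_spouse_target latent phenotype correlation between spouses.
#' @param h2_latent latent narrow-sense heritability in `[0, 1]`.
#' @param c2_shared shared-sibship environmental variance fraction;
#'   `h2_latent + c2_shared` must not exceed 1.
#' @param transform `"identity"`, `"exp"`, or a strictly increasing function
#'   applied to the latent value before age/sex effects and noise.
#' @param age_model named coefficients on the observed scale:
#'   `intercept`, `sex_effect` (female indicator), `age_slope`,
#'   `age_quadratic`, `sex_age`, `sex_age2`.
#' @param age_dist list with `parent_mean`, `parent_sd`, `offspring_mean`,
#'   `offspring_sd`, `min_age` (ages are truncated below at `min_age`).
#' @param sex_ratio probability that an individual is female.
#' @param n_exams examinations per phenotyped individual.
#' @param exam_noise_sd per-exam measurement noise SD on the observed scale.
#' @param sex_shift_latent additive shift of female offspring latent values
#'   applied before the transform (default 0).  With a convex transform this
#'   emulates a trait whose concentrations run higher in daughters than sons
#'   while both sexes share one underlying expressivity law, the setting in
#'   which percentile-matched sex comparisons differ but concentration-matched
#'   (quantile-quantile remapped) comparisons coincide.
#' @param seed integer seed recorded in the config; `generate_cohort()` seeds
#'   from it so regeneration is bit-for-bit reproducible.
#' @return an object of class `qh_config` (a validated list).
#' @export
cohort_config <- function(n_families = 1000,
                          sibship_size_dist = 0.55^(0:4) / sum(0.55^(0:4)),
                          p_both_parents = 0.42,
                          r_spouse_target = 0.04,
                          h2_latent = 0.5,
                          c2_shared = 0,
                          transform = "identity",
                          age_model = c(intercept = 3.5, sex_effect = 4,
                                        age_slope = 0.065, age_quadratic = 0,
                                        sex_age = 0.012, sex_age2 = 0),
                          age_dist = list(parent_mean = 60.5, parent_sd = 9.5,
                                          offspring_mean = 40, offspring_sd = 8.7,
                                          min_age = 16),
                          sex_ratio = 0.5,
                          n_exams = 2,
                          exam_noise_sd = 0.1,
                          sex_shift_latent = 0,
                          seed = 1L) {
  n_families <- check_count(n_families, "n_families")
  if (!is.numeric(sibship_size_dist) || length(sibship_size_dist) < 1 ||
      any(sibship_size_dist < 0) ||
      abs(sum(sibship_size_dist) - 1) > 1e-8)
    qh_validation_error("sibship_size_dist must be nonnegative and sum to 1")
  check_fraction(p_both_parents, "p_both_parents")
  check_fraction(r_spouse_target, "r_spouse_target", lo = -1 + 1e-12, hi = 1 - 1e-12)
  check_fraction(h2_latent, "h2_latent")
  check_fraction(c2_shared, "c2_shared")
  if (h2_latent + c2_shared > 1 + 1e-12)
    qh_validation_error("impossible variance decomposition: h2_latent + c2_shared > 1")
  trf <- resolve_transform(transform)
  need <- c("intercept", "sex_effect", "age_slope", "age_quadratic",
            "sex_age", "sex_age2")
  if (!all(need %in% names(age_model)))
    qh_validation_error("age_model must name coefficients: ",
                        paste(need, collapse = ", "))
  check_fraction(sex_ratio, "sex_ratio")
  n_exams <- check_count(n_exams, "n_exams")
  if (!is.numeric(exam_noise_sd) || exam_noise_sd < 0)
    qh_validation_error("exam_noise_sd must be nonnegative")
  cfg <- list(n_families = n_families,
              sibship_size_dist = sibship_size_dist,
              p_both_parents = p_both_parents,
              r_spouse_target = r_spouse_target,
              h2_latent = h2_latent, c2_shared = c2_shared,
              transform = transform, transform_fun = trf$fun,
              transform_name = trf$name,
              age_model = age_model[need], age_dist = age_dist,
              sex_ratio = sex_ratio, n_exams = n_exams,
              exam_noise_sd = exam_noise_sd,
              sex_shift_latent = sex_shift_latent, seed = as.integer(seed))
  class(cfg) <- "qh_config"
  cfg
}

# resolve a transform spec to a function and verify strict monotonicity on
# the latent support (checked numerically on [-8, 8])
resolve_transform <- function(transform) {
  if (is.function(transform)) {
    grid <- seq(-8, 8, length.out = 513)
    vals <- transform(grid)
    if (any(!is.finite(vals)) || any(diff(vals) <= 0))
      qh_validation_error("custom transform must be finite and strictly ",
                          "monotone increasing on the latent support")
    return(list(fun = transform, name = "custom"))
  }
  if (!is.character(transform) || length(transform) != 1L)
    qh_validation_error("transform must be a name or a function")
  switch(transform,
         identity = list(fun = function(z) z, name = "identity"),
         exp = list(fun = exp, name = "exp"),
         qh_validation_error("unknown transform '", transform,
                             "'; use 'identity', 'exp' or a function"))
}

age_model_value <- function(age_model, female, age) {
  unname(age_model["intercept"] + age_model["sex_effect"] * female +
         age_model["age_slope"] * age + age_model["age_quadratic"] * age^2 +
         age_model["sex_age"] * female * age +
         age_model["sex_age2"] * female * age^2)
}

#' Generate a synthetic nuclear-family cohort
#'
#' Draws families per [cohort_config()]: parent latent phenotypes are
#' standard bivariate normal with the target spouse correlation; parental
#' genetic values have variance `h2_latent` and covariance `h2_latent` with
#' the own latent phenotype; each offspring receives the mean parental
#' genetic value plus segregation variance `h2_latent / 2`, a sibship-shared
#' environmental term and unique environment filling the variance to 1.
#' Observed per-exam values apply the transform to the latent value and add
#' the age/sex model and exam noise.  Age/sex effects are added after the
#' transform so a linear age-sex adjustment removes them exactly in
#' expectation.
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `qh_cohort`: a list with `pedigree` (one row
#'   per individual: `individual_id`, `family_id`, `father_id`, `mother_id`,
#'   `sex`, `age`, `generation`, `cohort`, and the latent truth columns
#'   `latent` and `genetic` kept for validation), `phenotypes` (long format:
#'   `individual_id`, `exam_id`, `value`) and the `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "qh_config"))
    qh_validation_error("config must come from cohort_config()")
  set.seed(config$seed)
  nf <- config$n_families
  h2 <- config$h2_latent
  c2 <- config$c2_shared
  r <- config$r_spouse_target

  sib_k <- sample.int(length(config$sibship_size_dist), nf, replace = TRUE,
                      prob = config$sibship_size_dist)
  n_off <- sum(sib_k)

  # parent latent phenotypes: bivariate normal with correlation r
  p_f <- rnorm(nf)
  p_m <- r * p_f + sqrt(1 - r^2) * rnorm(nf)
  # parental genetic values: Var = h2, Cov(G, P) = h2
  g_f <- h2 * p_f + sqrt(h2 * (1 - h2)) * rnorm(nf)
  g_m <- h2 * p_m + sqrt(h2 * (1 - h2)) * rnorm(nf)
  c_fam <- sqrt(c2) * rnorm(nf)

  fam_of_off <- rep.int(seq_len(nf), sib_k)
  g_o <- (g_f[fam_of_off] + g_m[fam_of_off]) / 2 + sqrt(h2 / 2) * rnorm(n_off)
  e_var <- 1 - h2 - c2
  p_o <- g_o + c_fam[fam_of_off] + sqrt(max(e_var, 0)) * rnorm(n_off)

  fam_id <- sprintf("f%05d", seq_len(nf))
  fa_id <- paste0(fam_id, "_fa")
  mo_id <- paste0(fam_id, "_mo")
  off_id <- paste0(fam_id[fam_of_off], "_o",
                   unlist(lapply(sib_k, seq_len), use.names = FALSE))

  draw_age <- function(n, mean, sd) {
    pmax(config$age_dist$min_age, rnorm(n, mean, sd))
  }
  ped <- data.frame(
    individual_id = c(fa_id, mo_id, off_id),
    family_id = c(fam_id, fam_id, fam_id[fam_of_off]),
    father_id = c(rep(NA_character_, 2 * nf), fa_id[fam_of_off]),
    mother_id = c(rep(NA_character_, 2 * nf), mo_id[fam_of_off]),
    sex = c(rep("M", nf), rep("F", nf),
            ifelse(runif(n_off) < config$sex_ratio, "F", "M")),
    age = c(draw_age(nf, config$age_dist$parent_mean, config$age_dist$parent_sd),
            draw_age(nf, config$age_dist$parent_mean, config$age_dist$parent_sd),
            draw_age(n_off, config$age_dist$offspring_mean,
                     config$age_dist$offspring_sd)),
    generation = c(rep("parent", 2 * nf), rep("offspring", n_off)),
    latent = c(p_f, p_m, p_o),
    genetic = c(g_f, g_m, g_o),
    stringsAsFactors = FALSE
  )
  ped$cohort <- ifelse(ped$generation == "parent", "parent_cohort",
                       "offspring_cohort")

  # which parents keep phenotypes
  both <- runif(nf) < config$p_both_parents
  drop_father <- !both & (runif(nf) < 0.5)
  drop_mother <- !both & !drop_father
  phenotyped <- c(!drop_father, !drop_mother, rep(TRUE, n_off))

  who <- ped[phenotyped, c("individual_id", "sex", "age", "latent",
                           "generation")]
  ni <- nrow(who)
  shift <- config$sex_shift_latent *
    as.numeric(who$sex == "F" & who$generation == "offspring")
  base <- config$transform_fun(who$latent + shift) +
    age_model_value(config$age_model, as.numeric(who$sex == "F"), who$age)
  phen <- data.frame(
    individual_id = rep(who$individual_id, each = config$n_exams),
    exam_id = rep(seq_len(config$n_exams), times = ni),
    value = rep(base, each = config$n_exams) +
      rnorm(ni * config$n_exams, 0, config$exam_noise_sd),
    stringsAsFactors = FALSE
  )

  out <- list(pedigree = ped, phenotypes = phen, config = config)
  class(out) <- "qh_cohort"
  out
}

#' @export
print.qh_cohort <- function(x, ...) {
  ped <- x$pedigree
  cat("synthetic cohort:", x$config$n_families, "families,",
      sum(ped$generation == "offspring"), "offspring,",
      nrow(x$phenotypes), "phenotype records\n")
  cat("  h2_latent =", x$config$h2_latent,
      " c2_shared =", x$config$c2_shared,
      " r_spouse =", x$config$r_spouse_target,
      " transform =", x$config$transform_name, "\n")
  invisible(x)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Writes `pedigree.csv` and `phenotypes.csv` (each with a leading
#' `# seed: <seed>` comment line) and the configuration as `config.yaml`.
#'
#' @param cohort a `qh_cohort` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "qh_cohort"))
    qh_validation_error("cohort must come from generate_cohort()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- paste0("# seed: ", cohort$config$seed)
  write_with_header <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    write.csv(df, con, row.names = FALSE)
  }
  ped <- cohort$pedigree
  ped$latent <- NULL
  ped$genetic <- NULL
  write_with_header(ped, file.path(dir, "pedigree.csv"))
  write_with_header(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  cfg <- cohort$config
  cfg$transform_fun <- NULL
  cfg$transform <- cfg$transform_name
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `pedigree.csv` and `phenotypes.csv`.
#' @return a list with `pedigree` and `phenotypes` data frames (no latent
#'   truth columns; the on-disk format matches real-study input tables).
#' @export
read_cohort <- function(dir) {
  ped <- read.csv(file.path(dir, "pedigree.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
  phen <- read.csv(file.path(dir, "phenotypes.csv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  list(pedigree = ped, phenotypes = phen)
}

#' Monte-Carlo oracle for quantile-regression slopes of transformed
#' bivariate-normal pairs
#'
#' Simulates `n_oracle` pairs from a standard bivariate normal with
#' correlation `rho`, applies the transform to both coordinates, and
#' estimates the `tau`-quantile regression slope by direct minimization of
#' the exact check loss with a derivative-free simplex search.  This routine
#' is deliberately independent of the package's linear-programming solver so
#' it can serve as a calibration oracle for the cohort generator.
#'
#' @param rho latent correlation in (-1, 1).
#' @param transform as in [cohort_config()].
#' @param tau quantile level in (0, 1).
#' @param n_oracle number of simulated pairs.
#' @param seed integer seed.
#' @return the estimated slope (a single number).
#' @export
expected_quantile_slope_oracle <- function(rho, transform = "identity",
                                           tau = 0.5, n_oracle = 1e5,
                                           seed = 1L) {
  check_fraction(rho, "rho", lo = -1 + 1e-12, hi = 1 - 1e-12)
  check_fraction(tau, "tau", lo = 1e-12, hi = 1 - 1e-12)
  n_oracle <- check_count(n_oracle, "n_oracle", min = 10L)
  trf <- resolve_transform(transform)
  set.seed(seed)
  zx <- rnorm(n_oracle)
  zy <- rho * zx + sqrt(1 - rho^2) * rnorm(n_oracle)
  x <- trf$fun(zx)
  y <- trf$fun(zy)
  loss <- function(ab) {
    r <- y - ab[1] - ab[2] * x
    sum(r * (tau - (r < 0)))
  }
  start <- coef(lm.fit(cbind(1, x), y))
  fit <- optim(start, loss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  unname(fit$par[2])
}
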