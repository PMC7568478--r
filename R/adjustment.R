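#' Age- and sex-adjust phenotype values for a single examination
#'
#' Fits an ordinary least-squares regression of the phenotype on
#' `[1, female, age, age^2, female*age, female*age^2]` within one
#' examination stratum and returns the residuals.  This is the standard
#' adjustment for traits with sex- and age-dependent means; both sexes must
#' be present and the design must be full rank.
#'
#' @param records data frame with columns `value`, `age`, `sex` (`"M"`/`"F"`)
#'   for one examination stratum (one row per individual).
#' @return numeric vector of residuals aligned with `records` rows; residuals
#'   sum to zero up to numerical tolerance.
#' @export
adjust_exam <- function(records) {
  need <- c("value", "age", "sex")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    qh_validation_error("records must be a data frame with columns ",
                        paste(need, collapse = ", "))
  n <- nrow(records)
  if (n < 7L)
    qh_validation_error("adjustment needs at least 7 records ",
                        "(6 design parameters); got ", n)
  if (any(!is.finite(records$value)) || any(!is.finite(records$age)) ||
      any(records$age <= 0))
    qh_validation_error("values must be finite and ages positive")
  female <- as.numeric(records$sex == "F")
  if (length(unique(female)) < 2L)
    qh_validation_error("both sexes must be represented; collinear columns: ",
                        "female, female*age, female*age^2")
  X <- cbind(`(Intercept)` = 1, female = female, age = records$age,
             age2 = records$age^2, female_age = female * records$age,
             female_age2 = female * records$age^2)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    qh_validation_error("rank-deficient adjustment design; collinear columns: ",
                        paste(dropped, collapse = ", "))
  }
  unname(qr.resid(qx, records$value))
}

#' Average per-exam residuals into one adjusted value per individual
#'
#' @param residuals data frame with columns `individual_id` and `residual`
#'   (one row per individual per examination).
#' @return data frame with `individual_id`, `adjusted_value` (arithmetic mean
#'   of the available residuals) and `n_exams_used`.
#' @export
average_residuals <- function(residuals) {
  if (!is.data.frame(residuals) ||
      !all(c("individual_id", "residual") %in% names(residuals)))
    qh_validation_error("residuals must have columns individual_id, residual")
  m <- tapply(residuals$residual, residuals$individual_id, mean)
  k <- tapply(residuals$residual, residuals$individual_id, length)
  out <- data.frame(individual_id = names(m),
                    adjusted_value = as.numeric(m),
                    n_exams_used = as.integer(k),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Adjust a cohort's phenotypes per examination stratum and average residuals
#'
#' Applies [adjust_exam()] separately within each `(cohort, exam_id)` stratum
#' (or `exam_id` alone when the pedigree has no `cohort` column), pooling all
#' individuals within a stratum, then averages each individual's residuals
#' over available examinations with [average_residuals()].
#'
#' @param pedigree data frame with `individual_id`, `sex`, `age` (and
#'   optionally `cohort`).
#' @param phenotypes long-format data frame with `individual_id`, `exam_id`,
#'   `value`.
#' @return data frame with `individual_id`, `adjusted_value`, `n_exams_used`.
#' @export
adjust_phenotypes <- function(pedigree, phenotypes) {
  need_p <- c("individual_id", "sex", "age")
  if (!all(need_p %in% names(pedigree)))
    qh_validation_error("pedigree must have columns ",
                        paste(need_p, collapse = ", "))
  need_f <- c("individual_id", "exam_id", "value")
  if (!all(need_f %in% names(phenotypes)))
    qh_validation_error("phenotypes must have columns ",
                        paste(need_f, collapse = ", "))
  idx <- match(phenotypes$individual_id, pedigree$individual_id)
  if (anyNA(idx))
    qh_validation_error("phenotype rows reference individuals missing from ",
                        "the pedigree")
  dat <- data.frame(individual_id = phenotypes$individual_id,
                    exam_id = phenotypes$exam_id,
                    value = phenotypes$value,
                    age = pedigree$age[idx],
                    sex = pedigree$sex[idx],
                    stringsAsFactors = FALSE)
  stratum <- if ("cohort" %in% names(pedigree)) {
    paste(pedigree$cohort[idx], dat$exam_id, sep = "/")
  } else {
    as.character(dat$exam_id)
  }
  res <- numeric(nrow(dat))
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    res[rows] <- adjust_exam(dat[rows, , drop = FALSE])
  }
  average_residuals(data.frame(individual_id = dat$individual_id,
                               residual = res, stringsAsFactors = FALSE))
}
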