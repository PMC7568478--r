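#' Narrow-sense heritability from regression slopes between relatives
#'
#' Falconer's transforms: from the single-parent slope,
#' `h2 = 2 * beta_op / (1 + r_spouse)`; from the midparent slope, `h2 =
#' beta_om`; from the double-entry full-sib slope, `h2 = (sqrt(1 + 8 *
#' r_spouse * beta_fs) - 1) / (2 * r_spouse)`, with the analytic limit
#' `2 * beta_fs` as `r_spouse -> 0`.  The spouse correlation enters as a
#' plug-in constant; estimates outside `[0, 1]` are possible on noisy data
#' and produce a warning, not an error.
#'
#' @param beta_op,beta_om,beta_fs regression slope (vectorized).
#' @param r_spouse spouse correlation, greater than -1.
#' @return heritability estimate(s), same length as the slope input.
#' @export
h2_from_op <- function(beta_op, r_spouse) {
  if (!is.numeric(r_spouse) || length(r_spouse) != 1L || r_spouse <= -1)
    qh_validation_error("r_spouse must be a single number > -1")
  h2 <- 2 * beta_op / (1 + r_spouse)
  warn_h2_bounds(h2)
  h2
}

#' @rdname h2_from_op
#' @export
h2_from_midparent <- function(beta_om) {
  warn_h2_bounds(beta_om)
  beta_om
}

#' @rdname h2_from_op
#' @export
h2_from_fs <- function(beta_fs, r_spouse) {
  if (!is.numeric(r_spouse) || length(r_spouse) != 1L || r_spouse <= -1)
    qh_validation_error("r_spouse must be a single number > -1")
  if (abs(r_spouse) < 1e-8) {
    h2 <- 2 * beta_fs          # Taylor limit of the closed form
  } else {
    disc <- 1 + 8 * r_spouse * beta_fs
    if (any(disc < 0, na.rm = TRUE))
      qh_numeric_error("negative discriminant in the full-sib transform: ",
                       "1 + 8 * ", r_spouse, " * beta = ",
                       paste(signif(disc[disc < 0], 4), collapse = ", "))
    h2 <- (sqrt(disc) - 1) / (2 * r_spouse)
  }
  warn_h2_bounds(h2)
  h2
}

# the algebraic inverse of h2_from_fs: the full-sib slope implied by h2
# (verified by substitution: 1 + 8 r beta = (1 + 2 r h)^2)
fs_slope_from_h2 <- function(h2, r_spouse) {
  h2 * (1 + r_spouse * h2) / 2
}

warn_h2_bounds <- function(h2) {
  bad <- sum(h2 < 0 | h2 > 1, na.rm = TRUE)
  if (bad > 0)
    warning(bad, " heritability estimate(s) outside [0, 1]; ",
            "possible on noisy data", call. = FALSE)
  invisible(h2)
}

h2_transform <- function(relationship, r_spouse) {
  switch(relationship,
         offspring_parent = function(b) 2 * b / (1 + r_spouse),
         offspring_midparent = function(b) b,
         full_sib = function(b) {
           if (abs(r_spouse) < 1e-8) return(2 * b)
           disc <- 1 + 8 * r_spouse * b
           out <- rep(NA_real_, length(b))
           ok <- disc >= 0
           out[ok] <- (sqrt(disc[ok]) - 1) / (2 * r_spouse)
           out
         },
         qh_validation_error("unknown relationship '", relationship, "'"))
}

# |dh2/dbeta| for the delta-method standard error
h2_derivative <- function(relationship, r_spouse, beta) {
  switch(relationship,
         offspring_parent = rep(2 / (1 + r_spouse), length(beta)),
         offspring_midparent = rep(1, length(beta)),
         full_sib = {
           if (abs(r_spouse) < 1e-8) rep(2, length(beta)) else {
             disc <- 1 + 8 * r_spouse * beta
             ifelse(disc > 0, 2 / sqrt(disc), NA_real_)
           }
         })
}

#' Quantile-specific heritability curve from a slope curve
#'
#' Applies the relationship's Falconer transform to every slope on the
#' quantile grid and to every bootstrap replicate.  The primary standard
#' error at each quantile is the standard deviation of the transformed
#' replicates (exact under the bootstrap, no linearization); the
#' delta-method SE is reported alongside for comparison.  Full-sib
#' replicates with a negative discriminant are marked invalid; more than 1%
#' invalid replicates at any quantile is an error.
#'
#' @param set a `qh_sqreg` object.
#' @param relationship `"offspring_parent"`, `"offspring_midparent"` or
#'   `"full_sib"`.
#' @param r_spouse plug-in spouse correlation (fixed, not resampled).
#' @return an object of class `qh_h2curve`: `taus`, `h2`, `se` (bootstrap),
#'   `se_delta`, `replicates` (transformed bootstrap matrix), `relationship`,
#'   `r_spouse`, `df`, `n_invalid`.
#' @export
h2_curve <- function(set, relationship = c("offspring_parent",
                                           "offspring_midparent", "full_sib"),
                     r_spouse = 0) {
  if (!inherits(set, "qh_sqreg"))
    qh_validation_error("set must come from sqreg()")
  relationship <- match.arg(relationship)
  if (!is.numeric(r_spouse) || length(r_spouse) != 1L || r_spouse <= -1)
    qh_validation_error("r_spouse must be a single number > -1")
  trf <- h2_transform(relationship, r_spouse)
  h2 <- suppressWarnings(trf(set$slopes))
  if (any(is.na(h2)))
    qh_numeric_error("negative discriminant for the point estimate at ",
                     sum(is.na(h2)), " quantile(s)")
  reps <- apply(set$boot_slopes, 2, trf)
  n_invalid <- colSums(is.na(reps))
  if (any(n_invalid > 0.01 * set$B))
    qh_numeric_error("more than 1% of bootstrap replicates undefined at ",
                     "tau = ", paste(set$taus[n_invalid > 0.01 * set$B],
                                     collapse = ", "))
  se <- apply(reps, 2, sd, na.rm = TRUE)
  se_delta <- h2_derivative(relationship, r_spouse, set$slopes) *
    sqrt(diag(set$vcov))
  warn_h2_bounds(h2)
  out <- list(taus = set$taus, h2 = h2, se = se, se_delta = se_delta,
              replicates = reps, relationship = relationship,
              r_spouse = r_spouse, df = set$df, B = set$B,
              n_invalid = n_invalid)
  class(out) <- "qh_h2curve"
  out
}

#' @export
print.qh_h2curve <- function(x, ...) {
  cat("quantile-specific heritability (", x$relationship,
      ", r_spouse = ", x$r_spouse, ", df = ", x$df, ")\n", sep = "")
  show <- vapply(headline_taus, function(t) which.min(abs(x$taus - t)), 1L)
  tab <- data.frame(percentile = 100 * x$taus[show],
                    h2 = round(x$h2[show], 3),
                    se = round(x$se[show], 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
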