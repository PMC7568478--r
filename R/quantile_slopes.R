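#' Default percentile grid for simultaneous quantile regression
#'
#' The 91 percentiles from the 5th to the 95th; the tails beyond are
#' excluded by default because their fits are less stable.
#'
#' @return numeric vector of quantile levels.
#' @export
default_taus <- function() seq(0.05, 0.95, by = 0.01)

headline_taus <- c(0.10, 0.25, 0.50, 0.75, 0.90)

as_pair_data <- function(pairs) {
  if (inherits(pairs, "qh_pairs")) return(pairs$pairs)
  if (is.data.frame(pairs)) {
    need <- c("dependent_value", "predictor_value")
    if (!all(need %in% names(pairs)))
      qh_validation_error("pairs must have columns ",
                          paste(need, collapse = ", "))
    if (is.null(pairs$weight)) pairs$weight <- 1
    if (is.null(pairs$family_id))
      pairs$family_id <- as.character(seq_len(nrow(pairs)))
    return(pairs)
  }
  qh_validation_error("pairs must be a qh_pairs object or a data frame")
}

#' Fit one weighted quantile regression
#'
#' Minimizes the asymmetrically weighted absolute-residual (check-loss)
#' objective `sum_i w_i * rho_tau(y_i - a - b x_i)` exactly, via a primal-dual
#' interior-point solve of the equivalent linear program followed by a vertex
#' polish (an optimal basic solution interpolates two data points).
#'
#' @param pairs a `qh_pairs` object or data frame with `dependent_value`,
#'   `predictor_value` and optional `weight`.
#' @param tau quantile level in (0, 1).
#' @return list with `intercept`, `slope`, `objective` (the minimized check
#'   loss), `tau` and `converged`.
#' @export
qreg_fit <- function(pairs, tau) {
  check_fraction(tau, "tau", lo = 1e-9, hi = 1 - 1e-9)
  d <- as_pair_data(pairs)
  if (nrow(d) < 3L)
    qh_validation_error("quantile regression needs at least 3 pairs")
  if (any(d$weight <= 0))
    qh_validation_error("weights must be positive")
  if (max(d$predictor_value) - min(d$predictor_value) <= 0)
    qh_validation_error("predictor is constant; slope undefined")
  fit <- tryCatch(
    rq_fit_cpp(d$predictor_value, d$dependent_value, d$weight, tau),
    error = function(e) qh_numeric_error("quantile regression failed: ",
                                         conditionMessage(e)))
  list(intercept = fit$intercept, slope = fit$slope,
       objective = fit$objective, tau = tau, converged = fit$converged)
}

#' Simultaneous quantile regression with bootstrap covariance
#'
#' Fits the quantile-regression slope at every level in `taus` on the full
#' data, then estimates the joint covariance of the slope curve from `B`
#' bootstrap resamples.  The default resampling unit is the family: all of a
#' family's pairs enter a resample together, which respects the dependence
#' created by double entry and by the half weights.  `boot_unit =
#' "observation"` resamples individual pairs for compatibility with
#' conventional software defaults.
#'
#' @param pairs a `qh_pairs` object (or data frame with a `family_id`
#'   column).
#' @param taus quantile grid; must contain the headline percentiles
#'   0.10, 0.25, 0.50, 0.75, 0.90.
#' @param B number of bootstrap resamples (at least 50; default 1000).
#' @param seed integer seed for the bootstrap.
#' @param boot_unit `"family"` (cluster bootstrap, default) or
#'   `"observation"`.
#' @return an object of class `qh_sqreg`: `taus`, `slopes`, `intercepts`,
#'   `objectives`, `boot_slopes` (B x K replicate matrix), `vcov` (K x K,
#'   from the replicates), `df` (from the pair set), `B`, `seed`,
#'   `boot_unit`, `n_pairs`, `n_redraws` (degenerate resamples redrawn).
#' @export
sqreg <- function(pairs, taus = default_taus(), B = 1000, seed = 1L,
                  boot_unit = c("family", "observation")) {
  boot_unit <- match.arg(boot_unit)
  B <- check_count(B, "B", min = 50L)
  taus <- sort(unique(as.numeric(taus)))
  if (any(taus <= 0) || any(taus >= 1))
    qh_validation_error("taus must lie strictly inside (0, 1)")
  if (!all(vapply(headline_taus,
                  function(t) any(abs(taus - t) < 1e-9), logical(1))))
    qh_validation_error("tau grid must include 0.10, 0.25, 0.50, 0.75, 0.90")
  d <- as_pair_data(pairs)
  if (nrow(d) < 3L)
    qh_validation_error("quantile regression needs at least 3 pairs")
  if (max(d$predictor_value) - min(d$predictor_value) <= 0)
    qh_validation_error("predictor is constant; slope undefined")
  df <- if (inherits(pairs, "qh_pairs")) pairs$df else nrow(d) - 2L

  full <- rq_grid_cpp(d$predictor_value, d$dependent_value, d$weight, taus)

  cl <- if (boot_unit == "family") as.character(d$family_id) else
    as.character(seq_len(nrow(d)))
  fam_codes <- match(cl, unique(cl)) - 1L
  nfam <- length(unique(cl))
  set.seed(seed)
  bt <- rq_boot_cpp(d$predictor_value, d$dependent_value, d$weight,
                    fam_codes, nfam, taus, B)
  if (bt$redraws > 0.01 * B)
    qh_numeric_error("more than 1% of bootstrap resamples were degenerate (",
                     bt$redraws, " redraws for B = ", B, ")")
  V <- stats::cov(bt$slopes)
  out <- list(taus = taus, slopes = full$slope, intercepts = full$intercept,
              objectives = full$objective, boot_slopes = bt$slopes,
              vcov = V, df = as.integer(df), B = B, seed = as.integer(seed),
              boot_unit = boot_unit, n_pairs = nrow(d),
              n_families = nfam, n_redraws = bt$redraws,
              pair_kind = if (inherits(pairs, "qh_pairs")) pairs$pair_kind
                          else "generic")
  class(out) <- "qh_sqreg"
  out
}

#' @export
print.qh_sqreg <- function(x, ...) {
  cat("simultaneous quantile regression (", x$pair_kind, "): ",
      length(x$taus), " quantiles, ", x$n_pairs, " pairs, B = ", x$B,
      ", df = ", x$df, "\n", sep = "")
  show <- vapply(headline_taus, function(t) which.min(abs(x$taus - t)), 1L)
  se <- sqrt(diag(x$vcov))[show]
  tab <- data.frame(tau = x$taus[show], slope = round(x$slopes[show], 4),
                    boot_se = round(se, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Test a linear combination of quantile-regression slopes
#'
#' @param set a `qh_sqreg` object.
#' @param contrast numeric vector, one entry per tau in `set$taus`.
#' @return list with `estimate`, `se`, `t`, `p` (two-sided, Student t with
#'   the pair-set degrees of freedom) and `df`.
#' @export
slope_contrast <- function(set, contrast) {
  if (!inherits(set, "qh_sqreg"))
    qh_validation_error("set must come from sqreg()")
  if (length(contrast) != length(set$taus))
    qh_validation_error("contrast length ", length(contrast),
                        " does not match ", length(set$taus), " quantiles")
  est <- sum(contrast * set$slopes)
  v <- drop(crossprod(contrast, set$vcov %*% contrast))
  scale <- max(diag(set$vcov)) * sum(contrast^2)
  if (v < -1e-8 * max(scale, 1e-300))
    qh_numeric_error("covariance matrix is not positive semidefinite")
  se <- sqrt(max(v, 0))
  t <- if (se > 0) est / se else NA_real_
  p <- if (se > 0) 2 * pt(-abs(t), df = set$df) else NA_real_
  list(estimate = est, se = se, t = t, p = p, df = set$df)
}
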