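#' Orthogonal-polynomial contrasts over a percentile grid
#'
#' Builds mutually orthogonal linear, quadratic and cubic contrast vectors
#' over the percentile grid `100 * taus` by Gram-Schmidt orthogonalization
#' against the constant (via [stats::poly()]).  Each contrast sums to zero.
#' The linear contrast is rescaled so that applying it to a curve returns
#' the least-squares slope per one-percent increase of the distribution;
#' higher-degree contrasts keep the orthonormal scaling (their t and p
#' values are scale-invariant).
#'
#' @param taus quantile grid (at least `max_degree + 1` distinct values).
#' @param max_degree highest polynomial degree (1-3; default 3).
#' @return matrix with one column per degree (`linear`, `quadratic`,
#'   `cubic`), rows aligned with `taus`.
#' @export
orthogonal_contrasts <- function(taus, max_degree = 3) {
  max_degree <- check_count(max_degree, "max_degree")
  if (max_degree > 3) qh_validation_error("max_degree must be 1, 2 or 3")
  pct <- 100 * as.numeric(taus)
  if (length(unique(pct)) < max_degree + 1)
    qh_validation_error("degenerate grid: need at least ", max_degree + 1,
                        " distinct taus for degree ", max_degree)
  Z <- poly(pct, degree = max_degree)           # orthonormal columns
  C <- matrix(0, nrow = length(pct), ncol = max_degree,
              dimnames = list(NULL, c("linear", "quadratic",
                                      "cubic")[seq_len(max_degree)]))
  # per-percentile scaling: contrast'curve = OLS slope in percent units
  ctr <- pct - mean(pct)
  C[, 1] <- ctr / sum(ctr^2)
  if (max_degree >= 2) C[, 2] <- Z[, 2]
  if (max_degree >= 3) C[, 3] <- Z[, 3]
  C
}

#' Trend test across percentiles for a slope or heritability curve
#'
#' Tests whether the quantile-specific curve is constant or changes as a
#' linear, quadratic or cubic function of the percentile, using
#' orthogonal-polynomial contrasts.  For each contrast c the estimate is
#' `c'curve`, its standard error `sqrt(c' V c)` with V the bootstrap
#' covariance of the curve, and the p-value is two-sided Student t with the
#' pair-set degrees of freedom.
#'
#' @param object a `qh_sqreg` (slope scale) or `qh_h2curve` (heritability
#'   scale, covariance from the transformed replicates).
#' @param max_degree highest polynomial degree to test (default 3).
#' @return object of class `qh_trend`: data frame `table` with columns
#'   `degree`, `estimate`, `se`, `t`, `p`, plus `df`, `scale` and the
#'   contrast `basis`.
#' @export
trend_test <- function(object, max_degree = 3) {
  if (inherits(object, "qh_sqreg")) {
    curve <- object$slopes
    V <- object$vcov
    taus <- object$taus
    df <- object$df
    scale <- "slope"
  } else if (inherits(object, "qh_h2curve")) {
    curve <- object$h2
    if (any(object$n_invalid > 0))
      qh_numeric_error("cannot test trends with invalid replicates present")
    V <- stats::cov(object$replicates)
    taus <- object$taus
    df <- object$df
    scale <- "h2"
  } else {
    qh_validation_error("object must come from sqreg() or h2_curve()")
  }
  if (is.null(V)) qh_validation_error("bootstrap covariance is missing")
  C <- orthogonal_contrasts(taus, max_degree)
  est <- drop(crossprod(C, curve))
  se <- sqrt(pmax(colSums(C * (V %*% C)), 0))
  t <- ifelse(se > 0, est / se, NA_real_)
  p <- ifelse(is.na(t), NA_real_, 2 * pt(-abs(t), df = df))
  out <- list(table = data.frame(degree = colnames(C), estimate = est,
                                 se = se, t = t, p = p,
                                 stringsAsFactors = FALSE),
              df = df, scale = scale, basis = C)
  class(out) <- "qh_trend"
  out
}

#' @export
print.qh_trend <- function(x, ...) {
  cat("trend across percentiles (", x$scale, " scale, df = ", x$df, ")\n",
      sep = "")
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 4)
  tab$t <- round(tab$t, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("linear estimate is per one-percent increase of the distribution\n")
  invisible(x)
}
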