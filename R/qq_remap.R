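#' Empirical quantile function with fixed interpolation rule
#'
#' Linear interpolation between adjacent order statistics at plotting
#' positions `p_i = (i - 0.5) / n`, clamped to the extreme order statistics
#' beyond the first/last position.  The inverse (empirical CDF) uses the
#' same rule, so `F(Q(p)) = p` on the interior grid.
#'
#' @param values numeric sample (at least 20 values, at least 2 distinct).
#' @return object of class `qh_qf` with functions `Q(p)` and `F(x)` and the
#'   sorted sample.
#' @export
empirical_qf <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20L)
    qh_validation_error("empirical quantile function needs at least 20 ",
                        "values for stable tails; got ", n)
  if (length(unique(values)) < 2L)
    qh_validation_error("need at least 2 distinct values")
  s <- sort(values)
  p <- (seq_len(n) - 0.5) / n
  Q <- function(prob) approx(p, s, xout = prob, rule = 2, ties = "ordered")$y
  Fn <- function(x) approx(s, p, xout = x, rule = 2, ties = "mean")$y
  out <- list(Q = Q, F = Fn, sorted = s, n = n)
  class(out) <- "qh_qf"
  out
}

#' Group curve bundle for quantile-quantile comparisons
#'
#' Packages a group's quantile-specific curve (slopes or heritability), its
#' bootstrap replicates, degrees of freedom and the phenotype sample whose
#' empirical quantile function maps percentiles to concentrations.
#'
#' @param taus quantile grid of the curve.
#' @param values curve values on `taus`.
#' @param replicates bootstrap replicate matrix (B x length(taus)).
#' @param df degrees of freedom for the group's tests.
#' @param sample phenotype sample defining the group's concentration scale
#'   (typically the unadjusted dependent values of the group).
#' @return object of class `qh_group_curve`.
#' @export
group_curve <- function(taus, values, replicates, df, sample) {
  taus <- as.numeric(taus)
  if (length(values) != length(taus) || ncol(replicates) != length(taus))
    qh_validation_error("curve, replicates and taus lengths do not match")
  out <- list(taus = taus, values = as.numeric(values),
              replicates = as.matrix(replicates), df = as.integer(df),
              qf = empirical_qf(sample))
  class(out) <- "qh_group_curve"
  out
}

# interpolate a curve (defined on taus) at new quantile levels; NA outside
# the fitted grid
interp_curve <- function(taus, values, at) {
  approx(taus, values, xout = at, rule = 1, ties = "ordered")$y
}

#' Re-plot a group curve at reference-distribution concentrations
#'
#' For each reference percentile p the concentration is `c = Q_ref(p)`, the
#' group's own percentile at that concentration is `p_g = F_group(c)`, and
#' the remapped value is the linear interpolation of the group curve at
#' `p_g`.  Points where `p_g` leaves the group's fitted 5th-95th percentile
#' support are masked (`valid = FALSE`, value `NA`), never extrapolated.
#'
#' @param group a [group_curve()] object.
#' @param ref_qf [empirical_qf()] of the reference (typically combined)
#'   distribution.
#' @param ref_p reference percentiles (default: the group's tau grid).
#' @return data frame with `ref_p`, `concentration`, `group_p`, `value`,
#'   `se` (SD of the remapped replicates) and `valid`.
#' @export
remap_curve <- function(group, ref_qf, ref_p = group$taus) {
  if (!inherits(group, "qh_group_curve"))
    qh_validation_error("group must come from group_curve()")
  if (!inherits(ref_qf, "qh_qf"))
    qh_validation_error("ref_qf must come from empirical_qf()")
  conc <- ref_qf$Q(ref_p)
  pg <- group$qf$F(conc)
  lo <- min(group$taus) - 1e-9
  hi <- max(group$taus) + 1e-9
  valid <- pg >= max(0.05, lo) & pg <= min(0.95, hi)
  val <- rep(NA_real_, length(ref_p))
  se <- rep(NA_real_, length(ref_p))
  if (any(valid)) {
    val[valid] <- interp_curve(group$taus, group$values, pg[valid])
    reps <- t(apply(group$replicates, 1,
                    function(r) interp_curve(group$taus, r, pg[valid])))
    if (sum(valid) == 1L) reps <- matrix(reps, ncol = 1L)
    se[valid] <- apply(reps, 2, sd)
  }
  data.frame(ref_p = ref_p, concentration = conc, group_p = pg,
             value = val, se = se, valid = valid)
}

#' Pointwise comparison of two group curves
#'
#' Compares curves at matched percentiles of each group's own distribution
#' (`matching = "percentile"`) or at matched concentrations via
#' quantile-quantile remapping onto a reference distribution
#' (`matching = "concentration"`).  Standard errors assume independent
#' groups: `SE = sqrt(SE_A^2 + SE_B^2)`; p-values are two-sided Student t
#' with the combined degrees of freedom.
#'
#' @param group_a,group_b [group_curve()] objects on identical tau grids.
#' @param matching `"percentile"` or `"concentration"`.
#' @param ref_qf reference-distribution [empirical_qf()]; required for
#'   concentration matching (typically the combined sample of both groups).
#' @return data frame with the comparison grid, per-group values,
#'   `difference`, `se`, `t`, `p` and `valid`.
#' @export
group_difference <- function(group_a, group_b,
                             matching = c("percentile", "concentration"),
                             ref_qf = NULL) {
  matching <- match.arg(matching)
  if (!inherits(group_a, "qh_group_curve") ||
      !inherits(group_b, "qh_group_curve"))
    qh_validation_error("groups must come from group_curve()")
  if (length(group_a$taus) != length(group_b$taus) ||
      any(abs(group_a$taus - group_b$taus) > 1e-9))
    qh_validation_error("mismatched tau grids; no silent re-gridding")
  df <- group_a$df + group_b$df
  if (matching == "percentile") {
    va <- group_a$values; vb <- group_b$values
    sa <- apply(group_a$replicates, 2, sd)
    sb <- apply(group_b$replicates, 2, sd)
    grid <- data.frame(ref_p = group_a$taus,
                       concentration = NA_real_, valid = TRUE)
  } else {
    if (!inherits(ref_qf, "qh_qf"))
      qh_validation_error("concentration matching needs ref_qf from ",
                          "empirical_qf()")
    ra <- remap_curve(group_a, ref_qf)
    rb <- remap_curve(group_b, ref_qf)
    va <- ra$value; vb <- rb$value
    sa <- ra$se; sb <- rb$se
    grid <- data.frame(ref_p = ra$ref_p, concentration = ra$concentration,
                       valid = ra$valid & rb$valid)
  }
  diff <- ifelse(grid$valid, va - vb, NA_real_)
  se <- ifelse(grid$valid, sqrt(sa^2 + sb^2), NA_real_)
  t <- ifelse(grid$valid & se > 0, diff / se, NA_real_)
  p <- ifelse(is.na(t), NA_real_, 2 * pt(-abs(t), df = df))
  cbind(grid[, c("ref_p", "concentration")],
        data.frame(value_a = va, value_b = vb, difference = diff, se = se,
                   t = t, p = p, valid = grid$valid))
}
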