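#' Pipeline run configuration
#'
#' A fully serializable description of one analysis run: input tables, tau
#' grid, bootstrap size and unit, seed, dependent-variable mode, optional
#' log transform of the phenotype, relationships to analyze, and whether to
#' run the sex-specific quantile-quantile comparison.  A run is reproducible
#' from the configuration and input files alone.
#'
#' @param input directory containing `pedigree.csv` and `phenotypes.csv`
#'   (as written by [write_cohort()]).
#' @param output output directory for stage artifacts.
#' @param taus quantile grid (must include 0.10, 0.25, 0.50, 0.75, 0.90).
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param dependent `"adjusted"` or `"raw"` dependent variable.
#' @param transform `"none"` or `"log"` (natural log of the phenotype before
#'   any analysis).
#' @param boot_unit `"family"` or `"observation"`.
#' @param relationships subset of `c("offspring_parent", "full_sib")`.
#' @param r_spouse plug-in spouse correlation, or `NULL` to estimate it from
#'   the data.
#' @param sex_compare run the male/female offspring-parent comparison with
#'   quantile-quantile remapping.
#' @return object of class `qh_run_config`.
#' @export
run_config <- function(input, output, taus = default_taus(), B = 1000,
                       seed = 1L, dependent = c("adjusted", "raw"),
                       transform = c("none", "log"),
                       boot_unit = c("family", "observation"),
                       relationships = c("offspring_parent", "full_sib"),
                       r_spouse = NULL, sex_compare = FALSE) {
  cfg <- list(input = input, output = output, taus = as.numeric(taus),
              B = check_count(B, "B", min = 50L), seed = as.integer(seed),
              dependent = match.arg(dependent),
              transform = match.arg(transform),
              boot_unit = match.arg(boot_unit),
              relationships = match.arg(relationships,
                                        c("offspring_parent", "full_sib"),
                                        several.ok = TRUE),
              r_spouse = r_spouse, sex_compare = isTRUE(sex_compare))
  class(cfg) <- "qh_run_config"
  cfg
}

write_stage_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes adjust, pair construction, simultaneous quantile regression,
#' heritability transform, trend tests and (optionally) the sex-specific
#' quantile-quantile comparison, writing every stage artifact plus a summary
#' table (heritability at the 10th/25th/50th/75th/90th percentiles with
#' bootstrap SEs and trend p-values) and a run log with seeds and record
#' counts into the output directory.
#'
#' @param config a [run_config()] object.
#' @return invisibly, a list with the in-memory stage objects and the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "qh_run_config"))
    qh_validation_error("config must come from run_config()")
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("seed: ", config$seed),
                 paste0("package_version: ",
                        as.character(utils::packageVersion("quantherit"))))
  dat <- read_cohort(config$input)
  ped <- dat$pedigree
  phen <- dat$phenotypes
  if (config$transform == "log") {
    if (any(phen$value <= 0))
      qh_validation_error("log transform requires strictly positive values")
    phen$value <- log(phen$value)
  }
  log_lines <- c(log_lines,
                 paste0("individuals: ", nrow(ped)),
                 paste0("phenotype_records: ", nrow(phen)))

  adjusted <- adjust_phenotypes(ped, phen)
  write_stage_csv(adjusted, file.path(config$output, "adjusted.csv"))

  r_sp <- config$r_spouse %||% spouse_correlation(ped, adjusted)
  log_lines <- c(log_lines, paste0("r_spouse: ", format(r_sp, digits = 6)),
                 paste0("r_spouse_source: ",
                        if (is.null(config$r_spouse)) "estimated" else "fixed"))

  builders <- list(offspring_parent = build_offspring_parent,
                   full_sib = build_full_sib)
  fits <- list(); curves <- list(); trends <- list(); summaries <- list()
  for (rel in config$relationships) {
    pairs <- builders[[rel]](ped, adjusted, dependent = config$dependent,
                             phenotypes = phen)
    write_stage_csv(pairs$pairs,
                    file.path(config$output, paste0("pairs_", rel, ".csv")))
    jsonlite::write_json(list(pair_kind = pairs$pair_kind, df = pairs$df,
                              n_families = pairs$n_families,
                              n_pairs = nrow(pairs$pairs),
                              n_excluded = pairs$n_excluded),
                         file.path(config$output,
                                   paste0("pairs_", rel, ".json")),
                         auto_unbox = TRUE)
    log_lines <- c(log_lines,
                   paste0(rel, ": ", nrow(pairs$pairs), " pairs, df=",
                          pairs$df, ", excluded=", pairs$n_excluded))
    fit <- sqreg(pairs, taus = config$taus, B = config$B,
                 seed = config$seed, boot_unit = config$boot_unit)
    fits[[rel]] <- fit
    write_stage_csv(data.frame(tau = fit$taus, slope = fit$slopes,
                               intercept = fit$intercepts,
                               boot_se = sqrt(diag(fit$vcov))),
                    file.path(config$output, paste0("slopes_", rel, ".csv")))
    write_stage_csv(as.data.frame(fit$vcov),
                    file.path(config$output, paste0("vcov_", rel, ".csv")))
    log_lines <- c(log_lines,
                   paste0(rel, ": bootstrap redraws=", fit$n_redraws))
    curve <- suppressWarnings(h2_curve(fit, relationship = rel,
                                       r_spouse = r_sp))
    curves[[rel]] <- curve
    write_stage_csv(data.frame(tau = curve$taus, h2 = curve$h2,
                               se = curve$se, se_delta = curve$se_delta,
                               method = "bootstrap", relationship = rel,
                               r_spouse = r_sp),
                    file.path(config$output, paste0("h2_", rel, ".csv")))
    trends[[rel]] <- list(slope = trend_test(fit), h2 = trend_test(curve))
    show <- vapply(headline_taus, function(t) which.min(abs(fit$taus - t)), 1L)
    summaries[[rel]] <- data.frame(
      relationship = rel, percentile = 100 * fit$taus[show],
      slope = fit$slopes[show], slope_se = sqrt(diag(fit$vcov))[show],
      h2 = curve$h2[show], h2_se = curve$se[show],
      p_linear = trends[[rel]]$slope$table$p[1],
      stringsAsFactors = FALSE)
  }
  jsonlite::write_json(
    lapply(trends, function(tr) lapply(tr, function(x) x$table)),
    file.path(config$output, "trend.json"), auto_unbox = TRUE, digits = NA)
  summary_df <- do.call(rbind, summaries)
  write_stage_csv(summary_df, file.path(config$output, "summary.csv"))

  remap <- NULL
  if (config$sex_compare) {
    remap <- sex_comparison(ped, phen, adjusted, config)
    write_stage_csv(remap$matched_percentile,
                    file.path(config$output, "compare_percentile.csv"))
    write_stage_csv(remap$matched_concentration,
                    file.path(config$output, "remapped.csv"))
  }

  writeLines(log_lines, file.path(config$output, "log.txt"))
  invisible(list(output = config$output, adjusted = adjusted,
                 r_spouse = r_sp, fits = fits, curves = curves,
                 trends = trends, summary = summary_df, remap = remap))
}

# male vs female offspring-parent comparison at matched percentiles and at
# matched concentrations (reference: combined unadjusted offspring sample)
sex_comparison <- function(ped, phen, adjusted, config) {
  raw <- raw_lookup(phen)
  groups <- list()
  for (sx in c("M", "F")) {
    keep_off <- ped$generation == "offspring" & ped$sex != sx
    sub_ped <- ped
    # drop the other sex's offspring (parents stay available as predictors)
    sub_ped <- sub_ped[!(keep_off), , drop = FALSE]
    pairs <- build_offspring_parent(sub_ped, adjusted,
                                    dependent = config$dependent,
                                    phenotypes = phen)
    fit <- sqreg(pairs, taus = config$taus, B = config$B, seed = config$seed,
                 boot_unit = config$boot_unit)
    off_ids <- sub_ped$individual_id[sub_ped$generation == "offspring"]
    groups[[sx]] <- group_curve(fit$taus, fit$slopes, fit$boot_slopes,
                                fit$df, raw[names(raw) %in% off_ids])
  }
  all_off <- ped$individual_id[ped$generation == "offspring"]
  ref <- empirical_qf(raw[names(raw) %in% all_off])
  list(matched_percentile = group_difference(groups$M, groups$F,
                                             matching = "percentile"),
       matched_concentration = group_difference(groups$M, groups$F,
                                                matching = "concentration",
                                                ref_qf = ref),
       groups = groups, ref_qf = ref)
}
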