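## Relative-pair construction: weighted offspring-parent, offspring-midparent,
## spouse and double-entry full-sib pairs, with family-aware degrees of
## freedom (sum(k_i) - 2 for offspring-parent/midparent, sum(k_i - 1) for
## sibships, k_i = offspring count of family i).

new_pair_set <- function(pairs, pair_kind, df, n_families, n_excluded = 0L) {
  rownames(pairs) <- NULL
  out <- list(pairs = pairs, pair_kind = pair_kind, df = as.integer(df),
              n_families = as.integer(n_families),
              n_excluded = as.integer(n_excluded))
  class(out) <- "qh_pairs"
  out
}

#' @export
print.qh_pairs <- function(x, ...) {
  cat(x$pair_kind, "pair set:", nrow(x$pairs), "pairs from", x$n_families,
      "families; df =", x$df)
  if (x$n_excluded > 0) cat(";", x$n_excluded, "offspring excluded")
  cat("\n")
  invisible(x)
}

# check pedigree integrity and return offspring rows (those with a parent id)
offspring_rows <- function(pedigree) {
  need <- c("individual_id", "family_id", "father_id", "mother_id")
  if (!all(need %in% names(pedigree)))
    qh_validation_error("pedigree must have columns ",
                        paste(need, collapse = ", "))
  if (anyDuplicated(pedigree$individual_id))
    qh_validation_error("pedigree ids are not unique")
  off <- pedigree[!is.na(pedigree$father_id) | !is.na(pedigree$mother_id), ,
                  drop = FALSE]
  bad <- off$individual_id == off$father_id | off$individual_id == off$mother_id
  if (any(bad, na.rm = TRUE))
    qh_validation_error("pedigree integrity: individual listed as own parent: ",
                        paste(head(off$individual_id[which(bad)]), collapse = ", "))
  off
}

value_lookup <- function(adjusted) {
  if (!is.data.frame(adjusted) ||
      !all(c("individual_id", "adjusted_value") %in% names(adjusted)))
    qh_validation_error("adjusted values must have columns individual_id, ",
                        "adjusted_value")
  setNames(adjusted$adjusted_value, adjusted$individual_id)
}

# per-individual mean raw value, for the unadjusted-dependent analysis mode
raw_lookup <- function(phenotypes) {
  m <- tapply(phenotypes$value, phenotypes$individual_id, mean)
  setNames(as.numeric(m), names(m))
}

# dependent values for offspring: adjusted residuals (default) or raw
# exam-averaged values when the unadjusted-dependent mode is requested
dependent_values <- function(ids, adj, dependent, phenotypes) {
  if (dependent == "adjusted") return(unname(adj[ids]))
  if (is.null(phenotypes))
    qh_validation_error("dependent = 'raw' needs the phenotypes table")
  unname(raw_lookup(phenotypes)[ids])
}

#' Build weighted offspring-parent pairs
#'
#' One pair per available child-parent combination: weight 1/2 per pair when
#' both parents are phenotyped, weight 1 when only one is.  The dependent
#' value is the offspring's adjusted residual (or raw exam-averaged value
#' with `dependent = "raw"`); the predictor is always the parent's adjusted
#' value.  Degrees of freedom are `sum(k_i) - 2` over contributing families.
#'
#' @param pedigree pedigree table (see [generate_cohort()]).
#' @param adjusted output of [adjust_phenotypes()].
#' @param dependent `"adjusted"` or `"raw"` offspring values.
#' @param phenotypes long phenotype table; required when `dependent = "raw"`.
#' @return a `qh_pairs` object.
#' @export
build_offspring_parent <- function(pedigree, adjusted,
                                   dependent = c("adjusted", "raw"),
                                   phenotypes = NULL) {
  dependent <- match.arg(dependent)
  off <- offspring_rows(pedigree)
  adj <- value_lookup(adjusted)
  dep <- dependent_values(off$individual_id, adj, dependent, phenotypes)
  fa <- unname(adj[off$father_id])
  mo <- unname(adj[off$mother_id])
  usable <- !is.na(dep) & (!is.na(fa) | !is.na(mo))
  n_excluded <- sum(!is.na(dep) & is.na(fa) & is.na(mo))

  o <- off[usable, , drop = FALSE]
  dep <- dep[usable]; fa <- fa[usable]; mo <- mo[usable]
  if (nrow(o) == 0L)
    qh_validation_error("no offspring with a phenotyped parent")
  w <- ifelse(!is.na(fa) & !is.na(mo), 0.5, 1.0)
  pairs <- rbind(
    data.frame(family_id = o$family_id[!is.na(fa)],
               dependent_value = dep[!is.na(fa)],
               predictor_value = fa[!is.na(fa)],
               weight = w[!is.na(fa)], stringsAsFactors = FALSE),
    data.frame(family_id = o$family_id[!is.na(mo)],
               dependent_value = dep[!is.na(mo)],
               predictor_value = mo[!is.na(mo)],
               weight = w[!is.na(mo)], stringsAsFactors = FALSE)
  )
  k <- table(o$family_id)
  new_pair_set(pairs, "offspring_parent", df = sum(k) - 2L,
               n_families = length(k), n_excluded = n_excluded)
}

#' Build offspring-midparent pairs
#'
#' Restricted to families where both parents are phenotyped: one pair per
#' offspring with the mean of the two parents' adjusted values as predictor,
#' weight 1.  Degrees of freedom are `sum(k_i) - 2`.
#'
#' @inheritParams build_offspring_parent
#' @return a `qh_pairs` object.
#' @export
build_midparent <- function(pedigree, adjusted,
                            dependent = c("adjusted", "raw"),
                            phenotypes = NULL) {
  dependent <- match.arg(dependent)
  off <- offspring_rows(pedigree)
  adj <- value_lookup(adjusted)
  dep <- dependent_values(off$individual_id, adj, dependent, phenotypes)
  fa <- unname(adj[off$father_id])
  mo <- unname(adj[off$mother_id])
  usable <- !is.na(dep) & !is.na(fa) & !is.na(mo)
  o <- off[usable, , drop = FALSE]
  if (nrow(o) == 0L)
    qh_validation_error("no offspring with both parents phenotyped")
  pairs <- data.frame(family_id = o$family_id,
                      dependent_value = dep[usable],
                      predictor_value = (fa[usable] + mo[usable]) / 2,
                      weight = 1, stringsAsFactors = FALSE)
  k <- table(o$family_id)
  new_pair_set(pairs, "offspring_midparent", df = sum(k) - 2L,
               n_families = length(k),
               n_excluded = sum(!is.na(dep)) - nrow(o))
}

#' Build double-entry full-sib pairs
#'
#' Sibships are sets of offspring sharing both parents (identified by
#' `(family_id, father_id, mother_id)`; half-sibs are excluded).  A sibship
#' of size k contributes all k(k-1) ordered pairs, so both variables share
#' one marginal distribution and the regression slope equals the
#' correlation.  Degrees of freedom are `sum(k_i - 1)` over sibships.
#'
#' @inheritParams build_offspring_parent
#' @return a `qh_pairs` object.
#' @export
build_full_sib <- function(pedigree, adjusted,
                           dependent = c("adjusted", "raw"),
                           phenotypes = NULL) {
  dependent <- match.arg(dependent)
  off <- offspring_rows(pedigree)
  off <- off[!is.na(off$father_id) & !is.na(off$mother_id), , drop = FALSE]
  adj <- value_lookup(adjusted)
  dep <- dependent_values(off$individual_id, adj, dependent, phenotypes)
  pred <- unname(adj[off$individual_id])
  usable <- !is.na(dep) & !is.na(pred)
  o <- off[usable, , drop = FALSE]
  dep <- dep[usable]; pred <- pred[usable]
  sibship <- paste(o$family_id, o$father_id, o$mother_id, sep = "\r")
  by_sib <- split(seq_along(sibship), sibship)
  sizes <- lengths(by_sib)
  out <- vector("list", length(sizes))
  n_out <- 0L
  for (rows in by_sib[sizes >= 2]) {
    grid <- expand.grid(i = rows, j = rows)
    grid <- grid[grid$i != grid$j, , drop = FALSE]
    n_out <- n_out + 1L
    out[[n_out]] <- data.frame(family_id = o$family_id[grid$i],
                               dependent_value = dep[grid$i],
                               predictor_value = pred[grid$j],
                               weight = 1, stringsAsFactors = FALSE)
  }
  pairs <- if (n_out > 0) do.call(rbind, out[seq_len(n_out)]) else
    data.frame(family_id = character(), dependent_value = numeric(),
               predictor_value = numeric(), weight = numeric())
  if (nrow(pairs) == 0L)
    qh_validation_error("no sibships of size >= 2 with phenotyped members")
  new_pair_set(pairs, "full_sib", df = sum(sizes - 1L),
               n_families = sum(sizes >= 2),
               n_excluded = sum(sizes == 1))
}

#' Spouse correlation of adjusted phenotypes
#'
#' Pearson correlation between spouses' adjusted values, computed on
#' double-entered couples so the estimate is symmetric in spouse ordering.
#'
#' @inheritParams build_offspring_parent
#' @return a single correlation.
#' @export
spouse_correlation <- function(pedigree, adjusted) {
  off <- offspring_rows(pedigree)
  couples <- unique(off[!is.na(off$father_id) & !is.na(off$mother_id),
                        c("father_id", "mother_id")])
  adj <- value_lookup(adjusted)
  x <- unname(adj[couples$father_id])
  y <- unname(adj[couples$mother_id])
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    qh_validation_error("spouse correlation needs at least 3 phenotyped ",
                        "couples; got ", sum(ok))
  cor(c(x[ok], y[ok]), c(y[ok], x[ok]))
}
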