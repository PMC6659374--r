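#' Normalize concentrations to creatinine
#'
#' Expresses every metabolite per mmol of creatinine, removing
#' urine-dilution variation: `value_norm = value[umol/L] /
#' creatinine[mmol/L]`. The creatinine column itself (identically 100
#' after self-normalization) is dropped. Samples whose creatinine is
#' absent or non-positive cannot be normalized and are excluded, with
#' their ids recorded in `attr(., "excluded_samples")`.
#'
#' @param table A [conc_table()] in umol/L containing a `creatinine`
#'   column.
#' @return A [conc_table()] in umol/mmol creatinine, one column fewer.
#' @export
normalize_to_creatinine <- function(table) {
  stopifnot(inherits(table, "conc_table"))
  if (table$units != "umol_per_L")
    stop("normalize_to_creatinine expects umol_per_L input, got ",
         table$units)
  mets <- colnames(table$values)
  if (!"creatinine" %in% mets) stop("no creatinine column present")
  crea_umol <- table$values[, "creatinine"]
  crea_absent <- table$absent_mask[, "creatinine"]
  bad <- crea_absent | !is.finite(crea_umol) | crea_umol <= 0
  if (all(bad)) stop("creatinine absent or non-positive for every sample")
  keep_mets <- setdiff(mets, "creatinine")
  v <- table$values[!bad, keep_mets, drop = FALSE] /
    (crea_umol[!bad] / 1000)
  out <- conc_table(v, units = "umol_per_mmol_creatinine",
                    absent_mask = table$absent_mask[!bad, keep_mets,
                                                    drop = FALSE])
  attr(out, "excluded_samples") <- rownames(table$values)[bad]
  out
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean` with the sample SD (n-1 denominator). Scale-invariant
#' for positive scalings.
#'
#' @param values Numeric vector, n >= 2 after NA removal.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("cv_percent needs n >= 2 values")
  m <- mean(values)
  if (m == 0) stop("cv_percent undefined: mean is zero")
  100 * sd(values) / m
}

#' Intra-assay CV% per metabolite
#'
#' CV over replicate preparations of one physical sample (the whole
#' quantitative process: preparation, measurement, fitting). With several
#' replicate groups the per-group CVs are averaged arithmetically.
#'
#' @param table A [conc_table()] (any units; replicates share one truth).
#' @param design A [cohort_design()] with `replicate_group` set for the
#'   replicate samples.
#' @return Named numeric vector of CV% per metabolite, with the number of
#'   usable replicate groups as `attr(., "n_groups")`.
#' @export
intra_assay_cv <- function(table, design) {
  s <- design$samples
  grp <- split(s$sample_id, s$replicate_group)
  grp <- grp[vapply(grp, length, 1L) >= 2]
  if (!length(grp)) stop("no replicate group of size >= 2 in design")
  v <- table$values
  v[table$absent_mask] <- NA
  out <- sapply(colnames(v), function(met) {
    cvs <- vapply(grp, function(ids) {
      vals <- v[intersect(ids, rownames(v)), met]
      if (sum(!is.na(vals)) < 2) return(NA_real_)
      cv_percent(vals)
    }, numeric(1))
    mean(cvs, na.rm = TRUE)
  })
  attr(out, "n_groups") <- length(grp)
  out
}

#' Intra-individual CV% per metabolite
#'
#' Day-to-day variation: a CV is computed per individual over their
#' collection days, then averaged (unweighted) across individuals.
#' Conventionally computed on creatinine-normalized values — pass the
#' output of [normalize_to_creatinine()].
#'
#' @param table A [conc_table()].
#' @param design A [cohort_design()] with `collection_day` populated.
#' @return Named numeric vector of CV% per metabolite; individuals with
#'   fewer than 2 usable days are skipped with a warning.
#' @export
intra_individual_cv <- function(table, design) {
  s <- design$samples
  s <- s[s$sample_id %in% rownames(table$values), ]
  per_ind <- split(s$sample_id, s$individual)
  usable <- per_ind[vapply(per_ind, length, 1L) >= 2]
  if (length(usable) < length(per_ind))
    warning(length(per_ind) - length(usable),
            " individual(s) with < 2 collection days skipped")
  if (!length(usable)) stop("no individual with >= 2 collection days")
  v <- table$values
  v[table$absent_mask] <- NA
  sapply(colnames(v), function(met) {
    cvs <- vapply(usable, function(ids) {
      vals <- v[ids, met]
      if (sum(!is.na(vals)) < 2) return(NA_real_)
      cv_percent(vals)
    }, numeric(1))
    mean(cvs, na.rm = TRUE)
  })
}

#' Inter-individual CV% per metabolite
#'
#' Population variation across individuals, on creatinine-normalized
#' values. With several samples per individual, per-individual means are
#' taken first when `average_individuals = TRUE` (default).
#'
#' @param table A [conc_table()].
#' @param design A [cohort_design()].
#' @param average_individuals Average repeated samples per individual
#'   before taking the CV.
#' @return Named numeric vector of CV% per metabolite.
#' @export
inter_individual_cv <- function(table, design,
                                average_individuals = TRUE) {
  s <- design$samples
  s <- s[s$sample_id %in% rownames(table$values), ]
  v <- table$values
  v[table$absent_mask] <- NA
  sapply(colnames(v), function(met) {
    vals <- v[s$sample_id, met]
    if (average_individuals)
      vals <- tapply(vals, s$individual, mean, na.rm = TRUE)
    vals <- vals[is.finite(vals)]
    if (length(vals) < 2) return(NA_real_)
    cv_percent(vals)
  })
}

#' Three-layer variability report
#'
#' Convenience wrapper assembling intra-assay, intra-individual and
#' inter-individual CV% (each layer computed only where the design
#' provides it) plus the absent fraction per metabolite.
#'
#' @param table A [conc_table()] (creatinine-normalized for the two
#'   biological layers, by convention).
#' @param design A [cohort_design()].
#' @return data.frame, one row per metabolite.
#' @export
cv_report <- function(table, design) {
  mets <- colnames(table$values)
  out <- data.frame(metabolite = mets,
                    intra_assay_cv = NA_real_,
                    intra_individual_cv = NA_real_,
                    inter_individual_cv = NA_real_,
                    absent_fraction = colMeans(table$absent_mask),
                    row.names = NULL)
  s <- design$samples
  if (any(!is.na(s$replicate_group)))
    out$intra_assay_cv <- unname(intra_assay_cv(table, design)[mets])
  multi_day <- any(tapply(s$collection_day, s$individual,
                          function(d) sum(!is.na(d)) >= 2))
  if (isTRUE(multi_day))
    out$intra_individual_cv <-
      unname(intra_individual_cv(table, design)[mets])
  if (length(unique(s$individual)) >= 2)
    out$inter_individual_cv <-
      unname(inter_individual_cv(table, design)[mets])
  out
}

#' Below-detection statistics
#'
#' Marks entries absent under the limit-of-detection rule `area <
#' lod_mult x noise-equivalent area` (3x by default) and reports the
#' absent fraction per metabolite. With `noise_equiv = NULL` the table's
#' existing absent mask is summarised instead.
#'
#' @param table A [conc_table()].
#' @param noise_equiv Named vector: noise-equivalent value per metabolite
#'   on the table's scale (e.g. the concentration a 1-SD-noise-sized area
#'   would convert to).
#' @param lod_mult LOD multiplier (default 3; 0 disables the rule).
#' @return List: `fraction` (named per-metabolite absent fraction),
#'   `mask` (the updated logical matrix).
#' @export
absence_stats <- function(table, noise_equiv = NULL, lod_mult = 3) {
  mask <- table$absent_mask
  if (!is.null(noise_equiv) && lod_mult > 0) {
    for (met in intersect(colnames(table$values), names(noise_equiv)))
      mask[, met] <- mask[, met] |
        (table$values[, met] < lod_mult * noise_equiv[[met]])
  }
  list(fraction = colMeans(mask), mask = mask)
}
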