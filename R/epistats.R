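#' Log-transform and scale metabolic measures to SD units
#'
#' Natural log followed by column standardization (subtract the mean,
#' divide by the sample SD). Strictly positive input is required under the
#' default policy; `pseudo_policy = "exclude"` turns non-positive or
#' absent entries into NA instead (excluded column-wise from the moments).
#'
#' @param table A [conc_table()], matrix or data.frame (samples x
#'   measures).
#' @param pseudo_policy `"strict"` (error on non-positive values, naming
#'   the offending cell) or `"exclude"`.
#' @param fluid Optional per-measure source tag (e.g. "urine"/"serum"),
#'   recycled and stored alongside.
#' @return A `scaled_matrix`: the standardized matrix with attributes
#'   `center`, `scale`, `fluid`.
#' @export
log_sd_scale <- function(table, pseudo_policy = c("strict", "exclude"),
                         fluid = NULL) {
  pseudo_policy <- match.arg(pseudo_policy)
  m <- if (inherits(table, "conc_table")) {
    v <- table$values
    v[table$absent_mask] <- NA          # absent entries never enter
    v
  } else as.matrix(table)
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    if (pseudo_policy == "strict")
      stop("non-positive value at sample '",
           rownames(m)[bad[1, 1]] %||% bad[1, 1], "', measure '",
           colnames(m)[bad[1, 2]] %||% bad[1, 2],
           "'; log undefined (use pseudo_policy='exclude')")
    m[bad] <- NA
  }
  lm_ <- log(m)
  ctr <- colMeans(lm_, na.rm = TRUE)
  scl <- apply(lm_, 2, sd, na.rm = TRUE)
  if (any(!is.finite(scl) | scl == 0))
    stop("constant (zero-SD) column: ",
         paste(colnames(m)[!is.finite(scl) | scl == 0], collapse = ", "))
  z <- sweep(sweep(lm_, 2, ctr), 2, scl, "/")
  structure(z, center = ctr, scale = scl,
            fluid = if (is.null(fluid)) NULL else
              rep_len(fluid, ncol(z)),
            class = c("scaled_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partial correlation of two variables given covariates
#'
#' Residualizes `x` and `y` on the covariates (with intercept) by least
#' squares, correlates the residuals, and tests with
#' `t = r sqrt((n - 2 - q) / (1 - r^2))` on `n - 2 - q` df, `q` the number
#' of covariates. Complete cases only.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector, matrix or data.frame (or NULL for the
#'   marginal correlation).
#' @return List `(r, p, n)`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  cc <- is.finite(x) & is.finite(y)
  if (!is.null(C)) cc <- cc & apply(C, 1, function(r) all(is.finite(r)))
  q <- if (is.null(C)) 0L else ncol(C)
  n <- sum(cc)
  if (n <= q + 2) stop("insufficient complete cases: n = ", n,
                       " with q = ", q, " covariates")
  x <- x[cc]; y <- y[cc]
  if (!is.null(C)) {
    D <- cbind(1, C[cc, , drop = FALSE])
    x <- lm.fit(D, x)$residuals
    y <- lm.fit(D, y)$residuals
  }
  r <- cor(x, y)
  df <- n - 2L - q
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tt), df), n = n)
}

#' Pairwise partial-correlation map
#'
#' All pairwise sex-adjusted (or otherwise-adjusted) partial correlations
#' between two sets of measures, with a significance mask at a supplied
#' threshold and an ordering: a caller-supplied list (pathway-organised
#' maps) or average-linkage hierarchical clustering on `1 - |r|`.
#' Pairwise-complete observations per pair.
#'
#' @param scaled A [log_sd_scale()] output (or plain matrix).
#' @param covariates Covariate vector/matrix aligned on rows.
#' @param subset_a,subset_b Column names of the two sides (defaults: all
#'   columns on both sides — a square intra-fluid map).
#' @param ordering `"given"` (keep supplied order), `"cluster"`, or a
#'   character vector giving an explicit order.
#' @param p_threshold Significance threshold for the mask.
#' @return A `correlation_map`: `r` and `p` matrices, logical
#'   `significant`, `order_a`/`order_b`, and summary stats `median_abs_r`,
#'   `iqr_abs_r` over the off-diagonal (square case) or all (rectangular)
#'   pairs.
#' @export
correlation_map <- function(scaled, covariates = NULL,
                            subset_a = colnames(scaled),
                            subset_b = colnames(scaled),
                            ordering = "given", p_threshold = 0.05) {
  if (!length(subset_a) || !length(subset_b))
    stop("subsets must be non-empty")
  A <- as.matrix(scaled)[, subset_a, drop = FALSE]
  B <- as.matrix(scaled)[, subset_b, drop = FALSE]
  r <- matrix(NA_real_, ncol(A), ncol(B),
              dimnames = list(subset_a, subset_b))
  p <- r
  for (i in seq_along(subset_a)) for (j in seq_along(subset_b)) {
    if (identical(subset_a[i], subset_b[j])) { r[i, j] <- 1; p[i, j] <- 0; next }
    pc <- partial_correlation(A[, i], B[, j], covariates)
    r[i, j] <- pc$r; p[i, j] <- pc$p
  }
  square <- identical(subset_a, subset_b)
  vals <- if (square) abs(r[upper.tri(r)]) else abs(as.vector(r))
  ord_a <- subset_a; ord_b <- subset_b
  if (identical(ordering, "cluster")) {
    if (square) {
      hc <- hclust(as.dist(1 - abs(r)), method = "average")
      ord_a <- ord_b <- subset_a[hc$order]
    } else {
      ha <- hclust(dist(abs(r)), method = "average")
      hb <- hclust(dist(t(abs(r))), method = "average")
      ord_a <- subset_a[ha$order]; ord_b <- subset_b[hb$order]
    }
  } else if (is.character(ordering) && length(ordering) > 1) {
    ord_a <- intersect(ordering, subset_a)
    ord_b <- intersect(ordering, subset_b)
  }
  structure(list(r = r[ord_a, ord_b, drop = FALSE],
                 p = p[ord_a, ord_b, drop = FALSE],
                 significant = (p < p_threshold)[ord_a, ord_b,
                                                 drop = FALSE],
                 order_a = ord_a, order_b = ord_b,
                 median_abs_r = median(vals),
                 iqr_abs_r = unname(quantile(vals, c(0.25, 0.75))),
                 p_threshold = p_threshold),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf(paste0("<correlation_map> %d x %d: median |r| %.3f ",
                     "(IQR %.3f-%.3f), %d significant at p < %g\n"),
              nrow(x$r), ncol(x$r), x$median_abs_r, x$iqr_abs_r[1],
              x$iqr_abs_r[2], sum(x$significant, na.rm = TRUE),
              x$p_threshold))
  invisible(x)
}

#' Effective number of independent tests
#'
#' Number of principal components needed to explain strictly more than
#' `threshold` of the variance of the column correlation matrix — the
#' count used to relax Bonferroni correction among correlated measures.
#'
#' @param scaled Matrix of measures (rows = individuals).
#' @param threshold Cumulative variance share to exceed (default 0.99).
#' @return Integer `m_eff`.
#' @export
effective_tests <- function(scaled, threshold = 0.99) {
  m <- as.matrix(scaled)
  if (anyNA(m)) stop("effective_tests requires complete data")
  if (nrow(m) < 2) stop("need more than one individual")
  ev <- eigen(cor(m), symmetric = TRUE, only.values = TRUE)$values
  share <- cumsum(ev) / sum(ev)
  as.integer(which(share > threshold)[1])
}

#' Bonferroni threshold with reporting-style rounding
#'
#' `alpha / m_eff`; with `rounding = "signif1"` the result is rounded to
#' one significant figure, the convention used when quoting corrected
#' thresholds (0.05/40 -> 0.001, 0.05/27 -> 0.002, 0.05/66 -> 0.0008).
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m_eff Effective number of tests (>= 1).
#' @param rounding `"none"` (exact) or `"signif1"`.
#' @return The threshold.
#' @export
bonferroni_threshold <- function(alpha, m_eff,
                                 rounding = c("none", "signif1")) {
  rounding <- match.arg(rounding)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m_eff < 1) stop("m_eff must be >= 1")
  th <- alpha / m_eff
  if (rounding == "signif1") signif(th, 1) else th
}

#' Per-outcome exposure association in SD units
#'
#' Ordinary least squares of each SD-scaled outcome on the exposure
#' (SD-scaled itself by default, so the slope is SD-per-SD), optionally
#' adjusted for covariates. Listwise complete cases within each
#' regression.
#'
#' @param scaled A [log_sd_scale()] output (outcomes in columns).
#' @param exposure Numeric vector (e.g. BMI in kg/m^2).
#' @param covariates Optional covariate matrix/vector.
#' @param scale_exposure SD-scale the exposure first (default TRUE).
#' @return data.frame: `outcome`, `beta` (SD units), `se`, `p`, `n`.
#' @export
exposure_association <- function(scaled, exposure, covariates = NULL,
                                 scale_exposure = TRUE) {
  if (sd(exposure, na.rm = TRUE) == 0) stop("constant exposure")
  e <- if (scale_exposure)
    (exposure - mean(exposure, na.rm = TRUE)) / sd(exposure, na.rm = TRUE)
  else exposure
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  out <- lapply(colnames(scaled), function(met) {
    y <- scaled[, met]
    cc <- is.finite(y) & is.finite(e)
    if (!is.null(C)) cc <- cc & apply(C, 1, function(r) all(is.finite(r)))
    D <- cbind(`(Intercept)` = 1, exposure = e[cc],
               if (!is.null(C)) C[cc, , drop = FALSE])
    fit <- lm.fit(D, y[cc])
    n <- sum(cc); k <- ncol(D)
    sigma2 <- sum(fit$residuals^2) / (n - k)
    XtXinv <- chol2inv(chol(crossprod(D)))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    beta <- fit$coefficients[["exposure"]]
    data.frame(outcome = met, beta = beta, se = se,
               p = 2 * pt(-abs(beta / se), n - k), n = n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Inverse rank-based normal transformation
#'
#' Blom scores: `qnorm((rank - 3/8) / (n + 1/4))` with average ranks for
#' ties. Invariant under monotone rescaling of the input. An all-tied
#' input degenerates to all zeros (flagged via `attr(., "degenerate")`).
#'
#' @param values Numeric vector, n >= 3 (NAs propagated).
#' @return Normal scores, same length and order.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) stop("inverse_normal_transform needs n >= 3")
  out <- rep(NA_real_, length(values))
  if (length(unique(values[ok])) == 1L) {
    out[ok] <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Genotype dosage matrix
#'
#' @param dosage Individuals x variants matrix of expected allele dosages
#'   in [0, 2], with dimnames.
#' @param info Per-variant imputation info score in [0, 1] (default 1).
#' @param map Optional data.frame `variant`, `chromosome`, `position`.
#' @return A `genotype_matrix` list with per-variant MAF
#'   (`min(p, 1 - p)` of mean dosage / 2) precomputed.
#' @export
genotype_matrix <- function(dosage, info = NULL, map = NULL) {
  dosage <- as.matrix(dosage)
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("var", seq_len(ncol(dosage)))
  p <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  if (is.null(info)) info <- rep(1, ncol(dosage))
  if (any(info < 0 | info > 1, na.rm = TRUE))
    stop("info scores must lie in [0, 1]")
  structure(list(dosage = dosage, maf = maf,
                 info = setNames(info, colnames(dosage)), map = map),
            class = "genotype_matrix")
}

#' Read a genotype dosage matrix from TSV
#'
#' Rows are individuals (first column id), columns variants; optional
#' trailing header rows are not supported — info scores come in a
#' companion two-column TSV (`variant`, `info`).
#'
#' @param path Dosage TSV.
#' @param info_path Optional info-score TSV.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, info_path = NULL) {
  df <- read_table(path, as_data_frame = TRUE)
  m <- as.matrix(df)
  mode(m) <- "numeric"
  info <- NULL
  if (!is.null(info_path)) {
    it <- read.delim(info_path, stringsAsFactors = FALSE)
    info <- it$info[match(colnames(m), it$variant)]
  }
  genotype_matrix(m, info = info)
}

#' Additive genetic association scan
#'
#' The phenotype is residualized on the covariates (sex plus leading
#' genomic principal components, conventionally), the residuals are
#' inverse-normal transformed, and each variant passing the MAF and
#' imputation-info filters is tested by OLS of the transformed residuals
#' on allele dosage (additive model, Wald p).
#'
#' @param phenotype Named numeric vector (names = individual ids) or plain
#'   vector aligned with the dosage rows.
#' @param genotypes A [genotype_matrix()].
#' @param covariates Optional matrix/data.frame aligned with the
#'   phenotype.
#' @param maf_min MAF filter (default 0.05).
#' @param info_min Info filter (default 0.8).
#' @return data.frame `variant`, `maf`, `info`, `beta`, `se`, `p`, `n`;
#'   filtered variants are absent.
#' @export
genetic_scan <- function(phenotype, genotypes, covariates = NULL,
                         maf_min = 0.05, info_min = 0.8) {
  G <- genotypes$dosage
  if (!is.null(names(phenotype)) && !is.null(rownames(G))) {
    if (!setequal(names(phenotype), rownames(G)))
      stop("phenotype and genotype individuals are misaligned")
    G <- G[names(phenotype), , drop = FALSE]
  } else if (length(phenotype) != nrow(G)) {
    stop("phenotype and genotype individuals are misaligned")
  }
  keep <- genotypes$maf >= maf_min & genotypes$info >= info_min
  G <- G[, keep, drop = FALSE]
  if (!ncol(G)) stop("no variant passes the MAF/info filters")

  y <- as.numeric(phenotype)
  cc <- is.finite(y)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    cc <- cc & apply(C, 1, function(r) all(is.finite(r)))
    D <- cbind(1, C[cc, , drop = FALSE])
    y <- rep(NA_real_, length(phenotype))
    y[cc] <- lm.fit(D, as.numeric(phenotype)[cc])$residuals
  }
  y <- inverse_normal_transform(y)
  use <- is.finite(y)
  y <- y[use]; G <- G[use, , drop = FALSE]
  n <- length(y)

  # vectorized per-variant simple regression
  gm <- colMeans(G)
  Gc <- sweep(G, 2, gm)
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  sxy <- as.numeric(crossprod(Gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  tt <- beta / se
  data.frame(variant = colnames(G),
             maf = unname(genotypes$maf[keep]),
             info = unname(genotypes$info[keep]),
             beta = beta, se = se,
             p = 2 * pt(-abs(tt), n - 2), n = n,
             row.names = NULL)
}
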