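#' Spectrum quality control flags
#'
#' Flags the failure modes that exclude spectra from automated modelling:
#' `shimming` — the TSP reference line is broader than `fwhm_max_hz`
#' (non-optimal field homogeneity broadens every line); `baseline` — the
#' median absolute level in a signal-free zone exceeds
#' `baseline_mult` x the noise SD (distorted baseline; the multiplier
#' default of 30 sits well above the generator's own smooth-baseline
#' amplitude so an ordinary spectrum never trips it); `tsp_missing` — no
#' usable reference peak near 0 ppm. Flags only; the caller decides
#' exclusion.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param fwhm_max_hz Shimming threshold on the TSP FWHM (default 1.8 Hz).
#' @param baseline_mult Baseline threshold multiplier (default 30).
#' @param quiet_zone `c(high, low)` ppm signal-free region.
#' @return Named logical vector `c(shimming, baseline, tsp_missing)` with
#'   the measured TSP FWHM (Hz) and baseline level attached as attributes.
#' @export
qc_spectrum <- function(spectrum, fwhm_max_hz = 1.8, baseline_mult = 30,
                        quiet_zone = c(9.9, 9.5)) {
  noise <- noise_estimate(spectrum, quiet_zone[1], quiet_zone[2])
  idx <- ppm_window(spectrum, 0.1, -0.1)
  x <- spectrum$ppm[idx]; y <- spectrum$intensity[idx]
  pk <- which.max(y)
  tsp_missing <- y[pk] < 50 * max(noise, 1e-300)
  fwhm_hz <- NA_real_
  if (!tsp_missing && pk > 1 && pk < length(y)) {
    half <- y[pk] / 2
    # interpolated half-height crossings either side of the maximum
    right <- pk + which(y[(pk + 1):length(y)] < half)[1]   # lower ppm side
    left <- pk - which(rev(y[1:(pk - 1)]) < half)[1]
    if (!is.na(right) && !is.na(left)) {
      xr <- approx(y[c(right - 1, right)], x[c(right - 1, right)],
                   xout = half)$y
      xl <- approx(y[c(left, left + 1)], x[c(left, left + 1)],
                   xout = half)$y
      fwhm_hz <- abs(xl - xr) * spectrum$frequency_mhz
    }
  }
  qidx <- ppm_window(spectrum, quiet_zone[1], quiet_zone[2])
  base_level <- median(abs(spectrum$intensity[qidx]))
  flags <- c(shimming = isTRUE(fwhm_hz > fwhm_max_hz),
             baseline = base_level > baseline_mult * max(noise, 1e-300),
             tsp_missing = tsp_missing)
  attr(flags, "tsp_fwhm_hz") <- fwhm_hz
  attr(flags, "baseline_level") <- base_level
  attr(flags, "noise_sd") <- noise
  flags
}

#' Extract binned spectral features
#'
#' Mean intensity in equal-width ppm bins, one window after another in
#' declared order (bins run from the high-ppm edge down, matching display
#' orientation). Linear in the spectrum.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param windows data.frame with columns `high_ppm`, `low_ppm`, `n_bins`.
#' @return Numeric feature vector of length `sum(n_bins)`.
#' @export
extract_features <- function(spectrum, windows) {
  stopifnot(all(c("high_ppm", "low_ppm", "n_bins") %in% names(windows)))
  out <- numeric(0)
  for (i in seq_len(nrow(windows))) {
    hi <- windows$high_ppm[i]; lo <- windows$low_ppm[i]
    nb <- windows$n_bins[i]
    if (hi > spectrum$ppm[1] || lo < spectrum$ppm[length(spectrum$ppm)])
      stop("feature window [", hi, ", ", lo, "] outside spectrum axis")
    edges <- seq(hi, lo, length.out = nb + 1)
    vals <- vapply(seq_len(nb), function(b) {
      idx <- ppm_window(spectrum, edges[b], edges[b + 1])
      if (!length(idx)) return(NA_real_)
      mean(spectrum$intensity[idx])
    }, numeric(1))
    if (anyNA(vals))
      stop("feature window [", hi, ", ", lo, "] has empty bins at this ",
           "spectral resolution; reduce n_bins")
    out <- c(out, vals)
  }
  out
}

#' Default feature windows for the packaged automated models
#'
#' The metabolite's own fit window plus its known interfering neighbour
#' region, binned at roughly the linewidth scale.
#'
#' @param metabolite `"creatinine"` or `"glucose"`.
#' @return data.frame of feature windows.
#' @export
default_feature_windows <- function(metabolite) {
  switch(metabolite,
    creatinine = data.frame(high_ppm = c(3.14, 4.20),
                            low_ppm = c(2.96, 3.95),
                            n_bins = c(36, 30)),
    glucose = data.frame(high_ppm = c(5.40, 3.65),
                         low_ppm = c(5.05, 3.30),
                         n_bins = c(42, 30)),
    stop("no packaged feature windows for '", metabolite,
         "'; supply your own"))
}

# closed-form ridge on standardized predictors; returns function-ready
# coefficients on the raw feature scale
ridge_solve <- function(X, y, lambda) {
  mx <- colMeans(X)
  sx <- apply(X, 2, sd)
  sx[sx == 0] <- 1                      # constant bins carry no signal
  Z <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y)
  p <- ncol(Z)
  beta_s <- solve(crossprod(Z) + diag(lambda, p), crossprod(Z, y - my))
  beta <- as.numeric(beta_s) / sx
  list(coefficients = beta, intercept = my - sum(beta * mx))
}

ridge_cv <- function(X, y, lambda_grid, k = 5, seed = 1) {
  set.seed(seed)
  n <- nrow(X)
  fold <- sample(rep(seq_len(k), length.out = n))
  errs <- sapply(lambda_grid, function(lam) {
    se <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- ridge_solve(X[tr, , drop = FALSE], y[tr], lam)
      pred <- X[!tr, , drop = FALSE] %*% m$coefficients + m$intercept
      se <- se + sum((y[!tr] - pred)^2)
    }
    se / n
  })
  lambda_grid[which.min(errs)]
}

# concentration-tertile-stratified train/test split
stratified_split <- function(y, train_frac = 2 / 3, seed = 1) {
  set.seed(seed)
  qs <- quantile(y, c(1 / 3, 2 / 3))
  stratum <- findInterval(y, qs, rightmost.closed = FALSE) + 1L
  train <- logical(length(y))
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    train[sample(idx, round(train_frac * length(idx)))] <- TRUE
  }
  train
}

#' Train an automated regression quantification model
#'
#' Ridge-penalized linear regression of reference CTLS signal areas on
#' binned spectral intensities: the fully automated stand-in for the
#' interactive line-shape fit, reducing quantification of a new spectrum
#' to one dot product. The penalty is chosen by k-fold cross-validation on
#' a concentration-stratified training split; agreement on the held-out
#' split is summarised by [bland_altman()].
#'
#' @param spectra List of QC-passing [nmr_spectrum()]s.
#' @param labels Numeric vector of reference areas (converged CTLS fits),
#'   aligned with `spectra`.
#' @param metabolite Metabolite name (also selects default windows).
#' @param windows Feature windows (default [default_feature_windows()]).
#' @param lambda_grid Ridge penalty grid.
#' @param train_frac Training fraction (default 2/3 for a 2:1 split).
#' @param k Cross-validation folds (default 5).
#' @param seed Integer seed; training is deterministic under it.
#' @return A `quant_model`: feature windows, coefficients, intercept,
#'   chosen lambda, training metadata, and `agreement`
#'   (the held-out [bland_altman()] report).
#' @export
train_quant_model <- function(spectra, labels, metabolite,
                              windows = default_feature_windows(metabolite),
                              lambda_grid = 10^seq(-6, 2, by = 1),
                              train_frac = 2 / 3, k = 5, seed = 1) {
  n <- length(spectra)
  if (n < 50) stop("need at least 50 spectra to train (got ", n, ")")
  if (length(labels) != n) stop("labels must align with spectra")
  if (sd(labels) == 0) stop("degenerate labels: zero variance")
  X <- t(vapply(spectra, extract_features, numeric(sum(windows$n_bins)),
                windows = windows))
  train <- stratified_split(labels, train_frac, seed)
  lam <- ridge_cv(X[train, , drop = FALSE], labels[train], lambda_grid,
                  k = k, seed = seed + 1L)
  m <- ridge_solve(X[train, , drop = FALSE], labels[train], lam)
  pred_test <- as.numeric(X[!train, , drop = FALSE] %*% m$coefficients +
                            m$intercept)
  agreement <- bland_altman(pred_test, labels[!train])
  structure(list(metabolite = metabolite, windows = windows,
                 coefficients = m$coefficients, intercept = m$intercept,
                 lambda = lam, n_train = sum(train), n_test = sum(!train),
                 seed = seed, cv_folds = k, agreement = agreement),
            class = "quant_model")
}

#' @export
print.quant_model <- function(x, ...) {
  cat(sprintf("<quant_model> %s: %d features, lambda %.3g, trained on %d\n",
              x$metabolite, length(x$coefficients), x$lambda, x$n_train))
  a <- x$agreement
  cat(sprintf("  held-out (n=%d): slope %.4f, mean bias %.4g [%.4g, %.4g]\n",
              a$n, a$slope, a$mean_bias, a$loa_lower, a$loa_upper))
  invisible(x)
}

#' Predict a signal area from a spectrum
#'
#' Linear prediction from binned features; negative predictions are
#' clipped to 0 and flagged (`attr(., "clipped")`) — near-zero urinary
#' concentrations routinely predict slightly negative.
#'
#' @param object A `quant_model`.
#' @param spectrum An [nmr_spectrum()] or list of them.
#' @param ... Unused.
#' @return Numeric area(s).
#' @export
predict.quant_model <- function(object, spectrum, ...) {
  if (inherits(spectrum, "nmr_spectrum")) spectrum <- list(spectrum)
  raw <- vapply(spectrum, function(sp)
    sum(extract_features(sp, object$windows) * object$coefficients) +
      object$intercept, numeric(1))
  out <- pmax(raw, 0)
  attr(out, "clipped") <- raw < 0
  out
}

#' Bland-Altman method agreement
#'
#' Differences `d = predicted - reference`: mean bias, limits of agreement
#' `mean(d) +/- 1.96 sd(d)` (sample SD, n-1), plus the ordinary
#' least-squares line of predicted on reference and of the bias on the
#' reference (with R^2 — a flat, near-zero-R^2 bias line is the signature
#' of agreement that does not degrade across the concentration range).
#'
#' @param predicted,reference Equal-length numeric vectors, n >= 3.
#' @return An `agreement_report` list: `mean_bias`, `loa_lower`,
#'   `loa_upper`, `slope`, `intercept`, `bias_slope`, `bias_intercept`,
#'   `bias_r2`, `n`.
#' @export
bland_altman <- function(predicted, reference) {
  n <- length(predicted)
  if (length(reference) != n) stop("length mismatch")
  if (n < 3) stop("need n >= 3 pairs")
  d <- predicted - reference
  bias <- mean(d)
  s <- sd(d)
  # closed-form simple regressions (stable for degenerate perfect fits)
  sxx <- sum((reference - mean(reference))^2)
  if (sxx == 0) stop("reference values are constant")
  slope <- sum((reference - mean(reference)) *
                 (predicted - mean(predicted))) / sxx
  bslope <- sum((reference - mean(reference)) * (d - bias)) / sxx
  sdd <- sum((d - bias)^2)
  r2 <- if (sdd == 0) 0 else bslope^2 * sxx / sdd
  structure(list(mean_bias = bias,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 slope = slope,
                 intercept = mean(predicted) - slope * mean(reference),
                 bias_slope = bslope,
                 bias_intercept = bias - bslope * mean(reference),
                 bias_r2 = r2, n = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement> n=%d: bias %.4g [LoA %.4g, %.4g]; ",
                     "pred~ref slope %.4f; bias~ref R^2 %.2g\n"),
              x$n, x$mean_bias, x$loa_lower, x$loa_upper, x$slope,
              x$bias_r2))
  invisible(x)
}

#' Serialize / restore an automated quantification model
#'
#' Plain-JSON round trip (windows, coefficients, metadata) so trained
#' models can ship as text.
#'
#' @param model A `quant_model`.
#' @param path JSON path.
#' @return `path` / the restored `quant_model`.
#' @export
write_quant_model <- function(model, path) {
  obj <- unclass(model)
  obj$agreement <- unclass(obj$agreement)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_quant_model
#' @export
read_quant_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$windows <- as.data.frame(obj$windows)
  obj$agreement <- structure(as.list(obj$agreement),
                             class = "agreement_report")
  structure(obj, class = "quant_model")
}
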