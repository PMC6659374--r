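#' Simulation configuration
#'
#' Collects the knobs of the synthetic urine spectrum generator. Defaults
#' describe the emulated acquisition: a 600 MHz spectrum of a 5-mm tube
#' prepared as 630 ul urine + 70 ul buffer (dilution 700/630) with TSP as
#' internal chemical-shift and concentration reference, water suppression
#' leaving a 4.50-5.00 ppm dead zone, ~1 Hz lines, a smooth baseline and
#' additive Gaussian noise.
#'
#' @param ppm_max,ppm_min,n_points Axis: 32768 points over 10 .. -0.5 ppm.
#' @param frequency_mhz Spectrometer frequency (MHz).
#' @param linewidth_hz Default line FWHM in Hz.
#' @param noise_sd Additive Gaussian noise SD as a fraction of the TSP peak
#'   height (default 5e-4).
#' @param jitter Scale factor on per-group shift jitter: each group's centre
#'   is perturbed uniformly within `+/- jitter * mobility_ppm` per sample
#'   (the pH / ionic-strength proxy).
#' @param baseline_amplitude SD of the signed amplitudes of the baseline
#'   Gaussians, as a fraction of the TSP peak height (default 2e-3, i.e. a
#'   few multiples of the default noise SD).
#' @param baseline_n,baseline_fwhm_range Number of broad baseline Gaussians
#'   and their FWHM range in ppm (>= 1 ppm keeps the baseline smooth at the
#'   scale line-shape fitting assumes).
#' @param water_zone `c(low, high)` ppm interval attenuated by water
#'   suppression.
#' @param water_attenuation Multiplicative attenuation inside the zone.
#' @param tsp_conc_mmol_per_L In-tube TSP concentration (mmol/L).
#' @param dilution Tube volume over urine volume (700/630).
#' @param freeze_jitter If `TRUE`, [simulate_replicates()] reuses one jitter
#'   draw across replicates (replicates share a single tube, so shift
#'   positions are common while noise and baseline are not).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ppm_max = 10.0, ppm_min = -0.5, n_points = 32768L,
                       frequency_mhz = 600, linewidth_hz = 1.0,
                       noise_sd = 5e-4, jitter = 1.0,
                       baseline_amplitude = 0.002, baseline_n = 3L,
                       baseline_fwhm_range = c(1, 3),
                       water_zone = c(4.50, 5.00),
                       water_attenuation = 1e-3,
                       tsp_conc_mmol_per_L = 0.5,
                       dilution = 700 / 630,
                       freeze_jitter = FALSE) {
  if (ppm_max <= ppm_min) stop("ppm_max must exceed ppm_min")
  if (n_points < 2) stop("n_points must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (dilution < 1) stop("dilution must be >= 1")
  structure(list(ppm_max = ppm_max, ppm_min = ppm_min,
                 n_points = as.integer(n_points),
                 frequency_mhz = frequency_mhz,
                 linewidth_hz = linewidth_hz, noise_sd = noise_sd,
                 jitter = jitter, baseline_amplitude = baseline_amplitude,
                 baseline_n = as.integer(baseline_n),
                 baseline_fwhm_range = baseline_fwhm_range,
                 water_zone = water_zone,
                 water_attenuation = water_attenuation,
                 tsp_conc_mmol_per_L = tsp_conc_mmol_per_L,
                 dilution = dilution, freeze_jitter = freeze_jitter),
            class = "sim_config")
}

sim_axis <- function(config)
  seq(config$ppm_max, config$ppm_min, length.out = config$n_points)

# TSP reference area in concentration-equivalent units (umol/L x protons);
# all rendered signal areas share this scale, so the TSP ratio recovers
# absolute concentrations.
tsp_ref_area <- function(config) config$tsp_conc_mmol_per_L * 1000 * 9

tsp_peak_height <- function(config) {
  fwhm_ppm <- config$linewidth_hz / config$frequency_mhz
  2 * tsp_ref_area(config) / (pi * fwhm_ppm)
}

# draws one uniform jitter offset per proton group, named metabolite|label
draw_jitter <- function(signatures, config) {
  offs <- list()
  for (sig in signatures) {
    for (g in sig$groups) {
      key <- paste(sig$name, g$label, sep = "|")
      offs[[key]] <- runif(1, -1, 1) * config$jitter * g$mobility_ppm
    }
  }
  offs
}

#' Render one synthetic urine spectrum
#'
#' Sums Lorentzian multiplets for every named metabolite (line areas
#' proportional to in-tube concentration times proton count), adds the TSP
#' 9-proton reference singlet at 0 ppm, a smooth random baseline and iid
#' Gaussian noise, and attenuates the water-suppression zone. Deterministic
#' under a fixed seed.
#'
#' @param signatures Named list of [metabolite_signature()]s.
#' @param concentrations Named vector of in-tube concentrations (umol/L)
#'   for a subset of the signature names.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @param jitter_offsets Optional precomputed jitter (as produced
#'   internally); used to freeze shift positions across replicates.
#' @param sample_id Sample identifier.
#' @return An [nmr_spectrum()]; the realized jitter is attached as
#'   `metadata$jitter`.
#' @export
render_sample <- function(signatures, concentrations, config = sim_config(),
                          seed = NULL, jitter_offsets = NULL,
                          sample_id = "sim") {
  unknown <- setdiff(names(concentrations), names(signatures))
  if (length(unknown))
    stop("no signature for metabolite(s): ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  axis <- sim_axis(config)
  fwhm_ppm <- config$linewidth_hz / config$frequency_mhz
  if (is.null(jitter_offsets))
    jitter_offsets <- draw_jitter(signatures[names(concentrations)], config)

  signal <- numeric(length(axis))
  for (met in names(concentrations)) {
    conc <- concentrations[[met]]
    if (conc == 0) next
    for (g in signatures[[met]]$groups) {
      key <- paste(met, g$label, sep = "|")
      jit <- jitter_offsets[[key]]
      if (is.null(jit)) jit <- 0
      pat <- multiplet_pattern(g$couplings, config$frequency_mhz)
      for (i in seq_len(nrow(pat))) {
        signal <- signal + lorentzian(
          axis, g$center_ppm + jit + pat$offset_ppm[i],
          conc * g$n_protons * pat$weight[i], fwhm_ppm)
      }
    }
  }
  signal <- signal + lorentzian(axis, 0.0, tsp_ref_area(config), fwhm_ppm)

  tsp_h <- tsp_peak_height(config)
  if (config$baseline_amplitude > 0 && config$baseline_n > 0) {
    for (b in seq_len(config$baseline_n)) {
      c0 <- runif(1, config$ppm_min, config$ppm_max)
      fw <- runif(1, config$baseline_fwhm_range[1],
                  config$baseline_fwhm_range[2])
      amp <- rnorm(1, 0, config$baseline_amplitude * tsp_h)
      signal <- signal + amp * exp(-4 * log(2) * ((axis - c0) / fw)^2)
    }
  }
  wz <- config$water_zone
  in_water <- axis >= wz[1] & axis <= wz[2]
  signal[in_water] <- signal[in_water] * config$water_attenuation
  if (config$noise_sd > 0)
    signal <- signal + rnorm(length(axis), 0, config$noise_sd * tsp_h)

  nmr_spectrum(axis, signal, config$frequency_mhz, sample_id,
               metadata = list(jitter = jitter_offsets))
}

cv_to_sigma <- function(cv_pct) {
  if (any(cv_pct < 0)) stop("CV% must be >= 0")
  sqrt(log(1 + (cv_pct / 100)^2))
}

#' Simulate a urine cohort with layered biological variation
#'
#' Individual-level geometric means are drawn log-normal with
#' `sigma = sqrt(log(1 + (CV/100)^2))` from the requested inter-individual
#' CV%; day-level values are drawn log-normal around each individual's mean
#' from the intra-individual CV%. Under the default
#' `cv_scale = "normalized"` the requested CVs describe
#' creatinine-normalized levels (the scale on which urine metabolite
#' variability is conventionally reported): each non-creatinine metabolite
#' is generated as a log-normal normalized level multiplied by the
#' individual's creatinine concentration, which itself carries the
#' urine-dilution variation. `cv_scale = "absolute"` instead applies the
#' CVs directly to the raw concentration columns.
#'
#' @param signatures Named list of signatures; must include creatinine
#'   under the default `cv_scale`.
#' @param n_individuals Number of individuals.
#' @param inter_cv Named vector of inter-individual CV% covering
#'   `names(signatures)`.
#' @param intra_cv Named vector of intra-individual CV% (required when
#'   `days_per_individual > 1`).
#' @param days_per_individual Collection days per individual (>= 1).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param base_conc Named vector of median concentrations (umol/L in neat
#'   urine); defaults to the packaged reference medians.
#' @param cv_scale `"normalized"` (default) or `"absolute"`; see Details.
#' @param bmi_effects Optional named vector: per-SD-of-BMI additive effect
#'   on the metabolite's log level.
#' @param render If `FALSE`, skip spectrum rendering and return truth +
#'   design only (fast path for statistical simulations).
#' @return List with elements `spectra` (list of [nmr_spectrum()], or NULL),
#'   `truth` (a [conc_table()] of neat-urine umol/L), `design`
#'   (a [cohort_design()]) and `config`.
#' @export
simulate_cohort <- function(signatures, n_individuals, inter_cv,
                            intra_cv = NULL, days_per_individual = 1,
                            config = sim_config(), seed = 1,
                            base_conc = NULL,
                            cv_scale = c("normalized", "absolute"),
                            bmi_effects = NULL, render = TRUE) {
  cv_scale <- match.arg(cv_scale)
  mets <- names(signatures)
  missing_cv <- setdiff(mets, names(inter_cv))
  if (length(missing_cv))
    stop("inter_cv missing for: ", paste(missing_cv, collapse = ", "))
  if (days_per_individual > 1) {
    if (is.null(intra_cv)) stop("intra_cv required when days > 1")
    missing_cv <- setdiff(mets, names(intra_cv))
    if (length(missing_cv))
      stop("intra_cv missing for: ", paste(missing_cv, collapse = ", "))
  }
  if (cv_scale == "normalized" && !"creatinine" %in% mets)
    stop("cv_scale='normalized' requires a creatinine signature")
  if (is.null(base_conc)) {
    ref <- urine_reference()
    base_conc <- setNames(ref$median_umol_per_L, ref$metabolite)
  }
  missing_bc <- setdiff(mets, names(base_conc))
  if (length(missing_bc))
    stop("base_conc missing for: ", paste(missing_bc, collapse = ", "))

  set.seed(seed)
  n <- n_individuals
  days <- days_per_individual
  sex <- rbinom(n, 1, 0.5)
  bmi <- rnorm(n, 26, 4)

  sig_inter <- cv_to_sigma(inter_cv[mets])
  sig_intra <- if (days > 1) cv_to_sigma(intra_cv[mets]) else
    setNames(rep(0, length(mets)), mets)

  # per-individual log levels, then per-day log levels
  log_level <- matrix(NA_real_, n * days, length(mets),
                      dimnames = list(NULL, mets))
  for (m in mets) {
    ind <- log(base_conc[[m]]) + rnorm(n, 0, sig_inter[[m]])
    if (!is.null(bmi_effects) && m %in% names(bmi_effects))
      ind <- ind + bmi_effects[[m]] * (bmi - 26) / 4
    day_lvl <- rep(ind, each = days) +
      rnorm(n * days, 0, sig_intra[[m]])
    log_level[, m] <- day_lvl
  }
  truth <- exp(log_level)
  if (cv_scale == "normalized") {
    # non-creatinine columns were drawn as normalized levels relative to
    # the creatinine median; rescale by realized creatinine
    crea <- truth[, "creatinine"]
    other <- setdiff(mets, "creatinine")
    truth[, other] <- truth[, other, drop = FALSE] *
      (crea / base_conc[["creatinine"]])
  }

  sample_id <- sprintf("I%04d_D%02d", rep(seq_len(n), each = days),
                       rep(seq_len(days), times = n))
  rownames(truth) <- sample_id
  design <- cohort_design(
    data.frame(sample_id = sample_id,
               individual = sprintf("I%04d", rep(seq_len(n), each = days)),
               collection_day = rep(seq_len(days), times = n),
               stringsAsFactors = FALSE),
    data.frame(individual = sprintf("I%04d", seq_len(n)),
               sex = sex, bmi = bmi, stringsAsFactors = FALSE))

  spectra <- NULL
  if (render) {
    spectra <- vector("list", nrow(truth))
    names(spectra) <- sample_id
    for (i in seq_len(nrow(truth))) {
      conc_tube <- truth[i, ] / config$dilution
      spectra[[i]] <- render_sample(signatures, conc_tube, config,
                                    sample_id = sample_id[i])
    }
  }
  list(spectra = spectra,
       truth = conc_table(truth, units = "umol_per_L"),
       design = design, config = config)
}

#' Simulate replicate preparations of one sample
#'
#' One truth vector, `n_reps` independent realizations of preparation /
#' measurement noise. When `config$freeze_jitter` is `TRUE` the
#' chemical-shift jitter is drawn once and shared (replicates come from a
#' single tube), so replicates differ only in baseline and noise.
#'
#' @param base_concentrations Named vector (umol/L, neat urine).
#' @param n_reps Number of replicates (>= 2; default 10).
#' @param signatures Named signature list (default packaged library).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `spectra`, `truth` ([conc_table()]) and `design`
#'   (all replicates in one replicate group).
#' @export
simulate_replicates <- function(base_concentrations, n_reps = 10,
                                signatures = read_signature_library(),
                                config = sim_config(), seed = 1) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  set.seed(seed)
  jit <- if (config$freeze_jitter)
    draw_jitter(signatures[names(base_concentrations)], config) else NULL
  ids <- sprintf("REP%02d", seq_len(n_reps))
  spectra <- vector("list", n_reps)
  names(spectra) <- ids
  conc_tube <- base_concentrations / config$dilution
  for (i in seq_len(n_reps))
    spectra[[i]] <- render_sample(signatures, conc_tube, config,
                                  jitter_offsets = jit, sample_id = ids[i])
  truth <- matrix(rep(base_concentrations, each = n_reps), nrow = n_reps,
                  dimnames = list(ids, names(base_concentrations)))
  design <- cohort_design(
    data.frame(sample_id = ids, individual = "I0001",
               replicate_group = "R1", stringsAsFactors = FALSE))
  list(spectra = spectra, truth = conc_table(truth, units = "umol_per_L"),
       design = design, config = config)
}

#' Simulate a genotype dosage matrix
#'
#' Hardy-Weinberg dosages (0/1/2 summed Bernoulli draws) for unlinked
#' variants with allele frequencies drawn uniformly from `maf_range`, plus
#' simulated imputation info scores. A small helper for exercising the
#' genetic scan; not a population-genetic simulator.
#'
#' @param n_individuals,n_variants Matrix dimensions.
#' @param maf_range Allele-frequency range to draw from.
#' @param info_range Imputation info score range to draw from.
#' @param seed Integer seed.
#' @return A `genotype_matrix`: list with `dosage` (individuals x variants),
#'   `maf`, `info`, and a `map` data.frame (variant, chromosome, position).
#' @export
simulate_genotypes <- function(n_individuals, n_variants,
                               maf_range = c(0.05, 0.5),
                               info_range = c(0.7, 1.0), seed = 1) {
  set.seed(seed)
  p <- runif(n_variants, maf_range[1], maf_range[2])
  dosage <- sapply(p, function(pi) rbinom(n_individuals, 2, pi))
  ids <- sprintf("rs%06d", seq_len(n_variants))
  colnames(dosage) <- ids
  rownames(dosage) <- sprintf("I%04d", seq_len(n_individuals))
  genotype_matrix(dosage, info = runif(n_variants, info_range[1],
                                       info_range[2]),
                  map = data.frame(variant = ids,
                                   chromosome = sample(1:22, n_variants,
                                                       replace = TRUE),
                                   position = sample.int(1e8, n_variants,
                                                         replace = TRUE)))
}
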