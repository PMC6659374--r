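test_that("fit model structure mirrors the prior knowledge", {
  m <- build_fit_model(sig_library["alanine"], c(1.6, 1.3), 600)
  expect_equal(nrow(m$components), 2)       # CH3 doublet only (CH at 3.78)
  expect_equal(length(m$metabolites), 1)
  expect_equal(nrow(m$groups), 1)
  expect_equal(m$n_widths, 1)
  expect_equal(unname(m$n_protons_used["alanine"]), 3)
  # relative amplitudes: 3 protons split 50/50
  expect_equal(m$components$rel_amp, c(1.5, 1.5))

  # creatinine: two singlets with amplitude ratio fixed at 3:2
  m2 <- build_fit_model(sig_library["creatinine"], c(4.3, 2.9), 600)
  expect_equal(sort(m2$components$rel_amp), c(2, 3))
  expect_equal(length(unique(m2$components$area_idx)), 1)

  # two metabolites in one window: 2 areas + per-group centers + 2 widths
  m3 <- build_fit_model(sig_library[c("alanine", "lactate")],
                        c(1.6, 1.15), 600)
  expect_equal(length(m3$metabolites), 2)
  expect_equal(nrow(m3$groups), 2)          # one CH3 group each in window
  expect_warning(
    build_fit_model(sig_library[c("alanine", "formate")], c(1.6, 1.3),
                    600),
    "formate")
  expect_error(
    suppressWarnings(build_fit_model(sig_library["formate"], c(1.6, 1.3),
                                     600)),
    "empty fit model")
})

test_that("a noiseless single line is recovered to 1e-6 relative", {
  cfg <- clean_config()
  sp <- render_sample(sig_library, c(glycine = 700), cfg, seed = 1)
  m <- build_fit_model(sig_library["glycine"], c(3.65, 3.45), 600)
  f <- ctls_fit(m, sp)
  expect_true(f$converged)
  expect_lt(abs(f$metabolites$area / (700 * 2) - 1), 1e-6)
  expect_lt(abs(f$metabolites$width_ppm / (1 / 600) - 1), 1e-4)
})

test_that("two doublets separated by 0.7 FWHM are both recovered", {
  # two alanine-like CH3 doublets 0.7 linewidths apart, noise off
  sig_a <- metabolite_signature("metA", list(
    proton_group(1.400, 3, list(c(7, 1)), 0.003, "CH3")))
  sig_b <- metabolite_signature("metB", list(
    proton_group(1.400 + 0.7 / 600, 3, list(c(7, 1)), 0.003, "CH3")))
  sigs <- list(metA = sig_a, metB = sig_b)
  cfg <- clean_config()
  sp <- render_sample(sigs, c(metA = 200, metB = 350), cfg, seed = 1)
  m <- build_fit_model(sigs, c(1.6, 1.2), 600)
  f <- ctls_fit(m, sp)
  got <- setNames(f$metabolites$area, f$metabolites$metabolite)
  expect_lt(abs(got["metA"] / 600 - 1), 0.005)
  expect_lt(abs(got["metB"] / 1050 - 1), 0.005)

  # independent oracle: with geometry frozen at truth, the 2-area problem
  # is linear least squares
  idx <- ppm_window(sp, 1.6, 1.2)
  x <- sp$ppm[idx]; y <- sp$intensity[idx]
  design <- sapply(sigs, function(s) {
    g <- s$groups[[1]]
    pat <- multiplet_pattern(g$couplings, 600)
    rowSums(sapply(seq_len(nrow(pat)), function(i)
      lorentzian(x, g$center_ppm + pat$offset_ppm[i],
                 g$n_protons * pat$weight[i], 1 / 600)))
  })
  ls <- qr.solve(design, y)
  # TSP's Lorentzian tail contributes ~1e-5 relative at 1.4 ppm
  expect_equal(unname(ls), c(200, 350), tolerance = 2e-5)
})

test_that("frozen-geometry fits equal closed-form least squares to 1e-8", {
  cfg <- clean_config()
  sigs <- sig_library[c("lactate", "threonine")]
  sp <- render_sample(sigs, c(lactate = 140, threonine = 120), cfg,
                      seed = 2)
  m <- build_fit_model(sigs, c(1.45, 1.2), 600,
                       options = list(baseline_order = 0L))
  f <- ctls_fit(m, sp, options = list(fix_centers = TRUE,
                                      fix_widths = TRUE))
  # oracle: linear LS with unit-area profiles at reference geometry
  idx <- ppm_window(sp, 1.45, 1.2)
  x <- sp$ppm[idx]; y <- sp$intensity[idx]
  design <- sapply(sigs, function(s) {
    g <- s$groups[[1]]
    pat <- multiplet_pattern(g$couplings, 600)
    rowSums(sapply(seq_len(nrow(pat)), function(i)
      lorentzian(x, g$center_ppm + pat$offset_ppm[i],
                 g$n_protons * pat$weight[i], 1 / 600)))
  })
  # design columns have area n_protons per unit coefficient, so the LS
  # coefficients are the per-proton areas of the constrained fit
  ls <- qr.solve(cbind(design, 1), y)[1:2]
  expect_equal(unname(f$metabolites$area_per_proton), unname(ls),
               tolerance = 1e-8)
})

test_that("a pure-noise window fits to zero areas and converges", {
  cfg <- sim_config(baseline_amplitude = 0, jitter = 0)
  sp <- render_sample(sig_library, c(formate = 0), cfg, seed = 3)
  m <- build_fit_model(sig_library["formate"], c(8.6, 8.3), 600)
  f <- ctls_fit(m, sp)
  expect_true(f$converged)
  noise <- noise_estimate(sp)
  # area indistinguishable from zero at the noise scale
  height_equiv <- 2 * f$metabolites$area / (pi * f$metabolites$width_ppm)
  expect_lt(height_equiv, 5 * noise)
  expect_gte(f$metabolites$area, 0)
})

test_that("fitted areas are monotone in true concentration", {
  cfg <- fast_config()
  m <- build_fit_model(sig_library["citrate"], c(2.85, 2.4), 600)
  areas <- vapply(c(500, 1000, 2000, 4000), function(cc) {
    sp <- render_sample(sig_library, c(citrate = cc), cfg, seed = 77)
    ctls_fit(m, sp)$metabolites$area
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("residual RMS stays at the injected noise level", {
  cfg <- sim_config()
  conc <- ref_conc / cfg$dilution
  sp <- render_sample(sig_library, conc, cfg, seed = 8)
  noise <- cfg$noise_sd * 2 * (0.5 * 1000 * 9) /
    (pi * cfg$linewidth_hz / cfg$frequency_mhz)
  for (w in list(c(1.6, 1.15), c(2.85, 2.4), c(8.6, 8.3))) {
    mets <- names(sig_library)
    m <- suppressWarnings(build_fit_model(sig_library, w, 600))
    f <- ctls_fit(m, sp)
    expect_lt(f$rms, 1.5 * noise)
  }
})

test_that("unidentified residual signals are detected and capped", {
  cfg <- sim_config(baseline_amplitude = 0, jitter = 0)
  sp <- render_sample(sig_library, c(glycine = 700), cfg, seed = 9)
  m <- build_fit_model(sig_library["glycine"], c(3.65, 3.45), 600)
  f <- ctls_fit(m, sp)
  m1 <- detect_unidentified(f, m)
  expect_null(m1$extra_singlets)   # clean residual: nothing added

  # inject an unmodelled singlet at 10x noise height
  noise <- noise_estimate(sp)
  spike_area <- 10 * noise * pi * (1 / 600) / 2
  sp2 <- sp
  sp2$intensity <- sp$intensity +
    lorentzian(sp$ppm, 3.55, spike_area * 3, 1 / 600)
  f2 <- ctls_fit(m, sp2)
  m2 <- detect_unidentified(f2, m)
  expect_equal(nrow(m2$extra_singlets), 1)
  expect_lt(abs(m2$extra_singlets$center[1] - 3.55), 0.002)
  f3 <- ctls_fit(m2, sp2)
  # glycine area survives the companion singlet
  expect_lt(abs(f3$metabolites$area / 1400 - 1), 0.01)

  # a forest of spurious bumps is capped at max_extra
  sp3 <- sp
  for (c0 in seq(3.46, 3.64, by = 0.01))
    sp3$intensity <- sp3$intensity +
      lorentzian(sp3$ppm, c0, spike_area * 5, 1 / 600)
  f4 <- ctls_fit(m, sp3)
  m4 <- detect_unidentified(f4, m, max_extra = 5)
  expect_lte(nrow(m4$extra_singlets), 5)
})

test_that("area_to_concentration does the TSP reference arithmetic", {
  # area/n == tsp_area/9 with 0.5 mmol/L TSP and 700/630 dilution
  c1 <- area_to_concentration(5, 1, 45, 9, 0.5, 700 / 630)
  expect_equal(c1, 0.5 * 1000 * 700 / 630, tolerance = 1e-12)
  expect_equal(round(c1, 1), 555.6)
  expect_equal(area_to_concentration(0, 3, 45), 0)
  # ratio invariance
  expect_equal(area_to_concentration(10, 2, 90),
               area_to_concentration(20, 2, 180), tolerance = 1e-12)
  expect_error(area_to_concentration(5, 1, 0), "QC")
})

test_that("quantify_sample recovers truth and flags missing TSP", {
  cfg <- sim_config()
  conc <- ref_conc
  sp <- render_sample(sig_library, conc / cfg$dilution, cfg, seed = 10)
  q1 <- quantify_sample(sp, sig_library, config = cfg)
  q2 <- quantify_sample(sp, sig_library, config = cfg)
  expect_identical(q1$concentrations, q2$concentrations)   # deterministic
  err <- abs(q1$concentrations / conc[names(q1$concentrations)] - 1)
  expect_lt(median(err), 0.05)

  # a spectrum with no TSP fails reference QC
  cfg0 <- sim_config(tsp_conc_mmol_per_L = 1e-9)
  sp0 <- render_sample(sig_library, c(alanine = 300) / cfg0$dilution,
                       cfg0, seed = 11)
  expect_error(quantify_sample(sp0, sig_library, config = cfg0), "TSP")
})

test_that("windows inside the water zone and uncovered windows error", {
  m <- build_fit_model(sig_library["glycine"], c(3.65, 3.45), 600)
  sp <- nmr_spectrum(seq(2, 1, length.out = 50), rnorm(50))
  expect_error(ctls_fit(m, sp), "cover")
  sig_w <- metabolite_signature("wz", list(
    proton_group(4.7, 1, list(), 0.01, "x")))
  mw <- build_fit_model(list(wz = sig_w), c(4.9, 4.55), 600)
  sp2 <- render_sample(sig_library, c(alanine = 1), clean_config(),
                       seed = 1)
  expect_error(ctls_fit(mw, sp2), "water")
})
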