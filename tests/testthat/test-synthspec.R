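# brute-force multiplet oracle: enumerate every spin-state combination
# explicitly instead of convolving binomial patterns
multiplet_oracle <- function(couplings, freq) {
  states <- list(0)
  for (cp in couplings) {
    # each of the m equivalent partners contributes +/- J/2
    for (k in seq_len(cp[2]))
      states <- unlist(lapply(states, function(s)
        list(s - cp[1] / 2, s + cp[1] / 2)), recursive = FALSE)
  }
  hz <- round(unlist(states), 9)
  tab <- table(hz)
  data.frame(offset_ppm = as.numeric(names(tab)) / freq,
             weight = as.numeric(tab) / length(hz))
}

test_that("multiplet patterns follow first-order rules", {
  s <- multiplet_pattern(list(), 600)
  expect_equal(s, data.frame(offset_ppm = 0, weight = 1))

  d <- multiplet_pattern(list(c(7, 1)), 600)
  expect_equal(d$offset_ppm, c(-1, 1) * 7 / 1200, tolerance = 1e-12)
  expect_equal(d$weight, c(0.5, 0.5))

  q <- multiplet_pattern(list(c(7, 3)), 600)
  expect_equal(nrow(q), 4)
  expect_equal(q$weight, c(1, 3, 3, 1) / 8)
  expect_equal(diff(q$offset_ppm), rep(7 / 600, 3), tolerance = 1e-12)
})

test_that("multiplet patterns match the brute-force enumeration oracle", {
  cases <- list(list(c(10, 1), c(4, 1)),
                list(c(7.2, 3)),
                list(c(8, 2), c(3, 1)),
                list(c(6, 1), c(6, 1)))   # coincident lines merge
  for (cpl in cases) {
    got <- multiplet_pattern(cpl, 600)
    want <- multiplet_oracle(cpl, 600)
    expect_equal(got$offset_ppm, want$offset_ppm, tolerance = 1e-9)
    expect_equal(got$weight, want$weight, tolerance = 1e-12)
  }
  # dd with J1=10, J2=4: four equal lines at +/-(10+/-4)/2 Hz
  got <- multiplet_pattern(list(c(10, 1), c(4, 1)), 600)
  expect_equal(got$offset_ppm * 600, c(-7, -3, 3, 7), tolerance = 1e-9)
  expect_equal(got$weight, rep(0.25, 4))
})

test_that("multiplet invariants hold across random coupling sets", {
  set.seed(11)
  for (i in 1:20) {
    cpl <- replicate(sample(0:3, 1), c(runif(1, 0, 15), sample(1:3, 1)),
                     simplify = FALSE)
    pat <- multiplet_pattern(cpl, 600)
    expect_equal(sum(pat$weight), 1, tolerance = 1e-12)
    # symmetric about zero
    expect_equal(sort(pat$offset_ppm), sort(-pat$offset_ppm),
                 tolerance = 1e-9)
  }
})

test_that("lorentzian integrates to its area and peaks at 2A/(pi*fwhm)", {
  fwhm <- 0.002
  x <- seq(1 + 500 * fwhm, 1 - 500 * fwhm, length.out = 200001)
  y <- lorentzian(x, 1, 3.7, fwhm)
  integ <- -sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  expect_equal(integ, 3.7 * 2 / pi * atan(1000), tolerance = 1e-6)
  expect_lt(abs(integ / 3.7 - 1), 1e-3)   # within 0.1% over +/-500 fwhm
  expect_equal(max(y), 2 * 3.7 / (pi * fwhm), tolerance = 1e-9)
  # linearity: sum of two components == pointwise sum
  expect_equal(lorentzian(x, 1, 2, fwhm) + lorentzian(x, 1.01, 5, fwhm),
               lorentzian(x, 1, 2, fwhm) + lorentzian(x, 1.01, 5, fwhm))
  expect_error(lorentzian(x, 1, 1, 0), "positive")
})

test_that("render_sample reduces to the TSP singlet in the clean world", {
  cfg <- clean_config()
  sp <- render_sample(sig_library, c(alanine = 0), cfg, seed = 1)
  # all intensity concentrated at 0 ppm
  pk <- sp$ppm[which.max(sp$intensity)]
  expect_lt(abs(pk), 0.001)
  step <- abs(diff(sp$ppm[1:2]))
  total <- sum(sp$intensity) * step
  expect_equal(total, 0.5 * 1000 * 9, tolerance = 2e-3)
  expect_error(render_sample(sig_library, c(nosuch = 1), cfg),
               "nosuch")
})

test_that("rendered signal is conserved and linear in concentration", {
  cfg <- clean_config()
  conc <- c(alanine = 300, glycine = 800, creatinine = 9000)
  sp1 <- render_sample(sig_library, conc, cfg, seed = 2)
  step <- abs(diff(sp1$ppm[1:2]))
  expected <- sum(conc * c(4, 2, 5)) + 0.5 * 1000 * 9
  expect_equal(sum(sp1$intensity) * step, expected, tolerance = 1e-3)

  # doubling one metabolite doubles its region integral (same seed)
  conc2 <- conc; conc2["alanine"] <- 600
  sp2 <- render_sample(sig_library, conc2, cfg, seed = 2)
  idx <- ppm_window(sp1, 1.6, 1.3)
  expect_equal(sum(sp2$intensity[idx]) / sum(sp1$intensity[idx]), 2,
               tolerance = 1e-3)

  # water-zone attenuation flattens 4.5-5.0 ppm
  wz <- ppm_window(sp1, 5.0, 4.5)
  expect_lt(max(abs(sp1$intensity[wz])), 1)
})

test_that("rendering is deterministic under a fixed seed", {
  cfg <- fast_config()
  sp1 <- render_sample(sig_library, c(alanine = 300), cfg, seed = 42)
  sp2 <- render_sample(sig_library, c(alanine = 300), cfg, seed = 42)
  expect_identical(sp1$intensity, sp2$intensity)
  sp3 <- render_sample(sig_library, c(alanine = 300), cfg, seed = 43)
  expect_false(identical(sp1$intensity, sp3$intensity))
})

test_that("cohort truth columns reproduce requested CVs (log-normal oracle)", {
  mets <- c("alanine", "creatinine")
  cv <- c(alanine = 50, creatinine = 60)
  sim <- simulate_cohort(sig_library[mets], 5000, inter_cv = cv,
                         cv_scale = "absolute", seed = 3, render = FALSE)
  emp <- apply(sim$truth$values, 2, function(v) 100 * sd(v) / mean(v))
  # 3 Monte-Carlo SEs of a log-normal sample CV at n=5000
  se_cv <- function(cv, n) cv * sqrt(1 / (2 * n) + (cv / 100)^2 / n)
  expect_lt(abs(emp["alanine"] - 50), 3 * se_cv(50, 5000))
  expect_lt(abs(emp["creatinine"] - 60), 3 * se_cv(60, 5000))

  # normalized mode: the creatinine-scaled ratio carries the requested CV
  simn <- simulate_cohort(sig_library[mets], 5000, inter_cv = cv,
                          cv_scale = "normalized", seed = 4,
                          render = FALSE)
  ratio <- simn$truth$values[, "alanine"] /
    (simn$truth$values[, "creatinine"] / 1000)
  expect_lt(abs(100 * sd(ratio) / mean(ratio) - 50), 3 * se_cv(50, 5000))
})

test_that("zero inter-individual CV collapses the cohort to one truth row", {
  mets <- c("alanine", "creatinine")
  sim <- simulate_cohort(sig_library[mets], 8,
                         inter_cv = c(alanine = 0, creatinine = 0),
                         seed = 5, render = FALSE)
  expect_equal(max(apply(sim$truth$values, 2, sd)), 0)
  sim2 <- simulate_cohort(sig_library[mets], 8,
                          inter_cv = c(alanine = 0, creatinine = 0),
                          seed = 5, render = FALSE)
  expect_identical(sim$truth$values, sim2$truth$values)
  expect_error(simulate_cohort(sig_library[mets], 8,
                               inter_cv = c(alanine = -1, creatinine = 0),
                               render = FALSE), ">= 0")
  expect_error(simulate_cohort(sig_library[mets], 8,
                               inter_cv = c(alanine = 10), render = FALSE),
               "creatinine")
})

test_that("replicates share truth; frozen jitter + zero noise makes them identical", {
  conc <- c(alanine = 300, creatinine = 9000)
  cfg0 <- clean_config(freeze_jitter = TRUE, n_points = 8192L)
  reps <- simulate_replicates(conc, n_reps = 3,
                              signatures = sig_library[names(conc)],
                              config = cfg0, seed = 6)
  expect_identical(reps$spectra[[1]]$intensity, reps$spectra[[2]]$intensity)
  expect_equal(unique(reps$truth$values[, "alanine"]), 300)

  cfg1 <- fast_config(freeze_jitter = TRUE)
  reps1 <- simulate_replicates(conc, n_reps = 3,
                               signatures = sig_library[names(conc)],
                               config = cfg1, seed = 6)
  expect_false(identical(reps1$spectra[[1]]$intensity,
                         reps1$spectra[[2]]$intensity))
  expect_error(simulate_replicates(conc, n_reps = 1), "n_reps")
})
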