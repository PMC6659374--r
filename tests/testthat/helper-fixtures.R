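# shared fixtures: small signature subsets and fast configs for unit tests
# (acceptance tests use the full stated defaults)

sig_library <- read_signature_library()

ref_tbl <- urine_reference()
ref_conc <- setNames(ref_tbl$median_umol_per_L, ref_tbl$metabolite)
ref_inter <- setNames(ref_tbl$inter_individual_cv_pct, ref_tbl$metabolite)
ref_intra <- setNames(ref_tbl$intra_individual_cv_pct, ref_tbl$metabolite)

# a clean config: no noise, no baseline, no jitter -- exact arithmetic world
clean_config <- function(...)
  sim_config(noise_sd = 0, baseline_amplitude = 0, jitter = 0, ...)

# reduced-axis config for speed in tests that do not probe the default axis
fast_config <- function(...)
  sim_config(n_points = 8192L, ...)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
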