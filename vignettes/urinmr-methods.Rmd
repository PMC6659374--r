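---
title: "Quantitative urine NMR metabolomics with urinmr: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative urine NMR metabolomics with urinmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urinmr)
```

# The problem

Urine is an attractive biofluid for epidemiology — abundant, sterile,
non-invasive — but a hostile one for quantitative NMR. Unlike blood it is
not buffered, so pH, ionic strength and multivalent-cation concentrations
vary from sample to sample, shifting resonance positions; and the spectra
are dense, with heavy signal overlap. `urinmr` implements a complete
quantification and analysis chain for one-dimensional ¹H spectra of urine:

1. a **synthetic spectrum generator** that produces cohorts of urine-like
   spectra with known ground truth;
2. **constrained total line-shape (CTLS) fitting**, which resolves
   overlapping signals by exploiting molecular prior knowledge;
3. **automated regression quantification**, which learns to reproduce CTLS
   areas from binned spectral intensities so that a new spectrum is
   quantified by a dot product;
4. **variability statistics** — intra-assay, intra-individual and
   inter-individual CV% on creatinine-normalized concentrations;
5. **epidemiological and genetic statistics** — sex-adjusted partial
   correlation maps, PCA-based effective numbers of tests with Bonferroni
   thresholds, SD-unit exposure associations, and an additive genetic scan
   on inverse-normal-transformed residuals.

Because real cohort spectra are not redistributable, the generator is a
first-class, tested component: every downstream module is exercised
against simulated data with known truth.

# The signal model

A proton group with chemical shift $\delta_0$, $N$ equivalent protons and
scalar couplings $\{(J_k, m_k)\}$ contributes a first-order multiplet:
iterated convolution of $(m_k{+}1)$-line binomial patterns with spacing
$J_k/\nu_0$ ppm, where $\nu_0$ is the spectrometer frequency in MHz
(600 by default). Each line is a Lorentzian

$$ L(\delta) = \frac{2A}{\pi w}\,\frac{1}{1 + \left(2(\delta - c)/w\right)^2},
$$

with area $A$ and full width at half maximum $w$ (1 Hz by default —
a well-shimmed cryoprobe spectrum). Line areas are proportional to molar
concentration times proton count, which is what makes NMR quantitative:
one internal reference calibrates every metabolite. The reference is TSP,
a 9-proton singlet at 0 ppm at known in-tube concentration (0.5 mmol/L by
default), and the conversion is

$$ c = \frac{A/N}{A_\mathrm{TSP}/9}\; c_\mathrm{TSP} \times 1000 \times D,
$$

with $D = 700/630$ the tube dilution (630 µl urine + 70 µl buffer).

Second-order (strong-coupling) lineshape distortions are deliberately not
modelled; citrate's AB quartet is approximated as two doublets. Since the
generator and the fitter share the first-order model, this limits realism,
not internal consistency — a caveat for transferring conclusions to real
spectra (see *Limitations*).

# The synthetic cohort generator

`render_sample()` draws, per sample and proton group, a uniform shift
perturbation within the group's mobility window (`± mobility_ppm`), the
proxy for pH/ionic-strength variation; adds a smooth baseline (three broad
Gaussians, FWHM 1–3 ppm, signed amplitudes with SD 0.2% of the TSP peak
height); attenuates the water-suppression dead zone (4.50–5.00 ppm) by
10⁻³; and adds iid Gaussian noise with SD $5\times10^{-4}$ of the TSP peak
height. The default axis is 32768 points over 10 … −0.5 ppm.

`simulate_cohort()` adds the biological layers. CVs are converted to
log-normal widths by $\sigma = \sqrt{\ln(1 + (CV/100)^2)}$;
individual-level geometric means and day-level values are drawn
log-normal. One design decision deserves emphasis: published urinary
reference CVs are reported on the **creatinine-normalized scale**, so by
default (`cv_scale = "normalized"`) the generator draws each
non-creatinine metabolite as a log-normal *normalized* level and
multiplies by the individual's creatinine, which itself carries the
urine-dilution variation (our chosen world: inter-individual CV 60%,
day-to-day 40% — typical spot-urine dilution spread). The alternative
`cv_scale = "absolute"` applies CVs to raw concentration columns, which
is the natural world for moment-oracle tests but cannot reproduce a
normalized-scale calibration once creatinine varies. Packaged median
concentrations are round literature-scale values for an adult spot urine
(e.g. creatinine 10 mmol/L, citrate 2.5 mmol/L, hippurate 2 mmol/L); they
set signal-to-noise ratios, not any tested statistic.

The packaged signature library covers 18 metabolites — a deliberate,
documented stand-in for a full urine assignment list — with reference
shifts and couplings from public compilations, including intentionally
hard cases: the 1.2–1.5 ppm region packs five metabolites (alanine,
2-hydroxyisobutyrate, lactate, threonine, 3-hydroxyisovalerate) whose
lines interleave within a few linewidths, and creatine's CH₃ singlet sits
0.01 ppm from creatinine's.

# CTLS fitting

`build_fit_model()` turns signatures into a constrained model for one
spectral window: per metabolite one free area (per proton), per group one
free centre bounded by its mobility window, one shared linewidth per
metabolite (bounded to 0.3–5 Hz), and a polynomial baseline (order 1 by
default — windows are narrow). Relative line amplitudes inside a
metabolite are fixed by proton counts and binomial weights; creatinine's
CH₃/CH₂ singlets, for instance, are locked at 3:2. Fitting windows are
small (one or a few metabolites at a time), following standard practice
for line-shape analysis of biofluids.

`ctls_fit()` minimizes the sum of squared deviations with the
bound-constrained PORT optimizer (`nlminb`) using exact analytic
gradients. Initialization is two-stage: centres at reference shifts
(or, for groups whose mobility exceeds the linewidth, a matched-filter
scan of the multiplet profile over the mobility window — without it, a
group jittered several linewidths away sits in a zero-gradient valley and
fits to zero); then a non-negative linear solve for areas and baseline
with the geometry frozen. Because a matched-filter start can mis-assign
nearly degenerate overlapping groups, the fitter retries once from the
reference-shift geometry whenever the achieved residual RMS exceeds three
times the window's robust noise estimate, and keeps the better fit.
Numerical tie-break rules: candidate unidentified singlets within half a
linewidth of a modelled line are rejected; at most five extra singlets per
window; group centres with zero mobility are fixed.

With centres and widths frozen the objective is exactly quadratic, so the
fit must agree with closed-form least squares — a property the test suite
checks to 10⁻⁸ — and on noiseless single-line inputs areas are recovered
to 10⁻⁶ relative.

Urea is not in the packaged library: its resonance sits near the water
suppression zone, and the packaged subset opts for cleanly testable
regions; the water-zone attenuation and the "suppression-affected"
machinery are nonetheless in place for libraries that include it.

# Automated regression quantification

`train_quant_model()` regresses CTLS reference areas on mean intensities
in equal-width ppm bins over the metabolite's fit window plus known
interfering neighbour regions. The model family is ridge regression —
the minimal choice that keeps prediction a single dot product and handles
collinear bins — with the penalty chosen by 5-fold cross-validation on a
concentration-tertile-stratified 2:1 train/test split, all seeded.
Held-out agreement is summarised Bland-Altman style: mean bias, limits of
agreement (mean ± 1.96 × sample SD of differences), the
predicted-on-reference regression line, and the bias-on-reference line
with its R² (a flat, near-zero-R² bias line is the signature of agreement
that does not degrade across the range). QC happens before training:
spectra are flagged for shimming (TSP FWHM > 1.8 Hz), baseline distortion
(quiet-zone level > 30 × noise SD; the threshold deliberately clears the
generator's own smooth baseline) or a missing reference peak.

# Variability statistics

`cv_percent()` is `100 · sd/mean` with the sample SD (n−1) throughout.
The three layers: **intra-assay** — CV across replicate preparations of
one sample, averaged over replicate groups; **intra-individual** — CV per
individual across collection days, then an unweighted mean across
individuals; **inter-individual** — CV across individuals (per-individual
means first when several samples each). The two biological layers are
computed on creatinine-normalized values. Absent (below-detection) values
are excluded pairwise rather than zero-imputed — the CV of a mixture with
structural zeros is not the quantity reference tables report. The default
limit of detection is 3 × the noise-equivalent area, configurable.

# Epidemiological and genetic statistics

Measures are log-transformed and scaled to SD units; strictly positive
input is enforced unless the caller opts into NA-exclusion. Partial
correlations residualize both variables on the covariates (sex, in the
canonical use) and test with $t = r\sqrt{(n-2-q)/(1-r^2)}$. Correlation
maps order measures either by a supplied pathway list or by
average-linkage hierarchical clustering on $1-|r|$. The effective number
of tests is the number of principal components of the column correlation
matrix needed to exceed — strictly — 99% of variance, and Bonferroni
thresholds are reported rounded to one significant figure, matching the
reporting convention (0.05/40 → 0.001; 0.05/27 → 0.002; 0.05/66 → 0.0008;
the genome-wide threshold 5×10⁻⁸/40 = 1.25×10⁻⁹ is kept exact).

The genetic scan residualizes the phenotype on covariates, transforms the
residuals to normal scores with Blom constants (3/8, 1/4; average ranks
for ties), filters variants at MAF ≥ 5% and imputation info ≥ 0.8, and
tests each remaining variant by OLS on allele dosage. Exposure (e.g. BMI)
associations are OLS per outcome with the exposure SD-scaled by default so
effects read SD-per-SD; no sex adjustment is applied unless covariates
are passed (the default follows the minimal published model; a covariate
argument covers the alternative).

# What a green test establishes — and what it does not

The simulator emulates: first-order multiplets, Lorentzian lines with a
common width, shift jitter uniform and independent per group, a smooth
low-frequency baseline, a hard water-suppression zone, log-normal
biological variation, and noise proportional to a fixed reference. It
does **not** emulate: strong coupling, per-metabolite pH-shift
*dependencies* (jitter is independent across groups, while real pH moves
related groups coherently), radiation damping or lineshape asymmetry,
T₂/molecular-weight-dependent linewidth differences, chemical exchange
(urea), or spectrometer drift. Parameter-recovery results therefore
validate the estimator under its own model assumptions plus noise —
a necessary condition, not field performance.

# Numerical and design choices

* Optimizer: `nlminb` (PORT), analytic gradients, relative tolerance
  10⁻¹³, one restart from reference geometry on poor residuals.
* Shared linewidth per metabolite by default (`shared_width = "group"`
  available); the granularity is not standardized in the field.
* Window plan: packaged; overlapping metabolites share joint windows.
* Axis convention: ppm stored strictly decreasing; windows are half-open
  `[high, low)` so adjacent windows never double-count a point.
* Default spectrometer frequency 600 MHz when a file carries none.
* JCAMP-DX support is limited to uncompressed XYDATA (AFFN); vendor raw
  directories and time-domain processing are out of scope.
* Sample SD (n−1) in every CV and scaling step.
* Pipeline seeds fan out from one global seed by fixed offsets, so each
  stage is individually reproducible.

# Limitations

The packaged library is a fraction of what urine contains; conclusions
about overlap robustness transfer only to comparably crowded regions. The
automated models are trained and evaluated on simulated spectra from the
same generator — the realistic analogue would train on line-shape-fitted
real cohort spectra. CV calibration accuracy at cohort scale is limited
by log-normal sampling error (≈ ±2 CV points at n = 500 for a 50% CV),
which the acceptance tolerances reflect.
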