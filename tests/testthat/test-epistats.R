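test_that("log-SD scaling standardizes exactly and guards its domain", {
  x <- cbind(a = c(1, exp(1), exp(2)), b = c(2, 4, 8))
  z <- log_sd_scale(x)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-10)

  bad <- cbind(a = c(1, 0, 2))
  expect_error(log_sd_scale(bad), "non-positive")
  z2 <- log_sd_scale(bad, pseudo_policy = "exclude")
  expect_true(is.na(z2[2, 1]))
  expect_error(log_sd_scale(cbind(a = c(3, 3, 3))), "constant")
})

test_that("partial correlation equals the two-step residual oracle", {
  set.seed(51)
  n <- 20
  C <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  x <- 0.5 * C[, 1] + rnorm(n)
  y <- -0.3 * C[, 1] + 0.4 * x + rnorm(n)
  got <- partial_correlation(x, y, C)
  rx <- residuals(lm(x ~ C)); ry <- residuals(lm(y ~ C))
  r_o <- cor(rx, ry)
  expect_equal(got$r, r_o, tolerance = 1e-12)
  df <- n - 2 - 2
  t_o <- r_o * sqrt(df / (1 - r_o^2))
  expect_equal(got$p, 2 * pt(-abs(t_o), df), tolerance = 1e-12)
  expect_equal(got$n, n)

  # exchangeable in (x, y); invariant to affine covariate transforms
  swapped <- partial_correlation(y, x, C)
  expect_equal(swapped$r, got$r, tolerance = 1e-12)
  aff <- partial_correlation(x, y, cbind(3 * C[, 1] - 7, 2 * C[, 2] + 1))
  expect_equal(aff$r, got$r, tolerance = 1e-10)

  # orthogonal covariate leaves the marginal correlation untouched
  xo <- rep(c(-1, 1), 10)
  co <- rep(c(1, 1, -1, -1), 5)   # orthogonal to xo
  yo <- rnorm(20)
  yo <- yo - co * sum(yo * co) / sum(co^2)  # strip covariate component
  m <- cor(xo, yo)
  expect_equal(partial_correlation(xo, yo, co)$r, m, tolerance = 1e-10)

  expect_equal(partial_correlation(x, x, C)$r, 1, tolerance = 1e-12)
  expect_error(partial_correlation(x[1:4], y[1:4], C[1:4, ]),
               "insufficient")
})

test_that("correlation maps are symmetric, ordered and null-calibrated", {
  set.seed(52)
  n <- 995
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("m", 1:12)))
  sex <- rbinom(n, 1, 0.5)
  cm <- correlation_map(X, covariates = sex)
  expect_equal(unname(diag(cm$r)), rep(1, 12))
  expect_equal(cm$r, t(cm$r), tolerance = 1e-12)
  expect_true(all(abs(cm$r) <= 1))
  # null median |r| ~ 0.6745 / sqrt(n)
  expect_lt(abs(cm$median_abs_r - 0.6745 / sqrt(n)), 0.006)

  cmc <- correlation_map(X, covariates = sex, ordering = "cluster")
  expect_setequal(cmc$order_a, colnames(X))

  # rectangular inter-fluid map
  cm2 <- correlation_map(X, covariates = sex,
                         subset_a = paste0("m", 1:5),
                         subset_b = paste0("m", 6:12))
  expect_equal(dim(cm2$r), c(5L, 7L))
})

test_that("effective tests counts PCs past the strict >99% rule", {
  set.seed(53)
  # mutually independent columns: every PC needed
  X <- matrix(rnorm(4000 * 43), 4000, 43)
  expect_equal(effective_tests(X), 43L)
  # a duplicated column collapses one dimension
  Y <- cbind(x = rnorm(200), y = rnorm(200))
  Y2 <- cbind(Y, z = Y[, "x"])
  expect_equal(effective_tests(cbind(Y[, 1], Y[, 1])), 1L)
  # rank-3 construction plus tiny noise
  B <- matrix(rnorm(500 * 3), 500, 3)
  L <- matrix(rnorm(3 * 10), 3, 10)
  Z <- B %*% L + matrix(rnorm(500 * 10, sd = 1e-4), 500, 10)
  expect_equal(effective_tests(Z), 3L)
  expect_error(effective_tests(cbind(c(1, NA, 3))), "complete")
})

test_that("effective tests equals brute-force eigenvalue accumulation", {
  set.seed(54)
  for (i in 1:10) {
    X <- matrix(rnorm(60 * 10), 60, 10) %*%
      matrix(rnorm(100), 10, 10)   # random correlation structure
    thr <- runif(1, 0.5, 0.999)
    got <- effective_tests(X, thr)
    ev <- svd(cor(X))$d
    oracle <- which(cumsum(ev) / sum(ev) > thr)[1]
    expect_equal(got, as.integer(oracle))
  }
})

test_that("bonferroni thresholds reproduce reporting conventions", {
  expect_equal(bonferroni_threshold(0.05, 40), 0.00125)
  expect_equal(bonferroni_threshold(0.05, 40, "signif1"), 0.001)
  expect_equal(bonferroni_threshold(0.05, 27, "signif1"), 0.002)
  expect_equal(bonferroni_threshold(0.05, 66, "signif1"), 8e-4)
  expect_equal(bonferroni_threshold(5e-8, 40), 1.25e-9)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("exposure associations recover the standardized slope", {
  set.seed(55)
  n <- 1000
  e <- rnorm(n, 26, 4)
  es <- (e - mean(e)) / sd(e)
  raw <- 0.3 * es + rnorm(n)
  X <- cbind(met = exp(raw))           # log-normal outcome
  z <- log_sd_scale(X)
  res <- exposure_association(z, e)
  # outcome standardized: slope attenuates to 0.3/sqrt(0.3^2+1)
  target <- 0.3 / sqrt(0.3^2 + 1)
  expect_lt(abs(res$beta - target), 3 * res$se)
  # sign anti-symmetry
  res_neg <- exposure_association(z, -e)
  expect_equal(res_neg$beta, -res$beta, tolerance = 1e-10)
  # null outcome: flat
  z0 <- log_sd_scale(cbind(met = exp(rnorm(n))))
  res0 <- exposure_association(z0, e)
  expect_lt(abs(res0$beta), 3 * res0$se)
  expect_error(exposure_association(z, rep(1, n)), "constant")
})

test_that("inverse normal transform yields Blom scores", {
  # middle of an odd sample scores exactly zero
  v <- c(3, 9, 1, 7, 5)
  s <- inverse_normal_transform(v)
  expect_equal(s[v == 5], 0, tolerance = 1e-12)
  # direct Blom oracle at n = 5
  r <- rank(v)
  expect_equal(s, qnorm((r - 3 / 8) / (5 + 1 / 4)), tolerance = 1e-12)
  # rank invariance under monotone rescaling
  expect_equal(inverse_normal_transform(exp(v / 2)), s,
               tolerance = 1e-12)
  # ties get average ranks; all-tied degenerates to zeros
  s2 <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(s2[1], s2[2])
  s3 <- inverse_normal_transform(c(2, 2, 2))
  expect_equal(s3, c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(s3, "degenerate"))
})

test_that("genetic scan filters variants and tests additively", {
  set.seed(56)
  n <- 300
  g <- simulate_genotypes(n, 50, maf_range = c(0.02, 0.5), seed = 57)
  # monomorphic variant and low-info variant are filtered
  g$dosage[, 1] <- 0
  g$maf[1] <- 0
  g$info[2] <- 0.5
  pheno <- setNames(rnorm(n), rownames(g$dosage))
  res <- genetic_scan(pheno, g)
  expect_false(any(c(colnames(g$dosage)[1:2]) %in% res$variant))
  expect_true(all(res$maf >= 0.05 & res$info >= 0.8))

  # planted variant explaining ~15% of variance at n = 578
  g2 <- simulate_genotypes(578, 20, maf_range = c(0.1, 0.5),
                           info_range = c(0.9, 1), seed = 58)
  dos <- g2$dosage[, 7]
  y <- sqrt(0.15) * (dos - mean(dos)) / sd(dos) +
    sqrt(0.85) * rnorm(578)
  res2 <- genetic_scan(setNames(y, rownames(g2$dosage)), g2)
  expect_lt(res2$p[res2$variant == colnames(g2$dosage)[7]], 1.25e-9)

  # covariate residualization + INT leaves a near-null elsewhere
  expect_error(genetic_scan(setNames(rnorm(10), paste0("x", 1:10)), g2),
               "misaligned")
})

test_that("scan betas and p-values agree with per-variant lm", {
  set.seed(59)
  g <- simulate_genotypes(120, 8, seed = 60)
  sex <- rbinom(120, 1, 0.5)
  y <- rnorm(120) + 0.3 * sex
  res <- genetic_scan(setNames(y, rownames(g$dosage)), g,
                      covariates = sex)
  yr <- inverse_normal_transform(residuals(lm(y ~ sex)))
  keep <- g$maf >= 0.05 & g$info >= 0.8
  for (j in which(keep)) {
    f <- summary(lm(yr ~ g$dosage[, j]))$coefficients
    row <- res[res$variant == colnames(g$dosage)[j], ]
    expect_equal(row$beta, f[2, 1], tolerance = 1e-10)
    expect_equal(row$se, f[2, 2], tolerance = 1e-10)
    expect_equal(row$p, f[2, 4], tolerance = 1e-10)
  }
})

test_that("urine/serum-style block structure orders median correlations", {
  set.seed(61)
  n <- 400
  # urine block: near-independent; serum block: strong common factors
  urine <- matrix(rnorm(n * 8), n, 8,
                  dimnames = list(NULL, paste0("u", 1:8)))
  f1 <- rnorm(n)
  serum <- sapply(1:8, function(i) 0.8 * f1 + 0.6 * rnorm(n))
  colnames(serum) <- paste0("s", 1:8)
  Z <- scale(cbind(urine, serum))
  sex <- rbinom(n, 1, 0.5)
  m_uu <- correlation_map(Z, sex, paste0("u", 1:8), paste0("u", 1:8))
  m_ss <- correlation_map(Z, sex, paste0("s", 1:8), paste0("s", 1:8))
  m_us <- correlation_map(Z, sex, paste0("u", 1:8), paste0("s", 1:8))
  expect_lt(m_uu$median_abs_r, m_ss$median_abs_r)
  expect_lt(m_us$median_abs_r, m_ss$median_abs_r)
})
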