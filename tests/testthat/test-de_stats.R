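test_that("variance filter removes features strictly below the percentile", {
  m <- matrix(rep(c(1, 5), each = 4), 4, 2,
              dimnames = list(paste0("f", 1:4), c("s1", "s2")))
  out <- variance_filter(m, 1)  # all variances equal: nothing strictly below
  expect_equal(nrow(out), 4L)
  expect_length(attr(out, "removed"), 0L)

  set.seed(61)
  m2 <- matrix(rpois(101 * 4, 50), 101, 4,
               dimnames = list(paste0("f", 1:101), paste0("s", 1:4)))
  m2[101, ] <- 7  # constant: variance zero
  out2 <- variance_filter(m2, 1)
  expect_true("f101" %in% attr(out2, "removed"))

  m3 <- matrix(rnbinom(200 * 6, size = 2, mu = 100), 200, 6,
               dimnames = list(paste0("f", 1:200), paste0("s", 1:6)))
  v <- apply(m3, 1, var)
  cut <- quantile(v, 0.01, type = 7, names = FALSE)
  expect_setequal(attr(variance_filter(m3, 1), "removed"), rownames(m3)[v < cut])
  expect_error(variance_filter(m3[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("median-of-ratios size factors: symmetry, hand value, scale equivariance", {
  m <- matrix(c(3, 8, 20), 3, 4, dimnames = list(letters[1:3], paste0("s", 1:4)))
  expect_equal(unname(size_factors_median_of_ratios(m)), rep(1, 4))

  m2 <- matrix(c(10, 30, 50, 20, 60, 100), 3, 2,
               dimnames = list(letters[1:3], c("x", "y")))
  expect_equal(unname(size_factors_median_of_ratios(m2)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # scale equivariance: tripling one column triples its factor relative to
  # every other column, exactly (absolute factors absorb 3^(1/n) through the
  # geometric means, so the invariant lives in the ratios)
  set.seed(62)
  m3 <- matrix(rnbinom(50 * 4, size = 3, mu = 80) + 1, 50, 4,
               dimnames = list(paste0("f", 1:50), paste0("s", 1:4)))
  sf <- size_factors_median_of_ratios(m3)
  m4 <- m3; m4[, 2] <- m4[, 2] * 3
  sfs <- size_factors_median_of_ratios(m4)
  expect_equal(unname(sfs[2] / sfs[1]), unname(3 * sf[2] / sf[1]), tolerance = 1e-12)
  expect_equal(unname(sfs[3] / sfs[1]), unname(sf[3] / sf[1]), tolerance = 1e-12)
  expect_error(size_factors_median_of_ratios(matrix(c(0, 1, 1, 0), 2, 2)),
               "no feature")
})

test_that("size factors agree with an independent median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(63)
  m <- matrix(rnbinom(300 * 8, size = 4, mu = 150), 300, 8,
              dimnames = list(paste0("f", 1:300), paste0("s", 1:8)))
  expect_equal(size_factors_median_of_ratios(m),
               DESeq2::estimateSizeFactorsForMatrix(m), tolerance = 1e-12)
})

test_that("dispersion estimation floors underdispersed features and recovers truth", {
  m <- matrix(5, 1, 6, dimnames = list("x", paste0("s", 1:6)))
  expect_equal(as.numeric(estimate_dispersion(m, factors = rep(1, 6))), 1e-8)

  set.seed(64)
  pois <- matrix(rpois(20 * 25, 60), 25, 20,
                 dimnames = list(paste0("f", 1:25), paste0("s", 1:20)))
  a <- estimate_dispersion(pois, factors = rep(1, 20))
  expect_true(all(a <= 0.01))

  set.seed(65)
  hits <- replicate(200, {
    y <- rnbinom(50, size = 1 / 0.5, mu = 100)
    m1 <- matrix(y, 1, 50, dimnames = list("f", paste0("s", 1:50)))
    a <- estimate_dispersion(m1, factors = rep(1, 50))
    a >= 0.25 && a <= 0.9
  })
  expect_gte(mean(hits), 0.9)

  z <- matrix(0, 1, 6, dimnames = list("z", paste0("s", 1:6)))
  az <- suppressWarnings(estimate_dispersion(z, factors = rep(1, 6)))
  expect_true(is.na(az))
  expect_equal(attr(az, "skipped"), "z")
})

test_that("NB GLM recovers closed-form group fold changes and is offset-invariant", {
  X <- cbind(1, c(0, 0, 0, 1, 1, 1))
  f <- fit_nb_glm(c(10, 10, 10, 20, 20, 20), X, rep(1, 6), 1e-8)
  expect_equal(f$log2fc, 1, tolerance = 1e-6)
  expect_equal(f$base_mean, 15)

  f0 <- fit_nb_glm(c(12, 12, 12, 12, 12, 12), X, rep(1, 6), 1e-8)
  expect_equal(f0$log2fc, 0, tolerance = 1e-8)
  expect_equal(wald_test(f0$log2fc, f0$se)$p, 1, tolerance = 1e-6)

  y <- c(13, 9, 11, 25, 18, 22)
  f1 <- fit_nb_glm(y, X, rep(1, 6), 0.1)
  f2 <- fit_nb_glm(y * 4, X, rep(4, 6), 0.1)
  expect_equal(f1$log2fc, f2$log2fc, tolerance = 1e-6)

  fs <- fit_nb_glm(c(15, 18, 12, 0, 0, 0), X, rep(1, 6), 0.1)
  expect_true(fs$capped)
  expect_equal(fs$log2fc, -30)
})

test_that("Wald p-values match the normal reference and are calibrated under the null", {
  expect_equal(wald_test(0, 1)$p, 1)
  expect_equal(wald_test(1.959964, 1)$p, 0.05, tolerance = 1e-5)
  expect_true(is.na(wald_test(1, 0)$p))

  set.seed(66)
  X <- cbind(1, rep(c(0, 1), each = 5))
  p <- replicate(300, {
    y <- rnbinom(10, size = 1 / 0.2, mu = 100)
    a <- estimate_dispersion(matrix(y, 1, dimnames = list("f", paste0("s", 1:10))),
                             X, rep(1, 10))
    f <- fit_nb_glm(y, X, rep(1, 10), a)
    wald_test(f$log2fc, f$se)$p
  })
  expect_gte(mean(p < 0.05), 0.02)
  expect_lte(mean(p < 0.05), 0.09)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(67)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p) && all(q <= 1))
  }
})

test_that("fold-change classification follows the |log2FC| > 0.6, p < 0.05 rule", {
  expect_equal(classify_change(1.100, 0.007), "up")
  expect_equal(classify_change(-3.046, 0.036), "down")
  expect_equal(classify_change(0.054, 0.896), "no")
  expect_equal(classify_change(-0.579, 0.098), "no")
  # strict inequalities at both thresholds
  expect_equal(classify_change(c(0.6, 0.601, -0.6, -0.601), c(0.04, 0.04, 0.05, 0.04)),
               c("no", "up", "no", "down"))
})

test_that("the DE front end is deterministic and relabelling-invariant", {
  cfg <- sim_config(n_mirnas = 60L, n_per_condition = 5L, mean_range = c(50, 500),
                    de_fraction = 0.1, seed = 68)
  sim <- simulate_counts(cfg)
  cd <- two_group_coldata(sim$condition)
  fit <- mirna_de(sim$counts, cd)
  expect_s3_class(fit, "mirna_de")
  expect_true(all(fit$results$p_adj >= fit$results$p_unadj, na.rm = TRUE))

  set.seed(69)
  perm <- sample(ncol(sim$counts))
  fit2 <- mirna_de(sim$counts[, perm], cd[perm, , drop = FALSE])
  r1 <- fit$results[order(fit$results$mirna), ]
  r2 <- fit2$results[order(fit2$results$mirna), ]
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-9)
  expect_equal(r1$change, r2$change)

  flat <- matrix(rep(seq(40, 130, by = 10), 4), 10, 4,
                 dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))  # identical columns
  fit3 <- mirna_de(flat, two_group_coldata(rep(c("reference", "treatment"), each = 2)))
  expect_true(all(abs(fit3$results$log2fc) < 1e-6))
  expect_true(all(fit3$results$change == "no"))
})

test_that("accessor, volcano and plot methods expose the fitted results", {
  cfg <- sim_config(n_mirnas = 30L, n_per_condition = 4L, seed = 70)
  sim <- simulate_counts(cfg)
  fit <- mirna_de(sim$counts, two_group_coldata(sim$condition))
  expect_named(coef(fit), fit$results$mirna)
  v <- volcano_table(fit)
  expect_equal(v$neg_log10_p, -log10(fit$results$p_unadj))
  expect_output(print(fit), "Negative binomial")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("paired designs fit subject effects without changing the tested contrast", {
  cfg <- sim_config(n_mirnas = 40L, n_per_condition = 4L, mean_range = c(100, 400),
                    de_fraction = 0.25, true_lfc = 2, seed = 71)
  sim <- simulate_counts(cfg)
  cd <- two_group_coldata(sim$condition)
  cd$subject <- factor(rep(1:4, 2))
  fit <- mirna_de(sim$counts, cd, design = ~ subject + condition)
  expect_equal(fit$coef, "conditiontreatment")
  de <- sim$truth$de_flags[fit$results$mirna]
  expect_equal(sign(fit$results$log2fc[de]),
               unname(sign(sim$truth$lfc[fit$results$mirna][de])))
})

test_that("two-sample t-test power follows the noncentral t", {
  expect_equal(power_two_sample_t(10, 10, 0, alpha = 0.05), 0.05, tolerance = 1e-12)
  expect_equal(power_two_sample_t(6, 9, 0.8), 0.29, tolerance = 0.005)
  expect_gt(power_two_sample_t(1000, 1000, 0.8), 0.999)
  # equal-n case agrees with stats::power.t.test, which drops the (tiny)
  # opposite-tail rejection probability
  expect_equal(power_two_sample_t(12, 12, 0.7),
               power.t.test(n = 12, delta = 0.7, sd = 1)$power, tolerance = 1e-3)
})
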