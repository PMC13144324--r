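test_that("zero bicoherence gives null statistics and GL acceptance", {
  g <- gaussianity_test(rep(0, 200), n_eff = 150)
  expect_equal(g$t_g, 0)
  expect_false(g$reject)
  l <- linearity_test(rep(0, 200), n_eff = 150)
  expect_equal(l$t_l, 0)
  expect_equal(l$lambda0, 0)
  expect_false(l$reject)
  expect_equal(classify_recording(g$t_g, l$t_l, g$c_g, l$c_l), "GL")
})

test_that("null constants of the median test match numerical inversion", {
  # chi^2(2) median and density at the median drive the normal null
  expect_equal(2 * log(2), qchisq(0.5, df = 2), tolerance = 1e-12)
  expect_equal(dchisq(qchisq(0.5, df = 2), df = 2), 0.25, tolerance = 1e-12)
  # at alpha = 0.5 the critical value is exactly the null mean 2 log 2
  g <- gaussianity_test(rep(0.01, 100), n_eff = 100, alpha = 0.5)
  expect_equal(g$c_g, 2 * log(2), tolerance = 1e-12)
})

test_that("lambda0 clamps at zero and grows with innovation skewness", {
  # median scaled bicoherence below 2 log 2 -> exact zero
  l <- linearity_test(rep(0.01, 100), n_eff = 10)
  expect_identical(l$lambda0, 0)
  lam <- vapply(list(c("gaussian", 16), c("gamma", 16), c("gamma", 4)),
                function(sp) {
                  mean(vapply(1:5, function(i) {
                    x <- gen_linear(6000, ar = 0.5, innovation = sp[1],
                                    shape = as.numeric(sp[2]),
                                    seed = 300 + i * 17)
                    linearity_test(quick_hos(x)$bicoherence,
                                   n_eff = 130)$lambda0
                  }, numeric(1)))
                }, numeric(1))
  expect_true(lam[1] < lam[2])
  expect_true(lam[2] < lam[3])
})

test_that("linearity threshold exceeds the Gaussianity threshold", {
  for (P in c(50, 500, 5000)) {
    c_g <- 2 * log(2) + qnorm(0.95) * sqrt(4 / P)
    for (lambda0 in c(0, 0.5, 2)) {
      gc <- bisca:::gumbel_constants(P, lambda0)
      c_l <- gc$b_P - gc$a_P * log(-log(0.95))
      expect_gt(c_l, c_g)
    }
  }
})

test_that("both tests hold their size on Gaussian-linear AR processes", {
  # three AR settings, 150 seeded replicates each; empirical rejection
  # rates at alpha = 0.05 must lie within the binomial 95% interval.
  # The dependence-calibrated (surrogate) nulls are exercised: taper and
  # overlap correlations make the independent-pair asymptotics
  # anti-conservative at these settings.
  n <- 4800 # 24 s at 200 Hz
  n_rep <- 150
  ci <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  for (ar in list(0.5, c(0.5, -0.2), c(1.2, -0.6))) {
    n_eff <- neff_for_ar(ar, n, m = 60)
    rej <- t(vapply(seq_len(n_rep), function(i) {
      x <- gen_linear(n, ar = ar, seed = 5000 + i)
      gl <- gl_test(quick_hos(x)$bicoherence, n_eff, alpha = 0.05)
      c(gl$gauss$reject, gl$lin$reject)
    }, logical(2)))
    for (j in 1:2) {
      rate <- mean(rej[, j])
      expect_gt(rate, 0.05 - ci)
      expect_lt(rate, 0.05 + ci)
    }
  }
})

test_that("surrogate calibration widens both nulls at reference settings", {
  n_eff <- neff_for_ar(0.5, 4800, m = 40, seed = 4242)
  p_eff_g <- bisca:::effective_pairs_median(n_eff)
  expect_lt(p_eff_g, 1406) # dependent pairs: fewer effective ones
  expect_gt(p_eff_g, 10)
  x <- gen_linear(4800, ar = 0.5, seed = 9911)
  b <- quick_hos(x)$bicoherence
  l_surr <- linearity_test(b, n_eff, null = "surrogate")
  l_asym <- linearity_test(b, n_eff, null = "asymptotic")
  g_surr <- gaussianity_test(b, n_eff, null = "surrogate")
  g_asym <- gaussianity_test(b, n_eff, null = "asymptotic")
  expect_gt(l_surr$c_l, l_asym$c_l)
  expect_gt(g_surr$c_g, g_asym$c_g)
})

test_that("linearity detection power is monotone in coupling amplitude", {
  n_eff <- 130
  amps <- c(0.2, 0.4, 0.7, 1.2)
  power <- vapply(amps, function(a) {
    mean(vapply(1:15, function(i) {
      x <- gen_qpc(6000, FS, amplitude = a, noise_sd = sqrt(1.5),
                   seed = 900 + i * 13)
      linearity_test(quick_hos(x)$bicoherence, n_eff)$reject
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[4], power[1])
})

test_that("phase-randomized triads are not flagged as nonlinear", {
  n_eff <- neff_for_ar(0, 12000, m = 20) # white background reference
  det <- vapply(c(TRUE, FALSE), function(cpl) {
    mean(vapply(1:12, function(i) {
      x <- gen_qpc(12000, FS, coupled = cpl, seed = 1200 + i * 7)
      linearity_test(quick_hos(x)$bicoherence, n_eff)$reject
    }, logical(1)))
  }, numeric(1))
  expect_gte(det[1], 0.9)
  expect_lte(det[2], 0.25)
})

test_that("four-way classification covers the decision table", {
  expect_equal(classify_recording(1, 1, 2, 2), "GL")
  expect_equal(classify_recording(3, 1, 2, 2), "NGL")
  expect_equal(classify_recording(1, 3, 2, 2), "GNL")
  expect_equal(classify_recording(3, 3, 2, 2), "NGNL")
})

test_that("BH step-up behaves per definition", {
  expect_true(bh_fdr(0.001, 0.05))
  expect_identical(bh_fdr(numeric(0), 0.05), logical(0))
  # p_i = i / m exactly: all rejected iff q >= 1
  p <- (1:10) / 10
  expect_true(all(bh_fdr(p, 1)))
  expect_false(any(bh_fdr(p, 0.5)))
  # one strong p-value among many nulls
  p2 <- c(1e-6, rep(0.9, 99))
  mask <- bh_fdr(p2, 0.001)
  expect_identical(which(mask), 1L)
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "0, 1")
})

test_that("per-pair maps obey BH and never mark nonlinear-but-Gaussian when lambda0 is zero", {
  x <- gen_qpc(12000, FS, coupled = TRUE, seed = 71)
  hos <- quick_hos(x)
  pc <- pairwise_classification(hos$bicoherence, n_eff = 130, q = 0.001,
                                lambda0 = 0)
  # with lambda0 = 0 the linearity p-value equals the Gaussianity p-value,
  # so every linearity rejection is also a Gaussianity rejection
  expect_true(all(!pc$reject_lin | pc$reject_gauss))
  expect_false(any(pc$label == "GNL"))
  # the coupled bifrequency must be among the rejected pairs
  hit <- pc$reject_lin[pc$f1 == 14 & pc$f2 == 10]
  expect_true(hit)
  # all-null map rejects nothing
  pc0 <- pairwise_classification(hos$bicoherence, n_eff = 130, q = 0.001)
  flat <- pairwise_classification(
    structure(tibble::tibble(bin1 = 1:100, bin2 = 1:100, f1 = 1:100,
                             f2 = 1:100,
                             value = complex(real = rep(0.01, 100)),
                             magnitude = rep(0.01, 100), valid = TRUE),
              class = c("bisca_bicoherence", "tbl_df", "tbl", "data.frame")),
    n_eff = 100, q = 0.001)
  expect_false(any(flat$reject_gauss))
})

test_that("effective segments are reproducible and near N_s when independent", {
  x <- gen_linear(30000, ar = 0, seed = 88) # white noise
  es1 <- effective_segments(x, FS, window_samples = 100,
                            overlap_fraction = 0, nw = 1, m = 10, seed = 5)
  es2 <- effective_segments(x, FS, window_samples = 100,
                            overlap_fraction = 0, nw = 1, m = 10, seed = 5)
  expect_identical(es1$n_eff, es2$n_eff)
  # non-overlapping single-taper segments are nearly independent: n_eff is
  # N_s up to the sine-taper bienergy constant of the estimator
  # normalization (slightly above one), so it sits in [N_s, 1.6 N_s]
  expect_gt(es1$n_eff, 0.95 * es1$n_nominal)
  expect_lt(es1$n_eff, 1.6 * es1$n_nominal)
  # overlapped two-taper analysis: n_eff below K * N_s and seed-stable
  es3 <- effective_segments(gen_linear(6000, ar = 0.5, seed = 89), FS,
                            m = 8, seed = 9)
  expect_lt(es3$n_eff, 2 * es3$n_nominal)
  expect_gt(es3$n_eff, 1)
})
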