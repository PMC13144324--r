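test_that("noiseless model-generated spectra are fitted exactly", {
  p <- ref_params()
  g <- gen_from_bisca(p, n_eff = Inf, seed = 2)
  sf <- fit_spectrum(g$spectrum, k_peaks = 3, var_logs = 1,
                     trend_weight = 0)
  expect_true(sf$converged)
  expect_gt(sf$loglik, -1e-6)
  expect_equal(sf$params$rho$mu, p$rho$mu, tolerance = 1e-3)
})

test_that("spectral parameters are recovered under estimator noise", {
  p <- ref_params()
  mu_err <- h_err <- numeric(6)
  for (i in 1:6) {
    g <- gen_from_bisca(p, n_eff = 157, seed = 400 + i)
    sf <- fit_spectrum(g$spectrum, k_peaks = 3, n_eff = 157)
    mu_err[i] <- max(abs(sf$params$rho$mu - p$rho$mu))
    h_err[i] <- max(abs(sf$params$rho$h - p$rho$h) / p$rho$h)
  }
  expect_lte(median(mu_err), 2 / 3) # one grid bin
  expect_lte(median(h_err), 0.2)
})

test_that("joint fit recovers complex coupling amplitudes", {
  p <- ref_params()
  rel <- vapply(1:5, function(i) {
    g <- gen_from_bisca(p, n_eff = 157, seed = 500 + i)
    fj <- fit_joint(g$spectrum, g$bispectrum, k_peaks = 3, n_eff = 157)
    Mod(fj$params$bisp$h_rho[1] - p$bisp$h_rho[1]) / Mod(p$bisp$h_rho[1])
  }, numeric(1))
  expect_lt(median(rel), 0.3)
})

test_that("null coupling stays null after fitting", {
  p0 <- ref_params(h_b_rho = complex(length.out = 6), h_b_xi = 0 + 0i)
  g <- gen_from_bisca(p0, n_eff = 157, seed = 66)
  fj <- fit_joint(g$spectrum, g$bispectrum, k_peaks = 3, n_eff = 157)
  ct <- component_tests(decompose_bicoherence(fj), n_eff = 157)
  expect_false(ct$xi$lin$reject)
  expect_false(ct$rho$lin$reject)
})

test_that("fits are deterministic from a fixed initialization", {
  g <- gen_from_bisca(ref_params(), n_eff = 157, seed = 3)
  f1 <- fit_joint(g$spectrum, g$bispectrum, k_peaks = 3, n_eff = 157)
  f2 <- fit_joint(g$spectrum, g$bispectrum, k_peaks = 3, n_eff = 157)
  expect_identical(unlist(f1$params$rho), unlist(f2$params$rho))
  expect_identical(f1$loglik, f2$loglik)
})

test_that("AIC selects one peak for single-peak data", {
  p1 <- bisca_params(
    xi = list(h = 15, sigma = 4, nu = 1.2, d = 2.5),
    rho = list(h = 5, mu = 10, sigma = 1.5, nu = 1, d = 2.5),
    h_b_rho = 1 + 0.5i)
  g <- gen_from_bisca(p1, n_eff = 157, seed = 77)
  sel <- select_peaks(g$spectrum, g$bispectrum, k_range = 1:3, n_eff = 157)
  expect_equal(sel$params$k_peaks, 1L)
})

test_that("fit quality is non-decreasing in the candidate peak count", {
  g <- gen_from_bisca(ref_params(), n_eff = 157, seed = 78)
  sel <- select_peaks(g$spectrum, g$bispectrum, k_range = 1:4, n_eff = 157)
  tab <- sel$aic_table
  # nested models: allow only optimizer-level slack (1% of the total
  # improvement) in the monotonicity of the objective
  slack <- 0.01 * diff(range(tab$loglik))
  expect_true(all(diff(tab$loglik) > -slack))
  expect_true(all(c("aic", "loglik", "converged") %in% names(tab)))
})

test_that("harmonic-grid mode constrains centers to the ratio ladder", {
  p <- ref_params()
  g <- gen_from_bisca(p, n_eff = 157, seed = 79)
  sf <- fit_spectrum(g$spectrum, k_peaks = 3, mode = "harmonic",
                     n_eff = 157)
  mu_alpha <- sf$params$mu_alpha
  expect_equal(sf$params$rho$mu, c(1, 2, 3) * mu_alpha, tolerance = 1e-9)
  expect_equal(mu_alpha, 10, tolerance = 0.5)
})
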