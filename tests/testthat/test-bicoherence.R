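test_that("bicoherence is invariant under amplitude rescaling", {
  x <- gen_linear(3000, ar = 0.4, innovation = "gamma", seed = 12)
  base <- quick_hos(x)$bicoherence
  for (c in c(0.5, 2, 10)) {
    expect_equal(quick_hos(c * x)$bicoherence$value, base$value,
                 tolerance = 1e-10)
  }
})

test_that("Gaussian-noise mean squared bicoherence matches 1 / n_eff", {
  # independence-limit sanity band plus consistency with the surrogate
  # calibration on an independent realization of the same process
  x <- gen_linear(12000, ar = 0.5, seed = 41)
  hos <- quick_hos(x)
  m <- mean(hos$bicoherence$magnitude[hos$bicoherence$valid]^2)
  n_s <- hos$segments$n_segments
  expect_gt(1 / m, 0.5 * n_s)
  expect_lt(1 / m, 1.2 * 2 * n_s) # K * N_s upper sanity bound
  n_eff <- neff_for_ar(0.5, 12000, m = 20)
  expect_equal(m, 1 / n_eff$n_eff, tolerance = 0.2)
})

test_that("flat NGL surface recovers the innovation cumulant ratio", {
  # gamma(16) innovations have skewness 0.5; the bias-corrected level
  # estimator removes the 1/n_eff stochastic floor
  n_eff <- neff_for_ar(0.5, 12000, m = 20)
  est <- vapply(1:4, function(i) {
    x <- gen_linear(12000, ar = 0.5, innovation = "gamma", shape = 16,
                    seed = 100 + i)
    innovation_asymmetry(quick_hos(x)$bicoherence, n_eff)
  }, numeric(1))
  expect_equal(mean(est), 0.5, tolerance = 0.2)
})

test_that("NGL bicoherence is flat while GNL bicoherence is peaked", {
  ngl <- quick_hos(gen_linear(12000, ar = 0.5, innovation = "gamma",
                              shape = 4, seed = 51))$bicoherence
  gnl <- quick_hos(gen_qpc(12000, FS, seed = 52))$bicoherence
  cv <- function(b) stats::sd(b$magnitude[b$valid]) /
    mean(b$magnitude[b$valid])
  expect_lt(cv(ngl), cv(gnl))
})

test_that("pairs with degenerate spectral support are flagged invalid", {
  spec <- tibble::tibble(bin = 1:10, f = 1:10,
                         power = c(rep(1, 9), 0))
  spec <- structure(spec, class = c("bisca_spectrum", class(spec)),
                    band = c(f_min = 1, f_max = 10))
  dom <- build_bifrequency_domain(1, 10)
  bisp <- tibble::tibble(bin1 = dom$bin1, bin2 = dom$bin2, f1 = dom$f1,
                         f2 = dom$f2,
                         value = complex(real = rep(1, nrow(dom))))
  bisp <- structure(bisp, class = c("bisca_bispectrum", class(bisp)),
                    n_segments = 10, window_samples = 20, df = 1, fs = 20,
                    K = 1)
  b <- bicoherence(spec, bisp)
  bad <- b$bin1 + b$bin2 == 10
  expect_true(all(!b$valid[bad]))
  expect_true(all(b$valid[!bad]))
  expect_equal(attr(b, "n_valid"), sum(!bad))
})

test_that("diagonal bicoherence peak localizes harmonic doubling", {
  # alpha + alpha -> 2 alpha: coupled triad with f_a = f_b = 10 Hz
  x <- gen_qpc(12000, FS, f_a = 10, f_b = 10, coupled = TRUE, seed = 61)
  hos <- quick_hos(x)
  pk <- peak_frequencies(hos$spectrum, hos$bicoherence)
  expect_equal(pk$f_bmax, 10)
})

test_that("argmax ties break toward the lower frequency", {
  spec <- tibble::tibble(bin = 1:20, f = (1:20) / 2, power = rep(1, 20))
  spec <- structure(spec, class = c("bisca_spectrum", class(spec)),
                    band = c(f_min = 0.5, f_max = 10))
  dom <- build_bifrequency_domain(0.5, 8)
  bico <- tibble::tibble(bin1 = dom$bin1, bin2 = dom$bin2, f1 = dom$f1,
                         f2 = dom$f2,
                         value = complex(real = rep(0.3, nrow(dom))),
                         magnitude = rep(0.3, nrow(dom)),
                         valid = TRUE)
  class(bico) <- c("bisca_bicoherence", class(bico))
  pk <- peak_frequencies(spec, bico)
  expect_equal(pk$f_smax, 0.5)
  expect_equal(pk$f_bmax, 0.5)
})
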