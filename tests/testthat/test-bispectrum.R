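test_that("bifrequency domain enumerates the principal region", {
  d <- build_bifrequency_domain(df = 1, f_sum_max = 4, f_max = 2)
  expect_equal(d[, c("f1", "f2")],
               tibble::tibble(f1 = c(1, 2, 2), f2 = c(1, 1, 2)),
               ignore_attr = TRUE)
  expect_equal(attr(d, "P"), 3L)
  expect_error(build_bifrequency_domain(df = 1, f_sum_max = 1.5), "empty")
  expect_error(build_bifrequency_domain(df = 1, f_sum_max = 60, fs = 100),
               "Nyquist")
})

test_that("reference-grid pair count matches brute-force enumeration", {
  df <- FS / 300 # 2/3 Hz
  d <- build_bifrequency_domain(df, 50)
  brute <- 0L
  for (j1 in 1:200) for (j2 in 1:200) {
    if (j1 >= j2 && (j1 + j2) * df <= 50 + 1e-9) brute <- brute + 1L
  }
  expect_equal(nrow(d), brute)
  expect_true(all(d$f1 >= d$f2 & d$f2 > 0))
  expect_true(all(d$f1 + d$f2 <= 50 + 1e-9))
})

test_that("single-taper bispectrum equals the triple-correlation transform", {
  # For K = 1 and one segment the estimator reduces to
  # DFT2[c3_y](j1, j2) / (N * P111), where c3_y is the circular triple
  # correlation of the tapered segment. This checks the full taper-triple
  # machinery against a definition-level computation.
  n <- 64
  x <- gen_linear(n, ar = 0.3, innovation = "gamma", seed = 8)
  seg <- segment_signal(x, FS, window_samples = n)
  tp <- sine_tapers(n, 1)
  dom <- build_bifrequency_domain(FS / n, f_sum_max = 60, fs = FS)
  est <- multitaper_bispectrum(seg, tp, dom)

  y <- seg$segments[1, ] * tp$tapers[1, ]
  c3 <- matrix(0, n, n)
  for (t1 in 0:(n - 1)) for (t2 in 0:(n - 1)) {
    c3[t1 + 1, t2 + 1] <- mean(y * y[(0:(n - 1) + t1) %% n + 1] *
                                 y[(0:(n - 1) + t2) %% n + 1])
  }
  C3 <- stats::fft(c3)
  p111 <- sum(tp$tapers[1, ]^3)
  oracle <- C3[cbind(dom$bin1 + 1, dom$bin2 + 1)] / (n * p111)
  expect_lt(max(Mod(est$value - oracle) / Mod(oracle)), 1e-8)
})

test_that("bispectrum scales cubically and is exchange-symmetric", {
  x <- gen_linear(3000, ar = 0.4, innovation = "gamma", seed = 5)
  seg <- segment_signal(x, FS)
  tp <- sine_tapers(300, 2)
  dom <- build_bifrequency_domain(FS / 300, 30, fs = FS)
  base <- multitaper_bispectrum(seg, tp, dom)
  for (c in c(0.5, 2, 10)) {
    seg_c <- segment_signal(c * x, FS)
    expect_equal(multitaper_bispectrum(seg_c, tp, dom)$value,
                 c^3 * base$value, tolerance = 1e-10)
  }
  # swap f1/f2: same values after mapping back to the stored ordering
  swapped <- dom
  swapped$bin1 <- dom$bin2; swapped$bin2 <- dom$bin1
  swapped$f1 <- dom$f2; swapped$f2 <- dom$f1
  est_swap <- multitaper_bispectrum(seg, tp, swapped)
  expect_equal(est_swap$value, base$value, tolerance = 1e-12)
})

test_that("a coupled triad produces the bispectral peak at its bifrequency", {
  x <- gen_qpc(12000, FS, f_a = 10, f_b = 14, coupled = TRUE, seed = 31)
  hos <- quick_hos(x)
  i <- which.max(Mod(hos$bispectrum$value))
  expect_equal(hos$bispectrum$f1[i], 14)
  expect_equal(hos$bispectrum$f2[i], 10)
})
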