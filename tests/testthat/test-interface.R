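test_that("delimited recordings round-trip with explicit sampling rate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  x <- cbind(ch1 = rnorm(1200), ch2 = rnorm(1200))
  utils::write.table(x, path, row.names = FALSE, quote = FALSE, sep = "\t")
  rec <- read_recording(path, fs = 200)
  expect_equal(rec$labels, c("ch1", "ch2"))
  expect_equal(lengths(rec$signals), c(ch1 = 1200L, ch2 = 1200L))
  expect_equal(rec$signals$ch1, x[, 1], tolerance = 1e-6)
  expect_error(read_recording(path), "fs")
  expect_error(read_recording(tempfile()), "not found")
})

test_that("EDF files read back physical values and skip annotations", {
  path <- withr::local_tempfile(fileext = ".edf")
  tt <- (0:1199) / 200
  sigs <- list(C3 = 50 * sin(2 * pi * 10 * tt),
               C4 = 30 * cos(2 * pi * 6 * tt))
  write_edf_fixture(path, sigs, fs = 200, add_annotations = TRUE)
  expect_message(rec <- read_recording(path), "annotation")
  expect_equal(rec$labels, c("C3", "C4"))
  expect_equal(rec$fs, 200)
  # 16-bit quantization over a ~100 uV range
  expect_equal(rec$signals$C3, sigs$C3, tolerance = 0.01)
  expect_equal(rec$signals$C4, sigs$C4, tolerance = 0.01)
})

test_that("preprocessing preserves in-band amplitude and segment counts", {
  tt <- (0:13999) / 200
  x <- sin(2 * pi * 10 * tt)
  pp <- preprocess(x, fs = 200)
  y <- pp$chunks[[1]]
  mid <- y[2000:10000]
  expect_equal(stats::sd(mid), stats::sd(x[2000:10000]), tolerance = 0.01)
  # 60 s at 200 Hz yields 157 downstream segments
  pp60 <- preprocess(rnorm(12000), fs = 200)
  seg <- segment_preprocessed(pp60)
  expect_equal(seg$n_segments, 157)
  expect_error(preprocess(rep(0, 5000), fs = 200), "zero-run")
  expect_error(preprocess(rnorm(100), fs = 120), "twice")
})

test_that("zero-run dropouts split the signal so no window spans a splice", {
  x <- c(rnorm(3000), rep(0, 50), rnorm(2000))
  pp <- preprocess(x, fs = 200)
  expect_equal(length(pp$chunks), 2)
  expect_equal(pp$n_dropped_zero, 50)
  seg <- segment_preprocessed(pp)
  # each chunk is segmented separately
  counts <- vapply(pp$chunks, function(ch)
    floor((length(ch) - 300) / 75) + 1, numeric(1))
  expect_equal(seg$n_segments, sum(counts))
  # isolated zeros are not dropouts
  x2 <- rnorm(1000)
  x2[500] <- 0
  expect_equal(length(preprocess(x2, fs = 200)$chunks), 1)
})

test_that("resampling maps content to the common analysis rate", {
  tt <- (0:23999) / 400
  x <- sin(2 * pi * 10 * tt) + 0.05 * rnorm(24000)
  pp <- preprocess(x, fs = 400, resample_to = 200)
  expect_equal(length(pp$chunks[[1]]), 12000, tolerance = 0.01)
  hos <- estimate_hos(pp$chunks[[1]], fs = 200)
  pk <- peak_frequencies(hos$spectrum, hos$bicoherence)
  expect_equal(pk$f_smax, 10)
})

test_that("configuration defaults reproduce the reference settings", {
  cfg <- bisca_config()
  expect_equal(cfg$fs, 200)
  expect_equal(cfg$window_samples, 300L)
  expect_equal(cfg$overlap_fraction, 0.75)
  expect_equal(cfg$nw, 1.5)
  expect_equal(cfg$f_sum_max, 50)
  expect_equal(cfg$fdr_q, 0.001)
  expect_equal(cfg$m_surrogates, 100)
  expect_equal(cfg$k_range, 1:11)
  expect_equal(cfg$bandpass, c(0.5, 80))
  expect_equal(cfg$resample_to, 200)
  expect_equal(bisca_config(fs = 200, window_seconds = 1.5)$window_samples,
               300L)
})

test_that("the pipeline is deterministic and isolates channel failures", {
  cfg <- bisca_config(m_surrogates = 5, master_seed = 42)
  rec <- list(a = gen_linear(6000, ar = 0.5, seed = 1),
              b = gen_qpc(6000, FS, seed = 2),
              bad = rnorm(100)) # too short for one window
  p1 <- run_pipeline(rec, cfg, do_preprocess = FALSE)
  p2 <- run_pipeline(rec, cfg, do_preprocess = FALSE)
  expect_equal(names(p1$reports), c("a", "b"))
  expect_equal(names(p1$failures), "bad")
  expect_identical(cohort_table(p1), cohort_table(p2))
  # cohort percentages close over the classified channels
  s <- p1$summary
  expect_equal(s$total[s$gaussianity == "Total"], 100)
  expect_equal(s$linear[3] + s$nonlinear[3], 100)
  # per-channel JSON export round-trips
  path <- withr::local_tempfile(fileext = ".json")
  report_json(p1$reports$a, path)
  js <- jsonlite::fromJSON(path)
  expect_equal(js$label, p1$reports$a$gl$label)
  expect_equal(js$n_eff, p1$reports$a$n_eff$n_eff)
})

test_that("surface export flattens complex columns to re/im pairs", {
  hos <- quick_hos(gen_linear(3000, ar = 0.4, seed = 5))
  tab <- surface_table(hos$bicoherence)
  expect_true(all(c("value_re", "value_im") %in% names(tab)))
  expect_false(any(vapply(tab, is.complex, logical(1))))
})

test_that("average referencing removes the common signal", {
  rec <- structure(list(signals = list(a = rnorm(500), b = rnorm(500)),
                        fs = 200, labels = c("a", "b")),
                   class = "bisca_recording")
  ar <- average_reference(rec)
  expect_equal(ar$signals$a + ar$signals$b, rep(0, 500), tolerance = 1e-12)
})
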