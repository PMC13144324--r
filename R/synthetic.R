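# Seeded generators for the four reference signal classes and for
# model-generated spectral surfaces. These stand in for real EEG/iEEG in
# calibration, power and parameter-recovery studies: stationary zero-mean
# processes with controlled innovation cumulants, quadratic phase coupling,
# and harmonic waveforms with controlled even/odd content.

#' Standardized i.i.d. innovations
#'
#' Zero-mean, unit-variance innovations. `"gamma"` with shape `s` has
#' skewness `2 / sqrt(s)` (shape 16 gives 0.5); `"exponential"` has skewness
#' 2; `"gaussian"` has skewness 0.
#'
#' @param n Number of samples.
#' @param type One of `"gaussian"`, `"gamma"`, `"exponential"`.
#' @param shape Gamma shape parameter.
#' @param seed Optional seed (draws from the current RNG stream when `NULL`).
#' @return Numeric vector of length `n`.
#' @export
gen_innovations <- function(n, type = c("gaussian", "gamma", "exponential"),
                            shape = 16, seed = NULL) {
  type <- match.arg(type)
  draw <- function() {
    switch(type,
           gaussian = rnorm(n),
           gamma = (rgamma(n, shape = shape) - shape) / sqrt(shape),
           exponential = rexp(n) - 1)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Linear AR process (GL / NGL classes)
#'
#' Applies a stable AR filter to standardized i.i.d. innovations; a burn-in
#' of ten times the AR order is discarded. Gaussian innovations give the
#' Gaussian-linear null class; skewed innovations (nonzero third cumulant)
#' give the non-Gaussian-linear class with a flat bicoherence surface at the
#' innovation cumulant ratio.
#'
#' @param n Number of output samples.
#' @param ar AR coefficients (must define a stable filter).
#' @param innovation Innovation type, see [gen_innovations()].
#' @param shape Gamma shape (innovation skewness `2 / sqrt(shape)`).
#' @param seed Mandatory seed; identical seeds give identical output.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- gen_linear(2000, ar = 0.5, innovation = "gamma", seed = 1)
gen_linear <- function(n, ar = 0.5, innovation = "gaussian", shape = 16,
                       seed) {
  if (!ar_is_stable(ar)) abort("AR polynomial is unstable.")
  p <- max(1L, length(ar))
  burn <- 10L * p
  innov <- gen_innovations(n + burn, innovation, shape, seed = seed)
  ar_filter(innov, ar)[(burn + 1):(burn + n)]
}

#' Quadratically phase-coupled triad (GNL class)
#'
#' Sum of cosines at `f_a`, `f_b` and `f_a + f_b` in additive Gaussian
#' noise. Phases are redrawn independently every `epoch_samples` samples; in
#' the coupled case the third phase equals the sum of the first two (the
#' quadratic phase-coupling relation), otherwise it is an independent
#' uniform phase, which leaves the power spectrum unchanged but destroys the
#' bispectral peak.
#'
#' @param n,fs Length (samples) and sampling rate (Hz).
#' @param f_a,f_b Triad base frequencies in Hz (with `f_a + f_b` below
#'   Nyquist).
#' @param amplitude Cosine amplitude (shared by the three components).
#' @param coupled Logical: enforce the phase-coupling relation.
#' @param noise_sd Additive Gaussian noise SD; the default
#'   `sqrt(3/2) * amplitude` sets the rhythmic-to-noise power ratio to one
#'   (0 dB).
#' @param epoch_samples Phase-redraw epoch (default 300 samples).
#' @param seed Mandatory seed.
#' @return Numeric vector of length `n`.
#' @export
gen_qpc <- function(n, fs, f_a = 10, f_b = 14, amplitude = 1, coupled = TRUE,
                    noise_sd = sqrt(1.5) * amplitude, epoch_samples = 300,
                    seed) {
  if (f_a + f_b >= fs / 2) abort("`f_a + f_b` must be below Nyquist.")
  withr::with_seed(seed, {
    x <- numeric(n)
    tvec <- (0:(n - 1)) / fs
    n_ep <- ceiling(n / epoch_samples)
    for (e in seq_len(n_ep)) {
      id <- (((e - 1) * epoch_samples + 1):min(e * epoch_samples, n))
      tt <- tvec[id]
      ph_a <- runif(1, 0, 2 * pi)
      ph_b <- runif(1, 0, 2 * pi)
      ph_c <- if (coupled) ph_a + ph_b else runif(1, 0, 2 * pi)
      x[id] <- amplitude * (cos(2 * pi * f_a * tt + ph_a) +
                              cos(2 * pi * f_b * tt + ph_b) +
                              cos(2 * pi * (f_a + f_b) * tt + ph_c))
    }
    x + rnorm(n, sd = noise_sd)
  })
}

#' Harmonic waveform with controlled even/odd content
#'
#' Periodic waveform `sum_h A_h cos(2 pi h f0 t + h phi(t) + psi_h)` whose
#' fundamental phase `phi` diffuses slowly (random walk), so segments
#' decorrelate while the inter-harmonic phase relations are preserved.
#' Time-antisymmetric (odd-symmetric) dynamics produce only odd harmonics
#' and negligible bicoherence; asymmetric waveforms carry even harmonics and
#' strong quadratic phase coupling. Setting `phase_locked = FALSE` redraws
#' the harmonic offsets `psi_h` every epoch, destroying the coupling without
#' changing the power spectrum.
#'
#' @param n,fs Length (samples) and sampling rate (Hz).
#' @param f0 Fundamental frequency in Hz.
#' @param amplitudes Amplitudes per harmonic order (order 1 = fundamental).
#' @param even_content If `FALSE`, all even-order amplitudes are zeroed.
#' @param phase_locked If `TRUE` (default) harmonic offsets are constant.
#' @param phase_diffusion Random-walk step SD of the fundamental phase, in
#'   radians per sample (default 0.02).
#' @param noise_sd Additive Gaussian noise SD.
#' @param epoch_samples Epoch for `psi` redraws when not phase-locked.
#' @param seed Mandatory seed.
#' @return Numeric vector of length `n`.
#' @export
gen_harmonic_waveform <- function(n, fs, f0 = 10,
                                  amplitudes = c(1, 0.6, 0.35, 0.2),
                                  even_content = TRUE, phase_locked = TRUE,
                                  phase_diffusion = 0.02, noise_sd = 0.3,
                                  epoch_samples = 300, seed) {
  h_ord <- seq_along(amplitudes)
  if (max(h_ord) * f0 >= fs / 2) {
    abort("highest harmonic must be below Nyquist.")
  }
  amps <- amplitudes
  if (!even_content) amps[h_ord %% 2 == 0] <- 0
  withr::with_seed(seed, {
    phi <- cumsum(rnorm(n, sd = phase_diffusion)) + runif(1, 0, 2 * pi)
    tvec <- (0:(n - 1)) / fs
    psi <- runif(length(amps), 0, 2 * pi)
    x <- numeric(n)
    n_ep <- ceiling(n / epoch_samples)
    for (e in seq_len(n_ep)) {
      id <- (((e - 1) * epoch_samples + 1):min(e * epoch_samples, n))
      if (!phase_locked) psi <- runif(length(amps), 0, 2 * pi)
      for (h in h_ord) {
        if (amps[h] == 0) next
        x[id] <- x[id] + amps[h] *
          cos(2 * pi * h * f0 * tvec[id] + h * phi[id] + psi[h])
      }
    }
    x + rnorm(n, sd = noise_sd)
  })
}

#' Model-generated spectral surfaces with estimator noise
#'
#' Evaluates the Xi + Rho model on the analysis grids and perturbs it with
#' the estimators' asymptotic sampling noise: the log spectrum receives
#' additive Gaussian noise of variance `Var[log S_hat]`, and the bispectrum
#' receives complex Gaussian noise of variance
#' `S(f1) S(f2) S(f1+f2) / n_eff`. Used for parameter-recovery and
#' model-selection studies.
#'
#' @param params A [bisca_params()] object.
#' @param fs,window_samples Grid-defining settings (default 200 Hz, 300).
#' @param f_max Spectrum grid upper edge in Hz (default 50).
#' @param f_sum_max Bifrequency closure cap in Hz (default 50).
#' @param n_eff Effective segments controlling the noise level (default
#'   157); `Inf` gives noiseless surfaces.
#' @param K Taper count entering `Var[log S_hat]` (default 2).
#' @param seed Mandatory seed.
#' @return A list with `spectrum` (`bisca_spectrum`-classed tibble),
#'   `bispectrum` (`bisca_bispectrum`-classed tibble), `domain`, `params`,
#'   `var_logs`, `n_eff`.
#' @export
gen_from_bisca <- function(params, fs = 200, window_samples = 300,
                           f_max = 50, f_sum_max = 50, n_eff = 157, K = 2,
                           seed) {
  df <- fs / window_samples
  bins <- seq_len(floor(f_max / df + 1e-9))
  f <- bins * df
  domain <- build_bifrequency_domain(df, f_sum_max, fs = fs)
  var_logs <- if (is.finite(n_eff)) var_log_spectrum(K, n_eff) else 0
  ms <- model_spectrum(params, f)
  mb <- model_bispectrum(params, domain)
  s_at <- function(fq) model_spectrum(params, fq)$power
  noise_var <- if (is.finite(n_eff)) {
    s_at(domain$f1) * s_at(domain$f2) * s_at(domain$f1 + domain$f2) / n_eff
  } else 0
  surfaces <- withr::with_seed(seed, {
    pw <- exp(log(ms$power) + rnorm(length(f), sd = sqrt(var_logs)))
    bv <- mb$value + complex(
      real = rnorm(nrow(domain), sd = sqrt(noise_var / 2)),
      imaginary = rnorm(nrow(domain), sd = sqrt(noise_var / 2)))
    list(pw = pw, bv = bv)
  })
  spec <- tibble(bin = bins, f = f, power = surfaces$pw)
  spec <- structure(spec, class = c("bisca_spectrum", class(spec)),
                    fs = fs, df = df, window_samples = window_samples, K = K,
                    n_segments = n_eff, U2 = K / window_samples,
                    band = c(f_min = df, f_max = f_max))
  bisp <- tibble(bin1 = domain$bin1, bin2 = domain$bin2,
                 f1 = domain$f1, f2 = domain$f2, value = surfaces$bv)
  bisp <- structure(bisp, class = c("bisca_bispectrum", class(bisp)),
                    K = K, n_segments = n_eff, fs = fs, df = df,
                    window_samples = window_samples,
                    f_sum_max = f_sum_max)
  list(spectrum = spec, bispectrum = bisp, domain = domain, params = params,
       var_logs = var_logs, n_eff = n_eff)
}
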