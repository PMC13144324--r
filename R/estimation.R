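# Multitaper spectrum / bispectrum / bicoherence estimation.
#
# Conventions (kept throughout the package):
#   * per-segment, per-taper DFT X_{k,e}(f) = (1/N_t) sum_n x_e(n) v_k(n) e^{-i 2 pi f n}
#   * spectrum:   S_hat(f) = (1/U2) sum_k |X_{k,e}(f)|^2 averaged over segments,
#                 U2 = K / N_t
#   * bispectrum: B_hat(f1,f2) = (1/U3) sum_{k1,k2,k3} P_{k1k2k3}
#                 X_{k1,e}(f1) X_{k2,e}(f2) X*_{k3,e}(f1+f2), averaged over
#                 segments, with bienergy P_{k1k2k3} = sum_t v_k1 v_k2 v_k3
#                 and U3 = (1/N_t) sum P^2
# Under these constants Var[B_hat] = S(f1) S(f2) S(f1+f2) holds exactly, which
# is what the downstream tests are calibrated on.

# Tapered eigen-FFTs for all segments: complex array [bin0..nyquist, K, n_seg].
taper_ffts <- function(seg, tapers) {
  stopifnot(inherits(seg, "bisca_segments"), inherits(tapers, "bisca_tapers"))
  nt <- seg$window_samples
  if (ncol(tapers$tapers) != nt) {
    abort("taper length must equal `window_samples`.")
  }
  n_bins <- floor(nt / 2)
  out <- array(0 + 0i, dim = c(n_bins + 1L, tapers$K, seg$n_segments))
  for (e in seq_len(seg$n_segments)) {
    for (k in seq_len(tapers$K)) {
      out[, k, e] <- (fft(seg$segments[e, ] * tapers$tapers[k, ]) / nt)[
        seq_len(n_bins + 1L)]
    }
  }
  out
}

#' Multitaper power spectrum
#'
#' Averages sine-taper eigenspectra over tapers and segments. The spectrum is
#' returned on the full discrete grid `f = j * fs / N_t` for
#' `j = 1, ..., floor(N_t / 2)` (DC excluded); `f_min`/`f_max` mark the
#' analysis band used by [peak_frequencies()] and plotting but all bins up to
#' Nyquist are retained so bicoherence denominators are always available.
#'
#' @param seg A [segment_signal()] result.
#' @param tapers A [sine_tapers()] result, or `NULL` to build `K`
#'   tapers from `nw`.
#' @param nw Time-bandwidth product used when `tapers` is `NULL`.
#' @param f_min,f_max Analysis band edges in Hz; defaults are the first grid
#'   bin and Nyquist. `f_max` beyond Nyquist is an error.
#'
#' @return A tibble of class `bisca_spectrum` with columns `bin`, `f`,
#'   `power`, and attributes `fs`, `df`, `window_samples`, `K`, `n_segments`,
#'   `U2`, `band`.
#' @export
multitaper_spectrum <- function(seg, tapers = NULL, nw = 1.5,
                                f_min = NULL, f_max = NULL) {
  stopifnot(inherits(seg, "bisca_segments"))
  tapers <- tapers %||% sine_tapers(seg$window_samples, tapers_for_nw(nw))
  nt <- seg$window_samples
  df <- seg$fs / nt
  nyq <- seg$fs / 2
  f_min <- f_min %||% df
  f_max <- f_max %||% nyq
  if (f_max > nyq + 1e-9) abort("`f_max` exceeds the Nyquist frequency.")
  if (f_min <= 0) abort("`f_min` must be positive (DC is excluded).")

  X <- taper_ffts(seg, tapers)
  U2 <- tapers$K / nt
  pow_seg <- vapply(
    seq_len(seg$n_segments),
    function(e) rowSums(abs(X[, , e, drop = FALSE])^2) / U2,
    numeric(dim(X)[1]))
  power <- rowMeans(pow_seg)
  bins <- seq_len(floor(nt / 2)) # drop DC
  out <- tibble(bin = bins, f = bins * df, power = power[bins + 1L])
  structure(out,
            class = c("bisca_spectrum", class(out)),
            fs = seg$fs, df = df, window_samples = nt, K = tapers$K,
            n_segments = seg$n_segments, U2 = U2,
            band = c(f_min = f_min, f_max = f_max))
}

#' Closure-constrained bifrequency domain
#'
#' Enumerates the principal (non-redundant) bifrequency pairs
#' `f1 >= f2 > 0` with `f1 + f2 <= f_sum_max` on the discrete grid
#' `f = j * df`. Pairs are listed in row-major order (increasing `f2`, then
#' `f1`).
#'
#' @param df Grid step in Hz (`fs / N_t`).
#' @param f_sum_max Cap on `f1 + f2` in Hz (analysis default 50 Hz).
#' @param fs Sampling rate, used to enforce `f_sum_max <= fs / 2` when given.
#' @param f_max Optional cap on `f1` (the grid's upper band edge); by
#'   default only the closure constraint limits the pairs.
#'
#' @return A tibble of class `bisca_domain` with columns `bin1`, `bin2`,
#'   `f1`, `f2` and attributes `df`, `f_sum_max`, `P` (pair count).
#' @export
#' @examples
#' build_bifrequency_domain(df = 1, f_sum_max = 4, f_max = 2)
build_bifrequency_domain <- function(df, f_sum_max, fs = NULL, f_max = NULL) {
  if (!is.null(fs) && f_sum_max > fs / 2 + 1e-9) {
    abort("`f_sum_max` must not exceed the Nyquist frequency.")
  }
  j_sum_max <- floor(f_sum_max / df + 1e-9)
  j_max <- if (is.null(f_max)) j_sum_max else floor(f_max / df + 1e-9)
  if (j_sum_max < 2) {
    abort("empty bifrequency domain: `f_sum_max` is below 2 grid steps.")
  }
  rows <- lapply(seq_len(floor(j_sum_max / 2)), function(j2) {
    top <- min(j_sum_max - j2, j_max)
    if (top < j2) return(NULL)
    tibble(bin1 = seq.int(j2, top), bin2 = j2)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$bin2, .data$bin1)
  out$f1 <- out$bin1 * df
  out$f2 <- out$bin2 * df
  structure(out,
            class = c("bisca_domain", class(out)),
            df = df, f_sum_max = f_sum_max, P = nrow(out))
}

#' Multitaper bispectrum
#'
#' Weighted sum over all `K^3` taper triples of
#' `X_{k1}(f1) X_{k2}(f2) X*_{k3}(f1 + f2)` with bienergy weights
#' `P_{k1 k2 k3}`, normalized by `U3 = (1/N_t) sum P^2` and averaged
#' uniformly over segments. Scaling the input signal by `c` scales the
#' result by `c^3`.
#'
#' @inheritParams multitaper_spectrum
#' @param domain A [build_bifrequency_domain()] result; its grid step must
#'   match the segment grid and all `f1 + f2` must be at or below Nyquist.
#'
#' @return A tibble of class `bisca_bispectrum` with columns `bin1`, `bin2`,
#'   `f1`, `f2`, `value` (complex), and attributes `U3`, `bienergies`, `K`,
#'   `n_segments`, `fs`, `df`, `window_samples`.
#' @export
multitaper_bispectrum <- function(seg, tapers = NULL, domain, nw = 1.5) {
  stopifnot(inherits(seg, "bisca_segments"), inherits(domain, "bisca_domain"))
  tapers <- tapers %||% sine_tapers(seg$window_samples, tapers_for_nw(nw))
  nt <- seg$window_samples
  df <- seg$fs / nt
  if (abs(attr(domain, "df") - df) > 1e-9) {
    abort("domain grid step does not match the segment grid (fs / N_t).")
  }
  n_bins <- floor(nt / 2)
  if (max(domain$bin1 + domain$bin2) > n_bins) {
    abort("domain contains sum frequencies beyond Nyquist.")
  }
  X <- taper_ffts(seg, tapers)
  K <- tapers$K
  V <- tapers$tapers
  P3 <- array(0, dim = c(K, K, K))
  for (k1 in seq_len(K)) for (k2 in seq_len(K)) for (k3 in seq_len(K)) {
    P3[k1, k2, k3] <- sum(V[k1, ] * V[k2, ] * V[k3, ])
  }
  U3 <- sum(P3^2) / nt
  i1 <- domain$bin1 + 1L
  i2 <- domain$bin2 + 1L
  i3 <- domain$bin1 + domain$bin2 + 1L
  acc <- complex(length.out = nrow(domain))
  for (e in seq_len(seg$n_segments)) {
    for (k1 in seq_len(K)) for (k2 in seq_len(K)) for (k3 in seq_len(K)) {
      acc <- acc + P3[k1, k2, k3] *
        X[i1, k1, e] * X[i2, k2, e] * Conj(X[i3, k3, e])
    }
  }
  value <- acc / (U3 * seg$n_segments)
  out <- tibble(bin1 = domain$bin1, bin2 = domain$bin2,
                f1 = domain$f1, f2 = domain$f2, value = value)
  structure(out,
            class = c("bisca_bispectrum", class(out)),
            U3 = U3, bienergies = P3, K = K, n_segments = seg$n_segments,
            fs = seg$fs, df = df, window_samples = nt,
            f_sum_max = attr(domain, "f_sum_max"))
}

#' Bicoherence
#'
#' Normalizes the bispectrum by the square-rooted triple product of spectra,
#' `b(f1, f2) = B(f1, f2) / sqrt(S(f1) S(f2) S(f1 + f2))`. The result is
#' invariant under amplitude rescaling of the input signal. Pairs where any
#' spectral term falls below `eps_rel * max(S)` are flagged invalid and
#' excluded from the pair count used by the tests.
#'
#' @param spectrum A [multitaper_spectrum()] result covering every frequency
#'   in the bispectrum's domain, including all sums `f1 + f2`.
#' @param bispectrum A [multitaper_bispectrum()] result.
#' @param eps_rel Relative spectral floor (default `1e-12`).
#'
#' @return A tibble of class `bisca_bicoherence` with columns `bin1`, `bin2`,
#'   `f1`, `f2`, `value` (complex), `magnitude`, `valid`, and attributes
#'   `n_valid`, `n_segments`, `window_samples`, `df`, `fs`.
#' @export
bicoherence <- function(spectrum, bispectrum, eps_rel = 1e-12) {
  stopifnot(inherits(spectrum, "bisca_spectrum"),
            inherits(bispectrum, "bisca_bispectrum"))
  s <- numeric(max(spectrum$bin))
  s[spectrum$bin] <- spectrum$power
  need <- max(bispectrum$bin1 + bispectrum$bin2)
  if (need > length(s)) {
    abort("spectrum does not cover all sum frequencies of the domain.")
  }
  s1 <- s[bispectrum$bin1]
  s2 <- s[bispectrum$bin2]
  s3 <- s[bispectrum$bin1 + bispectrum$bin2]
  floor_val <- eps_rel * max(s)
  valid <- s1 > floor_val & s2 > floor_val & s3 > floor_val
  denom <- sqrt(pmax(s1, floor_val) * pmax(s2, floor_val) *
                  pmax(s3, floor_val))
  value <- bispectrum$value / denom
  value[!valid] <- NA_complex_
  out <- tibble(bin1 = bispectrum$bin1, bin2 = bispectrum$bin2,
                f1 = bispectrum$f1, f2 = bispectrum$f2,
                value = value, magnitude = Mod(value), valid = valid)
  structure(out,
            class = c("bisca_bicoherence", class(out)),
            n_valid = sum(valid),
            n_segments = attr(bispectrum, "n_segments"),
            window_samples = attr(bispectrum, "window_samples"),
            df = attr(bispectrum, "df"), fs = attr(bispectrum, "fs"),
            K = attr(bispectrum, "K"))
}

#' Spectral and diagonal-bicoherence peak frequencies
#'
#' `f_smax` is the frequency of the spectrum maximum within the analysis
#' band; `f_bmax` is the frequency `f` maximizing the main-diagonal
#' bicoherence magnitude `|b(f, f)|`. Ties are broken toward the lower
#' frequency.
#'
#' @param spectrum A [multitaper_spectrum()] result.
#' @param bico A [bicoherence()] result with diagonal pairs present.
#'
#' @return A tibble with one row: columns `f_smax`, `f_bmax` (Hz).
#' @export
peak_frequencies <- function(spectrum, bico) {
  band <- attr(spectrum, "band")
  sel <- spectrum$f >= band["f_min"] - 1e-9 & spectrum$f <= band["f_max"] + 1e-9
  sub <- spectrum[sel, ]
  f_smax <- sub$f[which.max(sub$power)] # which.max takes the first maximum
  diag <- bico[bico$bin1 == bico$bin2 & bico$valid, ]
  if (nrow(diag) == 0) abort("no valid diagonal pairs in the domain.")
  diag <- diag[order(diag$f1), ]
  f_bmax <- diag$f1[which.max(diag$magnitude)]
  tibble(f_smax = f_smax, f_bmax = f_bmax)
}

#' One-stop higher-order spectral estimation
#'
#' Segments a signal and computes the multitaper spectrum, bispectrum and
#' bicoherence with shared settings. This is the estimation unit reused by
#' the tests, the surrogate calibration and the pipeline.
#'
#' @inheritParams segment_signal
#' @param nw Time-bandwidth product (default 1.5, i.e. two sine tapers).
#' @param f_sum_max Bifrequency closure cap in Hz (default 50).
#' @param eps_rel Spectral floor passed to [bicoherence()].
#'
#' @return A list of class `bisca_hos` with elements `segments`, `spectrum`,
#'   `bispectrum`, `bicoherence`, `domain`.
#' @export
#' @examples
#' hos <- estimate_hos(rnorm(3000), fs = 200)
#' head(hos$bicoherence)
estimate_hos <- function(x, fs, window_samples = 300, overlap_fraction = 0.75,
                         nw = 1.5, f_sum_max = 50, channel_id = "x",
                         eps_rel = 1e-12) {
  seg <- segment_signal(x, fs, window_samples, overlap_fraction, channel_id)
  tapers <- sine_tapers(window_samples, tapers_for_nw(nw))
  domain <- build_bifrequency_domain(fs / window_samples,
                                     min(f_sum_max, fs / 2), fs = fs)
  spec <- multitaper_spectrum(seg, tapers)
  bisp <- multitaper_bispectrum(seg, tapers, domain)
  structure(list(segments = seg, spectrum = spec, bispectrum = bisp,
                 bicoherence = bicoherence(spec, bisp, eps_rel = eps_rel),
                 domain = domain),
            class = "bisca_hos")
}

#' Bias-corrected innovation asymmetry
#'
#' For a linear process driven by i.i.d. innovations the bicoherence
#' magnitude is flat at the cumulant ratio `|gamma_3| / gamma_2^(3/2)` of the
#' innovations. At realistic averaging depths the raw surface additionally
#' carries a stochastic floor of `1 / n_eff`, so the ratio is estimated as
#' `sqrt(N_t * max(mean(|b|^2) - 1 / n_eff, 0))`; the window-length factor
#' restores the deterministic level from the variance-standardized estimator
#' scale used throughout the package.
#'
#' @param bico A [bicoherence()] result.
#' @param n_eff Effective number of segments (scalar or
#'   [effective_segments()] result).
#'
#' @return The estimated cumulant ratio (non-negative scalar).
#' @export
innovation_asymmetry <- function(bico, n_eff) {
  n_eff <- effective_n(n_eff)
  nt <- attr(bico, "window_samples")
  m <- mean(bico$magnitude[bico$valid]^2)
  sqrt(max(nt * (m - 1 / n_eff), 0))
}
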