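# Parametric Xi + Rho model of the spectrum and bispectrum.
#
# The aperiodic background (Xi) and each oscillatory peak (Rho) contribute a
# squared kernel to the spectrum and a triple-kernel term to the bispectrum;
# both orders are additive across components because the processes are
# modeled as statistically independent.

NU_FLOOR <- 0.1
D_FLOOR <- 2

#' Generalized peak kernel
#'
#' `t(f; mu, sigma, nu, d) = (1 + |(f - mu) / sigma|^d)^(-nu)`: a flat-top,
#' adjustable-tail profile. `d = 2` gives the Student-t-type profile and
#' `nu = 1, d = 2` the Lorentzian; larger `d` flattens the top (matching the
#' smoothing of multitaper estimates), `nu` controls the tail weight.
#'
#' @param f Frequencies in Hz (vectorized).
#' @param mu Center in Hz.
#' @param sigma Width in Hz (> 0).
#' @param nu Tail exponent (> 0).
#' @param d Flatness exponent (>= 2 in fitted models).
#' @return Kernel values in `(0, 1]`, equal to 1 at `f = mu`.
#' @export
#' @examples
#' kernel_t(10, mu = 10, sigma = 2, nu = 1, d = 2) # 1 at the center
#' kernel_t(12, mu = 10, sigma = 2, nu = 1, d = 2) # Lorentzian half-power
kernel_t <- function(f, mu, sigma, nu, d) {
  (1 + abs((f - mu) / sigma)^d)^(-nu)
}

#' Bifrequency kernel
#'
#' Product of three peak kernels tied by the closure rule:
#' `t2(f1, f2) = t(f1; mu1) t(f2; mu2) t(f1 + f2; mu1 + mu2)` with shared
#' shape parameters. Equals 1 at `(mu1, mu2)`.
#'
#' @param f1,f2 Bifrequencies in Hz (vectorized).
#' @param mu1,mu2 Component centers in Hz.
#' @inheritParams kernel_t
#' @export
kernel_t2 <- function(f1, f2, mu1, mu2, sigma, nu, d) {
  kernel_t(f1, mu1, sigma, nu, d) * kernel_t(f2, mu2, sigma, nu, d) *
    kernel_t(f1 + f2, mu1 + mu2, sigma, nu, d)
}

# Ladder of harmonic-grid center ratios: fundamental and low harmonics enter
# first, then subharmonics, up to 11 candidate peaks.
harmonic_ratios <- function(k) {
  ladder <- c(1, 2, 3, 1 / 2, 4, 5, 1 / 3, 6, 7, 8, 9)
  if (k > length(ladder)) abort("at most 11 harmonic-grid peaks supported.")
  sort(ladder[seq_len(k)])
}

# Index table for the upper-triangular Rho bispectral amplitudes (m >= n).
rho_pair_index <- function(k) {
  if (k == 0) return(tibble(m = integer(0), n = integer(0)))
  dplyr::bind_rows(lapply(seq_len(k), function(m) tibble(m = m, n = seq_len(m))))
}

#' Construct a full Xi + Rho parameter set
#'
#' @param xi List with `h` (spectral amplitude, >= 0), `sigma`, `nu`, `d`.
#'   The Xi spectral center is fixed at 0 Hz.
#' @param rho List with vectors `h` and `mu` (one per peak, `mu` strictly
#'   increasing) and shared `sigma`, `nu`, `d`.
#' @param h_b_xi Complex bispectral amplitude of the Xi process.
#' @param h_b_rho Complex vector of Rho bispectral amplitudes, one per pair
#'   `(m, n)` with `1 <= n <= m <= K` in the order of `rho_pair_index(K)`.
#'   Recycled from 0 if omitted.
#' @param mu_xi_bisp Center of the Xi bifrequency kernel (default 0 Hz).
#' @param mode `"free"` (peak centers fitted freely) or `"harmonic"`
#'   (centers constrained to ratio multiples of a fundamental `mu_alpha`).
#' @param mu_alpha Fundamental center frequency (harmonic mode).
#'
#' @return A list of class `bisca_params`.
#' @export
bisca_params <- function(xi, rho, h_b_xi = 0 + 0i, h_b_rho = NULL,
                         mu_xi_bisp = 0, mode = c("free", "harmonic"),
                         mu_alpha = NULL) {
  mode <- match.arg(mode)
  k <- length(rho$h)
  if (length(rho$mu) != k) abort("`rho$h` and `rho$mu` lengths differ.")
  if (k > 1 && any(diff(rho$mu) <= 0)) {
    abort("peak centers must be strictly increasing.")
  }
  n_pairs <- k * (k + 1) / 2
  h_b_rho <- h_b_rho %||% complex(length.out = n_pairs)
  if (length(h_b_rho) != n_pairs) {
    abort(sprintf("`h_b_rho` must have %d entries (K (K + 1) / 2).", n_pairs))
  }
  structure(list(xi = xi, rho = rho,
                 bisp = list(h_xi = as.complex(h_b_xi),
                             h_rho = as.complex(h_b_rho),
                             mu_xi = mu_xi_bisp),
                 mode = mode, mu_alpha = mu_alpha, k_peaks = k),
            class = "bisca_params")
}

#' Model power spectrum
#'
#' `S(f) = h_xi t(f; 0, ...)^2 + sum_k h_rho_k t(f; mu_k, ...)^2`, with the
#' Xi and Rho parts returned separately; components sum to the total at
#' every bin.
#'
#' @param params A [bisca_params()] object.
#' @param f Frequencies in Hz (vector), or a `bisca_spectrum` whose grid is
#'   reused.
#' @return A tibble with columns `f`, `power`, `xi`, `rho`.
#' @export
model_spectrum <- function(params, f) {
  if (inherits(f, "bisca_spectrum")) f <- f$f
  xi <- spec_xi_vec(params, f)
  rho <- spec_rho_vec(params, f)
  tibble(f = f, power = xi + rho, xi = xi, rho = rho)
}

# tibble-free evaluators for the optimizer's inner loop
spec_xi_vec <- function(params, f) {
  params$xi$h * kernel_t(f, 0, params$xi$sigma, params$xi$nu, params$xi$d)^2
}

spec_rho_vec <- function(params, f) {
  rho <- numeric(length(f))
  for (k in seq_len(params$k_peaks)) {
    rho <- rho + params$rho$h[k] *
      kernel_t(f, params$rho$mu[k], params$rho$sigma, params$rho$nu,
               params$rho$d)^2
  }
  rho
}

spec_total_vec <- function(params, f) {
  spec_xi_vec(params, f) + spec_rho_vec(params, f)
}

#' Model bispectrum
#'
#' Real and imaginary parts are assembled independently: a Xi term with
#' centers `(mu_xi, mu_xi)` and Xi shape, plus a double sum over peak pairs
#' `1 <= n <= m <= K` of complex amplitudes times the shared-shape
#' bifrequency kernel.
#'
#' @param params A [bisca_params()] object.
#' @param domain A [build_bifrequency_domain()] result (or any data frame
#'   with `f1`, `f2` columns).
#' @return A tibble with columns `f1`, `f2`, `value`, `xi`, `rho` (complex).
#' @export
model_bispectrum <- function(params, domain) {
  f1 <- domain$f1
  f2 <- domain$f2
  xi <- bisp_xi_vec(params, f1, f2)
  rho <- bisp_rho_vec(params, f1, f2)
  tibble(f1 = f1, f2 = f2, value = xi + rho, xi = xi, rho = rho)
}

bisp_xi_vec <- function(params, f1, f2) {
  params$bisp$h_xi *
    kernel_t2(f1, f2, params$bisp$mu_xi, params$bisp$mu_xi,
              params$xi$sigma, params$xi$nu, params$xi$d)
}

bisp_rho_vec <- function(params, f1, f2) {
  rho <- complex(length.out = length(f1))
  i <- 0L
  for (m in seq_len(params$k_peaks)) {
    for (n in seq_len(m)) {
      i <- i + 1L
      rho <- rho + params$bisp$h_rho[i] *
        kernel_t2(f1, f2, params$rho$mu[m], params$rho$mu[n],
                  params$rho$sigma, params$rho$nu, params$rho$d)
    }
  }
  rho
}

bisp_total_vec <- function(params, f1, f2) {
  bisp_xi_vec(params, f1, f2) + bisp_rho_vec(params, f1, f2)
}

#' Log-spectrum sampling variance
#'
#' Asymptotic variance of the log multitaper spectrum, `trigamma(m)` with
#' `m = K * n_eff` equivalent averaged eigenspectra; constant across bins.
#'
#' @param K Taper count.
#' @param n_eff Effective number of segments.
#' @export
var_log_spectrum <- function(K, n_eff) {
  trigamma(K * effective_n(n_eff))
}

#' Joint log-likelihood of the Xi + Rho model
#'
#' `L = -(1/N_S) sum_f ((log S_hat - log S_model) / var_logs)^2`
#' `- (1/N_B) sum_pairs |B_hat - B_model|^2 / (S_model(f1) S_model(f2) S_model(f1+f2))`.
#' Higher is better; a perfect fit attains 0. The bispectral residuals are
#' weighted by the modeled spectral triple product, the sampling variance of
#' the bispectrum estimator.
#'
#' @param params A [bisca_params()] object.
#' @param spectrum Estimated spectrum (`bisca_spectrum` or tibble with `f`,
#'   `power`).
#' @param bispectrum Estimated bispectrum (tibble with `f1`, `f2`, `value`).
#' @param var_logs Per-bin variance of the log spectrum (scalar).
#' @return Scalar log-likelihood (<= 0).
#' @export
joint_loglik <- function(params, spectrum, bispectrum, var_logs) {
  sm <- model_spectrum(params, spectrum$f)$power
  if (any(sm <= 0)) return(-Inf)
  r_s <- (log(spectrum$power) - log(sm)) / var_logs
  s_at <- function(f) model_spectrum(params, f)$power
  denom <- s_at(bispectrum$f1) * s_at(bispectrum$f2) *
    s_at(bispectrum$f1 + bispectrum$f2)
  bm <- model_bispectrum(params, bispectrum)$value
  r_b <- Mod(bispectrum$value - bm)^2 / denom
  -(sum(r_s^2) / length(r_s)) - (sum(r_b) / length(r_b))
}
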