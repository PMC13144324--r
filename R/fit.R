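# Levenberg-Marquardt fitting of the Xi + Rho model.
#
# Positive parameters are optimized on the log scale; the flatness exponent
# is parameterized as d = 2 + exp(.) and the tail exponent as
# nu = 0.1 + exp(.). The spectral parameters are fitted first (warm start),
# then shared with the joint spectrum + bispectrum objective. The complex
# bispectral amplitudes enter linearly and are fitted as (Re, Im) pairs.

pack_theta2 <- function(params) {
  p <- params
  stopifnot(p$xi$d >= 2, p$rho$d >= 2 || p$k_peaks == 0)
  base <- c(log(p$xi$h), log(p$xi$sigma), log(pmax(p$xi$nu - NU_FLOOR, 1e-6)),
            log(pmax(p$xi$d - D_FLOOR, 1e-4)))
  centers <- if (p$mode == "harmonic") log(p$mu_alpha) else p$rho$mu
  c(base, log(pmax(p$rho$h, 1e-12)), centers,
    log(p$rho$sigma), log(pmax(p$rho$nu - NU_FLOOR, 1e-6)),
    log(pmax(p$rho$d - D_FLOOR, 1e-4)))
}

unpack_theta2 <- function(theta, k, mode) {
  xi <- list(h = exp(theta[1]), sigma = exp(theta[2]),
             nu = NU_FLOOR + exp(theta[3]), d = D_FLOOR + exp(theta[4]))
  h_rho <- exp(theta[4 + seq_len(k)])
  if (mode == "harmonic") {
    mu_alpha <- exp(theta[4 + k + 1])
    mu <- harmonic_ratios(k) * mu_alpha
    rest <- theta[(4 + k + 1 + 1):length(theta)]
  } else {
    mu_alpha <- NULL
    mu <- theta[4 + k + seq_len(k)]
    rest <- theta[(4 + 2 * k + 1):length(theta)]
  }
  ord <- order(mu)
  rho <- list(h = h_rho[ord], mu = mu[ord], sigma = exp(rest[1]),
              nu = NU_FLOOR + exp(rest[2]), d = D_FLOOR + exp(rest[3]))
  bisca_params(xi, rho, mode = mode, mu_alpha = mu_alpha)
}

n_theta2 <- function(k, mode) {
  4 + k + (if (mode == "harmonic") 1 else k) + 3
}

pack_theta3 <- function(params) {
  c(Re(params$bisp$h_xi), Im(params$bisp$h_xi),
    Re(params$bisp$h_rho), Im(params$bisp$h_rho))
}

apply_theta3 <- function(params, theta) {
  n_pairs <- params$k_peaks * (params$k_peaks + 1) / 2
  params$bisp$h_xi <- complex(real = theta[1], imaginary = theta[2])
  params$bisp$h_rho <- complex(real = theta[2 + seq_len(n_pairs)],
                               imaginary = theta[2 + n_pairs + seq_len(n_pairs)])
  params
}

# Lower-envelope trend of the log spectrum (running median), used by the
# optional Xi adherence penalty.
log_trend_envelope <- function(log_power) {
  k <- min(length(log_power) - (1 - length(log_power) %% 2),
           2 * floor(length(log_power) / 8) + 1)
  k <- max(k, 1)
  stats::runmed(log_power, k)
}

# Heuristic initialization: Xi from the low-frequency envelope, peaks from
# the largest local maxima of the detrended log spectrum.
init_spectrum_params <- function(spectrum, k_peaks, mode) {
  f <- spectrum$f
  pw <- pmax(spectrum$power, .Machine$double.xmin)
  lp <- log(pw)
  trend <- log_trend_envelope(lp)
  resid <- lp - trend
  n <- length(f)
  is_max <- c(FALSE, resid[2:(n - 1)] > resid[1:(n - 2)] &
                resid[2:(n - 1)] >= resid[3:n], FALSE)
  cand <- which(is_max)
  cand <- cand[order(resid[cand], decreasing = TRUE)]
  picks <- integer(0)
  min_sep <- max(1, floor(n / 25)) # keep picked peaks apart
  for (i in cand) {
    if (all(abs(i - picks) > min_sep)) picks <- c(picks, i)
    if (length(picks) == k_peaks) break
  }
  if (length(picks) < k_peaks) { # fall back to spread-out positions
    extra <- round(seq(2, n - 1, length.out = k_peaks - length(picks) + 2))
    extra <- setdiff(extra[-c(1, length(extra))], picks)
    picks <- c(picks, extra)[seq_len(k_peaks)]
  }
  picks <- sort(picks)
  mu <- f[picks]
  mu <- mu + seq_along(mu) * 1e-6 # enforce strict ordering
  h_rho <- pmax(pw[picks] - exp(trend[picks]), 0.05 * pw[picks])
  xi <- list(h = max(pw[seq_len(min(3, n))]), sigma = max(diff(range(f)) / 8,
                                                          2 * (f[2] - f[1])),
             nu = 1, d = 2.5)
  rho <- list(h = h_rho, mu = mu, sigma = max(1, 2 * (f[2] - f[1])),
              nu = 1, d = 2.5)
  mu_alpha <- if (mode == "harmonic") {
    ratios <- harmonic_ratios(k_peaks)
    mu[which.max(h_rho)] / ratios[which.max(h_rho)]
  } else NULL
  bisca_params(xi, rho, mode = mode, mu_alpha = mu_alpha)
}

spectrum_meta <- function(spectrum, n_eff, var_logs) {
  K <- attr(spectrum, "K") %||% 2
  n_eff <- effective_n(n_eff %||% attr(spectrum, "n_segments") %||% 157)
  list(K = K, n_eff = n_eff,
       var_logs = var_logs %||% var_log_spectrum(K, n_eff))
}

restrict_f <- function(df_tbl, f_max, col = "f") {
  if (is.null(f_max)) return(df_tbl)
  if (col == "f") df_tbl[df_tbl$f <= f_max + 1e-9, ]
  else df_tbl[df_tbl$f1 + df_tbl$f2 <= f_max + 1e-9, ]
}

#' Fit the spectral parameters (warm start)
#'
#' Levenberg-Marquardt minimization of the spectral part of the joint
#' objective only, from a smoothed-spectrum peak-picking initialization. A
#' small quadratic penalty (weight `trend_weight`) ties the Xi component to
#' the running-median lower envelope of the log spectrum so the aperiodic
#' part captures the broadband trend rather than a peak.
#'
#' @param spectrum A `bisca_spectrum` (or tibble with `f`, `power`).
#' @param k_peaks Number of oscillatory peaks.
#' @param mode `"free"` peak centers (default) or `"harmonic"` (centers
#'   constrained to the ratio ladder times a fitted fundamental).
#' @param n_eff Effective segments (for the log-spectrum variance); defaults
#'   to the spectrum's segment count.
#' @param var_logs Override for the log-spectrum variance.
#' @param trend_weight Weight of the Xi trend-adherence penalty
#'   (default 0.1).
#' @param f_max Restrict the fit to `f <= f_max` (Hz).
#' @param init Optional [bisca_params()] starting point.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#'
#' @return A list of class `bisca_spec_fit`: `params`, `loglik` (spectral
#'   term), `converged`, `n_iter`, `var_logs`.
#' @export
fit_spectrum <- function(spectrum, k_peaks, mode = c("free", "harmonic"),
                         n_eff = NULL, var_logs = NULL, trend_weight = 0.1,
                         f_max = NULL, init = NULL, control = list()) {
  mode <- match.arg(mode)
  if (k_peaks < 1) abort("`k_peaks` must be at least 1.")
  spectrum <- restrict_f(spectrum, f_max)
  meta <- spectrum_meta(spectrum, n_eff, var_logs)
  init <- init %||% init_spectrum_params(spectrum, k_peaks, mode)
  lp <- log(pmax(spectrum$power, .Machine$double.xmin))
  env <- log_trend_envelope(lp)
  n_s <- length(lp)
  resid_fn <- function(theta) {
    p <- unpack_theta2(theta, k_peaks, mode)
    s <- spec_total_vec(p, spectrum$f)
    r <- (lp - log(pmax(s, 1e-300))) / (meta$var_logs * sqrt(n_s))
    if (trend_weight > 0) {
      r <- c(r, sqrt(trend_weight / n_s) *
               (log(pmax(spec_xi_vec(p, spectrum$f), 1e-300)) - env))
    }
    r
  }
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 400, ftol = 1e-10,
                                         ptol = 1e-10), control))
  fit <- minpack.lm::nls.lm(pack_theta2(init), fn = resid_fn, control = ctrl)
  params <- unpack_theta2(fit$par, k_peaks, mode)
  ms <- model_spectrum(params, spectrum$f)
  ll <- -sum(((lp - log(ms$power)) / meta$var_logs)^2) / n_s
  structure(list(params = params, loglik = ll,
                 converged = fit$info %in% 1:4, n_iter = fit$niter,
                 var_logs = meta$var_logs, info = fit$info),
            class = "bisca_spec_fit")
}

#' Joint spectrum + bispectrum fit
#'
#' Levenberg-Marquardt over the full parameter set: the spectral shape
#' parameters are warm-started from [fit_spectrum()] and refined jointly
#' with the complex bispectral amplitudes against the objective
#' [joint_loglik()]. Accepted iterations never worsen the objective (a
#' property of the LM damping rule), and runs from the same initialization
#' are deterministic.
#'
#' @param spectrum,bispectrum Estimated surfaces (from [estimate_hos()] or
#'   [gen_from_bisca()]).
#' @param init A [bisca_params()] object or `bisca_spec_fit` warm start; if
#'   `NULL` a spectral fit with `k_peaks` is run first.
#' @param k_peaks Number of peaks (needed only when `init` is `NULL`).
#' @inheritParams fit_spectrum
#'
#' @return A list of class `bisca_fit`: `params`, `loglik` (printed joint
#'   objective, 0 is a perfect fit), `deviance` (variance-standardized, used
#'   for AIC), `aic`, `n_par`, `n_iter`, `converged`, `model_spectrum`,
#'   `model_bispectrum`, `data`, `var_logs`, `n_eff`.
#' @export
fit_joint <- function(spectrum, bispectrum, init = NULL, k_peaks = NULL,
                      mode = c("free", "harmonic"), n_eff = NULL,
                      var_logs = NULL, trend_weight = 0, f_max = NULL,
                      control = list()) {
  mode <- match.arg(mode)
  spectrum <- restrict_f(spectrum, f_max)
  bispectrum <- restrict_f(bispectrum, f_max, col = "f1")
  meta <- spectrum_meta(spectrum, n_eff, var_logs)
  if (is.null(init)) {
    if (is.null(k_peaks)) abort("give either `init` or `k_peaks`.")
    init <- fit_spectrum(spectrum, k_peaks, mode, n_eff = meta$n_eff,
                         var_logs = meta$var_logs)
  }
  if (inherits(init, "bisca_spec_fit")) init <- init$params
  k <- init$k_peaks
  mode <- init$mode
  n2 <- n_theta2(k, mode)
  lp <- log(pmax(spectrum$power, .Machine$double.xmin))
  env <- log_trend_envelope(lp)
  n_s <- length(lp)
  n_b <- nrow(bispectrum)
  f1 <- bispectrum$f1; f2 <- bispectrum$f2; f3 <- f1 + f2
  b_hat <- bispectrum$value
  # Residuals standardized by their sampling variances (Gaussian likelihood
  # of the log spectrum and natural-scale bispectrum): the total sum of
  # squares is the deviance used for AIC, so the optimum and the model
  # comparison live on the same scale. The normalized display objective
  # (joint_loglik) is evaluated at the optimum afterwards.
  n_f <- length(lp)
  f_all <- c(spectrum$f, f1, f2, f3)
  resid_fn <- function(theta) {
    p2 <- unpack_theta2(theta[seq_len(n2)], k, mode)
    p <- apply_theta3(p2, theta[(n2 + 1):length(theta)])
    s_all <- spec_total_vec(p, f_all)
    r_s <- (lp - log(pmax(s_all[seq_len(n_f)], 1e-300))) /
      sqrt(meta$var_logs)
    sss <- s_all[n_f + seq_len(n_b)] * s_all[n_f + n_b + seq_len(n_b)] *
      s_all[n_f + 2 * n_b + seq_len(n_b)]
    denom <- sqrt(pmax(sss, 1e-300) / meta$n_eff)
    bm <- bisp_total_vec(p, f1, f2)
    r <- c(r_s, Re(b_hat - bm) / denom, Im(b_hat - bm) / denom)
    if (trend_weight > 0) {
      r <- c(r, sqrt(trend_weight) *
               (log(pmax(spec_xi_vec(p, spectrum$f), 1e-300)) - env))
    }
    r
  }
  theta0 <- c(pack_theta2(init), pack_theta3(init))
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 200, ftol = 1e-6,
                                         ptol = 1e-6), control))
  fit <- minpack.lm::nls.lm(theta0, fn = resid_fn, control = ctrl)
  params <- apply_theta3(unpack_theta2(fit$par[seq_len(n2)], k, mode),
                         fit$par[(n2 + 1):length(fit$par)])
  ms <- model_spectrum(params, spectrum$f)
  mb <- model_bispectrum(params, bispectrum)
  s1 <- model_spectrum(params, f1)$power
  s2 <- model_spectrum(params, f2)$power
  s3 <- model_spectrum(params, f3)$power
  res2 <- Mod(b_hat - mb$value)^2 / (s1 * s2 * s3)
  ll <- -sum(((lp - log(ms$power)) / meta$var_logs)^2) / n_s -
    sum(res2) / n_b
  # Variance-standardized deviance: residuals scaled by their sampling
  # variances so AIC differences are on a likelihood scale.
  deviance <- sum((lp - log(ms$power))^2) / meta$var_logs +
    meta$n_eff * sum(res2)
  n_par <- length(theta0)
  structure(list(params = params, loglik = ll, deviance = deviance,
                 aic = deviance + 2 * n_par, n_par = n_par,
                 n_iter = fit$niter, converged = fit$info %in% 1:4,
                 model_spectrum = ms, model_bispectrum = mb,
                 data = list(spectrum = spectrum, bispectrum = bispectrum),
                 var_logs = meta$var_logs, n_eff = meta$n_eff,
                 info = fit$info),
            class = "bisca_fit")
}

#' @export
print.bisca_fit <- function(x, ...) {
  cat(sprintf(
    "<bisca_fit> K = %d peaks (%s centers), loglik = %.4g, AIC = %.4g, %s in %d iterations\n",
    x$params$k_peaks, x$params$mode, x$loglik, x$aic,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("  peak centers (Hz):",
      paste(sprintf("%.2f", x$params$rho$mu), collapse = ", "), "\n")
  invisible(x)
}

# Grow a fitted parameter set by one peak placed at the largest positive
# log-spectral residual; existing bispectral amplitudes are carried over to
# their re-indexed pairs, new pairs start at zero. Used for nested warm
# starts during peak-count selection.
augment_params <- function(params, spectrum) {
  ms <- model_spectrum(params, spectrum$f)
  resid <- log(pmax(spectrum$power, 1e-300)) - log(pmax(ms$power, 1e-300))
  # keep away from existing centers
  df_min <- max(diff(spectrum$f)[1] * 3, params$rho$sigma / 2)
  ok <- vapply(spectrum$f, function(f)
    all(abs(f - params$rho$mu) > df_min), logical(1))
  if (!any(ok)) ok <- rep(TRUE, length(resid))
  j <- which(ok)[which.max(resid[ok])]
  mu_new <- spectrum$f[j]
  h_new <- max(spectrum$power[j] - ms$power[j], 0.05 * spectrum$power[j])
  mu_all <- c(params$rho$mu, mu_new)
  h_all <- c(params$rho$h, h_new)
  ord <- order(mu_all)
  pos <- match(seq_along(params$rho$mu), ord) # old peak -> new index
  k_new <- length(mu_all)
  idx_old <- rho_pair_index(length(params$rho$mu))
  idx_new <- rho_pair_index(k_new)
  h_b_new <- complex(length.out = nrow(idx_new))
  for (r in seq_len(nrow(idx_old))) {
    m2 <- max(pos[idx_old$m[r]], pos[idx_old$n[r]])
    n2 <- min(pos[idx_old$m[r]], pos[idx_old$n[r]])
    h_b_new[which(idx_new$m == m2 & idx_new$n == n2)] <-
      params$bisp$h_rho[r]
  }
  bisca_params(
    xi = params$xi,
    rho = list(h = h_all[ord], mu = mu_all[ord] +
                 seq_len(k_new) * 1e-9, # keep strictly increasing
               sigma = params$rho$sigma, nu = params$rho$nu,
               d = params$rho$d),
    h_b_xi = params$bisp$h_xi, h_b_rho = h_b_new,
    mu_xi_bisp = params$bisp$mu_xi)
}

#' Select the number of peaks by AIC
#'
#' Fits every candidate peak count in `k_range` (spectral warm start, then
#' joint fit) and returns the minimum-AIC fit together with the full AIC
#' table (`aic_table` element). In free-centers mode each candidate beyond
#' the smallest is additionally warm-started from the previous candidate's
#' fit grown by one peak (nested warm start); the better of the two fits is
#' kept, which stabilizes the selection against local optima.
#'
#' @inheritParams fit_joint
#' @param k_range Candidate peak counts (default 1 to 11).
#' @return The best `bisca_fit`, with an extra element `aic_table` (tibble
#'   with columns `k`, `aic`, `loglik`, `deviance`, `converged`).
#' @export
select_peaks <- function(spectrum, bispectrum, k_range = 1:11,
                         mode = c("free", "harmonic"), n_eff = NULL,
                         var_logs = NULL, trend_weight = 0, f_max = NULL,
                         control = list()) {
  mode <- match.arg(mode)
  k_range <- sort(k_range)
  fits <- vector("list", length(k_range))
  errs <- character(length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- tryCatch({
      fit <- fit_joint(spectrum, bispectrum, k_peaks = k_range[i],
                       mode = mode, n_eff = n_eff, var_logs = var_logs,
                       trend_weight = trend_weight, f_max = f_max,
                       control = control)
      prev <- if (i > 1) fits[[i - 1]] else NULL
      # nested models can only improve the deviance; a fresh fit that fails
      # that bound sits in a local optimum, so retry from the previous fit
      # grown by one peak
      if (mode == "free" && !is.null(prev) &&
          k_range[i] == prev$params$k_peaks + 1 &&
          fit$deviance > prev$deviance - 1) {
        nested <- tryCatch(
          fit_joint(spectrum, bispectrum,
                    init = augment_params(prev$params,
                                          prev$data$spectrum),
                    n_eff = n_eff, var_logs = var_logs,
                    trend_weight = trend_weight, f_max = f_max,
                    control = control),
          error = function(e) NULL)
        if (!is.null(nested) && nested$aic < fit$aic) fit <- nested
      }
      fit
    },
    error = function(e) {
      errs[i] <<- conditionMessage(e)
      NULL
    })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    abort(paste0("all candidate peak counts failed:\n",
                 paste(sprintf("  K = %d: %s", k_range, errs),
                       collapse = "\n")))
  }
  tab <- tibble(
    k = k_range[ok],
    aic = vapply(fits[ok], function(f) f$aic, numeric(1)),
    loglik = vapply(fits[ok], function(f) f$loglik, numeric(1)),
    deviance = vapply(fits[ok], function(f) f$deviance, numeric(1)),
    converged = vapply(fits[ok], function(f) f$converged, logical(1)))
  best <- fits[ok][[which.min(tab$aic)]]
  best$aic_table <- tab
  best
}
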