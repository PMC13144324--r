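# Gaussianity and linearity tests on the bicoherence surface.
#
# Under the Gaussian-linear null, 2 * n_eff * |b(f1,f2)|^2 is chi-squared
# with 2 degrees of freedom at each bifrequency pair. The Gaussianity test
# uses the median over pairs (asymptotically normal around 2*log(2)); the
# linearity test uses the maximum, calibrated with a Gumbel approximation to
# the extreme of P noncentral chi-squared variables, with the noncentrality
# absorbed from any flat (input-non-Gaussianity) background.
#
# The asymptotic nulls assume independent bifrequency pairs. Taper averaging
# and segment overlap correlate neighboring pairs, which inflates the
# spread of the median and deflates the effective extent of the maximum, so
# both nulls also come in a surrogate-calibrated form: the AR surrogates
# already generated for n_eff yield the dependence-adjusted effective pair
# counts (see effective_pairs_* below), and these replace P in the same
# parametric nulls. The surrogate form is used automatically whenever the
# surrogate statistics are available.

effective_n <- function(n_eff) {
  if (inherits(n_eff, "bisca_effective_segments")) n_eff$n_eff else
    as.numeric(n_eff)
}

has_surrogate_stats <- function(n_eff) {
  inherits(n_eff, "bisca_effective_segments") &&
    !is.null(n_eff$surrogate_medians) &&
    all(is.finite(n_eff$surrogate_medians)) &&
    length(n_eff$surrogate_medians) >= 10
}

# Dependence-adjusted pair count for the median test: the scaled median is
# asymptotically N(2 log 2, sqrt(4 / P_eff)); match P_eff to the surrogate
# spread.
effective_pairs_median <- function(n_eff) {
  4 / stats::var(n_eff$surrogate_medians)
}

# Gumbel location/scale of the null maximum fitted by moments to the
# surrogate maxima (central, lambda0 = 0, case). Dependence and the
# estimated spectral denominators make the surrogate extremes both heavier
# and wider than the independent chi-squared(2) prediction; the moment fit
# absorbs both.
gumbel_from_surrogates <- function(n_eff) {
  mx <- n_eff$surrogate_maxima
  a_P <- stats::sd(mx) * sqrt(6) / pi
  b_P <- mean(mx) - 0.5772156649 * a_P
  list(b_P = b_P, a_P = a_P)
}

resolve_null <- function(null, n_eff) {
  null <- match.arg(null, c("auto", "asymptotic", "surrogate"))
  if (null == "auto") {
    if (has_surrogate_stats(n_eff)) "surrogate" else "asymptotic"
  } else {
    if (null == "surrogate" && !has_surrogate_stats(n_eff)) {
      abort("surrogate null requested but `n_eff` carries no surrogate statistics.")
    }
    null
  }
}

valid_magnitudes <- function(bico) {
  if (inherits(bico, "bisca_bicoherence")) {
    bico$magnitude[bico$valid]
  } else {
    m <- as.numeric(bico)
    m[is.finite(m)]
  }
}

#' Median-based Gaussianity test
#'
#' Effect size `b_g = sqrt(median |b|^2)` and statistic
#' `t_g = 2 * n_eff * b_g^2`, tested one-sided against the asymptotic null
#' `t_g ~ N(2 log 2, sqrt(4 / P))`. Large values indicate a diffuse,
#' widespread elevation of bicoherence, the signature of non-Gaussian input.
#'
#' @param bico A [bicoherence()] result (or a numeric vector of bicoherence
#'   magnitudes).
#' @param n_eff Effective number of segments ([effective_segments()] result
#'   or scalar).
#' @param alpha Significance level (default 0.05).
#' @param null `"asymptotic"` uses the independent-pair null with the
#'   nominal pair count `P`; `"surrogate"` replaces `P` by the
#'   dependence-adjusted effective pair count calibrated from the AR
#'   surrogates carried by `n_eff`; `"auto"` (default) picks `"surrogate"`
#'   whenever those statistics are available.
#' @param p_floor Minimum pair count for the normal approximation; fewer
#'   pairs triggers a warning but the test is still computed.
#'
#' @return A list of class `bisca_gauss_test`: `b_g`, `t_g`, `c_g`, `p_g`,
#'   `reject`, `P`, `p_eff`, `null`, `n_eff`, `alpha`.
#' @export
gaussianity_test <- function(bico, n_eff, alpha = 0.05, null = "auto",
                             p_floor = 10) {
  null <- resolve_null(null, n_eff)
  mags <- valid_magnitudes(bico)
  P <- length(mags)
  if (P < p_floor) {
    warn(sprintf(
      "only %d bifrequency pairs; the normal approximation of the median test is unreliable.",
      P))
  }
  if (null == "surrogate") {
    p_eff <- effective_pairs_median(n_eff)
    null_mean <- mean(n_eff$surrogate_medians)
  } else {
    p_eff <- P
    null_mean <- 2 * log(2)
  }
  n_eff <- effective_n(n_eff)
  b_g <- sqrt(median(mags^2))
  t_g <- 2 * n_eff * b_g^2
  null_sd <- sqrt(4 / p_eff)
  c_g <- null_mean + qnorm(1 - alpha) * null_sd
  p_g <- pnorm(t_g, mean = null_mean, sd = null_sd, lower.tail = FALSE)
  structure(list(b_g = b_g, t_g = t_g, c_g = c_g, p_g = p_g,
                 reject = t_g > c_g, P = P, p_eff = p_eff, null = null,
                 n_eff = n_eff, alpha = alpha),
            class = "bisca_gauss_test")
}

# Gumbel constants for the maximum of P chi^2(2, lambda0) variables.
gumbel_constants <- function(P, lambda0) {
  b_P <- qchisq(1 - 1 / P, df = 2, ncp = lambda0)
  a_P <- 1 / (P * dchisq(b_P, df = 2, ncp = lambda0))
  list(b_P = b_P, a_P = a_P)
}

#' Maximum-based linearity test
#'
#' Statistic `t_l = 2 * n_eff * max |b|^2`, compared with the Gumbel
#' approximation for the maximum of `P` independent noncentral
#' `chi^2(2, lambda0)` variables. The noncentrality
#' `lambda0 = max(median(2 n_eff |b|^2) - 2 log 2, 0)` absorbs a flat
#' non-Gaussian background so the test targets localized quadratic phase
#' coupling only.
#'
#' @inheritParams gaussianity_test
#'
#' @return A list of class `bisca_lin_test`: `b_l`, `t_l`, `lambda0`, `b_P`,
#'   `a_P`, `c_l`, `p_l`, `reject`, `P`, `null`, `n_eff`, `alpha`.
#' @export
linearity_test <- function(bico, n_eff, alpha = 0.05, null = "auto",
                           p_floor = 10) {
  null <- resolve_null(null, n_eff)
  mags <- valid_magnitudes(bico)
  P <- length(mags)
  if (P < p_floor) {
    warn(sprintf(
      "only %d bifrequency pairs; the Gumbel approximation of the max test is unreliable.",
      P))
  }
  n_eff_obj <- n_eff
  n_eff <- effective_n(n_eff)
  b_l <- max(mags)
  t_l <- 2 * n_eff * b_l^2
  lambda0 <- max(median(2 * n_eff * mags^2) - 2 * log(2), 0)
  if (null == "surrogate") {
    # Monte-Carlo rank calibration against the surrogate maxima, shifted by
    # the estimated noncentrality (the chi-squared(2, lambda0) upper tail
    # sits lambda0 above the central one, the same approximation the
    # lambda0 estimator uses for the median). The rank p-value has exact
    # size under the matched-AR Gaussian null; the Gumbel moments are kept
    # as a descriptive summary of the surrogate extreme distribution.
    mx <- n_eff_obj$surrogate_maxima + lambda0
    m_surr <- length(mx)
    p_l <- (1 + sum(mx >= t_l)) / (m_surr + 1)
    c_l <- as.numeric(stats::quantile(mx, 1 - alpha, type = 8))
    gc <- gumbel_from_surrogates(n_eff_obj)
    gc$b_P <- gc$b_P + lambda0
  } else {
    gc <- gumbel_constants(P, lambda0)
    c_l <- gc$b_P - gc$a_P * log(-log(1 - alpha))
    p_l <- 1 - exp(-exp(-(t_l - gc$b_P) / gc$a_P))
  }
  reject <- if (null == "surrogate") p_l <= alpha else t_l > c_l
  structure(list(b_l = b_l, t_l = t_l, lambda0 = lambda0,
                 b_P = gc$b_P, a_P = gc$a_P, c_l = c_l, p_l = p_l,
                 reject = reject, P = P, null = null,
                 n_eff = n_eff, alpha = alpha),
            class = "bisca_lin_test")
}

#' Four-way class label from test decisions
#'
#' Maps the two decisions (reject Gaussianity, reject linearity) to one of
#' `GL`, `NGL`, `GNL`, `NGNL`.
#'
#' @param t_g,t_l Test statistics.
#' @param c_g,c_l Critical values at the common level.
#' @return A single string.
#' @export
classify_recording <- function(t_g, t_l, c_g, c_l) {
  ng <- t_g >= c_g
  nl <- t_l >= c_l
  if (!ng && !nl) "GL" else if (ng && !nl) "NGL" else
    if (!ng && nl) "GNL" else "NGNL"
}

#' Combined Gaussianity/linearity report for one recording
#'
#' Runs both tests at a common level and assembles the four-way label.
#'
#' @inheritParams gaussianity_test
#' @return A list of class `bisca_gl_test` with elements `gauss`, `lin`,
#'   `label`, `n_eff`, `alpha`, `P`.
#' @export
#' @examples
#' hos <- estimate_hos(rnorm(6000), fs = 200)
#' gl_test(hos$bicoherence, n_eff = 150)
gl_test <- function(bico, n_eff, alpha = 0.05, null = "auto", p_floor = 10) {
  g <- gaussianity_test(bico, n_eff, alpha, null, p_floor)
  l <- linearity_test(bico, n_eff, alpha, null, p_floor)
  structure(list(gauss = g, lin = l,
                 label = classify_recording(g$t_g, l$t_l, g$c_g, l$c_l),
                 n_eff = effective_n(n_eff), alpha = alpha, P = g$P),
            class = "bisca_gl_test")
}

#' @export
print.bisca_gl_test <- function(x, ...) {
  cat(sprintf("<bisca_gl_test> label: %s (alpha = %g, P = %d, n_eff = %.1f)\n",
              x$label, x$alpha, x$P, x$n_eff))
  cat(sprintf("  Gaussianity: t_g = %.3f vs c_g = %.3f (p = %.3g)\n",
              x$gauss$t_g, x$gauss$c_g, x$gauss$p_g))
  cat(sprintf("  Linearity:   t_l = %.3f vs c_l = %.3f (p = %.3g, lambda0 = %.3f)\n",
              x$lin$t_l, x$lin$c_l, x$lin$p_l, x$lin$lambda0))
  invisible(x)
}

#' Benjamini-Hochberg step-up rejection mask
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical vector aligned with `pvals` (empty input gives an empty
#'   mask).
#' @export
bh_fdr <- function(pvals, q) {
  if (length(pvals) == 0) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH") <= q
}

#' Per-pair classification of the bifrequency plane
#'
#' Computes per-pair p-values from the `chi^2(2)` null of
#' `2 n_eff |b|^2` (Gaussianity family) and from the noncentral
#' `chi^2(2, lambda0)` null (linearity family), applies Benjamini-Hochberg
#' FDR within each family across the plane, and emits four-way labels per
#' pair.
#'
#' @inheritParams gaussianity_test
#' @param q FDR level (analysis default 0.001).
#' @param lambda0 Optional noncentrality; estimated from the median as in
#'   [linearity_test()] when `NULL`.
#'
#' @return A tibble of class `bisca_pair_class` with columns `f1`, `f2`,
#'   `magnitude`, `p_gauss`, `p_lin`, `reject_gauss`, `reject_lin`, `label`,
#'   plus attributes `q`, `lambda0`, `n_eff`.
#' @export
pairwise_classification <- function(bico, n_eff, q = 0.001, lambda0 = NULL) {
  stopifnot(inherits(bico, "bisca_bicoherence"))
  n_eff <- effective_n(n_eff)
  sub <- bico[bico$valid, ]
  x <- 2 * n_eff * sub$magnitude^2
  lambda0 <- lambda0 %||% max(median(x) - 2 * log(2), 0)
  p_gauss <- pchisq(x, df = 2, lower.tail = FALSE)
  p_lin <- pchisq(x, df = 2, ncp = lambda0, lower.tail = FALSE)
  reject_gauss <- bh_fdr(p_gauss, q)
  reject_lin <- bh_fdr(p_lin, q)
  label <- ifelse(!reject_gauss & !reject_lin, "GL",
                  ifelse(reject_gauss & !reject_lin, "NGL",
                         ifelse(!reject_gauss & reject_lin, "GNL", "NGNL")))
  out <- tibble(f1 = sub$f1, f2 = sub$f2, magnitude = sub$magnitude,
                p_gauss = p_gauss, p_lin = p_lin,
                reject_gauss = reject_gauss, reject_lin = reject_lin,
                label = label)
  structure(out, class = c("bisca_pair_class", class(out)),
            q = q, lambda0 = lambda0, n_eff = n_eff)
}
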