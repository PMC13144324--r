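# Shared fixtures, built in code at test time.

FS <- 200

# Shorter recordings than the 60-s reference keep the suites fast; the
# statistics they feed are calibration-level and independent of record
# length.
quick_hos <- function(x, fs = FS, ...) {
  estimate_hos(x, fs = fs, ...)
}

# Effective segments for simulated classes whose second-order structure is a
# known AR model: skip the Burg refit and use the class generator directly,
# mirroring the surrogate definition (Gaussian innovations, same settings).
# Returns a full effective-segments object including the surrogate median
# and maximum statistics so the dependence-calibrated nulls are available.
neff_for_ar <- function(ar, n, m = 30, seed = 777, fs = FS, ...) {
  stats_m <- vapply(seq_len(m), function(i) {
    x <- gen_linear(n, ar = ar, innovation = "gaussian",
                    seed = seed + i)
    hos <- estimate_hos(x, fs = fs, ...)
    b2 <- hos$bicoherence$magnitude[hos$bicoherence$valid]^2
    c(mean(b2), median(b2), max(b2))
  }, numeric(3))
  n_eff <- 1 / mean(stats_m[1, ])
  structure(list(n_eff = n_eff, n_nominal = NA_integer_,
                 ar_order = length(ar), ar_coefs = ar, m = m, seed = seed,
                 mean_b2 = mean(stats_m[1, ]),
                 surrogate_medians = 2 * n_eff * stats_m[2, ],
                 surrogate_maxima = 2 * n_eff * stats_m[3, ]),
            class = "bisca_effective_segments")
}

# Reference Xi + Rho parameter set used by fitting/decomposition suites:
# an aperiodic background with three harmonically related alpha-band peaks,
# quadratic coupling carried by the Rho component.
ref_params <- function(h_b_rho = c(2 + 1i, 0.8 - 0.4i, 0.3 + 0.2i,
                                   0 + 0i, 0 + 0i, 0 + 0i),
                       h_b_xi = 0 + 0i) {
  bisca_params(
    xi = list(h = 20, sigma = 4, nu = 1.2, d = 2.5),
    rho = list(h = c(6, 2.5, 1), mu = c(10, 20, 30), sigma = 1.5, nu = 1,
               d = 2.5),
    h_b_xi = h_b_xi, h_b_rho = h_b_rho)
}
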