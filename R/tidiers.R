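# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy bisca_gl_test
#' @export
tidy.bisca_gl_test <- function(x, ...) {
  tibble(test = c("gaussianity", "linearity"),
         effect_size = c(x$gauss$b_g, x$lin$b_l),
         statistic = c(x$gauss$t_g, x$lin$t_l),
         critical = c(x$gauss$c_g, x$lin$c_l),
         p.value = c(x$gauss$p_g, x$lin$p_l),
         reject = c(x$gauss$reject, x$lin$reject))
}

#' @method glance bisca_gl_test
#' @export
glance.bisca_gl_test <- function(x, ...) {
  tibble(label = x$label, t_g = x$gauss$t_g, t_l = x$lin$t_l,
         lambda0 = x$lin$lambda0, n_eff = x$n_eff, n_pairs = x$P,
         alpha = x$alpha)
}

#' @method tidy bisca_fit
#' @export
tidy.bisca_fit <- function(x, ...) {
  p <- x$params
  idx <- rho_pair_index(p$k_peaks)
  dplyr::bind_rows(
    tibble(component = "xi", term = c("h_s", "sigma", "nu", "d"),
           estimate = c(p$xi$h, p$xi$sigma, p$xi$nu, p$xi$d)),
    tibble(component = "rho",
           term = c(paste0("h_s_", seq_len(p$k_peaks)),
                    paste0("mu_", seq_len(p$k_peaks)),
                    "sigma", "nu", "d"),
           estimate = c(p$rho$h, p$rho$mu, p$rho$sigma, p$rho$nu, p$rho$d)),
    tibble(component = "xi", term = c("h_b_re", "h_b_im"),
           estimate = c(Re(p$bisp$h_xi), Im(p$bisp$h_xi))),
    tibble(component = "rho",
           term = c(sprintf("h_b_%d_%d_re", idx$m, idx$n),
                    sprintf("h_b_%d_%d_im", idx$m, idx$n)),
           estimate = c(Re(p$bisp$h_rho), Im(p$bisp$h_rho))))
}

#' @method glance bisca_fit
#' @export
glance.bisca_fit <- function(x, ...) {
  tibble(k_peaks = x$params$k_peaks, mode = x$params$mode,
         loglik = x$loglik, deviance = x$deviance, aic = x$aic,
         n_par = x$n_par, n_iter = x$n_iter, converged = x$converged,
         n_eff = x$n_eff)
}

#' @method tidy bisca_effective_segments
#' @export
tidy.bisca_effective_segments <- function(x, ...) {
  tibble(n_eff = x$n_eff, n_nominal = x$n_nominal, ar_order = x$ar_order,
         m_surrogates = x$m, seed = x$seed, mean_b2 = x$mean_b2)
}

#' @method tidy bisca_component_tests
#' @export
tidy.bisca_component_tests <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$xi), component = "xi", .before = 1),
    dplyr::mutate(tidy(x$rho), component = "rho", .before = 1))
}
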