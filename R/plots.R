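# ggplot2 visualization methods (diagnostics, not publication graphics).

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_point
#'   scale_fill_viridis_c labs facet_wrap scale_y_log10 theme_minimal
#' @export
ggplot2::autoplot

#' @method autoplot bisca_spectrum
#' @export
autoplot.bisca_spectrum <- function(object, ...) {
  band <- attr(object, "band")
  df <- object[object$f >= band["f_min"] & object$f <= band["f_max"], ]
  ggplot(df, aes(x = .data$f, y = .data$power)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "frequency (Hz)", y = "power",
         title = "Multitaper power spectrum") +
    theme_minimal()
}

#' @method autoplot bisca_bicoherence
#' @export
autoplot.bisca_bicoherence <- function(object, ...) {
  ggplot(object[object$valid, ],
         aes(x = .data$f1, y = .data$f2, fill = .data$magnitude)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = expression(f[1] ~ "(Hz)"), y = expression(f[2] ~ "(Hz)"),
         fill = "|b|", title = "Bicoherence magnitude") +
    theme_minimal()
}

#' @method autoplot bisca_fit
#' @export
autoplot.bisca_fit <- function(object, ...) {
  dat <- object$data$spectrum
  ms <- object$model_spectrum
  df <- dplyr::bind_rows(
    tibble(f = dat$f, power = dat$power, which = "estimate"),
    tibble(f = ms$f, power = ms$power, which = "model"),
    tibble(f = ms$f, power = ms$xi, which = "xi"),
    tibble(f = ms$f, power = ms$rho, which = "rho"))
  ggplot(df[df$power > 0, ],
         aes(x = .data$f, y = .data$power, colour = .data$which)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "frequency (Hz)", y = "power", colour = NULL,
         title = "Xi + Rho spectral fit") +
    theme_minimal()
}

#' @method autoplot bisca_decomposition
#' @export
autoplot.bisca_decomposition <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("f1", "f2", "mag_hat", "mag_xi", "mag_rho")],
    cols = c("mag_hat", "mag_xi", "mag_rho"),
    names_to = "component", values_to = "magnitude")
  df$component <- factor(df$component,
                         levels = c("mag_hat", "mag_xi", "mag_rho"),
                         labels = c("total", "xi", "rho"))
  ggplot(df, aes(x = .data$f1, y = .data$f2, fill = .data$magnitude)) +
    geom_raster() +
    facet_wrap(~component) +
    scale_fill_viridis_c() +
    labs(x = expression(f[1] ~ "(Hz)"), y = expression(f[2] ~ "(Hz)"),
         fill = "|b|", title = "Component bicoherence decomposition") +
    theme_minimal()
}
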