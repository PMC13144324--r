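# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats fft median qnorm pnorm qchisq dchisq pchisq p.adjust
#'   rnorm runif rgamma rexp ar setNames
#' @keywords internal
"_PACKAGE"

# Deterministic child seed derived from a master seed. Kept below 2^31 so it
# is always a valid integer seed.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1000003 + as.numeric(index) * 7919) %%
               2147483629)
}

check_finite_numeric <- function(x, what = "signal") {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", what))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite samples.", what))
  }
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
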