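#' Split a signal into overlapping, mean-removed analysis segments
#'
#' Cuts a single-channel time series into windows of `window_samples` samples
#' advanced by `hop = round(window_samples * (1 - overlap_fraction))` samples.
#' Each segment has its own mean removed (the estimators assume a zero-mean
#' process); trailing samples that do not fill a complete window are dropped.
#'
#' With the default analysis settings (200 Hz, 300-sample windows, 75%
#' overlap) a 60-second recording yields 157 segments.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param window_samples Segment length in samples (default 300).
#' @param overlap_fraction Fraction of overlap between consecutive segments,
#'   in `[0, 1)` (default 0.75).
#' @param channel_id Optional label carried through to reports.
#'
#' @return An object of class `bisca_segments`: a list with elements
#'   `segments` (an `n_segments x window_samples` matrix), `fs`,
#'   `window_samples`, `overlap_fraction`, `hop`, `n_segments`, `channel_id`.
#' @export
#' @examples
#' seg <- segment_signal(sin(2 * pi * 10 * (0:5999) / 200), fs = 200)
#' seg$n_segments
segment_signal <- function(x, fs, window_samples = 300,
                           overlap_fraction = 0.75, channel_id = "x") {
  check_finite_numeric(x)
  if (window_samples < 2) abort("`window_samples` must be at least 2.")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must be in [0, 1).")
  }
  n <- length(x)
  if (n < window_samples) {
    abort(sprintf(
      "signal has %d samples but one window needs %d.", n, window_samples))
  }
  hop <- max(1L, as.integer(round(window_samples * (1 - overlap_fraction))))
  n_segments <- as.integer(floor((n - window_samples) / hop)) + 1L
  starts <- (seq_len(n_segments) - 1L) * hop + 1L
  segs <- matrix(0, nrow = n_segments, ncol = window_samples)
  for (e in seq_len(n_segments)) {
    s <- x[starts[e]:(starts[e] + window_samples - 1L)]
    segs[e, ] <- s - mean(s)
  }
  structure(
    list(segments = segs, fs = fs, window_samples = as.integer(window_samples),
         overlap_fraction = overlap_fraction, hop = hop,
         n_segments = n_segments, channel_id = channel_id),
    class = "bisca_segments")
}

#' @export
print.bisca_segments <- function(x, ...) {
  cat(sprintf(
    "<bisca_segments> %d segments of %d samples (fs = %g Hz, overlap %g%%), channel '%s'\n",
    x$n_segments, x$window_samples, x$fs, 100 * x$overlap_fraction,
    x$channel_id))
  invisible(x)
}

#' Orthonormal sine tapers
#'
#' Sine tapers `v_k(n) = sqrt(2 / (N + 1)) * sin(pi * k * (n + 1) / (N + 1))`
#' for `n = 0, ..., N - 1`. Each taper has unit energy and distinct tapers are
#' exactly orthogonal. They trade slightly higher sidelobes for lower
#' amplitude bias than prolate tapers, which suits smooth EEG spectra.
#'
#' @param window_samples Taper length `N`.
#' @param K Number of tapers; with time-bandwidth product `NW` the usual
#'   choice is `K = 2 * NW - 1` (the analysis default `NW = 1.5` gives
#'   `K = 2`).
#'
#' @return An object of class `bisca_tapers`: list with `tapers`
#'   (`K x window_samples` matrix), `K` and `nw = (K + 1) / 2`.
#' @export
#' @examples
#' tp <- sine_tapers(300, 2)
#' rowSums(tp$tapers^2) # unit energy
sine_tapers <- function(window_samples, K = 2) {
  if (K < 1) abort("`K` must be at least 1.")
  if (window_samples < K + 1) {
    abort("`window_samples` must exceed the number of tapers.")
  }
  n <- seq_len(window_samples) # n + 1 for n = 0..N-1
  tapers <- t(vapply(
    seq_len(K),
    function(k) sqrt(2 / (window_samples + 1)) *
      sin(pi * k * n / (window_samples + 1)),
    numeric(window_samples)))
  structure(list(tapers = tapers, K = as.integer(K), nw = (K + 1) / 2),
            class = "bisca_tapers")
}

#' Number of tapers for a time-bandwidth product
#'
#' @param nw Time-bandwidth product (default 1.5).
#' @return `max(1, round(2 * nw - 1))`.
#' @export
tapers_for_nw <- function(nw = 1.5) {
  max(1L, as.integer(round(2 * nw - 1)))
}
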