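# Recording input (EDF and delimited text) and result export.

#' Read a multichannel recording
#'
#' Supports European Data Format (`.edf`) and delimited text with one
#' channel per column (header row optional, any of comma/tab/whitespace).
#' Delimited input requires an explicit sampling rate. Units are passed
#' through untouched.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#' @param fs Sampling rate in Hz (required for delimited input).
#' @return A list of class `bisca_recording`: `signals` (named list of
#'   numeric vectors), `fs`, `labels`, `source`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited"),
                           fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  }
  if (format == "edf") {
    rec <- read_edf(path)
  } else {
    if (is.null(fs)) abort("delimited input needs an explicit `fs`.")
    tab <- utils::read.table(path, header = looks_like_header(path),
                             sep = "", check.names = FALSE)
    tab <- tab[, vapply(tab, is.numeric, logical(1)), drop = FALSE]
    if (ncol(tab) == 0) abort("no numeric channels found.")
    labels <- colnames(tab) %||% paste0("ch", seq_len(ncol(tab)))
    signals <- setNames(lapply(tab, as.numeric), labels)
    rec <- list(signals = signals, fs = fs, labels = labels, source = path)
  }
  for (lb in names(rec$signals)) {
    if (length(rec$signals[[lb]]) == 0) {
      abort(sprintf("channel '%s' has zero length.", lb))
    }
    check_finite_numeric(rec$signals[[lb]], lb)
  }
  structure(rec, class = "bisca_recording")
}

looks_like_header <- function(path) {
  first <- readLines(path, n = 1)
  fields <- strsplit(trimws(first), "[,\t ]+")[[1]]
  any(is.na(suppressWarnings(as.numeric(fields))))
}

#' @export
print.bisca_recording <- function(x, ...) {
  cat(sprintf("<bisca_recording> %d channel(s) at %g Hz: %s\n",
              length(x$signals), x$fs,
              paste(utils::head(x$labels, 8), collapse = ", ")))
  invisible(x)
}

# Minimal EDF reader: ASCII header + 16-bit little-endian samples, digital
# values mapped to physical units per channel. Annotation channels ("EDF
# Annotations") are skipped. Written in-package because the environment has
# no R EDF reader; covers the plain continuous-recording profile only.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    out <- rawToChar(readBin(con, "raw", nc))
    trimws(out)
  }
  version <- rd(8)
  rd(80); rd(80); rd(8); rd(8) # patient, recording, date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_records)) {
    abort("malformed EDF header.")
  }
  field <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- field(16)
  field(80); field(8) # transducer, physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80) # prefilter
  spr <- as.integer(field(8))
  field(32)
  seek(con, header_bytes)
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (!any(keep)) abort("EDF file contains no signal channels.")
  store <- lapply(seq_len(ns), function(i) {
    if (keep[i]) vector("list", n_records) else NULL
  })
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                      endian = "little")
      if (length(vals) < spr[i]) abort("EDF data section truncated.")
      if (keep[i]) store[[i]][[r]] <- vals
    }
  }
  idx <- which(keep)
  signals <- lapply(idx, function(i) {
    dig <- as.numeric(unlist(store[[i]]))
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    (dig - dig_min[i]) * scale + phys_min[i]
  })
  fs_per <- spr[idx] / record_dur
  if (length(unique(fs_per)) > 1) {
    abort("EDF channels have inconsistent sampling rates.")
  }
  labels_keep <- make.unique(labels[idx])
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("read_edf: skipped %d annotation channel(s).", n_skipped))
  }
  list(signals = setNames(signals, labels_keep), fs = fs_per[1],
       labels = labels_keep, source = path, edf_version = version)
}

#' Flatten an estimate surface for delimited export
#'
#' Converts a spectrum, bispectrum, bicoherence or decomposition tibble into
#' a plain data frame in which every complex column is replaced by `_re` and
#' `_im` column pairs, suitable for `readr::write_csv()`.
#'
#' @param x A surface tibble produced by this package.
#' @return A plain tibble without complex columns.
#' @export
surface_table <- function(x) {
  out <- as_tibble(as.data.frame(x))
  cplx <- names(out)[vapply(out, is.complex, logical(1))]
  for (nm in cplx) {
    out[[paste0(nm, "_re")]] <- Re(out[[nm]])
    out[[paste0(nm, "_im")]] <- Im(out[[nm]])
    out[[nm]] <- NULL
  }
  out
}

#' Write a channel report as JSON
#'
#' Serializes the statistics, thresholds, p-values, label, fit summary and
#' provenance of a [run_pipeline()] channel report.
#'
#' @param report A `bisca_channel_report`.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "bisca_channel_report"))
  g <- report$gl$gauss
  l <- report$gl$lin
  obj <- list(
    channel = report$channel_id,
    label = report$gl$label,
    gaussianity = list(b_g = g$b_g, t_g = g$t_g, c_g = g$c_g, p_g = g$p_g),
    linearity = list(b_l = l$b_l, t_l = l$t_l, lambda0 = l$lambda0,
                     c_l = l$c_l, p_l = l$p_l),
    n_eff = report$n_eff$n_eff,
    n_segments = report$n_eff$n_nominal,
    ar_order = report$n_eff$ar_order,
    f_smax = report$peaks$f_smax,
    f_bmax = report$peaks$f_bmax,
    fit = if (!is.null(report$fit)) {
      list(k_peaks = report$fit$params$k_peaks,
           aic = report$fit$aic, loglik = report$fit$loglik,
           converged = report$fit$converged,
           mu_rho = report$fit$params$rho$mu,
           component_labels = if (!is.null(report$components)) {
             list(xi = report$components$xi$label,
                  rho = report$components$rho$label)
           })
    },
    provenance = report$provenance)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
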