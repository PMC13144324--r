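# Minimal EDF writer used only to build test fixtures at run time; kept in
# the test helpers (not the package) so the reader is checked against an
# independent implementation of the format.

write_edf_fixture <- function(path, signals, fs, record_seconds = 1,
                              add_annotations = FALSE) {
  ns_data <- length(signals)
  labels <- names(signals)
  spr <- as.integer(fs * record_seconds)
  n_records <- as.integer(min(lengths(signals)) / spr)
  phys_min <- vapply(signals, function(s) floor(min(s)) - 1, numeric(1))
  phys_max <- vapply(signals, function(s) ceiling(max(s)) + 1, numeric(1))
  dig_min <- rep(-32768, ns_data)
  dig_max <- rep(32767, ns_data)
  if (add_annotations) {
    labels <- c(labels, "EDF Annotations")
    phys_min <- c(phys_min, -1); phys_max <- c(phys_max, 1)
    dig_min <- c(dig_min, -32768); dig_max <- c(dig_max, 32767)
    spr_all <- c(rep(spr, ns_data), 10L)
  } else {
    spr_all <- rep(spr, ns_data)
  }
  ns <- length(labels)
  con <- file(path, "wb")
  on.exit(close(con))
  wrt <- function(x, width) {
    s <- formatC(as.character(x), width = width, flag = "-")
    writeChar(paste(substr(s, 1, width), collapse = ""), con,
              eos = NULL)
  }
  header_bytes <- 256 + 256 * ns
  wrt("0", 8); wrt("test patient", 80); wrt("test recording", 80)
  wrt("01.01.24", 8); wrt("00.00.00", 8)
  wrt(header_bytes, 8); wrt("", 44); wrt(n_records, 8)
  wrt(format(record_seconds), 8); wrt(ns, 4)
  for (lb in labels) wrt(lb, 16)
  for (i in seq_len(ns)) wrt("", 80)           # transducer
  for (i in seq_len(ns)) wrt("uV", 8)          # physical dimension
  for (v in phys_min) wrt(format(v), 8)
  for (v in phys_max) wrt(format(v), 8)
  for (v in dig_min) wrt(format(v), 8)
  for (v in dig_max) wrt(format(v), 8)
  for (i in seq_len(ns)) wrt("", 80)           # prefilter
  for (v in spr_all) wrt(v, 8)
  for (i in seq_len(ns)) wrt("", 32)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      if (i <= ns_data) {
        seg <- signals[[i]][((r - 1) * spr + 1):(r * spr)]
        dig <- round((seg - phys_min[i]) /
                       (phys_max[i] - phys_min[i]) *
                       (dig_max[i] - dig_min[i]) + dig_min[i])
        writeBin(as.integer(dig), con, size = 2, endian = "little")
      } else {
        writeBin(integer(spr_all[i]), con, size = 2, endian = "little")
      }
    }
  }
  invisible(path)
}
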