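# Minimal EDF writer used only to build test fixtures, written against the
# EDF field layout independently of the package reader.
write_edf_fixture <- function(path, data, sampling_rate,
                              phys_range = c(-100, 100)) {
  ns <- nrow(data)
  record_dur <- 1
  nsamp <- sampling_rate * record_dur
  n_records <- ncol(data) / nsamp
  stopifnot(n_records == round(n_records))
  pad <- function(s, w) sprintf("%-*s", w, format(s, scientific = FALSE,
                                                  trim = TRUE))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("test patient", 80), pad("test rec", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(256 * (ns + 1), 8), pad("", 44),
                pad(n_records, 8), pad(record_dur, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste0(sapply(vals, pad, w = w),
                                              collapse = ""), con, eos = NULL)
  labels <- if (!is.null(rownames(data))) rownames(data)
            else paste0("EEG", seq_len(ns))
  dmin <- -32768; dmax <- 32767
  field(labels, 16)
  field(rep("", ns), 80)                 # transducer
  field(rep("uV", ns), 8)                # physical dimension
  field(rep(phys_range[1], ns), 8)
  field(rep(phys_range[2], ns), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                 # prefiltering
  field(rep(nsamp, ns), 8)
  field(rep("", ns), 32)                 # reserved
  scale <- (dmax - dmin) / (phys_range[2] - phys_range[1])
  for (r in seq_len(n_records)) {
    cols <- (r - 1) * nsamp + seq_len(nsamp)
    for (i in seq_len(ns)) {
      dig <- round((data[i, cols] - phys_range[1]) * scale + dmin)
      writeBin(as.integer(pmin(dmax, pmax(dmin, dig))), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
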