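# Epoch-set container on disk, and an EDF (European Data Format) reader for
# slicing real continuous recordings into labeled epochs.
#
# Container layout (one directory):
#   spec.json      acquisition spec + seed + matrix dialect
#   codebook.csv   (+ codebook.csv.json sidecar)
#   epochs.csv     index: epoch_id,label,layout,onset_s,duration_s,file
#   epoch_*.bin    64-bit IEEE little-endian doubles, row-major
#                  (channels x samples), or epoch_*.csv for the text dialect

#' Write an epoch set to a directory
#'
#' @param epochset An `ssvep_epochset`.
#' @param path Output directory (created if missing).
#' @param dialect `"bin"` (64-bit little-endian doubles; round-trips
#'   bit-exact) or `"csv"` (plain text, full double precision).
#' @return `path`, invisibly.
#' @export
write_epochset <- function(epochset, path, dialect = c("bin", "csv")) {
  stopifnot(inherits(epochset, "ssvep_epochset"))
  dialect <- match.arg(dialect)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sp <- epochset$spec
  jsonlite::write_json(
    list(sampling_rate = sp$sampling_rate, montage = sp$montage,
         band = sp$band, seed = epochset$seed, dialect = dialect),
    file.path(path, "spec.json"), auto_unbox = TRUE, digits = NA)
  write_codebook(epochset$codebook, file.path(path, "codebook.csv"))
  n <- length(epochset$epochs)
  files <- sprintf("epoch_%04d.%s", seq_len(n), dialect)
  idx <- data.frame(
    epoch_id = seq_len(n) - 1L,
    label = vapply(epochset$epochs, function(e) e$label, integer(1)),
    layout = vapply(epochset$epochs, function(e) e$layout, character(1)),
    onset_s = vapply(epochset$epochs, function(e) e$onset, numeric(1)),
    duration_s = vapply(epochset$epochs, function(e) e$duration, numeric(1)),
    file = files)
  utils::write.csv(idx, file.path(path, "epochs.csv"), row.names = FALSE,
                   quote = FALSE, eol = "\n")
  for (i in seq_len(n)) {
    d <- epochset$epochs[[i]]$data
    fp <- file.path(path, files[i])
    if (dialect == "bin") {
      con <- file(fp, "wb")
      writeBin(as.vector(t(d)), con, size = 8, endian = "little")
      close(con)
    } else {
      utils::write.table(format(d, digits = 17, scientific = TRUE,
                                trim = TRUE),
                         fp, sep = ",", row.names = FALSE,
                         col.names = FALSE, quote = FALSE, eol = "\n")
    }
  }
  invisible(path)
}

#' Read an epoch set from a directory
#'
#' Inverse of [write_epochset()]; for the binary dialect the read data are
#' bit-identical to what was written. Malformed indices, missing matrix
#' files or shape mismatches raise parse errors naming the offending epoch.
#'
#' @param path Directory written by [write_epochset()].
#' @return An `ssvep_epochset`.
#' @export
read_epochset <- function(path) {
  spec_file <- file.path(path, "spec.json")
  if (!file.exists(spec_file))
    .err("parse_error", "missing spec.json in %s", path)
  meta <- jsonlite::read_json(spec_file, simplifyVector = TRUE)
  spec <- acquisition_spec(meta$sampling_rate, meta$montage, meta$band)
  cb <- read_codebook(file.path(path, "codebook.csv"))
  idx_file <- file.path(path, "epochs.csv")
  if (!file.exists(idx_file))
    .err("parse_error", "missing epochs.csv in %s", path)
  idx <- utils::read.csv(idx_file)
  need <- c("epoch_id", "label", "layout", "onset_s", "duration_s", "file")
  if (!all(need %in% names(idx)))
    .err("parse_error", "epochs.csv in %s lacks columns: %s", path,
         paste(setdiff(need, names(idx)), collapse = ", "))
  epochs <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    fp <- file.path(path, idx$file[i])
    if (!file.exists(fp))
      .err("parse_error", "epoch_id %d: matrix file %s not found",
           idx$epoch_id[i], idx$file[i])
    P <- round(idx$duration_s[i] * spec$sampling_rate)
    if (grepl("\\.bin$", fp)) {
      con <- file(fp, "rb")
      v <- readBin(con, "double", n = spec$n_channels * P + 1, size = 8,
                   endian = "little")
      close(con)
      if (length(v) != spec$n_channels * P)
        .err("parse_error", "epoch_id %d: expected %d values, found %d",
             idx$epoch_id[i], spec$n_channels * P, length(v))
      d <- matrix(v, nrow = spec$n_channels, byrow = TRUE)
    } else {
      d <- as.matrix(utils::read.csv(fp, header = FALSE))
      dimnames(d) <- NULL
      if (nrow(d) != spec$n_channels || ncol(d) != P)
        .err("parse_error", "epoch_id %d: matrix is %dx%d, expected %dx%d",
             idx$epoch_id[i], nrow(d), ncol(d), spec$n_channels, P)
    }
    rownames(d) <- spec$montage
    epochs[[i]] <- structure(
      list(data = d, onset = idx$onset_s[i], label = as.integer(idx$label[i]),
           layout = as.character(idx$layout[i]),
           duration = idx$duration_s[i], spec = spec),
      class = "ssvep_epoch")
  }
  structure(list(epochs = epochs, codebook = cb, spec = spec,
                 seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_),
            class = "ssvep_epochset")
}

# ---- EDF ------------------------------------------------------------------

# Minimal EDF reader: 256-byte fixed-width ASCII header, ns per-signal
# header blocks, then data records of int16 little-endian samples converted
# to physical units. Annotation channels are skipped. All retained signals
# must share one sampling rate.
.read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_records <- as.integer(fld(hdr, 237, 8))
  record_dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1)
    .err("parse_error", "EDF %s: bad signal count in header", path)
  sig_hdr <- rawToChar(readBin(con, "raw", 256 * ns))
  take <- function(width, offset) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1,
                    offset + i * width)), character(1))
  }
  labels <- take(16, 0)
  pmin_ <- as.numeric(take(8, ns * (16 + 80 + 8)))
  pmax_ <- as.numeric(take(8, ns * (16 + 80 + 8 + 8)))
  dmin_ <- as.numeric(take(8, ns * (16 + 80 + 8 + 8 + 8)))
  dmax_ <- as.numeric(take(8, ns * (16 + 80 + 8 + 8 + 8 + 8)))
  nsamp <- as.integer(take(8, ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80)))
  keep <- !grepl("Annotations", labels)
  if (!any(keep)) .err("parse_error", "EDF %s: no data signals", path)
  sig <- vector("list", ns)
  for (i in which(keep)) sig[[i]] <- numeric(n_records * nsamp[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < nsamp[i])
        .err("parse_error", "EDF %s: truncated at record %d", path, r)
      if (keep[i])
        sig[[i]][(r - 1) * nsamp[i] + seq_len(nsamp[i])] <-
          (v - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) + pmin_[i]
    }
  }
  rates <- nsamp[keep] / record_dur
  if (length(unique(rates)) != 1)
    .err("parse_error", "EDF %s: signals have differing sampling rates", path)
  data <- do.call(rbind, sig[keep])
  rownames(data) <- labels[keep]
  list(data = data, sampling_rate = rates[1], labels = labels[keep],
       n_samples = ncol(data))
}

#' Slice a continuous EDF recording into labeled epochs
#'
#' Reads a European Data Format file and cuts it into epochs according to
#' an event table. Slices are half-open `[onset, onset + duration)` in
#' seconds with 0-based sample indexing: the epoch at onset `o` starts at
#' sample `round(o * F)`.
#'
#' @param path EDF file.
#' @param events Data frame with columns `onset_s` and `label`, and either
#'   a `duration_s` column or the `duration` argument; or a path to such a
#'   CSV file.
#' @param duration Common epoch duration in seconds when `events` has no
#'   `duration_s` column.
#' @param codebook Optional `ssvep_codebook` attached to the returned set
#'   (labels must index it); defaults to a nominal codebook spanning the
#'   observed labels.
#' @param band Pass-band recorded in the acquisition spec (metadata).
#' @return An `ssvep_epochset`.
#' @export
read_edf <- function(path, events, duration = NULL, codebook = NULL,
                     band = c(0.5, 100)) {
  if (!file.exists(path)) .err("parse_error", "EDF file not found: %s", path)
  if (is.character(events)) events <- utils::read.csv(events)
  if (!all(c("onset_s", "label") %in% names(events)))
    .err("parse_error", "event table needs columns onset_s and label")
  dur <- if ("duration_s" %in% names(events)) events$duration_s
         else if (!is.null(duration)) rep(duration, nrow(events))
         else .err("parse_error", "no duration_s column and no duration given")
  raw <- .read_edf_raw(path)
  F <- raw$sampling_rate
  start <- round(events$onset_s * F)
  stop_ <- start + round(dur * F)
  bad <- which(start < 0 | stop_ > raw$n_samples)
  if (length(bad))
    .err("out_of_range",
         "event row(s) %s outside recording (0-%g s)",
         paste(bad, collapse = ", "), raw$n_samples / F)
  band[2] <- min(band[2], 0.45 * F)   # recorded band cannot exceed Nyquist
  spec <- acquisition_spec(F, raw$labels, band)
  if (is.null(codebook)) {
    mx <- max(events$label)
    codebook <- build_codebook(max(2, mx + 1), 8.0, 0.2, 0, 0.5 * pi)
  }
  epochs <- lapply(seq_len(nrow(events)), function(i) {
    d <- raw$data[, (start[i] + 1):stop_[i], drop = FALSE]
    structure(list(data = d, onset = events$onset_s[i],
                   label = as.integer(events$label[i]),
                   layout = if ("layout" %in% names(events))
                     as.character(events$layout[i]) else "EDF",
                   duration = dur[i], spec = spec),
              class = "ssvep_epoch")
  })
  structure(list(epochs = epochs, codebook = codebook, spec = spec,
                 seed = NA_integer_),
            class = "ssvep_epochset")
}
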