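#' Build an equally spaced frequency-phase codebook
#'
#' Constructs the hybrid frequency-phase code for an M-target SSVEP speller:
#' target `n` (0-based) flickers at `f0 + n * delta_f` Hz with initial phase
#' `(phi0 + n * delta_phi) mod 2pi`. Equal-interval frequency coding alone
#' separates targets in the spectrum; adding an equally spaced phase ramp
#' increases the difference between neighbouring codes, which is what makes
#' dense 0.2-Hz grids workable.
#'
#' The defaults produce the classic 40-target grid spanning 8.0-15.8 Hz in
#' 0.2-Hz steps with a phase interval of 0.5*pi, laid out 5 x 8 on screen.
#'
#' @param n_targets Number of targets M (>= 2).
#' @param f0 Lowest stimulation frequency in Hz.
#' @param delta_f Frequency interval in Hz (> 0).
#' @param phi0 Initial phase at the lowest frequency, radians.
#' @param delta_phi Phase interval between consecutive targets, radians.
#' @param grid_shape Integer vector `c(rows, cols)` describing the display
#'   layout; purely metadata. Defaults to `c(5, 8)` when `n_targets` is 40,
#'   otherwise a single row.
#' @return An object of class `ssvep_codebook`: a data frame with columns
#'   `index` (0-based), `frequency` (Hz) and `phase` (radians in
#'   `[0, 2pi)`), carrying the generating parameters as attributes.
#' @export
#' @examples
#' cb <- build_codebook()
#' cb$frequency[cb$index == 22]   # 12.4 Hz
build_codebook <- function(n_targets = 40, f0 = 8.0, delta_f = 0.2,
                           phi0 = 0, delta_phi = 0.5 * pi,
                           grid_shape = NULL) {
  if (!is.numeric(n_targets) || n_targets < 2 || n_targets != round(n_targets))
    .err("invalid_codebook", "n_targets must be an integer >= 2, got %s",
         format(n_targets))
  if (!is.numeric(delta_f) || delta_f <= 0)
    .err("invalid_codebook", "delta_f must be > 0, got %s", format(delta_f))
  if (f0 <= 0)
    .err("invalid_codebook", "f0 must be > 0, got %s", format(f0))
  n_targets <- as.integer(n_targets)
  idx <- seq_len(n_targets) - 1L
  freq <- f0 + idx * delta_f
  if (anyDuplicated(freq))
    .err("invalid_codebook", "frequency collision in codebook")
  phase <- .wrap_phase(phi0 + idx * delta_phi)
  if (is.null(grid_shape)) {
    grid_shape <- if (n_targets == 40L) c(5L, 8L) else c(1L, n_targets)
  }
  cb <- data.frame(index = idx, frequency = freq, phase = phase)
  structure(cb,
            f0 = f0, delta_f = delta_f, phi0 = phi0, delta_phi = delta_phi,
            grid_shape = as.integer(grid_shape),
            class = c("ssvep_codebook", "data.frame"))
}

#' @export
print.ssvep_codebook <- function(x, ...) {
  cat(sprintf("SSVEP frequency-phase codebook: %d targets, %.3g-%.3g Hz (step %.3g), phase step %.4g rad\n",
              nrow(x), min(x$frequency), max(x$frequency),
              attr(x, "delta_f"), attr(x, "delta_phi")))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more targets\n", nrow(x) - 6L))
  invisible(x)
}

#' Sampled-sine stimulus waveform for one target
#'
#' Generates the luminance sequence a display would present for one coded
#' target: a sine at the target's frequency and phase, sampled at the frame
#' rate and mapped to `[0, 1]` via `0.5 * (1 + sin(.))` so the code becomes
#' a displayable non-negative waveform.
#'
#' @param code One codebook row (or any list with `frequency` and `phase`).
#' @param frame_rate Display refresh rate in Hz; must exceed twice the
#'   stimulation frequency.
#' @param duration Waveform length in seconds.
#' @return An object of class `ssvep_waveform`: numeric vector of
#'   `round(duration * frame_rate)` luminance samples in `[0, 1]`, with the
#'   code and frame rate attached as attributes.
#' @export
#' @examples
#' w <- stimulus_waveform(list(frequency = 9, phase = 0), frame_rate = 60,
#'                        duration = 1)
#' length(w)  # 60
stimulus_waveform <- function(code, frame_rate, duration) {
  f <- code$frequency
  phi <- code$phase
  stopifnot(is.numeric(f), is.numeric(phi), length(f) == 1L)
  if (duration <= 0) .err("invalid_input", "duration must be > 0")
  if (frame_rate < 2 * f)
    .err("aliasing", "frame_rate %.4g Hz is below Nyquist for %.4g Hz stimulus",
         frame_rate, f)
  n <- round(duration * frame_rate)
  k <- seq_len(n) - 1
  samples <- 0.5 * (1 + sin(2 * pi * f * k / frame_rate + phi))
  structure(samples, frame_rate = frame_rate,
            frequency = f, phase = phi, class = "ssvep_waveform")
}

#' Write / read a codebook as CSV plus JSON sidecar
#'
#' The CSV has header `index,frequency_hz,phase_rad` with frequencies and
#' phases formatted at full double precision (round-trips bit-exact); the
#' sidecar `<path>.json` records the generating parameters.
#'
#' @param codebook An `ssvep_codebook`.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_codebook` returns `path` invisibly; `read_codebook` returns
#'   the reconstructed `ssvep_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "ssvep_codebook"))
  lines <- c("index,frequency_hz,phase_rad",
             sprintf("%d,%.17g,%.17g",
                     codebook$index, codebook$frequency, codebook$phase))
  writeLines(lines, path, useBytes = TRUE)
  meta <- list(f0 = attr(codebook, "f0"),
               delta_f = attr(codebook, "delta_f"),
               phi0 = attr(codebook, "phi0"),
               delta_phi = attr(codebook, "delta_phi"),
               n_targets = nrow(codebook),
               grid_shape = attr(codebook, "grid_shape"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) .err("parse_error", "codebook file not found: %s", path)
  tab <- utils::read.csv(path, colClasses = c("integer", "numeric", "numeric"))
  if (!identical(names(tab), c("index", "frequency_hz", "phase_rad")))
    .err("parse_error", "codebook %s: expected header index,frequency_hz,phase_rad",
         path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(f0 = tab$frequency_hz[1],
                    delta_f = if (nrow(tab) > 1) diff(tab$frequency_hz[1:2]) else 1,
                    phi0 = tab$phase_rad[1],
                    delta_phi = 0, grid_shape = c(1L, nrow(tab)))
  cb <- data.frame(index = tab$index, frequency = tab$frequency_hz,
                   phase = tab$phase_rad)
  structure(cb, f0 = meta$f0, delta_f = meta$delta_f, phi0 = meta$phi0,
            delta_phi = meta$delta_phi,
            grid_shape = as.integer(meta$grid_shape),
            class = c("ssvep_codebook", "data.frame"))
}
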