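#' Standard 21-electrode 10-20 montage
#'
#' Channel labels for the international 10-20 placement with 8 electrodes
#' per hemisphere plus midline Fz/Cz/Pz and the two ear electrodes.
#'
#' @return Character vector of 21 channel labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2", "A1", "A2")
}

#' EEG acquisition specification
#'
#' Describes how epochs were (or are to be) acquired: sampling rate, channel
#' montage and analog pass-band. Defaults match a typical SSVEP recording:
#' 1 kHz sampling, the 21-channel 10-20 montage, 0.5-100 Hz band.
#'
#' @param sampling_rate Sampling rate F in Hz; must exceed twice the upper
#'   band edge.
#' @param montage Ordered character vector of channel labels.
#' @param band Length-2 numeric `c(low, high)` pass-band in Hz.
#' @return Object of class `ssvep_acq`.
#' @export
acquisition_spec <- function(sampling_rate = 1000,
                             montage = montage_1020(),
                             band = c(0.5, 100)) {
  stopifnot(is.numeric(sampling_rate), length(band) == 2L,
            band[1] > 0, band[1] < band[2])
  if (sampling_rate <= 2 * band[2])
    .err("invalid_input",
         "sampling_rate %.4g must exceed twice the upper band edge %.4g",
         sampling_rate, band[2])
  structure(list(sampling_rate = sampling_rate,
                 n_channels = length(montage),
                 montage = as.character(montage),
                 band = as.numeric(band)),
            class = "ssvep_acq")
}

#' @export
print.ssvep_acq <- function(x, ...) {
  cat(sprintf("Acquisition: %g Hz, %d channels (%s...), band %g-%g Hz\n",
              x$sampling_rate, x$n_channels,
              paste(utils::head(x$montage, 4), collapse = ","),
              x$band[1], x$band[2]))
  invisible(x)
}

#' Default per-channel SSVEP gains for a montage
#'
#' SSVEP is strongest over visual cortex, so occipital electrodes (O1, O2,
#' and Oz/POz where present) get weight 1 and all other channels 0.2.
#'
#' @param montage Character vector of channel labels.
#' @return Named numeric vector of gains.
#' @export
occipital_gains <- function(montage = montage_1020()) {
  g <- rep(0.2, length(montage))
  names(g) <- montage
  g[montage %in% c("O1", "O2", "Oz", "POz", "PO3", "PO4", "PO5", "PO6",
                   "PO7", "PO8")] <- 1.0
  g
}

#' SSVEP response model for the forward simulator
#'
#' Parameterizes the simulated evoked response: number of harmonics and
#' their amplitude decay, per-channel signal gains, signal-to-noise ratio,
#' background-noise spectral slope, an optional mains-line component and a
#' constant visual-pathway latency.
#'
#' @param n_harmonics Number of response harmonics H (>= 1).
#' @param harmonic_decay Amplitude of harmonic k scales as `k^-harmonic_decay`.
#' @param snr_db Per-channel signal-to-noise ratio in dB; `Inf` for
#'   noiseless epochs.
#' @param channel_gains Numeric vector of per-channel gains, or `NULL` to
#'   resolve [occipital_gains()] against the acquisition montage at
#'   simulation time. Must be non-negative with at least one positive entry.
#' @param noise_exponent Spectral slope alpha of the `1/f^alpha` background
#'   noise (1 = pink, 0 = white).
#' @param line_amp Amplitude of a deterministic 50 Hz mains component added
#'   to every channel (0 disables it).
#' @param latency_s Constant response latency in seconds (delays the evoked
#'   signal without changing its coded phase convention).
#' @param layout_snr_db Optional named numeric vector of per-layout SNR
#'   offsets in dB (e.g. `c("AR-Pos2" = 2)`), added to `snr_db` when an
#'   epoch is simulated under that layout tag.
#' @return Object of class `ssvep_model`.
#' @export
ssvep_model <- function(n_harmonics = 5, harmonic_decay = 1, snr_db = 0,
                        channel_gains = NULL, noise_exponent = 1,
                        line_amp = 0, latency_s = 0,
                        layout_snr_db = NULL) {
  stopifnot(n_harmonics >= 1, n_harmonics == round(n_harmonics))
  if (!is.null(channel_gains)) {
    if (any(channel_gains < 0) || !any(channel_gains > 0))
      .err("invalid_input",
           "channel_gains must be non-negative with at least one positive entry")
  }
  structure(list(n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay,
                 snr_db = snr_db,
                 channel_gains = channel_gains,
                 noise_exponent = noise_exponent,
                 line_amp = line_amp,
                 latency_s = latency_s,
                 layout_snr_db = layout_snr_db),
            class = "ssvep_model")
}
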