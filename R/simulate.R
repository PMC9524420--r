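# Forward simulation of multi-channel SSVEP epochs: harmonic response at the
# coded frequency/phase over occipitally weighted channels, plus 1/f^alpha
# Gaussian background noise calibrated to a requested per-channel SNR.

# 1/f^alpha noise of length n, unit variance, via FFT spectral shaping of
# white Gaussian noise. alpha = 0 reduces to white noise; DC is removed.
.colored_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w - mean(w))
  W <- stats::fft(w)
  k <- 0:(n - 1)
  fidx <- pmin(k, n - k)          # symmetric frequency index, 0 at DC
  scale <- c(0, fidx[-1]^(-alpha / 2))
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Evoked waveform (single time course) for a coded target:
# sum over harmonics k of k^-decay * sin(2*pi*k*f*t + k*phi).
.evoked_course <- function(frequency, phase, model, sampling_rate, n_samples) {
  tt <- (seq_len(n_samples) - 1) / sampling_rate - model$latency_s
  s <- numeric(n_samples)
  for (k in seq_len(model$n_harmonics)) {
    s <- s + k^(-model$harmonic_decay) *
      sin(2 * pi * k * frequency * tt + k * phase)
  }
  s
}

.resolve_gains <- function(model, spec) {
  g <- model$channel_gains
  if (is.null(g)) g <- occipital_gains(spec$montage)
  if (length(g) == 1L) g <- rep(g, spec$n_channels)
  if (length(g) != spec$n_channels)
    .err("invalid_input", "channel_gains length %d != n_channels %d",
         length(g), spec$n_channels)
  as.numeric(g)
}

#' Simulate one SSVEP epoch
#'
#' Generates a channels x samples matrix containing the evoked harmonic
#' response for one coded target plus background noise. Each channel `c`
#' carries `gain[c]` times the sum over harmonics `k = 1..H` of
#' `k^-decay * sin(2 pi k f t + k phi)`, with `1/f^alpha` Gaussian noise
#' scaled so that the per-channel signal-to-noise power ratio equals the
#' model's `snr_db`. Identical inputs and seed give a bit-identical matrix.
#'
#' @param code One codebook row (list with `frequency`, `phase`, and
#'   optionally `index` used as the epoch label).
#' @param duration Epoch length in seconds.
#' @param model An [ssvep_model()].
#' @param spec An [acquisition_spec()].
#' @param seed Integer seed controlling the noise realization.
#' @param layout Layout tag stored as epoch metadata; if the model carries a
#'   matching `layout_snr_db` entry it offsets the SNR.
#' @param onset Epoch onset in seconds (metadata only).
#' @return Object of class `ssvep_epoch`: list with `data`
#'   (channels x samples, microvolt scale), `onset`, `label`, `layout`,
#'   `duration` and `spec`.
#' @export
#' @examples
#' cb <- build_codebook(4, 10, 1, 0, 0)
#' sp <- acquisition_spec(250, c("Oz", "O1", "O2"), band = c(0.5, 100))
#' ep <- simulate_epoch(cb[1, ], 1, ssvep_model(snr_db = 0), sp, seed = 1)
#' dim(ep$data)
simulate_epoch <- function(code, duration, model, spec, seed,
                           layout = "AR-Pos1", onset = 0) {
  stopifnot(inherits(model, "ssvep_model"), inherits(spec, "ssvep_acq"))
  if (duration <= 0) .err("invalid_input", "duration must be > 0")
  f <- code$frequency
  phi <- code$phase
  if (model$n_harmonics * f >= spec$sampling_rate / 2)
    .err("aliasing", "harmonic %d x %.4g Hz is at or above Nyquist (%g Hz)",
         model$n_harmonics, f, spec$sampling_rate / 2)
  P <- round(duration * spec$sampling_rate)
  gains <- .resolve_gains(model, spec)
  s <- .evoked_course(f, phi, model, spec$sampling_rate, P)
  data <- outer(gains, s)

  snr <- model$snr_db
  if (!is.null(model$layout_snr_db) && layout %in% names(model$layout_snr_db))
    snr <- snr + model$layout_snr_db[[layout]]
  if (is.finite(snr)) {
    sig_pow <- rowMeans(data^2)
    ref_pow <- mean(sig_pow[gains > 0])   # fallback scale for silent channels
    sig_pow[gains == 0] <- ref_pow
    noise <- withr::with_seed(as.integer(seed), {
      t(vapply(seq_len(spec$n_channels),
               function(i) .colored_noise(P, model$noise_exponent),
               numeric(P)))
    })
    noise_pow <- rowMeans(noise^2)
    target_pow <- sig_pow * 10^(-snr / 10)
    data <- data + noise * sqrt(target_pow / noise_pow)
  }
  if (model$line_amp != 0) {
    tt <- (seq_len(P) - 1) / spec$sampling_rate
    data <- data + rep(1, spec$n_channels) %o%
      (model$line_amp * sin(2 * pi * 50 * tt))
  }
  rownames(data) <- spec$montage
  structure(list(data = data, onset = onset,
                 label = if (!is.null(code$index)) as.integer(code$index) else NA_integer_,
                 layout = layout, duration = duration, spec = spec),
            class = "ssvep_epoch")
}

#' Simulate a balanced multi-trial SSVEP session
#'
#' Produces `n_targets x trials_per_target` epochs with a label sequence
#' shuffled deterministically from the seed; each epoch gets its own child
#' seed via [split_seed()], so the whole session is reproducible from one
#' integer.
#'
#' @param codebook An `ssvep_codebook`.
#' @param trials_per_target Trials per target (>= 1).
#' @param duration Epoch length in seconds.
#' @param model An [ssvep_model()].
#' @param spec An [acquisition_spec()].
#' @param seed Master seed.
#' @param layout Layout tag applied to every epoch.
#' @return Object of class `ssvep_epochset`: list with `epochs` (list of
#'   `ssvep_epoch`), `codebook`, `spec`, `seed`.
#' @export
simulate_session <- function(codebook, trials_per_target, duration, model,
                             spec, seed, layout = "AR-Pos1") {
  stopifnot(inherits(codebook, "ssvep_codebook"))
  if (nrow(codebook) < 1) .err("invalid_input", "empty codebook")
  if (trials_per_target < 1)
    .err("invalid_input", "trials_per_target must be >= 1")
  labels <- rep(codebook$index, each = trials_per_target)
  labels <- withr::with_seed(as.integer(seed), sample(labels))
  seeds <- split_seed(seed, length(labels))
  epochs <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    code <- codebook[codebook$index == labels[i], ]
    epochs[[i]] <- simulate_epoch(code, duration, model, spec, seeds[i],
                                  layout = layout,
                                  onset = (i - 1) * duration)
  }
  structure(list(epochs = epochs, codebook = codebook, spec = spec,
                 seed = as.integer(seed)),
            class = "ssvep_epochset")
}

#' @export
print.ssvep_epochset <- function(x, ...) {
  cat(sprintf("SSVEP epoch set: %d epochs, %d targets, %g Hz, %d channels\n",
              length(x$epochs), nrow(x$codebook),
              x$spec$sampling_rate, x$spec$n_channels))
  invisible(x)
}

# Extend a window at both ends by Burg autoregressive linear prediction.
# Unlike mirror padding this continues oscillatory content without a kink
# at the joint, so filter edge artifacts stay out of the kept window; Burg
# models are minimum-phase, so the extrapolation always decays.
.ar_extend <- function(x, npad, order = 20L) {
  ord <- min(order, length(x) - 1L)
  fit <- tryCatch(stats::ar.burg(x, aic = FALSE, order.max = ord,
                                 demean = FALSE),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0)
    return(list(left = rep(x[1], npad), right = rep(x[length(x)], npad)))
  cf <- fit$ar
  p <- length(cf)
  P <- length(x)
  predict_fwd <- function(v) {
    out <- numeric(npad)
    buf <- v[P:(P - p + 1)]
    for (i in seq_len(npad)) {
      out[i] <- sum(cf * buf)
      buf <- c(out[i], buf[-p])
    }
    out
  }
  list(left = rev(predict_fwd(rev(x))), right = predict_fwd(x))
}

# Forward-backward (zero-phase) filtering with AR-prediction padding at
# both ends, so edge transients land in the discarded pads rather than in
# the window. signal::filter returns a ts object; coerce before reversing.
.filtfilt_pad <- function(filt, x) {
  P <- length(x)
  npad <- min(P - 1, 250L)
  ext <- .ar_extend(x, npad)
  y <- as.numeric(signal::filter(filt, c(ext$left, x, ext$right)))
  z <- rev(as.numeric(signal::filter(filt, rev(y))))
  z[(npad + 1):(npad + P)]
}

# Zero-phase band-pass of a channels x samples matrix: per-channel
# demeaning, then a 2nd-order Butterworth high-pass at `low` cascaded with
# a 4th-order low-pass at `high`, each applied forward-backward (filtfilt
# with reflection padding), so the passband is preserved without phase
# distortion and out-of-band tones drop far more than 40 dB per octave.
.bandpass_mat <- function(data, low, high, sampling_rate) {
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    .err("invalid_input", "invalid band [%g, %g] at sampling rate %g",
         low, high, sampling_rate)
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  out <- data - rowMeans(data)
  for (i in seq_len(nrow(out))) {
    x <- .filtfilt_pad(hp, out[i, ])
    out[i, ] <- .filtfilt_pad(lp, x)
  }
  out
}

#' Zero-phase band-pass filter an epoch
#'
#' Forward-backward Butterworth filtering of every channel; the output epoch
#' has the same shape and metadata.
#'
#' @param epoch An `ssvep_epoch`.
#' @param low,high Band edges in Hz, `0 < low < high < Nyquist`.
#' @return Filtered `ssvep_epoch`.
#' @export
bandpass <- function(epoch, low, high) {
  stopifnot(inherits(epoch, "ssvep_epoch"))
  epoch$data <- .bandpass_mat(epoch$data, low, high, epoch$spec$sampling_rate)
  epoch
}
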