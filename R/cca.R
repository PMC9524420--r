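# Canonical correlation analysis between multi-channel EEG and harmonic
# references, the frequency decision rule, circular-shift phase templates,
# and the filter-bank variant.

# Row-center a channels x samples matrix.
.center_rows <- function(X) X - rowMeans(X)

# Ridge added to a covariance block: each diagonal entry grows by a 1e-10
# relative amount, keeping the solve well-posed on short windows while
# perturbing rho by O(1e-10). Scaling the ridge per channel variance (not
# by the trace) keeps rho exactly invariant under per-channel rescaling.
.ridge <- function(C, scale = 1e-10) {
  d <- nrow(C)
  C + diag(scale * diag(C), d, d)
}

.chol_or_null <- function(C) tryCatch(chol(C), error = function(e) NULL)

#' Canonical correlation between an EEG segment and a reference set
#'
#' Finds projection vectors `wx`, `wy` maximizing the Pearson correlation
#' between `wx' X` and `wy' Y` and returns the maximal (first) canonical
#' correlation rho. Computed by Cholesky-whitening the two covariance blocks
#' and taking the largest singular value of the whitened cross-covariance;
#' covariance blocks receive a relative ridge of 1e-9 so short windows stay
#' solvable. rho is invariant (to ~1e-8) under any invertible linear
#' recombination of the channels of either input.
#'
#' @param X Channels x samples numeric matrix (e.g. an epoch's data).
#' @param Y Reference matrix with the same number of columns (samples).
#' @return Object of class `ssvep_cca`: list with `rho` in `[0, 1]` and the
#'   weight vectors `wx`, `wy`.
#' @export
#' @examples
#' Y <- make_reference(10, 2, 1000, 500)
#' X <- matrix(sin(2 * pi * 10 * (1:500) / 1000), nrow = 1)
#' cca_coefficient(X, Y)$rho  # 1 to numerical precision
cca_coefficient <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y))
    .err("invalid_input", "X and Y must have the same number of samples (%d vs %d)",
         ncol(X), ncol(Y))
  P <- ncol(X)
  if (P <= nrow(X) + nrow(Y))
    .err("invalid_input",
         "need more samples (%d) than combined dimensions (%d + %d)",
         P, nrow(X), nrow(Y))
  Xc <- .center_rows(X); Yc <- .center_rows(Y)
  Cxx <- .ridge(tcrossprod(Xc) / (P - 1))
  Cyy <- .ridge(tcrossprod(Yc) / (P - 1))
  Cxy <- tcrossprod(Xc, Yc) / (P - 1)
  Lx <- .chol_or_null(Cxx); Ly <- .chol_or_null(Cyy)
  if (is.null(Lx) || is.null(Ly)) {
    # escalate once for nearly degenerate inputs: absolute ridge scaled to
    # the mean channel variance (covers zero-variance channels too)
    esc <- function(C) C + diag(1e-6 * mean(diag(C)), nrow(C), nrow(C))
    Lx <- .chol_or_null(esc(Cxx)); Ly <- .chol_or_null(esc(Cyy))
    if (is.null(Lx) || is.null(Ly))
      .err("singular_input", "degenerate covariance: constant or empty input")
    warning("rank-deficient covariance: regularized solve", call. = FALSE)
  }
  A <- forwardsolve(t(Lx), Cxy)              # Lx^-T Cxy
  K <- t(forwardsolve(t(Ly), t(A)))          # Lx^-T Cxy Ly^-1
  sv <- svd(K)
  rho <- min(1, max(0, sv$d[1]))
  structure(list(rho = rho,
                 wx = backsolve(Lx, sv$u[, 1]),
                 wy = backsolve(Ly, sv$v[, 1])),
            class = "ssvep_cca")
}

# rho for a centered data matrix against each of a list of reference
# matrices; the hot inner loop of classification.
.rho_scores <- function(data, refs) {
  vapply(refs, function(Y) cca_coefficient(data, Y)$rho, numeric(1))
}

.make_refs <- function(frequencies, n_harmonics, sampling_rate, n_samples) {
  lapply(frequencies, make_reference, n_harmonics = n_harmonics,
         sampling_rate = sampling_rate, n_samples = n_samples)
}

.decoding_result <- function(rho, codebook) {
  pred <- which.max(rho)   # ties resolve to the lowest index
  structure(list(rho_per_target = as.numeric(rho),
                 predicted_index = codebook$index[pred],
                 predicted_frequency = codebook$frequency[pred]),
            class = "ssvep_decoding")
}

#' @export
print.ssvep_decoding <- function(x, ...) {
  cat(sprintf("Decoded target %d (%.4g Hz), rho_max = %.4f\n",
              x$predicted_index, x$predicted_frequency,
              max(x$rho_per_target)))
  invisible(x)
}

#' Classify an epoch by harmonic-reference CCA
#'
#' Computes the canonical correlation between the epoch and the harmonic
#' reference set of every codebook frequency, and predicts the target whose
#' reference attains the maximal correlation (ties broken toward the lowest
#' index).
#'
#' @param epoch An `ssvep_epoch` (or channels x samples matrix plus
#'   `sampling_rate`).
#' @param codebook An `ssvep_codebook`.
#' @param n_harmonics Harmonics per reference.
#' @param sampling_rate Required only when `epoch` is a bare matrix.
#' @return Object of class `ssvep_decoding`: `rho_per_target`,
#'   `predicted_index` (0-based codebook index), `predicted_frequency`.
#' @export
classify <- function(epoch, codebook, n_harmonics = 5, sampling_rate = NULL) {
  if (inherits(epoch, "ssvep_epoch")) {
    data <- epoch$data
    sampling_rate <- epoch$spec$sampling_rate
  } else {
    data <- as.matrix(epoch)
    if (is.null(sampling_rate))
      .err("invalid_input", "sampling_rate required for matrix input")
  }
  refs <- .make_refs(codebook$frequency, n_harmonics, sampling_rate,
                     ncol(data))
  .decoding_result(.rho_scores(data, refs), codebook)
}

#' Circularly shift a zero-phase template to another stimulation phase
#'
#' Phase-coded targets that share a frequency differ only by a time shift of
#' the steady-state response. A template recorded (or averaged) at phase 0
#' is mapped to phase `phi` by circular shift of
#' `round(((2 pi - phi) mod 2 pi) / (2 pi f) * F)` samples; `phi = 0` is the
#' identity and shifting by `2 pi` equals shifting by 0.
#'
#' @param template Numeric vector, or channels x samples matrix (columns are
#'   shifted).
#' @param frequency Stimulation frequency f in Hz.
#' @param phase Target phase in radians (wrapped into `[0, 2 pi)`).
#' @param sampling_rate Sampling rate F in Hz.
#' @return Shifted template of the same shape.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * (0:99) / 1000)
#' y <- phase_shift_template(x, 10, pi, 1000)  # = sin(2 pi 10 t + pi)
phase_shift_template <- function(template, frequency, phase, sampling_rate) {
  phi <- .wrap_phase(phase)
  mat <- is.matrix(template)
  P <- if (mat) ncol(template) else length(template)
  if (P < sampling_rate / frequency)
    .err("invalid_input", "template shorter than one cycle of %.4g Hz",
         frequency)
  s <- round(((2 * pi - phi) %% (2 * pi)) / (2 * pi * frequency) * sampling_rate)
  idx <- ((seq_len(P) - 1 - s) %% P) + 1
  if (mat) template[, idx, drop = FALSE] else template[idx]
}

#' Build per-target averaged templates from labeled epochs
#'
#' Averages the trials of each label into one channels x samples template,
#' the training step of template-extended CCA. With
#' `from_zero_phase = TRUE` the zero-phase target's average is instead
#' propagated to every phase by [phase_shift_template()] (all targets must
#' then share one frequency per phase group; used to exercise the shift
#' machinery on purely phase-coded sets).
#'
#' @param epochset An `ssvep_epochset`.
#' @param exclude Integer vector of epoch positions to leave out (e.g. the
#'   held-out trial during cross-validation).
#' @return Named list of templates, one per label present.
#' @export
build_templates <- function(epochset, exclude = integer(0)) {
  eps <- epochset$epochs
  keep <- setdiff(seq_along(eps), exclude)
  labs <- vapply(eps[keep], function(e) e$label, integer(1))
  out <- list()
  for (l in unique(labs)) {
    sel <- keep[labs == l]
    acc <- eps[[sel[1]]]$data
    if (length(sel) > 1)
      for (i in sel[-1]) acc <- acc + eps[[i]]$data
    out[[as.character(l)]] <- acc / length(sel)
  }
  out
}

#' Filter-bank specification for FBCCA
#'
#' Defaults follow the standard filter-bank construction for SSVEP decoding:
#' 5 sub-bands whose lower edges step up through the harmonic bands
#' (8, 16, 24, 32, 40 Hz) with a common upper edge of 88 Hz, combined with
#' weights `w(b) = b^-1.25 + 0.25`.
#'
#' @param n_subbands Number of sub-bands.
#' @param band_edges List of `c(low, high)` pairs in Hz, or `NULL` for the
#'   defaults.
#' @param weights Positive per-band weights, or `NULL` for the default decay.
#' @return Object of class `ssvep_filterbank`.
#' @export
filterbank_spec <- function(n_subbands = 5, band_edges = NULL,
                            weights = NULL) {
  if (is.null(band_edges))
    band_edges <- lapply(seq_len(n_subbands), function(b) c(8 * b, 88))
  if (is.null(weights))
    weights <- seq_len(length(band_edges))^(-1.25) + 0.25
  lows <- vapply(band_edges, `[`, numeric(1), 1)
  highs <- vapply(band_edges, `[`, numeric(1), 2)
  if (any(lows <= 0) || any(lows >= highs))
    .err("invalid_input", "filter-bank edges must satisfy 0 < low < high")
  if (is.unsorted(lows))
    .err("invalid_input", "filter-bank sub-bands must be ordered by lower edge")
  if (any(weights <= 0))
    .err("invalid_input", "filter-bank weights must be positive")
  structure(list(n_subbands = length(band_edges),
                 band_edges = band_edges,
                 weights = as.numeric(weights)),
            class = "ssvep_filterbank")
}

# Sub-band decomposition of a channels x samples matrix (zero-phase
# Butterworth band-pass per sub-band). Upper edges are clipped below
# Nyquist so one filter-bank spec serves any sampling rate.
.subband_mats <- function(data, fb, sampling_rate) {
  nyq <- sampling_rate / 2
  lapply(fb$band_edges, function(be) {
    hi <- min(be[2], 0.95 * nyq)
    if (be[1] >= hi)
      .err("invalid_input", "sub-band [%g, %g] invalid at sampling rate %g",
           be[1], be[2], sampling_rate)
    .bandpass_mat(data, be[1], hi, sampling_rate)
  })
}

# Weighted sum over sub-bands of squared canonical correlations, one score
# per reference.
.fb_scores <- function(data, refs, fb, sampling_rate) {
  subs <- .subband_mats(data, fb, sampling_rate)
  scores <- numeric(length(refs))
  for (b in seq_along(subs)) {
    rho_b <- .rho_scores(subs[[b]], refs)
    scores <- scores + fb$weights[b] * rho_b^2
  }
  scores
}

#' Classify an epoch by filter-bank CCA
#'
#' Decomposes the epoch into sub-bands, computes the canonical correlation
#' of each sub-band against every reference, and combines them as a
#' weighted sum of squared correlations before the argmax decision. The
#' sub-band weighting emphasizes the fundamental while still harvesting the
#' harmonic content of the SSVEP.
#'
#' @inheritParams classify
#' @param fb An [filterbank_spec()].
#' @return An `ssvep_decoding`. Note `rho_per_target` holds the combined
#'   (weighted sum of squared rho) scores, which exceed 1 when multiple
#'   sub-bands correlate; the argmax decision is unaffected.
#' @export
filterbank_classify <- function(epoch, codebook, fb = filterbank_spec(),
                                n_harmonics = 5, sampling_rate = NULL) {
  if (inherits(epoch, "ssvep_epoch")) {
    data <- epoch$data
    sampling_rate <- epoch$spec$sampling_rate
  } else {
    data <- as.matrix(epoch)
    if (is.null(sampling_rate))
      .err("invalid_input", "sampling_rate required for matrix input")
  }
  refs <- .make_refs(codebook$frequency, n_harmonics, sampling_rate,
                     ncol(data))
  .decoding_result(.fb_scores(data, refs, fb, sampling_rate), codebook)
}

# Template-extended scoring: combine squared reference correlation and
# squared template correlation with equal weight. `templates` is a named
# list keyed by label.
.ecca_scores <- function(data, refs, templates, codebook) {
  rho_ref <- .rho_scores(data, refs)
  rho_tmp <- vapply(seq_len(nrow(codebook)), function(m) {
    tmp <- templates[[as.character(codebook$index[m])]]
    if (is.null(tmp)) return(0)
    cca_coefficient(data, tmp[, seq_len(ncol(data)), drop = FALSE])$rho
  }, numeric(1))
  rho_ref^2 + rho_tmp^2
}
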