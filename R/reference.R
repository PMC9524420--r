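#' Sine-cosine harmonic reference matrix for one stimulation frequency
#'
#' Builds the canonical reference set used to detect an SSVEP at frequency
#' `fm`: rows alternate `sin(2 pi k fm t)` and `cos(2 pi k fm t)` for
#' harmonics `k = 1..H`, evaluated at `t = 1/F, 2/F, ..., P/F`.
#'
#' @param frequency Stimulation frequency fm in Hz.
#' @param n_harmonics Number of harmonics H; `H * fm` must stay below
#'   Nyquist.
#' @param sampling_rate Sampling rate F in Hz.
#' @param n_samples Number of samples P.
#' @return Matrix of dimension `2H x P` with attributes `frequency`,
#'   `n_harmonics`, `sampling_rate`; class `ssvep_reference`.
#' @export
#' @examples
#' Y <- make_reference(10, 2, 1000, 500)
#' dim(Y)  # 4 x 500
make_reference <- function(frequency, n_harmonics, sampling_rate, n_samples) {
  stopifnot(frequency > 0, n_harmonics >= 1, n_samples >= 2)
  if (n_harmonics * frequency >= sampling_rate / 2)
    .err("aliasing", "harmonic %d x %.4g Hz is at or above Nyquist (%g Hz)",
         n_harmonics, frequency, sampling_rate / 2)
  t <- seq_len(n_samples) / sampling_rate
  Y <- matrix(0, nrow = 2 * n_harmonics, ncol = n_samples)
  for (k in seq_len(n_harmonics)) {
    Y[2 * k - 1, ] <- sin(2 * pi * k * frequency * t)
    Y[2 * k, ]     <- cos(2 * pi * k * frequency * t)
  }
  structure(Y, frequency = frequency, n_harmonics = n_harmonics,
            sampling_rate = sampling_rate, class = c("ssvep_reference", "matrix", "array"))
}
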