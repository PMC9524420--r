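# Independent oracles used to cross-check the production implementations.

# Largest canonical correlation via explicit generalized eigenproblem on the
# joint covariance: rho^2 is the top eigenvalue of
# Cxx^-1 Cxy Cyy^-1 Cyx. Independent of the Cholesky/SVD production path.
oracle_cca_rho <- function(X, Y) {
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  P <- ncol(X)
  Cxx <- tcrossprod(Xc) / (P - 1)
  Cyy <- tcrossprod(Yc) / (P - 1)
  Cxy <- tcrossprod(Xc, Yc) / (P - 1)
  M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  ev <- eigen(M, only.values = TRUE)$values
  sqrt(max(pmin(pmax(Re(ev), 0), 1)))
}

# Bits per selection, written as a scalar piecewise evaluation (limits
# handled explicitly), structurally unlike the vectorized production code.
oracle_bits <- function(N, p) {
  out <- log(N, base = 2)
  if (p > 0) out <- out + p * log(p, base = 2)
  if (p < 1) out <- out + (1 - p) * log((1 - p) / (N - 1), base = 2)
  out
}

# Phase of the fundamental of a real signal sampled at t = 0, 1/F, ... :
# for x[t] = sin(2 pi f t / F + phi) over an integer number of cycles the
# DFT coefficient at f is P exp(i phi) / (2 i), so phi = Arg + pi/2.
estimate_phase <- function(x, frequency, sampling_rate) {
  t <- seq_along(x) - 1
  coeff <- sum(x * exp(-2i * pi * frequency * t / sampling_rate))
  (Arg(coeff) + pi / 2) %% (2 * pi)
}

# Small acquisition/model fixtures used across tests; 250 Hz and few
# channels keep the suite fast while preserving all structure.
test_spec <- function(n_channels = 4, sampling_rate = 250)
  acquisition_spec(sampling_rate, paste0("CH", seq_len(n_channels)),
                   band = c(0.5, 100))

test_model <- function(snr_db = 0, n_channels = 4, ...)
  ssvep_model(snr_db = snr_db, channel_gains = rep(1, n_channels), ...)
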