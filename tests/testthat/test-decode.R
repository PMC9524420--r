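test_that("harmonic references have the stated layout and values", {
  Y <- make_reference(10, 2, 1000, 500)
  expect_equal(dim(Y), c(4L, 500L))
  expect_equal(Y[1, 1], sin(2 * pi * 10 / 1000))
  expect_equal(Y[2, 1], cos(2 * pi * 10 / 1000))
  expect_equal(Y[3, 1], sin(2 * pi * 20 / 1000))
  # rows pairwise orthogonal when the window holds integer cycles
  G <- tcrossprod(Y)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-10)
  expect_error(make_reference(100, 3, 500, 100), class = "aliasing")
})

test_that("CCA attains 1 for self-correlation and in-span sinusoids", {
  withr::local_seed(11)
  X <- matrix(rnorm(5 * 300), 5)
  expect_equal(cca_coefficient(X, X)$rho, 1.0, tolerance = 1e-9)
  Y <- make_reference(10, 2, 1000, 500)
  x <- matrix(sin(2 * pi * 10 * (1:500) / 1000 + 0.7), nrow = 1)
  expect_equal(cca_coefficient(x, Y)$rho, 1.0, tolerance = 1e-9)
})

test_that("CCA matches the generalized-eigenproblem oracle on random instances", {
  withr::local_seed(202)
  for (i in 1:50) {
    nch <- sample(2:8, 1)
    P <- sample(100:1000, 1)
    X <- matrix(rnorm(nch * P), nch)
    Y <- make_reference(runif(1, 6, 20), sample(1:3, 1), 1000, P)
    expect_equal(cca_coefficient(X, Y)$rho, oracle_cca_rho(X, Y),
                 tolerance = 1e-8)
  }
  # third route: stats::cancor (QR-based) on one fixed instance
  X <- matrix(rnorm(4 * 400), 4)
  Y <- make_reference(11, 2, 1000, 400)
  expect_equal(cca_coefficient(X, Y)$rho,
               stats::cancor(t(X), t(Y))$cor[1], tolerance = 1e-8)
})

test_that("CCA is invariant to channel scaling and recombination", {
  withr::local_seed(5)
  X <- matrix(rnorm(6 * 400), 6)
  Y <- make_reference(12, 2, 1000, 400)
  r0 <- cca_coefficient(X, Y)$rho
  X2 <- X; X2[3, ] <- X2[3, ] * 1e3
  expect_lt(abs(cca_coefficient(X2, Y)$rho - r0), 1e-8)
  A <- matrix(rnorm(36), 6)   # invertible with prob. 1
  expect_lt(abs(cca_coefficient(A %*% X, Y)$rho - r0), 1e-7)
  expect_true(r0 >= 0 && r0 <= 1)
})

test_that("CCA rejects malformed and fully degenerate inputs", {
  Y <- make_reference(10, 1, 1000, 200)
  expect_error(cca_coefficient(matrix(rnorm(300), 1), Y),
               class = "invalid_input")
  expect_error(cca_coefficient(matrix(0, 2, 200), Y),
               class = "singular_input")
  # too few samples relative to dimensions
  expect_error(cca_coefficient(matrix(rnorm(10 * 12), 10),
                               make_reference(10, 3, 1000, 12)),
               class = "invalid_input")
})

test_that("noiseless epochs classify to their own target", {
  cb <- build_codebook()
  sp <- test_spec()
  m <- test_model(snr_db = Inf)
  for (idx in c(0, 9, 22, 31, 39)) {
    ep <- simulate_epoch(cb[cb$index == idx, ], 0.5, m, sp, seed = 1)
    expect_equal(classify(ep, cb)$predicted_index, idx)
  }
})

test_that("a 12.4 Hz epoch correlates maximally at 12.4 Hz, above neighbors", {
  cb <- build_codebook()
  sp <- test_spec(sampling_rate = 1000)
  m <- test_model(snr_db = 0)
  ep <- simulate_epoch(cb[cb$index == 22, ], 2, m, sp, seed = 9)
  dec <- classify(ep, cb)
  expect_equal(dec$predicted_frequency, 12.4)
  rho <- dec$rho_per_target
  expect_gt(rho[23], rho[22])   # vs 12.2 Hz
  expect_gt(rho[23], rho[24])   # vs 12.6 Hz
})

test_that("pure-noise epochs give a valid index and weak correlations", {
  cb <- build_codebook()
  sp <- test_spec()
  m <- test_model(snr_db = -200)   # signal drowned: effectively pure noise
  ep <- simulate_epoch(cb[5, ], 1, m, sp, seed = 31)
  dec <- classify(ep, cb)
  expect_true(dec$predicted_index %in% cb$index)
  expect_true(all(dec$rho_per_target < 0.5))
})

test_that("circular phase shift reproduces analytic sinusoids", {
  t <- 0:999
  x <- sin(2 * pi * 10 * t / 1000)
  # phase 0 is the identity
  expect_identical(phase_shift_template(x, 10, 0, 1000), x)
  # and so is a 2*pi shift
  expect_identical(phase_shift_template(x, 10, 2 * pi, 1000), x)
  # pi shift = 50 samples; equals sin(2 pi 10 t + pi) exactly on a
  # periodic window
  y <- phase_shift_template(x, 10, pi, 1000)
  expect_equal(y, sin(2 * pi * 10 * t / 1000 + pi), tolerance = 1e-9)
  # group property: phi then 2*pi - phi returns the original when both
  # shifts are integral in samples
  z <- phase_shift_template(phase_shift_template(x, 10, pi / 2, 1000),
                            10, 3 * pi / 2, 1000)
  expect_equal(z, x, tolerance = 1e-12)
  # matrices shift by column
  m <- rbind(x, 2 * x)
  ym <- phase_shift_template(m, 10, pi, 1000)
  expect_equal(ym[2, ], 2 * y, tolerance = 1e-9)
})

test_that("single full-band sub-band FBCCA reduces to plain CCA decisions", {
  cb <- build_codebook(4, 9, 1.5, 0, pi / 2)
  sp <- test_spec()
  m <- test_model(snr_db = -5)
  es <- simulate_session(cb, 2, 1, m, sp, seed = 3)
  fb1 <- filterbank_spec(band_edges = list(c(0.5, 100)), weights = 1)
  for (ep in es$epochs) {
    expect_equal(filterbank_classify(ep, cb, fb1)$predicted_index,
                 classify(ep, cb)$predicted_index)
  }
})

test_that("default filter bank decodes noiseless epochs and is no worse than CCA", {
  cb <- build_codebook()
  sp <- test_spec()
  ep <- simulate_epoch(cb[cb$index == 22, ], 0.5, test_model(snr_db = Inf),
                       sp, seed = 1)
  expect_equal(filterbank_classify(ep, cb)$predicted_frequency, 12.4)
  # low-SNR paired comparison pooled over fixed-seed sessions: harvesting
  # harmonic sub-bands should not hurt, and typically helps
  m <- test_model(snr_db = -10)
  hits_cca <- hits_fb <- 0L
  for (seed in c(17, 18, 19)) {
    es <- simulate_session(cb, 1, 1, m, sp, seed = seed)
    truth <- vapply(es$epochs, function(e) e$label, integer(1))
    pred_cca <- vapply(es$epochs, function(e)
      classify(e, cb)$predicted_index, integer(1))
    pred_fb <- vapply(es$epochs, function(e)
      filterbank_classify(e, cb)$predicted_index, integer(1))
    hits_cca <- hits_cca + sum(pred_cca == truth)
    hits_fb <- hits_fb + sum(pred_fb == truth)
  }
  expect_gte(hits_fb, hits_cca)
})

test_that("averaged templates support template-extended scoring", {
  cb <- build_codebook(4, 9, 1.5, 0, pi / 2)
  sp <- test_spec()
  es <- simulate_session(cb, 3, 1, test_model(snr_db = Inf), sp, seed = 2)
  tmpl <- build_templates(es)
  expect_setequal(names(tmpl), as.character(cb$index))
  # noiseless trials average to themselves: template equals trial data
  lab0 <- es$epochs[[1]]$label
  expect_equal(tmpl[[as.character(lab0)]], es$epochs[[1]]$data,
               tolerance = 1e-12)
  # leave-one-out exclusion changes nothing in the noiseless case
  tmpl_loo <- build_templates(es, exclude = 1)
  expect_equal(tmpl_loo[[as.character(lab0)]], tmpl[[as.character(lab0)]],
               tolerance = 1e-12)
})
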