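test_that("bits per selection matches the closed form and its anchors", {
  expect_equal(bits_per_selection(40, 1.0), log2(40), tolerance = 1e-12)
  for (N in c(2, 5, 40, 100))
    expect_equal(bits_per_selection(N, 1 / N), 0, tolerance = 1e-12)
  expect_equal(bits_per_selection(40, 0.9), oracle_bits(40, 0.9),
               tolerance = 1e-12)
  expect_equal(bits_per_selection(40, 0.9), 4.3244, tolerance = 1e-4)
  expect_error(bits_per_selection(40, 1.2), class = "invalid_input")
  expect_error(bits_per_selection(1, 0.5), class = "invalid_input")
})

test_that("bits per selection is monotone in accuracy above chance", {
  for (N in c(4, 40)) {
    p <- seq(1 / N + 1e-6, 1, length.out = 50)
    B <- bits_per_selection(N, p)
    expect_true(all(diff(B) > 0))
    expect_true(all(B <= log2(N) + 1e-12))
  }
})

test_that("ITR follows B * 60 / T", {
  expect_equal(itr(40, 1.0, 60), log2(40), tolerance = 1e-12)
  expect_equal(itr(40, 1.0, 1.0), log2(40) * 60, tolerance = 1e-12)
  expect_equal(itr(40, 0.9, 1.1), oracle_bits(40, 0.9) * 60 / 1.1,
               tolerance = 1e-12)
  expect_equal(itr(40, 0.9, 1.1), 235.9, tolerance = 1e-1)
  expect_error(itr(40, 0.9, 0), class = "invalid_input")
})

test_that("noiseless LOO evaluation is perfect at every data length", {
  cb <- build_codebook(4, 9, 1.5, 0, pi / 2)
  sp <- test_spec()
  es <- simulate_session(cb, 3, 2, test_model(snr_db = Inf), sp, seed = 5)
  cfg <- eval_config(data_lengths = c(0.5, 1, 2))
  rep_ <- loo_cv(es, decoder_config("cca"), cfg)
  expect_equal(rep_$summary$accuracy, rep(1, 3))
  expect_equal(rep_$summary$bits, rep(log2(4), 3), tolerance = 1e-12)
  expect_equal(rep_$summary$itr, log2(4) * 60 / (c(0.5, 1, 2) + 0.5),
               tolerance = 1e-12)
  for (cm in rep_$confusion) {
    expect_equal(sum(diag(cm)), 12)
    expect_equal(sum(cm), 12)
  }
  expect_true(all(rep_$summary$reaches_threshold))
  # determinism: identical reports on repeated runs
  rep2 <- loo_cv(es, decoder_config("cca"), cfg)
  expect_identical(rep_$summary, rep2$summary)
})

test_that("template-extended LOO works and guards its trial-count precondition", {
  cb <- build_codebook(3, 9, 2, 0, pi)
  sp <- test_spec()
  es <- simulate_session(cb, 3, 1, test_model(snr_db = Inf), sp, seed = 8)
  rep_ <- loo_cv(es, decoder_config("ecca"),
                 eval_config(data_lengths = c(0.5, 1)))
  expect_equal(rep_$summary$accuracy, c(1, 1))
  es1 <- simulate_session(cb, 1, 1, test_model(snr_db = Inf), sp, seed = 8)
  expect_error(loo_cv(es1, decoder_config("ecca"),
                      eval_config(data_lengths = 0.5)),
               class = "invalid_input")
})

test_that("evaluation metrics are invariant to target relabeling", {
  cb <- build_codebook(4, 9, 1.5, 0, pi / 2)
  sp <- test_spec()
  es <- simulate_session(cb, 2, 1, test_model(snr_db = -8), sp, seed = 13)
  cfg <- eval_config(data_lengths = c(0.5, 1))
  r1 <- loo_cv(es, decoder_config("cca"), cfg)
  # permute target identities consistently in codebook and labels
  perm <- c(2L, 3L, 0L, 1L)
  cb2 <- cb
  cb2$index <- perm[cb$index + 1]
  o <- order(cb2$index)
  cb2 <- structure(cb2[o, ],
                   f0 = attr(cb, "f0"), delta_f = attr(cb, "delta_f"),
                   phi0 = attr(cb, "phi0"), delta_phi = attr(cb, "delta_phi"),
                   grid_shape = attr(cb, "grid_shape"),
                   class = class(cb))
  es2 <- es
  es2$codebook <- cb2
  es2$epochs <- lapply(es$epochs, function(e) {
    e$label <- perm[e$label + 1]
    e
  })
  r2 <- loo_cv(es2, decoder_config("cca"), cfg)
  expect_equal(r2$summary$accuracy, r1$summary$accuracy)
  expect_equal(r2$summary$bits, r1$summary$bits)
  expect_equal(r2$summary$itr, r1$summary$itr)
})

test_that("accuracy curves aggregate reports and locate the ITR optimum", {
  cb <- build_codebook(4, 9, 1.5, 0, pi / 2)
  sp <- test_spec()
  cfg <- eval_config(data_lengths = c(0.5, 1, 2))
  reports <- lapply(c(21, 22), function(s) {
    es <- simulate_session(cb, 2, 2, test_model(snr_db = Inf), sp, seed = s)
    loo_cv(es, decoder_config("cca"), cfg)
  })
  tab <- accuracy_curve(reports)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$accuracy_mean, rep(1, 3))
  # perfect accuracy everywhere: ITR is maximal at the shortest window
  expect_equal(attr(tab, "best_length"), 0.5)
  expect_true(all(c("accuracy_sd", "itr_sd") %in% names(tab)))
  # single report works too
  tab1 <- accuracy_curve(reports[[1]])
  expect_equal(nrow(tab1), 3)
  # mismatched grids are refused
  es <- simulate_session(cb, 2, 2, test_model(snr_db = Inf), sp, seed = 1)
  other <- loo_cv(es, decoder_config("cca"),
                  eval_config(data_lengths = c(1, 2)))
  expect_error(accuracy_curve(list(reports[[1]], other)),
               class = "invalid_input")
})

test_that("default decoder recovers targets at moderate SNR (regression floor)", {
  cb <- build_codebook()
  sp <- test_spec(8)
  accs <- vapply(1:10, function(seed) {
    es <- simulate_session(cb, 1, 2, test_model(snr_db = 0, n_channels = 8),
                           sp, seed = seed)
    r <- loo_cv(es, decoder_config("cca"), eval_config(data_lengths = 2))
    r$summary$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.9)
})
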