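# Simulated-online evaluation: leave-one-out cross-validation over data
# lengths, classification accuracy, bits per selection and the Wolpaw
# information transfer rate.

#' Bits per selection (Wolpaw formula)
#'
#' Information carried by one selection among `N` equiprobable targets at
#' recognition accuracy `p`:
#' `B = log2 N + p log2 p + (1 - p) log2((1 - p) / (N - 1))`,
#' with the convention `0 * log2(0) = 0`, so `B(N, 1) = log2 N` and
#' `B(N, 1/N) = 0`.
#'
#' @param n_targets Number of targets N (>= 2).
#' @param accuracy Recognition accuracy p in `[0, 1]`; vectorized.
#' @return Bits per selection.
#' @export
#' @examples
#' bits_per_selection(40, 1.0)   # log2(40) ~ 5.32
#' bits_per_selection(40, 0.9)   # ~ 4.32
bits_per_selection <- function(n_targets, accuracy) {
  if (n_targets < 2 || n_targets != round(n_targets))
    .err("invalid_input", "n_targets must be an integer >= 2")
  if (any(accuracy < 0 | accuracy > 1))
    .err("invalid_input", "accuracy must lie in [0, 1]")
  p <- accuracy
  term_p <- ifelse(p > 0, p * log2(p), 0)
  term_q <- ifelse(p < 1, (1 - p) * log2((1 - p) / (n_targets - 1)), 0)
  log2(n_targets) + term_p + term_q
}

#' Information transfer rate in bits per minute
#'
#' `ITR = B * 60 / T`, where `B` is [bits_per_selection()] and `T` the time
#' in seconds one selection takes (stimulation window plus any gaze-shift
#' interval).
#'
#' @inheritParams bits_per_selection
#' @param selection_time T in seconds (> 0); vectorized.
#' @return Bits per minute.
#' @export
#' @examples
#' itr(40, 0.9, 1.1)  # ~ 235.9 bits/min
itr <- function(n_targets, accuracy, selection_time) {
  if (any(selection_time <= 0))
    .err("invalid_input", "selection_time must be > 0")
  bits_per_selection(n_targets, accuracy) * 60 / selection_time
}

#' Evaluation configuration
#'
#' @param data_lengths Ascending positive stimulation windows in seconds;
#'   the default sweeps 0.5-4 s in 0.5-s steps.
#' @param gaze_shift_s Gaze-shift interval added to the data length when
#'   computing selection time T for the ITR. ITR scales with `1/T`, so this
#'   constant matters: 0.5 s is the convention in the SSVEP-speller
#'   literature.
#' @param accuracy_threshold Accuracy level used to flag which data lengths
#'   reach "usable" performance.
#' @param cv `"loo"` (leave-one-out) or `"k-fold"`.
#' @param k Folds when `cv = "k-fold"`.
#' @return Object of class `ssvep_evalconfig`.
#' @export
eval_config <- function(data_lengths = seq(0.5, 4, by = 0.5),
                        gaze_shift_s = 0.5, accuracy_threshold = 0.9,
                        cv = c("loo", "k-fold"), k = 5) {
  cv <- match.arg(cv)
  if (any(data_lengths <= 0) || is.unsorted(data_lengths, strictly = TRUE))
    .err("invalid_input", "data_lengths must be positive and ascending")
  if (accuracy_threshold <= 0 || accuracy_threshold >= 1)
    .err("invalid_input", "accuracy_threshold must lie in (0, 1)")
  structure(list(data_lengths = as.numeric(data_lengths),
                 gaze_shift_s = gaze_shift_s,
                 accuracy_threshold = accuracy_threshold,
                 cv = cv, k = as.integer(k)),
            class = "ssvep_evalconfig")
}

#' Decoder configuration for evaluation
#'
#' @param method `"cca"` (harmonic-reference CCA, no training), `"fbcca"`
#'   (filter-bank CCA, no training) or `"ecca"` (template-extended CCA:
#'   combines squared reference and squared averaged-template correlations
#'   with equal weight; needs >= 2 trials per label for cross-validation).
#' @param n_harmonics Harmonics per reference.
#' @param filterbank An [filterbank_spec()], used when `method = "fbcca"`.
#' @return Object of class `ssvep_decoder`.
#' @export
decoder_config <- function(method = c("cca", "fbcca", "ecca"),
                           n_harmonics = 5, filterbank = filterbank_spec()) {
  method <- match.arg(method)
  structure(list(method = method, n_harmonics = as.integer(n_harmonics),
                 filterbank = filterbank),
            class = "ssvep_decoder")
}

# Score every epoch of `mats` (list of channels x samples matrices, already
# truncated) against references; returns predicted 0-based labels.
.predict_set <- function(mats, codebook, decoder, sampling_rate,
                         fold_of = NULL, epochset = NULL, length_samples) {
  refs <- .make_refs(codebook$frequency, decoder$n_harmonics, sampling_rate,
                     length_samples)
  n <- length(mats)
  pred <- integer(n)
  if (decoder$method == "ecca") {
    folds <- unique(fold_of)
    tmpl <- lapply(folds, function(fd)
      build_templates(epochset, exclude = which(fold_of == fd)))
    names(tmpl) <- as.character(folds)
    for (i in seq_len(n)) {
      tm <- tmpl[[as.character(fold_of[i])]]
      scores <- .ecca_scores(mats[[i]], refs, tm, codebook)
      pred[i] <- codebook$index[which.max(scores)]
    }
  } else {
    for (i in seq_len(n)) {
      scores <- switch(decoder$method,
        cca = .rho_scores(mats[[i]], refs),
        fbcca = .fb_scores(mats[[i]], refs, decoder$filterbank,
                           sampling_rate))
      pred[i] <- codebook$index[which.max(scores)]
    }
  }
  pred
}

#' Simulated-online evaluation by cross-validation
#'
#' For each data length `L`, every epoch is truncated to its first
#' `round(L * F)` samples (a causal window, emulating online operation) and
#' decoded; template-based decoding builds its per-target averaged
#' templates only from the other trials (leave-one-out) or from the other
#' folds (k-fold). Plain CCA and FBCCA need no training, so cross-validation
#' degenerates to per-trial scoring for them. The report carries accuracy,
#' bits per selection and ITR per data length, plus the confusion matrix.
#' Deterministic given the epoch set.
#'
#' @param epochset An `ssvep_epochset`.
#' @param decoder A [decoder_config()].
#' @param config An [eval_config()].
#' @return Object of class `ssvep_evalreport`: list with `summary` (data
#'   frame: data_length, selection_time, n_trials, accuracy, bits, itr,
#'   reaches_threshold), `confusion` (list of M x M matrices keyed by data
#'   length, true label in rows), `config`, `decoder`, `n_targets`.
#' @export
loo_cv <- function(epochset, decoder = decoder_config(),
                   config = eval_config()) {
  stopifnot(inherits(epochset, "ssvep_epochset"))
  eps <- epochset$epochs
  if (length(eps) < 2) .err("invalid_input", "need at least 2 epochs")
  cb <- epochset$codebook
  F <- epochset$spec$sampling_rate
  truth <- vapply(eps, function(e) e$label, integer(1))
  if (decoder$method == "ecca") {
    cnt <- table(truth)
    short <- names(cnt)[cnt < 2]
    if (length(short))
      .err("invalid_input",
           "template decoding needs >= 2 trials per label; label(s) %s have fewer",
           paste(short, collapse = ", "))
  }
  fold_of <- if (config$cv == "loo") seq_along(eps)
             else rep_len(seq_len(config$k), length(eps))
  M <- nrow(cb)
  rows <- vector("list", length(config$data_lengths))
  confusion <- list()
  for (j in seq_along(config$data_lengths)) {
    L <- config$data_lengths[j]
    P <- round(L * F)
    if (P > ncol(eps[[1]]$data))
      .err("invalid_input", "data length %g s exceeds epoch duration", L)
    mats <- lapply(eps, function(e) e$data[, seq_len(P), drop = FALSE])
    es_trunc <- epochset
    es_trunc$epochs <- lapply(seq_along(eps), function(i) {
      e <- eps[[i]]; e$data <- mats[[i]]; e
    })
    pred <- .predict_set(mats, cb, decoder, F, fold_of, es_trunc, P)
    acc <- mean(pred == truth)
    Tsel <- L + config$gaze_shift_s
    rows[[j]] <- data.frame(
      data_length = L, selection_time = Tsel, n_trials = length(eps),
      accuracy = acc,
      bits = bits_per_selection(M, acc),
      itr = itr(M, acc, Tsel),
      reaches_threshold = acc >= config$accuracy_threshold)
    cm <- matrix(0L, M, M, dimnames = list(true = cb$index,
                                           predicted = cb$index))
    for (i in seq_along(pred))
      cm[as.character(truth[i]), as.character(pred[i])] <-
        cm[as.character(truth[i]), as.character(pred[i])] + 1L
    confusion[[format(L)]] <- cm
  }
  structure(list(summary = do.call(rbind, rows), confusion = confusion,
                 config = config, decoder = decoder, n_targets = M),
            class = "ssvep_evalreport")
}

#' @export
print.ssvep_evalreport <- function(x, ...) {
  cat(sprintf("Simulated-online evaluation (%s, %s): %d targets\n",
              x$decoder$method, x$config$cv, x$n_targets))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Aggregate evaluation reports into an accuracy/ITR curve
#'
#' Combines one or more reports (e.g. across simulated subjects or seeds)
#' sharing a data-length grid into a tidy table with mean and sd of
#' accuracy and ITR per length, and identifies the ITR-optimal data length
#' — the short-window optimum that trades accuracy against selection time.
#'
#' @param reports One `ssvep_evalreport` or a (optionally named) list of
#'   them.
#' @return Data frame with columns condition, data_length, accuracy_mean,
#'   accuracy_sd, itr_mean, itr_sd, and attribute `best_length` (the data
#'   length maximizing mean ITR across conditions).
#' @export
accuracy_curve <- function(reports) {
  if (inherits(reports, "ssvep_evalreport")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  grids <- lapply(reports, function(r) r$summary$data_length)
  if (!all(vapply(grids, identical, logical(1), grids[[1]])))
    .err("invalid_input", "reports do not share a data-length grid")
  if (is.null(names(reports)))
    names(reports) <- paste0("condition", seq_along(reports))
  acc <- sapply(reports, function(r) r$summary$accuracy)
  it <- sapply(reports, function(r) r$summary$itr)
  acc <- matrix(acc, ncol = length(reports))
  it <- matrix(it, ncol = length(reports))
  sd0 <- function(m) if (ncol(m) > 1) apply(m, 1, stats::sd) else rep(NA_real_, nrow(m))
  out <- data.frame(
    data_length = grids[[1]],
    accuracy_mean = rowMeans(acc), accuracy_sd = sd0(acc),
    itr_mean = rowMeans(it), itr_sd = sd0(it))
  long <- do.call(rbind, lapply(names(reports), function(nm) {
    s <- reports[[nm]]$summary
    data.frame(condition = nm, data_length = s$data_length,
               accuracy = s$accuracy, itr = s$itr)
  }))
  attr(out, "per_condition") <- long
  attr(out, "best_length") <- out$data_length[which.max(out$itr_mean)]
  out
}
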