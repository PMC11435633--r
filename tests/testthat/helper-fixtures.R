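# Shared fixture builders and independent oracles. Everything is generated
# in code under fixed seeds; nothing is read from disk.

# short protocol: 2 songs per valence, 6-s songs, 3-s silences, 250 Hz
tiny_protocol <- function(n_participants = 2L) {
  protocol_config(n_songs_per_valence = 2L, song_duration_s = 6,
                  silence_duration_s = 3, fs = 250,
                  n_participants = n_participants)
}

# random labelled window set (no signal structure; for plumbing tests)
random_window_set <- function(n = 30L, labels = NULL, participants = NULL,
                              split = NULL, seed = 1L, size = 125L) {
  set.seed(seed)
  labels <- labels %||% sample(c("negative", "neutral", "positive"), n, TRUE)
  participants <- participants %||% rep(0L, n)
  ws <- dfcgn:::new_window_set(array(rnorm(n * 3 * size), c(n, 3, size)),
                               labels, participants, split = split)
  ws
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-band sinusoid window set: the GAN toy class
sine_window_set <- function(n = 200L, band = c(8, 13), fs = 500,
                            size = 125L, amp = 10, noise = 1, seed = 3L) {
  set.seed(seed)
  W <- array(0, c(n, 3, size))
  t <- (seq_len(size) - 1) / fs
  for (i in seq_len(n)) for (ch in 1:3) {
    f <- runif(3, band[1], band[2])
    ph <- runif(3, 0, 2 * pi)
    x <- rowSums(sapply(1:3, function(k) sin(2 * pi * f[k] * t + ph[k])))
    W[i, ch, ] <- amp * x / sqrt(3) + rnorm(size, 0, noise)
  }
  dfcgn:::new_window_set(W, rep("positive", n), rep(0L, n),
                         split = rep("train", n))
}

# the separable 2-participant cohort used for end-to-end recovery checks:
# 100 windows per participant per class (200 per class), split 70/20/10
separable_cohort_windows <- function(seed = 5L) {
  cfg <- run_config(protocol = protocol_config(n_participants = 2L),
                    spectra = separable_spectrum_spec(seed = 11L),
                    use_gan = FALSE, seed = seed)
  ws <- preprocess_cohort(cfg)
  keep <- unlist(lapply(split(seq_along(ws$labels),
                              interaction(ws$participant_ids, ws$labels)),
                        function(ix) ix[1:100]))
  ws <- subset_windows(ws, sort(keep))
  make_splits(ws, seed = seed)
}

# heavyweight shared fixture: trained classifier on the separable cohort
# (computed once per test run, reused by the acceptance checks)
.fixture_env <- new.env(parent = emptyenv())
trained_separable_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    ws <- separable_cohort_windows(seed = 5L)
    g <- build_channel_graph(dfcgn:::pooled_signal(
      subset_windows(ws, ws$split == "train")), tau = 0.3)
    model <- build_model(model_config(), g, seed = 5L)
    fit <- train_dfcgn(model, ws, train_config(epochs = 30L, seed = 5L))
    .fixture_env$ws <- ws
    .fixture_env$fit <- fit
  }
  list(ws = .fixture_env$ws, fit = .fixture_env$fit)
}

# independent naive metric computation from a confusion matrix (loop form)
naive_metrics <- function(cm) {
  n <- sum(cm)
  k <- nrow(cm)
  acc <- sum(diag(cm)) / n
  sens <- prec <- spec <- numeric(0)
  for (i in seq_len(k)) {
    TP <- cm[i, i]; FN <- sum(cm[i, ]) - TP
    FP <- sum(cm[, i]) - TP; TN <- n - TP - FN - FP
    if (TP + FN > 0) {
      sens <- c(sens, TP / (TP + FN))
      prec <- c(prec, if (TP + FP > 0) TP / (TP + FP) else 0)
      spec <- c(spec, TN / (TN + FP))
    }
  }
  pe <- 0
  for (i in seq_len(k)) pe <- pe + (sum(cm[i, ]) / n) * (sum(cm[, i]) / n)
  list(accuracy = acc, sensitivity = mean(sens), precision = mean(prec),
       specificity = mean(spec), kappa = (acc - pe) / (1 - pe))
}

# brute-force sliding-window slicer used as the windowing oracle
naive_windows <- function(sig, size, stride) {
  n <- ncol(sig)
  out <- list()
  s <- 1L
  while (s + size - 1L <= n) {
    out[[length(out) + 1L]] <- sig[, s:(s + size - 1L), drop = FALSE]
    s <- s + stride
  }
  out
}
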