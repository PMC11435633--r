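# small separable window set for quick learning checks: two classes in
# disjoint frequency bands (alpha vs gamma), learnable in a few epochs
quick_windows <- function(n_per = 60L, seed = 70L) {
  set.seed(seed)
  n <- 2L * n_per
  t <- (0:124) / 500
  W <- array(0, c(n, 3, 125))
  bands <- list(negative = c(8, 13), positive = c(30, 45))
  amps <- c(negative = 10, positive = 25)   # amplitude cue for the
  labels <- rep(c("negative", "positive"), each = n_per)  # handcrafted stats
  for (i in seq_len(n)) for (ch in 1:3) {
    b <- bands[[labels[i]]]
    f <- runif(3, b[1], b[2]); ph <- runif(3, 0, 2 * pi)
    x <- rowSums(sapply(1:3, function(k) sin(2 * pi * f[k] * t + ph[k])))
    W[i, ch, ] <- amps[[labels[i]]] * x / sqrt(3) + rnorm(125)
  }
  ws <- dfcgn:::new_window_set(W, labels, rep_len(0:1, n))
  make_splits(ws, seed = seed)
}

quick_graph <- function(ws) {
  suppressWarnings(build_channel_graph(dfcgn:::pooled_signal(ws), tau = 0))
}

test_that("training reduces loss and a zero learning rate freezes the model", {
  ws <- quick_windows()
  g <- quick_graph(ws)
  mc <- model_config(n_classes = 2)
  fit <- train_dfcgn(build_model(mc, g, seed = 1), ws,
                     train_config(epochs = 5, seed = 1))
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  frozen <- train_dfcgn(build_model(mc, g, seed = 1), ws,
                        train_config(epochs = 3, learning_rate = 0, seed = 1))
  expect_lt(diff(range(frozen$history$val_loss)), 1e-10)
  # seeded reproducibility of the whole loss curve
  fit2 <- train_dfcgn(build_model(mc, g, seed = 1), ws,
                      train_config(epochs = 5, seed = 1))
  expect_identical(fit$history, fit2$history)
})

test_that("training guards against GAN leakage and empty splits", {
  ws <- quick_windows()
  g <- quick_graph(ws)
  m <- build_model(model_config(n_classes = 2), g, seed = 1)
  bad <- ws
  bad$provenance[which(bad$split == "test")[1]] <- "gan"
  expect_error(train_dfcgn(m, bad, train_config(epochs = 1)), "leakage")
  none <- ws
  none$split <- factor(rep("unassigned", length(none$split)),
                       levels = levels(none$split))
  expect_error(train_dfcgn(m, none, train_config(epochs = 1)), "train split")
})

test_that("k-fold assignment balances folds and never touches the test split", {
  ws <- quick_windows(n_per = 50)
  g <- quick_graph(ws)
  res <- kfold_cv(ws, k = 5, model_config(n_gconv_layers = 2,
                                          cheb_orders = c(3, 3),
                                          n_classes = 2),
                  train_config(epochs = 2, seed = 1), graph = g, seed = 1)
  expect_length(res$accuracies, 5L)
  sizes <- vapply(res$reports, function(r) sum(r$confusion), numeric(1))
  expect_lte(diff(range(sizes)), 2)   # 90 pooled windows over 5 folds
  expect_equal(sum(sizes), sum(ws$split %in% c("train", "val")))
  expect_error(kfold_cv(ws, k = 1), "k must be")
  expect_error(kfold_cv(ws, k = 1000), "rarest")
})

test_that("leave-one-subject-out returns one accuracy per participant", {
  ws <- quick_windows(n_per = 60)
  res <- loo_eval(ws, model_config(n_classes = 2),
                  train_config(epochs = 15, seed = 2), seed = 2)
  expect_length(res$accuracies, 2L)
  expect_equal(res$mean_accuracy, mean(res$accuracies))
  expect_gt(res$mean_accuracy, 0.9)   # band-separable classes
  one <- subset_windows(ws, ws$participant_ids == 0)
  expect_error(loo_eval(one), ">= 2 participants")
})

test_that("additive noise hits the requested SNR and is seeded", {
  ws <- random_window_set(n = 1000, seed = 71)
  noisy <- add_noise_snr(ws, 0, seed = 5)
  p_noise <- mean((noisy$windows - ws$windows)^2)
  p_sig <- mean(ws$windows^2)
  expect_lt(abs(p_noise / p_sig - 1), 0.05)
  # high SNR barely changes the norm
  n60 <- add_noise_snr(ws, 60, seed = 5)
  expect_lt(abs(sqrt(sum(n60$windows^2)) / sqrt(sum(ws$windows^2)) - 1), 0.01)
  expect_identical(add_noise_snr(ws, 0, seed = 5)$windows, noisy$windows)
  zero <- random_window_set(n = 2, seed = 72)
  zero$windows[1, , ] <- 0
  expect_warning(add_noise_snr(zero, 0), "zero-power")
})

test_that("handcrafted features match closed forms and naive loops", {
  const <- matrix(3, 3, 125)
  expect_warning(f <- handcrafted_features(const), "zero-variance")
  expect_equal(unname(f[c("ch1_mean", "ch1_variance", "ch1_skewness",
                          "ch1_kurtosis", "ch1_power")]),
               c(3, 0, 0, 0, 9))
  # full-period sine: crest factor sqrt(2)
  t <- seq_len(1000)
  sine <- matrix(rep(sin(2 * pi * 5 * t / 1000), 3), 3, byrow = TRUE)
  fs <- handcrafted_features(sine)
  expect_equal(unname(fs["ch1_crest"]), sqrt(2), tolerance = 1e-6)
  # naive loop oracle on a random window
  set.seed(73)
  w <- matrix(rnorm(3 * 125), 3)
  f <- handcrafted_features(w)
  x <- w[2, ]
  mu <- sum(x) / 125
  m2 <- sum((x - mu)^2) / 125
  expect_equal(unname(f["ch2_mean"]), mu, tolerance = 1e-12)
  expect_equal(unname(f["ch2_variance"]), m2, tolerance = 1e-12)
  expect_equal(unname(f["ch2_skewness"]), (sum((x - mu)^3) / 125) / m2^1.5,
               tolerance = 1e-12)
  expect_equal(unname(f["ch2_kurtosis"]), (sum((x - mu)^4) / 125) / m2^2,
               tolerance = 1e-12)
  expect_equal(unname(f["ch2_crest"]), max(abs(x)) / sqrt(sum(x^2) / 125),
               tolerance = 1e-12)
  expect_equal(unname(f["ch2_power"]), sum(x^2) / 125, tolerance = 1e-12)
})

test_that("shallow baselines learn the band-separable toy problem", {
  ws <- quick_windows(n_per = 60, seed = 74)
  for (method in c("knn", "svm", "mlp")) {
    r <- baseline_fit(ws, method, "handcrafted", seed = 1)
    expect_gt(r$accuracy, 0.8)
  }
  r_cnn <- baseline_fit(ws, "cnn", "raw", seed = 1, epochs = 40)
  expect_gt(r_cnn$accuracy, 0.8)
})
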