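# Evaluation protocols: stratified k-fold cross-validation,
# leave-one-subject-out, additive-noise robustness sweeps, and the
# handcrafted-feature / shallow-classifier baselines.

#' Stratified k-fold cross-validation over train+val windows
#'
#' Folds are drawn within each class over the pooled train and validation
#' windows; the test split is never touched. Each fold trains a fresh model
#' on the remaining folds and evaluates on the held fold.
#'
#' @param ws a `window_set` with splits assigned.
#' @param k folds (default 5).
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param graph optional fixed `channel_graph`; `NULL` rebuilds one per fold
#'   from that fold's training windows.
#' @param tau correlation threshold when rebuilding the graph.
#' @param seed RNG seed for the fold assignment.
#' @return list with `reports` (per-fold `metrics_report`), `accuracies`,
#'   `mean_accuracy`, `sd_accuracy`.
#' @export
kfold_cv <- function(ws, k = 5L, mcfg = model_config(),
                     tcfg = train_config(), graph = NULL, tau = 0.3,
                     seed = 1L) {
  if (k < 2L) stop_config("k must be >= 2")
  pool <- which(as.character(ws$split) %in% c("train", "val"))
  labs <- as.character(ws$labels)[pool]
  if (k > min(table(labs))) stop_config("k exceeds windows of the rarest class")
  fold <- integer(length(pool))
  set.seed(derive_seed(seed, 11L))
  for (cl in unique(labs)) {
    idx <- which(labs == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- pool[fold != f]
    te_idx <- pool[fold == f]
    wtr <- subset_windows(ws, tr_idx)
    wtr$split <- factor(rep("train", length(tr_idx)),
                        levels = levels(ws$split))
    g <- graph %||% build_channel_graph(pooled_signal(wtr), tau = tau)
    model <- build_model(mcfg, g, seed = derive_seed(seed, 13L, f))
    fit <- train_dfcgn(model, wtr, tcfg)
    scores <- predict(fit, subset_windows(ws, te_idx))
    reports[[f]] <- compute_metrics(ws$labels[te_idx], scores,
                                    levels = class_levels_for(mcfg$n_classes),
                                    roc = FALSE)
  }
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  list(reports = reports, accuracies = acc,
       mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc))
}

# concatenate a window set back into one channels x samples matrix
pooled_signal <- function(ws) {
  d <- dim(ws$windows)
  out <- matrix(0, d[2], d[1] * d[3])
  for (i in seq_len(d[1]))
    out[, ((i - 1) * d[3] + 1):(i * d[3])] <- array(ws$windows[i, , ], d[2:3])
  out
}

#' Leave-one-subject-out evaluation
#'
#' For every participant, trains a fresh model on all other participants'
#' windows (connectivity graph rebuilt from those windows only) and
#' evaluates on the held-out participant.
#'
#' @param ws a `window_set` covering >= 2 participants.
#' @param mcfg,tcfg model / training configuration.
#' @param tau correlation threshold for the per-fold graph.
#' @param seed RNG seed.
#' @return list with per-participant `accuracies` and `mean_accuracy`.
#' @export
loo_eval <- function(ws, mcfg = model_config(), tcfg = train_config(),
                     tau = 0.3, seed = 1L) {
  parts <- sort(unique(ws$participant_ids))
  if (length(parts) < 2L) stop_config("leave-one-out needs >= 2 participants")
  acc <- numeric(length(parts))
  names(acc) <- paste0("participant_", parts)
  for (j in seq_along(parts)) {
    p <- parts[j]
    tr_idx <- which(ws$participant_ids != p)
    te_idx <- which(ws$participant_ids == p)
    wtr <- subset_windows(ws, tr_idx)
    wtr$split <- factor(rep("train", length(tr_idx)), levels = levels(ws$split))
    g <- build_channel_graph(pooled_signal(wtr), tau = tau)
    model <- build_model(mcfg, g, seed = derive_seed(seed, 17L, j))
    fit <- train_dfcgn(model, wtr, tcfg)
    scores <- predict(fit, subset_windows(ws, te_idx))
    y <- label_indices(ws$labels[te_idx], mcfg$n_classes)
    acc[j] <- mean(max.col(scores) == y)
  }
  list(accuracies = acc, mean_accuracy = mean(acc))
}

#' Add white Gaussian noise at a target SNR
#'
#' Noise is scaled per window so `10 log10(P_signal / P_noise) = snr_db`.
#' Zero-power windows are left untouched with a warning.
#'
#' @param ws a `window_set`.
#' @param snr_db target signal-to-noise ratio in dB (finite).
#' @param seed RNG seed.
#' @return the `window_set` with noisy windows.
#' @export
add_noise_snr <- function(ws, snr_db, seed = 1L) {
  stopifnot(is.finite(snr_db))
  W <- ws$windows
  d <- dim(W)
  set.seed(derive_seed(seed, 23L))
  skipped <- 0L
  for (i in seq_len(d[1])) {
    w <- W[i, , ]
    P <- mean(w^2)
    if (P == 0) { skipped <- skipped + 1L; next }
    sigma <- sqrt(P / 10^(snr_db / 10))
    W[i, , ] <- w + stats::rnorm(length(w), 0, sigma)
  }
  if (skipped > 0) warning(sprintf("%d zero-power window(s) skipped", skipped))
  ws$windows <- W
  ws
}

#' Accuracy as a function of SNR
#'
#' Evaluates a trained model on noisy copies of the given windows across an
#' SNR grid (infinite SNR = clean). Accuracy at each SNR is averaged over
#' `reps` independent noise draws to damp Monte-Carlo error.
#'
#' @param fit a `dfcgn_fit` (or `dfcgn_model`).
#' @param ws evaluation windows (typically the test split).
#' @param snr_list SNR grid in dB (default 20, 10, 5, 0, -5, -10).
#' @param reps noise draws per SNR (default 3).
#' @param seed RNG seed.
#' @return data.frame with `snr_db` and `accuracy`.
#' @export
noise_robustness <- function(fit, ws, snr_list = c(20, 10, 5, 0, -5, -10),
                             reps = 3L, seed = 1L) {
  model <- if (inherits(fit, "dfcgn_fit")) fit$model else fit
  y <- label_indices(ws$labels, model$config$n_classes)
  acc <- vapply(seq_along(snr_list), function(i) {
    s <- snr_list[i]
    if (!is.finite(s)) {
      scores <- dfcgn_forward(model, ws$windows)
      return(mean(max.col(scores) == y))
    }
    mean(vapply(seq_len(reps), function(r) {
      noisy <- add_noise_snr(ws, s, seed = derive_seed(seed, 29L, i, r))
      scores <- dfcgn_forward(model, noisy$windows)
      mean(max.col(scores) == y)
    }, numeric(1)))
  }, numeric(1))
  data.frame(snr_db = snr_list, accuracy = acc)
}

#' Handcrafted statistical features of one window
#'
#' Per channel: mean, variance, skewness (`m3 / sigma^3`), kurtosis
#' (`m4 / sigma^4`, non-excess), crest factor (`max|x| / RMS`) and mean
#' power (`mean x^2`). A zero-variance channel gets skewness and kurtosis 0
#' with a warning.
#'
#' @param window channels x samples matrix.
#' @return named numeric vector, 6 statistics per channel.
#' @export
handcrafted_features <- function(window) {
  stats_one <- function(x) {
    mu <- mean(x)
    m2 <- mean((x - mu)^2)
    if (m2 == 0) {
      warning("zero-variance channel: skewness/kurtosis set to 0")
      sk <- 0; ku <- 0
    } else {
      sk <- mean((x - mu)^3) / m2^1.5
      ku <- mean((x - mu)^4) / m2^2
    }
    rms <- sqrt(mean(x^2))
    crest <- if (rms > 0) max(abs(x)) / rms else 0
    c(mean = mu, variance = m2, skewness = sk, kurtosis = ku,
      crest = crest, power = mean(x^2))
  }
  chn <- rownames(window) %||% paste0("ch", seq_len(nrow(window)))
  out <- lapply(seq_len(nrow(window)), function(i) {
    v <- stats_one(window[i, ])
    names(v) <- paste(chn[i], names(v), sep = "_")
    v
  })
  unlist(out)
}

# feature matrix for a whole window set
feature_matrix <- function(ws) {
  d <- dim(ws$windows)
  t(vapply(seq_len(d[1]),
           function(i) handcrafted_features(array(ws$windows[i, , ], d[2:3])),
           numeric(6 * d[2])))
}

#' Shallow / CNN baselines on handcrafted features or raw windows
#'
#' Trains a reference classifier on the train split and reports metrics on
#' the test split: `knn` (k = 5), `svm` (RBF), `mlp` (single hidden layer),
#' or `cnn` (a plain 1-D convolutional network without graph mixing).
#'
#' @param ws a `window_set` with splits assigned.
#' @param method one of `"knn"`, `"svm"`, `"mlp"`, `"cnn"`.
#' @param representation `"handcrafted"` (18-feature vectors) or `"raw"`.
#' @param seed RNG seed.
#' @param epochs CNN training epochs (default 30).
#' @return a `metrics_report` on the test split.
#' @export
baseline_fit <- function(ws, method = c("knn", "svm", "mlp", "cnn"),
                         representation = c("handcrafted", "raw"),
                         seed = 1L, epochs = 30L) {
  method <- match.arg(method)
  representation <- match.arg(representation)
  split <- as.character(ws$split)
  tr <- which(split == "train")
  te <- which(split == "test")
  stopifnot(length(tr) > 0, length(te) > 0)
  lv <- levels(droplevels(ws$labels))
  ytr <- droplevels(ws$labels[tr])
  yte <- droplevels(factor(ws$labels[te], levels = lv))

  if (method == "cnn") {
    return(baseline_cnn(ws, tr, te, lv, representation, seed, epochs))
  }
  if (representation == "handcrafted") {
    M <- feature_matrix(ws)
  } else {
    d <- dim(ws$windows)
    M <- matrix(ws$windows, d[1], d[2] * d[3])
  }
  mu <- colMeans(M[tr, , drop = FALSE])
  sg <- apply(M[tr, , drop = FALSE], 2, stats::sd)
  sg[sg == 0] <- 1
  M <- sweep(sweep(M, 2, mu), 2, sg, "/")
  Xtr <- M[tr, , drop = FALSE]; Xte <- M[te, , drop = FALSE]
  set.seed(derive_seed(seed, 31L))
  scores <- switch(method,
    knn = {
      pr <- class::knn(Xtr, Xte, ytr, k = 5, prob = FALSE)
      onehot_scores(pr, lv)
    },
    svm = {
      m <- e1071::svm(Xtr, ytr, probability = TRUE)
      p <- attr(predict(m, Xte, probability = TRUE), "probabilities")
      p[, lv, drop = FALSE]
    },
    mlp = {
      tgt <- nnet::class.ind(ytr)
      m <- nnet::nnet(Xtr, tgt, size = 12, decay = 1e-4, maxit = 300,
                      softmax = ncol(tgt) > 2, entropy = ncol(tgt) == 2,
                      MaxNWts = 20000, trace = FALSE)
      p <- predict(m, Xte)
      if (ncol(p) == 1) p <- cbind(1 - p, p)
      colnames(p) <- colnames(tgt)
      p[, lv, drop = FALSE]
    })
  compute_metrics(yte, scores, levels = lv, roc = FALSE)
}

onehot_scores <- function(pred, lv) {
  S <- matrix(0, length(pred), length(lv), dimnames = list(NULL, lv))
  S[cbind(seq_along(pred), match(as.character(pred), lv))] <- 1
  S
}

# plain 1-D CNN baseline: strided convolutions, no graph mixing
baseline_cnn <- function(ws, tr, te, lv, representation, seed, epochs) {
  if (representation == "handcrafted") {
    M <- feature_matrix(ws)
    X <- array(M, c(nrow(M), 1L, ncol(M)))
    chans <- c(8, 8)
  } else {
    X <- ws$windows
    chans <- c(8, 8, 16, 16)
  }
  sdev <- stats::sd(X[tr, , , drop = FALSE]); if (sdev == 0) sdev <- 1
  X <- X / sdev
  y <- match(as.character(ws$labels), lv)
  n_cls <- length(lv)
  d <- dim(X)
  k <- 5L
  set.seed(derive_seed(seed, 37L))
  params <- list()
  cin <- d[2]; L <- d[3]
  for (i in seq_along(chans)) {
    params[[sprintf("c%d_W", i)]] <- glorot(cin * k, chans[i], c(chans[i], cin * k))
    params[[sprintf("c%d_b", i)]] <- numeric(chans[i])
    cin <- chans[i]
    L <- (L + 2 * 2 - k) %/% 2L + 1L
  }
  params$h_W <- glorot(cin * L, n_cls, c(cin * L, n_cls))
  params$h_b <- numeric(n_cls)
  fwd <- function(X) {
    caches <- list()
    for (i in seq_along(chans)) {
      cv <- conv1d_fwd(X, params[[sprintf("c%d_W", i)]],
                       params[[sprintf("c%d_b", i)]], stride = 2L, pad = 2L)
      a <- leaky_relu_fwd(cv$Y, 0.01)
      caches[[i]] <- list(conv = cv$cache, mask = a$mask)
      X <- a$Y
    }
    dd <- dim(X)
    flat <- matrix(aperm(X, c(1, 3, 2)), dd[1], dd[2] * dd[3])
    logits <- flat %*% params$h_W + rep(params$h_b, each = dd[1])
    list(scores = softmax_rows(logits), flat = flat, dimX = dd, caches = caches)
  }
  opt <- optimizer_new("adam", lr = 1e-3)
  ntr <- length(tr)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(ntr)
    for (s in seq(1L, ntr, by = 16L)) {
      take <- tr[ord[s:min(s + 15L, ntr)]]
      f <- fwd(X[take, , , drop = FALSE])
      lg <- loss_and_grad(f$scores, y[take], "cross_entropy")
      grads <- list(h_W = crossprod(f$flat, lg$dlogits),
                    h_b = colSums(lg$dlogits))
      dflat <- lg$dlogits %*% t(params$h_W)
      dd <- f$dimX
      dX <- aperm(array(dflat, c(dd[1], dd[3], dd[2])), c(1, 3, 2))
      for (i in rev(seq_along(chans))) {
        dX <- leaky_relu_bwd(dX, f$caches[[i]]$mask, 0.01)
        bw <- conv1d_bwd(dX, params[[sprintf("c%d_W", i)]], f$caches[[i]]$conv)
        grads[[sprintf("c%d_W", i)]] <- bw$dW
        grads[[sprintf("c%d_b", i)]] <- bw$db
        dX <- bw$dX
      }
      st <- optimizer_step(opt, params, grads)
      opt <- st$opt
      params <- st$params
    }
  }
  scores <- fwd(X[te, , , drop = FALSE])$scores
  colnames(scores) <- lv
  compute_metrics(factor(ws$labels[te], levels = lv), scores,
                  levels = lv, roc = FALSE)
}
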