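# Supervised training loop for the graph-convolutional classifier.

#' Training configuration
#'
#' Defaults follow the tuned pipeline: Adam, learning rate 0.001, batch 16,
#' cross-entropy loss, weight decay 6e-6, 200 epochs.
#'
#' @param optimizer one of `"adam"`, `"sgd"`, `"adadelta"`, `"adamax"`.
#' @param learning_rate step size (>= 0; 0 freezes the model).
#' @param batch_size minibatch size.
#' @param loss `"cross_entropy"` or `"mse"` (on softmax outputs).
#' @param weight_decay L2 penalty coefficient.
#' @param epochs training epochs.
#' @param seed RNG seed for shuffling and dropout.
#' @return a `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 0.001,
                         batch_size = 16L, loss = "cross_entropy",
                         weight_decay = 6e-6, epochs = 200L, seed = 1L) {
  if (!optimizer %in% c("adam", "sgd", "adadelta", "adamax"))
    stop_config("unsupported optimizer '%s'", optimizer)
  if (!loss %in% c("cross_entropy", "mse")) stop_config("unsupported loss")
  if (learning_rate < 0 || batch_size < 1 || epochs < 1)
    stop_config("learning_rate must be >= 0, batch_size and epochs >= 1")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), loss = loss,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

label_indices <- function(labels, n_classes) {
  lv <- class_levels_for(n_classes)
  y <- match(as.character(labels), lv)
  if (anyNA(y))
    stop_config("labels outside the %d-class set {%s}", n_classes,
                paste(lv, collapse = ", "))
  y
}

# loss value and d(loss)/d(logits) for a scored batch
loss_and_grad <- function(scores, y, loss) {
  B <- nrow(scores)
  onehot <- matrix(0, B, ncol(scores))
  onehot[cbind(seq_len(B), y)] <- 1
  p <- pmin(pmax(scores, 1e-12), 1)
  if (loss == "cross_entropy") {
    L <- -mean(log(p[cbind(seq_len(B), y)]))
    dlogits <- (scores - onehot) / B
  } else {
    L <- mean((scores - onehot)^2)
    dp <- 2 * (scores - onehot) / (B * ncol(scores))
    dlogits <- scores * (dp - rowSums(dp * scores))
  }
  list(loss = L, dlogits = dlogits)
}

eval_batch <- function(model, X, y, loss) {
  scores <- dfcgn_forward(model, X, training = FALSE)
  lg <- loss_and_grad(scores, y, loss)
  list(loss = lg$loss, acc = mean(max.col(scores) == y))
}

#' Train the classifier
#'
#' Trains on the `train` split, monitors the `val` split every epoch, and
#' returns the parameters of the epoch with the best validation accuracy.
#' Windows generated by the GAN are only allowed in the train split (hard
#' error otherwise). The input scale (1 / sd of the training windows) is
#' fixed from the train split and stored in the model.
#'
#' @param model a `dfcgn_model` from [build_model()].
#' @param ws a `window_set` with splits assigned.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return a `dfcgn_fit`: `model` (best checkpoint), `history` data.frame
#'   with per-epoch train/val loss and accuracy.
#' @export
train_dfcgn <- function(model, ws, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "dfcgn_model"), inherits(ws, "window_set"))
  split <- as.character(ws$split)
  if (any(ws$provenance == "gan" & split != "train"))
    stop("data leakage: GAN windows outside the train split", call. = FALSE)
  tr <- which(split == "train")
  va <- which(split == "val")
  if (length(tr) == 0) stop("empty train split", call. = FALSE)
  ncl <- model$config$n_classes
  ytr <- label_indices(ws$labels[tr], ncl)
  Xtr <- ws$windows[tr, , , drop = FALSE]
  sdev <- stats::sd(Xtr)
  model$input_scale <- if (sdev > 0) 1 / sdev else 1
  Xva <- if (length(va)) ws$windows[va, , , drop = FALSE] else NULL
  yva <- if (length(va)) label_indices(ws$labels[va], ncl) else NULL

  opt <- optimizer_new(cfg$optimizer, lr = cfg$learning_rate,
                       weight_decay = cfg$weight_decay)
  history <- data.frame()
  best <- list(acc = -Inf, params = model$params)
  n <- length(tr)
  set.seed(derive_seed(cfg$seed, 5L))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_acc <- 0; nb <- 0
    for (s in seq(1L, n, by = cfg$batch_size)) {
      take <- ord[s:min(s + cfg$batch_size - 1L, n)]
      xb <- Xtr[take, , , drop = FALSE]
      yb <- ytr[take]
      fw <- dfcgn_forward(model, xb, training = TRUE, with_cache = TRUE)
      lg <- loss_and_grad(fw$scores, yb, cfg$loss)
      grads <- dfcgn_backward(model, lg$dlogits, fw$cache)
      grads$input <- NULL
      if (cfg$learning_rate > 0) {
        st <- optimizer_step(opt, model$params, grads)
        opt <- st$opt
        model$params <- st$params
      }
      ep_loss <- ep_loss + lg$loss
      ep_acc <- ep_acc + mean(max.col(fw$scores) == yb)
      nb <- nb + 1
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                      train_acc = ep_acc / nb,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(Xva)) {
      ev <- eval_batch(model, Xva, yva, cfg$loss)
      row$val_loss <- ev$loss
      row$val_acc <- ev$acc
      if (ev$acc >= best$acc) best <- list(acc = ev$acc, params = model$params)
    } else {
      best <- list(acc = row$train_acc, params = model$params)
    }
    history <- rbind(history, row)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f acc %.3f  val %.3f", ep,
                      row$train_loss, row$train_acc, row$val_acc))
  }
  model$params <- best$params
  structure(list(model = model, history = history), class = "dfcgn_fit")
}

#' @export
print.dfcgn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<dfcgn_fit> %d epochs; final train acc %.3f; best val acc %.3f\n",
              nrow(h), h$train_acc[nrow(h)],
              suppressWarnings(max(h$val_acc, na.rm = TRUE))))
  invisible(x)
}

#' @export
predict.dfcgn_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}
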