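# 1-D convolutional generative adversarial network for per-class EEG
# segment augmentation. The generator maps a latent vector to a
# channels x segment_len segment through a dense projection followed by six
# convolutional layers (five zero-stuffing upsample + conv stages and one
# final conv); the discriminator mirrors it with six strided convolutions
# and a sigmoid read-out. Training alternates one discriminator and one
# generator step per batch; the generator uses the non-saturating loss
# while the classic two-term minimax value is logged every epoch.

#' GAN configuration
#'
#' @param n_conv_layers convolutional layers in each sub-network (default 6).
#' @param optimizer_name one of `"adamax"`, `"adam"`, `"sgd"` (default adamax).
#' @param learning_rate optimizer step size (default 0.001).
#' @param batch_size minibatch size (default 8).
#' @param latent_dim latent noise length (default 64).
#' @param segment_len generated segment length in samples (default 125).
#' @param n_channels signal channels (default 3).
#' @param epochs training epochs (default 30).
#' @param seed RNG seed.
#' @return a `gan_config`.
#' @export
gan_config <- function(n_conv_layers = 6L, optimizer_name = "adamax",
                       learning_rate = 0.001, batch_size = 8L,
                       latent_dim = 64L, segment_len = 125L,
                       n_channels = 3L, epochs = 30L, seed = 1L) {
  if (latent_dim <= 0 || batch_size <= 0 || learning_rate <= 0)
    stop_config("latent_dim, batch_size and learning_rate must be positive")
  if (!optimizer_name %in% c("adam", "sgd", "adamax"))
    stop_config("unsupported optimizer '%s'", optimizer_name)
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 optimizer_name = optimizer_name,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 latent_dim = as.integer(latent_dim),
                 segment_len = as.integer(segment_len),
                 n_channels = as.integer(n_channels),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "gan_config")
}

#' Empirical two-term GAN value
#'
#' `V(G, D) = mean(log d_real) + mean(log(1 - d_fake))`, the quantity the
#' discriminator ascends and the generator descends (through its second
#' term). Probabilities are clamped to `[eps, 1 - eps]` before the logs.
#'
#' @param d_real discriminator outputs on real data, in (0, 1).
#' @param d_fake discriminator outputs on generated data.
#' @param eps clamp (default 1e-7).
#' @return scalar value.
#' @export
gan_value <- function(d_real, d_fake, eps = 1e-7) {
  if (length(d_real) == 0 || length(d_fake) == 0)
    stop("empty probability vector", call. = FALSE)
  d_real <- pmin(pmax(d_real, eps), 1 - eps)
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  mean(log(d_real)) + mean(log(1 - d_fake))
}

# layer plans -------------------------------------------------------------

gan_gen_plan <- function(cfg) {
  n_up <- cfg$n_conv_layers - 1L             # upsampling stages
  L0 <- ceiling(cfg$segment_len / 2^n_up)
  chans <- c(24, 24, 16, 16, 8, 8)[seq_len(cfg$n_conv_layers)]
  list(L0 = L0, ch0 = chans[1], chans = chans, k = 5L,
       out_len = L0 * 2^n_up)
}

gan_disc_plan <- function(cfg) {
  chans <- c(8, 8, 16, 16, 24, 24)[seq_len(cfg$n_conv_layers)]
  L <- cfg$segment_len
  lens <- integer(cfg$n_conv_layers)
  for (i in seq_len(cfg$n_conv_layers)) {
    L <- (L + 2 * 2 - 5) %/% 2 + 1           # k = 5, pad = 2, stride = 2
    lens[i] <- L
  }
  list(chans = chans, lens = lens, k = 5L, flat = chans[length(chans)] * L)
}

gan_init_params <- function(cfg) {
  gp <- gan_gen_plan(cfg)
  dp <- gan_disc_plan(cfg)
  k <- 5L
  params <- list()
  params$g_dense_W <- glorot(cfg$latent_dim, gp$ch0 * gp$L0,
                             c(cfg$latent_dim, gp$ch0 * gp$L0))
  params$g_dense_b <- numeric(gp$ch0 * gp$L0)
  cin <- gp$ch0
  for (i in seq_len(cfg$n_conv_layers)) {
    cout <- if (i == cfg$n_conv_layers) cfg$n_channels else gp$chans[i + 1] %||% gp$chans[i]
    params[[sprintf("g_conv%d_W", i)]] <- glorot(cin * k, cout, c(cout, cin * k))
    params[[sprintf("g_conv%d_b", i)]] <- numeric(cout)
    cin <- cout
  }
  cin <- cfg$n_channels
  for (i in seq_len(cfg$n_conv_layers)) {
    cout <- dp$chans[i]
    params[[sprintf("d_conv%d_W", i)]] <- glorot(cin * k, cout, c(cout, cin * k))
    params[[sprintf("d_conv%d_b", i)]] <- numeric(cout)
    cin <- cout
  }
  params$d_dense_W <- glorot(dp$flat, 1, c(dp$flat, 1))
  params$d_dense_b <- 0
  params
}

# generator forward: Z [B x latent] -> segments [B x C x segment_len]
gan_gen_fwd <- function(params, cfg, Z) {
  gp <- gan_gen_plan(cfg)
  B <- nrow(Z)
  cache <- list(Z = Z)
  H <- Z %*% params$g_dense_W + rep(params$g_dense_b, each = B)
  a <- leaky_relu_fwd(H)
  cache$dense_mask <- a$mask
  X <- array(aperm(array(a$Y, c(B, gp$L0, gp$ch0)), c(1, 3, 2)),
             c(B, gp$ch0, gp$L0))
  for (i in seq_len(cfg$n_conv_layers)) {
    last <- i == cfg$n_conv_layers
    if (!last) {
      X <- upsample_zero_fwd(X, 2L)
      # scale by 2 to keep expected magnitude after zero-stuffing
      X <- 2 * X
    }
    cv <- conv1d_fwd(X, params[[sprintf("g_conv%d_W", i)]],
                     params[[sprintf("g_conv%d_b", i)]], stride = 1L, pad = 2L)
    cache[[sprintf("conv%d", i)]] <- cv$cache
    X <- cv$Y
    if (!last) {
      a <- leaky_relu_fwd(X)
      cache[[sprintf("mask%d", i)]] <- a$mask
      X <- a$Y
    }
  }
  cache$full_len <- dim(X)[3]
  X <- X[, , seq_len(cfg$segment_len), drop = FALSE]    # crop to segment
  list(Y = X, cache = cache)
}

gan_gen_bwd <- function(params, cfg, dY, cache) {
  gp <- gan_gen_plan(cfg)
  B <- dim(dY)[1]
  grads <- list()
  dX <- array(0, c(B, dim(dY)[2], cache$full_len))
  dX[, , seq_len(cfg$segment_len)] <- dY
  for (i in rev(seq_len(cfg$n_conv_layers))) {
    last <- i == cfg$n_conv_layers
    if (!last) dX <- leaky_relu_bwd(dX, cache[[sprintf("mask%d", i)]])
    bw <- conv1d_bwd(dX, params[[sprintf("g_conv%d_W", i)]],
                     cache[[sprintf("conv%d", i)]])
    grads[[sprintf("g_conv%d_W", i)]] <- bw$dW
    grads[[sprintf("g_conv%d_b", i)]] <- bw$db
    dX <- bw$dX
    if (!last) dX <- upsample_zero_bwd(2 * dX, 2L)   # undo upsample+scale
  }
  dH <- matrix(aperm(dX, c(1, 3, 2)), B, gp$L0 * gp$ch0)
  dH <- leaky_relu_bwd(dH, cache$dense_mask)
  grads$g_dense_W <- crossprod(cache$Z, dH)
  grads$g_dense_b <- colSums(dH)
  grads
}

# discriminator forward: X [B x C x L] -> logits [B]
gan_disc_fwd <- function(params, cfg, X) {
  cache <- list()
  for (i in seq_len(cfg$n_conv_layers)) {
    cv <- conv1d_fwd(X, params[[sprintf("d_conv%d_W", i)]],
                     params[[sprintf("d_conv%d_b", i)]], stride = 2L, pad = 2L)
    cache[[sprintf("conv%d", i)]] <- cv$cache
    a <- leaky_relu_fwd(cv$Y)
    cache[[sprintf("mask%d", i)]] <- a$mask
    X <- a$Y
  }
  d <- dim(X)
  flat <- matrix(aperm(X, c(1, 3, 2)), d[1], d[2] * d[3])
  cache$flat <- flat
  cache$dimX <- d
  logits <- drop(flat %*% params$d_dense_W) + params$d_dense_b
  list(logits = logits, cache = cache)
}

# backward from d(loss)/d(logit); returns grads and dX for the generator path
gan_disc_bwd <- function(params, cfg, dlogit, cache) {
  grads <- list()
  d <- cache$dimX
  grads$d_dense_W <- crossprod(cache$flat, matrix(dlogit, ncol = 1))
  grads$d_dense_b <- sum(dlogit)
  dflat <- matrix(dlogit, ncol = 1) %*% t(params$d_dense_W)
  dX <- aperm(array(dflat, c(d[1], d[3], d[2])), c(1, 3, 2))
  for (i in rev(seq_len(cfg$n_conv_layers))) {
    dX <- leaky_relu_bwd(dX, cache[[sprintf("mask%d", i)]])
    bw <- conv1d_bwd(dX, params[[sprintf("d_conv%d_W", i)]],
                     cache[[sprintf("conv%d", i)]])
    grads[[sprintf("d_conv%d_W", i)]] <- bw$dW
    grads[[sprintf("d_conv%d_b", i)]] <- bw$db
    dX <- bw$dX
  }
  c(grads, list(dX_input = dX))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Train the augmentation GAN on one class of training windows
#'
#' Hard data-hygiene guard: the input must contain only training-split
#' windows of a single class; anything else raises an error, so augmented
#' samples can never be informed by validation or test data. Segments are
#' standardized by their global standard deviation before training; the
#' scale is stored in the returned pair and reapplied by [synthesize()].
#'
#' @param real a `window_set` restricted to one class's train split.
#' @param config a [gan_config()].
#' @param verbose print per-epoch values.
#' @return a `gan_pair` with generator/discriminator parameters and a
#'   per-epoch history of the minimax value and generator loss.
#' @export
train_gan <- function(real, config = gan_config(), verbose = FALSE) {
  stopifnot(inherits(real, "window_set"))
  if (any(as.character(real$split) != "train"))
    stop("data leakage: train_gan received non-train windows", call. = FALSE)
  labs <- unique(as.character(real$labels))
  if (length(labs) != 1L)
    stop("train_gan expects windows of a single class", call. = FALSE)
  X <- real$windows
  n <- dim(X)[1]
  if (dim(X)[3] != config$segment_len)
    stop_config("window length %d != configured segment_len %d",
                dim(X)[3], config$segment_len)
  scale <- stats::sd(X)
  if (scale == 0) scale <- 1
  Xs <- X / scale

  params <- with_seed(derive_seed(config$seed, 1L), gan_init_params(config))
  opt_d <- optimizer_new(config$optimizer_name, lr = config$learning_rate)
  opt_g <- optimizer_new(config$optimizer_name, lr = config$learning_rate)
  d_names <- grep("^d_", names(params), value = TRUE)
  g_names <- grep("^g_", names(params), value = TRUE)
  history <- data.frame(epoch = integer(0), value = numeric(0),
                        loss_g = numeric(0))
  B <- config$batch_size
  set.seed(derive_seed(config$seed, 2L))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    vals <- c(); lgs <- c()
    for (s in seq(1L, n, by = B)) {
      take <- ord[s:min(s + B - 1L, n)]
      xb <- Xs[take, , , drop = FALSE]
      bs <- length(take)
      # --- discriminator step
      Z <- matrix(stats::rnorm(bs * config$latent_dim), bs)
      gf <- gan_gen_fwd(params, config, Z)
      fr <- gan_disc_fwd(params, config, xb)
      ff <- gan_disc_fwd(params, config, gf$Y)
      # BCE-with-logits: minimizing it maximizes the two-term value
      dl_real <- (sigmoid(fr$logits) - 1) / bs
      dl_fake <- sigmoid(ff$logits) / bs
      gr <- gan_disc_bwd(params, config, dl_real, fr$cache)
      gfk <- gan_disc_bwd(params, config, dl_fake, ff$cache)
      grads_d <- Map(`+`, gr[d_names], gfk[d_names])
      st <- optimizer_step(opt_d, params[d_names], grads_d)
      opt_d <- st$opt
      params[d_names] <- st$params
      # --- generator step (non-saturating loss)
      Z <- matrix(stats::rnorm(bs * config$latent_dim), bs)
      gf <- gan_gen_fwd(params, config, Z)
      ff <- gan_disc_fwd(params, config, gf$Y)
      dl <- (sigmoid(ff$logits) - 1) / bs
      bwd_d <- gan_disc_bwd(params, config, dl, ff$cache)
      grads_g <- gan_gen_bwd(params, config, bwd_d$dX_input, gf$cache)
      st <- optimizer_step(opt_g, params[g_names], grads_g[g_names])
      opt_g <- st$opt
      params[g_names] <- st$params
      vals <- c(vals, gan_value(sigmoid(fr$logits), sigmoid(ff$logits)))
      lgs <- c(lgs, mean(softplus(-ff$logits)))
    }
    history <- rbind(history, data.frame(epoch = ep, value = mean(vals),
                                         loss_g = mean(lgs)))
    if (verbose)
      message(sprintf("epoch %3d  V = %8.4f  loss_G = %8.4f",
                      ep, mean(vals), mean(lgs)))
  }
  structure(list(config = config, params = params, scale = scale,
                 label = labs, history = history, trained = TRUE),
            class = "gan_pair")
}

#' @export
print.gan_pair <- function(x, ...) {
  cat(sprintf("<gan_pair> class '%s', %d conv layers, %d epochs trained\n",
              x$label, x$config$n_conv_layers, nrow(x$history)))
  invisible(x)
}

#' Generate a stacked synthetic signal from a trained GAN
#'
#' Draws `ceil(n_samples_total / segment_len)` latent vectors, decodes them,
#' concatenates the segments along time and truncates to the requested
#' length.
#'
#' @param pair a trained `gan_pair`.
#' @param n_samples_total samples to produce (may be 0).
#' @param seed RNG seed for the latent draws.
#' @return channels x `n_samples_total` matrix with attribute
#'   `provenance = "gan"`.
#' @export
synthesize <- function(pair, n_samples_total, seed = 1L) {
  if (!isTRUE(pair$trained)) stop("GAN pair is not trained", call. = FALSE)
  cfg <- pair$config
  if (n_samples_total == 0)
    return(structure(matrix(0, cfg$n_channels, 0), provenance = "gan"))
  n_seg <- ceiling(n_samples_total / cfg$segment_len)
  Z <- with_seed(derive_seed(seed, 97L),
                 matrix(stats::rnorm(n_seg * cfg$latent_dim), n_seg))
  Y <- gan_gen_fwd(pair$params, cfg, Z)$Y * pair$scale
  out <- matrix(0, cfg$n_channels, n_seg * cfg$segment_len)
  for (i in seq_len(n_seg)) {
    out[, ((i - 1) * cfg$segment_len + 1):(i * cfg$segment_len)] <-
      array(Y[i, , ], c(cfg$n_channels, cfg$segment_len))
  }
  structure(out[, seq_len(n_samples_total), drop = FALSE], provenance = "gan")
}
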