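# Minimal neural-network primitives: batched 1-D convolution via im2col,
# dense layers, activations and first-order optimizers. Everything operates
# on plain arrays; gradients are hand-derived and checked against numerical
# differentiation in the test suite.
#
# Array layout conventions:
#   batched 1-D signals  [B x C x L]   (batch, channels, length)
#   conv weights         [C_out x (C_in * k)] with rows of im2col patches
#   dense weights        [F_in x F_out]

nn_pad <- function(X, pad) {
  if (pad == 0) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1], d[2], d[3] + 2 * pad))
  Xp[, , (pad + 1):(pad + d[3])] <- X
  Xp
}

# im2col: [B x C x Lp] -> patch matrix [(C*k) x (L_out*B)], column-major in
# (t, b); row layout (j within kernel inner, channel outer).
nn_im2col <- function(Xp, k, stride) {
  d <- dim(Xp)
  starts <- seq(1L, d[3] - k + 1L, by = stride)
  L_out <- length(starts)
  idx <- as.vector(outer(0:(k - 1L), starts, `+`))       # [k * L_out]
  Xperm <- aperm(Xp, c(3, 2, 1))                          # [Lp, C, B]
  P <- Xperm[idx, , , drop = FALSE]                       # [k*L_out, C, B]
  dim(P) <- c(k, L_out, d[2], d[1])
  P <- aperm(P, c(1, 3, 2, 4))                            # [k, C, L_out, B]
  dim(P) <- c(k * d[2], L_out * d[1])
  list(P = P, L_out = L_out, starts = starts)
}

# forward 1-D convolution; returns output and cache for backward
conv1d_fwd <- function(X, W, b, stride = 1L, pad = 0L) {
  d <- dim(X)
  C_out <- nrow(W)
  k <- ncol(W) / d[2]
  Xp <- nn_pad(X, pad)
  ic <- nn_im2col(Xp, k, stride)
  Y <- W %*% ic$P + b                                     # [C_out, L_out*B]
  dim(Y) <- c(C_out, ic$L_out, d[1])
  Y <- aperm(Y, c(3, 1, 2))                               # [B, C_out, L_out]
  list(Y = Y, cache = list(P = ic$P, dimX = d, k = k, stride = stride,
                           pad = pad, starts = ic$starts, L_out = ic$L_out))
}

conv1d_bwd <- function(dY, W, cache) {
  d <- cache$dimX
  B <- d[1]; C_in <- d[2]
  L_out <- cache$L_out
  C_out <- nrow(W)
  dYm <- aperm(dY, c(2, 3, 1))                            # [C_out, L_out, B]
  dim(dYm) <- c(C_out, L_out * B)
  dW <- dYm %*% t(cache$P)
  db <- rowSums(dYm)
  dP <- t(W) %*% dYm                                      # [(C_in*k), L_out*B]
  k <- cache$k
  dim(dP) <- c(k, C_in, L_out, B)
  Lp <- d[3] + 2 * cache$pad
  dXp_perm <- array(0, c(Lp, C_in, B))                    # [Lp, C, B]
  for (j in seq_len(k)) {
    posj <- cache$starts + j - 1L
    dPj <- array(dP[j, , , ], c(C_in, L_out, B))
    dXp_perm[posj, , ] <- dXp_perm[posj, , , drop = FALSE] +
      aperm(dPj, c(2, 1, 3))
  }
  dX <- aperm(dXp_perm, c(3, 2, 1))                       # [B, C, Lp]
  if (cache$pad > 0) dX <- dX[, , (cache$pad + 1):(cache$pad + d[3]), drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# zero-stuffing upsample by factor s along the length axis
upsample_zero_fwd <- function(X, s) {
  d <- dim(X)
  Y <- array(0, c(d[1], d[2], d[3] * s))
  Y[, , seq(1, d[3] * s, by = s)] <- X
  Y
}

upsample_zero_bwd <- function(dY, s) {
  d3 <- dim(dY)[3]
  dY[, , seq(1, d3, by = s), drop = FALSE]
}

leaky_relu_fwd <- function(X, slope = 0.2) {
  mask <- X > 0
  list(Y = ifelse(mask, X, slope * X), mask = mask)
}

leaky_relu_bwd <- function(dY, mask, slope = 0.2) {
  dY * ifelse(mask, 1, slope)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable row-wise softmax
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

glorot <- function(fan_in, fan_out, dims) {
  sd <- sqrt(2 / (fan_in + fan_out))
  array(stats::rnorm(prod(dims), 0, sd), dims)
}

# --- optimizers -----------------------------------------------------------
# A parameter store is a flat named list of arrays; gradients mirror it.

optimizer_new <- function(name = c("adam", "adamax", "sgd", "adadelta"),
                          lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8, weight_decay = 0, rho = 0.95) {
  name <- match.arg(name)
  structure(list(name = name, lr = lr, beta1 = beta1, beta2 = beta2,
                 eps = eps, weight_decay = weight_decay, rho = rho,
                 t = 0L, m = list(), v = list()),
            class = "dfcgn_optimizer")
}

optimizer_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (opt$weight_decay > 0) g <- g + opt$weight_decay * params[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- array(0, dim(as.array(params[[nm]])))
      opt$v[[nm]] <- array(0, dim(as.array(params[[nm]])))
    }
    p <- params[[nm]]
    dim0 <- dim(p)
    switch(opt$name,
      sgd = {
        p <- p - opt$lr * g
      },
      adam = {
        opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
        opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
        mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
        vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
        p <- p - opt$lr * mhat / (sqrt(vhat) + opt$eps)
      },
      adamax = {
        opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
        opt$v[[nm]] <- pmax(opt$beta2 * opt$v[[nm]], abs(g))
        p <- p - (opt$lr / (1 - opt$beta1^opt$t)) * opt$m[[nm]] /
          (opt$v[[nm]] + opt$eps)
      },
      adadelta = {
        opt$m[[nm]] <- opt$rho * opt$m[[nm]] + (1 - opt$rho) * g^2
        upd <- sqrt(opt$v[[nm]] + opt$eps) / sqrt(opt$m[[nm]] + opt$eps) * g
        opt$v[[nm]] <- opt$rho * opt$v[[nm]] + (1 - opt$rho) * upd^2
        p <- p - opt$lr * upd
      })
    # arithmetic with the moment buffers may promote vectors to 1-d arrays;
    # restore the parameter's original shape
    if (is.null(dim0)) p <- as.vector(p) else dim(p) <- dim0
    params[[nm]] <- p
  }
  list(opt = opt, params = params)
}
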