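# Four-layer graph-convolutional classifier. Each window is a graph signal:
# 3 nodes (channels) carrying 125 time samples as features. A layer filters
# across nodes with Chebyshev polynomials of the scaled Laplacian (order K)
# while mixing features with a [K x F_in x F_out] weight tensor, then
# max-pools the feature axis by 2 and applies a Leaky-ReLU; dropout is
# applied to the raw input only. The pooled features of the last layer are
# flattened into a dense softmax head.

#' Classifier configuration
#'
#' @param n_gconv_layers graph-convolution layers (default 4).
#' @param cheb_orders per-layer Chebyshev order K (default `c(3, 3, 3, 3)`).
#' @param layer_feature_widths per-layer output feature counts; `NULL`
#'   keeps each layer's width equal to its input width (the default chain
#'   125 -> 62 -> 31 -> 15 -> 7 after pooling).
#' @param pool_size max-pool factor on the feature axis (default 2).
#' @param leaky_relu_slope negative-side slope (default 0.01).
#' @param dropout_rate input dropout probability (default 0.3).
#' @param n_classes 2 or 3.
#' @param input_width features (time samples) per node (default 125).
#' @param n_nodes graph nodes / channels (default 3).
#' @return a `model_config` with the derived per-layer width chain.
#' @export
model_config <- function(n_gconv_layers = 4L, cheb_orders = rep(3L, 4L),
                         layer_feature_widths = NULL, pool_size = 2L,
                         leaky_relu_slope = 0.01, dropout_rate = 0.3,
                         n_classes = 3L, input_width = 125L, n_nodes = 3L) {
  n_gconv_layers <- as.integer(n_gconv_layers)
  if (length(cheb_orders) == 1L) cheb_orders <- rep(cheb_orders, n_gconv_layers)
  if (length(cheb_orders) != n_gconv_layers)
    stop_config("need one Chebyshev order per layer")
  if (any(cheb_orders < 1)) stop_config("Chebyshev orders must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_config("dropout_rate must lie in [0, 1)")
  if (!n_classes %in% c(2L, 3L)) stop_config("n_classes must be 2 or 3")
  f_in <- integer(n_gconv_layers)
  f_out <- integer(n_gconv_layers)
  w <- as.integer(input_width)
  for (l in seq_len(n_gconv_layers)) {
    f_in[l] <- w
    f_out[l] <- if (is.null(layer_feature_widths)) w
                else as.integer(layer_feature_widths[l])
    if (f_out[l] < 1) stop_config("layer %d width underflows", l)
    w <- f_out[l] %/% pool_size
    if (w < 1) stop_config("pooling exhausts features at layer %d", l)
  }
  structure(list(n_gconv_layers = n_gconv_layers,
                 cheb_orders = as.integer(cheb_orders),
                 f_in = f_in, f_out = f_out, f_final = w,
                 pool_size = as.integer(pool_size),
                 leaky_relu_slope = leaky_relu_slope,
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 input_width = as.integer(input_width),
                 n_nodes = as.integer(n_nodes)),
            class = "model_config")
}

#' Build a DFCGN classifier
#'
#' @param config a [model_config()].
#' @param graph a `channel_graph` with Laplacian (node count must match).
#' @param seed RNG seed for the Glorot-style initialization.
#' @return a `dfcgn_model`.
#' @export
build_model <- function(config, graph, seed = 1L) {
  stopifnot(inherits(config, "model_config"), inherits(graph, "channel_graph"))
  if (is.null(graph$L)) graph <- laplacian(graph)
  if (nrow(graph$L) != config$n_nodes)
    stop_config("graph has %d nodes, config expects %d",
                nrow(graph$L), config$n_nodes)
  params <- with_seed(seed, {
    p <- list()
    for (l in seq_len(config$n_gconv_layers)) {
      K <- config$cheb_orders[l]
      p[[sprintf("conv%d_W", l)]] <-
        glorot(K * config$f_in[l], config$f_out[l],
               c(K, config$f_in[l], config$f_out[l]))
      p[[sprintf("conv%d_b", l)]] <- numeric(config$f_out[l])
    }
    flat <- config$n_nodes * config$f_final
    p$head_W <- glorot(flat, config$n_classes, c(flat, config$n_classes))
    p$head_b <- numeric(config$n_classes)
    p
  })
  Tk <- cheb_basis(graph, max(config$cheb_orders))
  structure(list(config = config, graph = graph, Tk = Tk, params = params,
                 input_scale = 1, seed = as.integer(seed)),
            class = "dfcgn_model")
}

#' @export
print.dfcgn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dfcgn_model> %d GConv layers (K = %s), %d nodes, %d classes\n",
              cfg$n_gconv_layers, paste(cfg$cheb_orders, collapse = ","),
              cfg$n_nodes, cfg$n_classes))
  widths <- c(cfg$f_in[1], cfg$f_out %/% cfg$pool_size)
  cat(sprintf("  feature chain: %s; flatten %d; %d trainable parameters\n",
              paste(widths, collapse = " -> "),
              cfg$n_nodes * cfg$f_final, count_parameters(x)))
  invisible(x)
}

#' Number of trainable scalars in a model
#' @param model a `dfcgn_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# [B,N,F] -> [B*N, F] with row index (i-1)*B + b
bnf_to_mat <- function(A) {
  d <- dim(A)
  dim(A) <- c(d[1] * d[2], d[3])
  A
}

# apply node operator M [N x N] across the node axis of [B,N,F]
node_mix <- function(M, X) {
  d <- dim(X)
  Xp <- aperm(X, c(2, 1, 3))
  dim(Xp) <- c(d[2], d[1] * d[3])
  Y <- M %*% Xp
  dim(Y) <- c(d[2], d[1], d[3])
  aperm(Y, c(2, 1, 3))
}

#' Forward pass of the classifier
#'
#' Pipeline: input dropout (training only) -> `n_gconv_layers` x (Chebyshev
#' graph convolution -> feature max-pool -> Leaky-ReLU) -> flatten -> dense
#' -> softmax. Rows of the returned score matrix sum to 1.
#'
#' @param model a `dfcgn_model`.
#' @param X batch `[B x n_nodes x input_width]` (a `window_set`'s tensor
#'   slice) or a single `[n_nodes x input_width]` matrix.
#' @param training apply dropout (uses the current RNG stream).
#' @param with_cache also return intermediate activations for backprop.
#' @return scores `[B x n_classes]`, or `list(scores, cache)`.
#' @export
dfcgn_forward <- function(model, X, training = FALSE, with_cache = FALSE) {
  cfg <- model$config
  if (length(dim(X)) == 2L) X <- array(X, c(1L, dim(X)))
  d <- dim(X)
  if (d[2] != cfg$n_nodes || d[3] != cfg$input_width)
    stop_config("batch shape [%d x %d] does not match model [%d x %d]",
                d[2], d[3], cfg$n_nodes, cfg$input_width)
  B <- d[1]
  X <- X * model$input_scale
  cache <- list()
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    mask <- array(stats::rbinom(length(X), 1L, keep), dim(X)) / keep
    X <- X * mask
    cache$drop_mask <- mask
  }
  for (l in seq_len(cfg$n_gconv_layers)) {
    K <- cfg$cheb_orders[l]
    W <- model$params[[sprintf("conv%d_W", l)]]
    b <- model$params[[sprintf("conv%d_b", l)]]
    Zm <- matrix(0, B * cfg$n_nodes, cfg$f_out[l])
    Ms <- vector("list", K)
    for (k in seq_len(K)) {
      Sk <- node_mix(model$Tk[[k]], X)
      Mk <- bnf_to_mat(Sk)
      Ms[[k]] <- Mk
      Zm <- Zm + Mk %*% array(W[k, , ], c(cfg$f_in[l], cfg$f_out[l]))
    }
    Zm <- Zm + rep(b, each = B * cfg$n_nodes)
    Z <- array(Zm, c(B, cfg$n_nodes, cfg$f_out[l]))
    # max-pool feature axis
    Fp <- cfg$f_out[l] %/% cfg$pool_size
    idx <- seq_len(Fp * cfg$pool_size)
    Zr <- Z[, , idx, drop = FALSE]
    dim(Zr) <- c(B, cfg$n_nodes, cfg$pool_size, Fp)
    if (cfg$pool_size == 2L) {
      A1 <- array(Zr[, , 1L, ], c(B, cfg$n_nodes, Fp))
      A2 <- array(Zr[, , 2L, ], c(B, cfg$n_nodes, Fp))
      P <- pmax(A1, A2)
      am <- array(2L, dim(P)); am[A1 >= A2] <- 1L
    } else {
      P <- apply(Zr, c(1, 2, 4), max)
      am <- apply(Zr, c(1, 2, 4), which.max)
    }
    a <- leaky_relu_fwd(P, cfg$leaky_relu_slope)
    cache[[sprintf("layer%d", l)]] <- list(Ms = Ms, argmax = am,
                                           relu_mask = a$mask, f_out = cfg$f_out[l])
    X <- a$Y
  }
  flat <- matrix(X, B, cfg$n_nodes * cfg$f_final)
  logits <- flat %*% model$params$head_W +
    rep(model$params$head_b, each = B)
  scores <- softmax_rows(logits)
  if (!with_cache) return(scores)
  cache$flat <- flat
  list(scores = scores, cache = cache)
}

# backward pass from d(loss)/d(logits); mirrors dfcgn_forward
dfcgn_backward <- function(model, dlogits, cache) {
  cfg <- model$config
  B <- nrow(dlogits)
  grads <- list()
  grads$head_W <- crossprod(cache$flat, dlogits)
  grads$head_b <- colSums(dlogits)
  dflat <- dlogits %*% t(model$params$head_W)
  dX <- array(dflat, c(B, cfg$n_nodes, cfg$f_final))
  for (l in rev(seq_len(cfg$n_gconv_layers))) {
    lc <- cache[[sprintf("layer%d", l)]]
    dX <- leaky_relu_bwd(dX, lc$relu_mask, cfg$leaky_relu_slope)
    # un-pool: route gradient to the argmax slot
    Fp <- dim(dX)[3]
    dZ <- array(0, c(B, cfg$n_nodes, lc$f_out))
    for (p in seq_len(cfg$pool_size)) {
      sel <- lc$argmax == p
      tgt <- (seq_len(Fp) - 1L) * cfg$pool_size + p
      slab <- array(0, dim(dX))
      slab[sel] <- dX[sel]
      dZ[, , tgt] <- slab
    }
    dZm <- bnf_to_mat(dZ)
    K <- cfg$cheb_orders[l]
    W <- model$params[[sprintf("conv%d_W", l)]]
    dW <- array(0, dim(W))
    dXm_acc <- matrix(0, B * cfg$n_nodes, cfg$f_in[l])
    for (k in seq_len(K)) {
      Wk <- array(W[k, , ], c(cfg$f_in[l], lc$f_out))
      dW[k, , ] <- crossprod(lc$Ms[[k]], dZm)
      dMk <- dZm %*% t(Wk)
      dSk <- array(dMk, c(B, cfg$n_nodes, cfg$f_in[l]))
      dXm_acc <- dXm_acc + bnf_to_mat(node_mix(t(model$Tk[[k]]), dSk))
    }
    grads[[sprintf("conv%d_W", l)]] <- dW
    grads[[sprintf("conv%d_b", l)]] <- colSums(dZm)
    dX <- array(dXm_acc, c(B, cfg$n_nodes, cfg$f_in[l]))
  }
  if (!is.null(cache$drop_mask)) dX <- dX * cache$drop_mask
  grads$input <- dX * model$input_scale
  grads
}

#' @export
predict.dfcgn_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "window_set")) newdata$windows else newdata
  scores <- dfcgn_forward(object, X, training = FALSE)
  if (type == "prob") return(scores)
  cls <- class_levels_for(object$config$n_classes)
  factor(cls[max.col(scores)], levels = cls)
}

class_levels_for <- function(n_classes) {
  if (n_classes == 2L) c("negative", "positive") else emotion_levels
}
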