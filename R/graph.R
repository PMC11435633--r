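# Channel connectivity graph and spectral filtering.
#
# The classifier treats the EEG channels as nodes of a small weighted graph
# whose edges are absolute Pearson correlations between channel time series.
# Filtering is defined through the graph Laplacian L = D - W: exact spectral
# filtering via the eigensystem L = U diag(lambda) U^T, and the Chebyshev
# polynomial approximation used by the trainable layers, which never forms
# the eigendecomposition.

#' Functional-connectivity adjacency from a multichannel signal
#'
#' `W[i, j] = |Pearson r(channel_i, channel_j)|` off the diagonal, 0 on it.
#' A constant channel has undefined correlations; they are set to 0 with a
#' warning.
#'
#' @param signal channels x samples matrix (at least 2 samples).
#' @param tau correlation threshold stored for later [sparsify()] (not
#'   applied here).
#' @return a `channel_graph` with the adjacency filled in.
#' @export
correlation_adjacency <- function(signal, tau = 0.3) {
  if (ncol(signal) < 2L) stop("need at least 2 samples per channel", call. = FALSE)
  sds <- apply(signal, 1, stats::sd)
  W <- matrix(0, nrow(signal), nrow(signal),
              dimnames = list(rownames(signal), rownames(signal)))
  ok <- sds > 0
  if (!all(ok)) warning("constant channel(s): correlations set to 0")
  if (sum(ok) >= 2) {
    C <- abs(stats::cor(t(signal[ok, , drop = FALSE])))
    W[ok, ok] <- C
  }
  diag(W) <- 0
  structure(list(W = W, tau = tau, Ddeg = NULL, L = NULL, U = NULL,
                 lambda = NULL, lambda_max = NULL),
            class = "channel_graph")
}

#' Threshold-sparsify an adjacency matrix
#'
#' Entries strictly below `tau` are zeroed; symmetry is preserved and the
#' operation is idempotent. A warning is raised if a node loses all edges.
#'
#' @param W adjacency matrix or `channel_graph`.
#' @param tau threshold in `[0, 1]`.
#' @return same type as the input, with the thresholded adjacency.
#' @export
sparsify <- function(W, tau) {
  if (tau < 0 || tau > 1) stop_config("tau must lie in [0, 1]")
  g <- NULL
  if (inherits(W, "channel_graph")) { g <- W; W <- g$W }
  W2 <- W
  W2[W2 < tau] <- 0
  if (any(rowSums(W2) == 0 & rowSums(W) > 0))
    warning("sparsify isolated at least one node")
  if (!is.null(g)) {
    g$W <- W2
    g$tau <- tau
    return(g)
  }
  W2
}

#' Laplacian and eigensystem of a channel graph
#'
#' Fills `Ddeg` (diagonal degree matrix `D_ii = sum_j W_ij`), the Laplacian
#' `L = D - W` (or the symmetric-normalized `I - D^-1/2 W D^-1/2` when
#' `normalized = TRUE`), and its eigensystem `L = U diag(lambda) U^T` with
#' eigenvalues ascending and each eigenvector's largest-magnitude entry made
#' positive (a deterministic sign convention).
#'
#' @param g a `channel_graph` or a symmetric nonnegative adjacency matrix.
#' @param normalized use the symmetric-normalized Laplacian.
#' @return the completed `channel_graph`.
#' @export
laplacian <- function(g, normalized = FALSE) {
  if (!inherits(g, "channel_graph"))
    g <- structure(list(W = g, tau = NA_real_), class = "channel_graph")
  W <- g$W
  if (max(abs(W - t(W))) > 1e-9) stop("adjacency must be symmetric", call. = FALSE)
  if (any(W < 0)) stop("adjacency must be nonnegative", call. = FALSE)
  d <- rowSums(W)
  Ddeg <- diag(d, nrow(W))
  if (normalized) {
    dis <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- diag(1, nrow(W)) - (dis %o% dis) * W
  } else {
    L <- Ddeg - W
  }
  es <- eigen(L, symmetric = TRUE)
  ord <- order(es$values)
  lambda <- es$values[ord]
  U <- es$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  g$Ddeg <- Ddeg
  g$L <- L
  g$U <- U
  g$lambda <- lambda
  g$lambda_max <- max(lambda)
  g
}

#' Build a channel graph from training data in one call
#'
#' Convenience wrapper: correlation adjacency, thresholding at `tau`, then
#' Laplacian eigensystem. To avoid test leakage the signal should pool
#' training-split data only.
#'
#' @param signal channels x samples matrix.
#' @param tau correlation threshold.
#' @param normalized normalized Laplacian flag.
#' @return a complete `channel_graph`.
#' @export
build_channel_graph <- function(signal, tau = 0.3, normalized = FALSE) {
  g <- correlation_adjacency(signal, tau = tau)
  g <- sparsify(g, tau)
  laplacian(g, normalized = normalized)
}

#' @export
print.channel_graph <- function(x, ...) {
  cat(sprintf("<channel_graph> %d nodes, tau = %s%s\n", nrow(x$W),
              format(x$tau), if (is.null(x$L)) " (adjacency only)" else ""))
  if (!is.null(x$lambda))
    cat("  eigenvalues:", paste(signif(x$lambda, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Graph Fourier transform and inverse
#'
#' `gft` projects a node-indexed signal onto the Laplacian eigenbasis
#' (`q_hat = U^T q`); `igft` reconstructs (`q = U q_hat`). With an
#' orthonormal `U` the round trip is exact and norms are preserved.
#'
#' @param q node-signal vector `[N]` or matrix `[N x F]`.
#' @param g a `channel_graph` with eigensystem, or the `U` matrix itself.
#' @return transformed signal of the same shape.
#' @export
gft <- function(q, g) {
  U <- if (inherits(g, "channel_graph")) g$U else g
  q <- as.matrix(q)
  if (nrow(q) != nrow(U)) stop("signal/eigenbasis shape mismatch", call. = FALSE)
  crossprod(U, q)
}

#' @rdname gft
#' @export
igft <- function(q_hat, g) {
  U <- if (inherits(g, "channel_graph")) g$U else g
  q_hat <- as.matrix(q_hat)
  if (nrow(q_hat) != ncol(U)) stop("signal/eigenbasis shape mismatch", call. = FALSE)
  U %*% q_hat
}

#' Exact spectral filtering on the graph
#'
#' Applies `y = U diag(g(lambda)) U^T x`: transform to the spectral domain,
#' scale each graph frequency by the filter response, transform back.
#'
#' @param x node-signal `[N]` or `[N x F]`.
#' @param response function mapping eigenvalue(s) to filter gain(s).
#' @param g a `channel_graph` with eigensystem.
#' @return filtered signal, same shape as `x`.
#' @export
spectral_filter <- function(x, response, g) {
  stopifnot(inherits(g, "channel_graph"), !is.null(g$U))
  x <- as.matrix(x)
  gl <- vapply(g$lambda, response, numeric(1))
  g$U %*% (gl * crossprod(g$U, x))
}

# Scaled Laplacian 2L/lambda_max - I; an edgeless graph (lambda_max = 0)
# falls back to lambda_max = 2 so the scaling stays defined.
scaled_laplacian <- function(g) {
  lm <- g$lambda_max
  if (is.null(lm) || lm <= 0) lm <- 2
  2 * g$L / lm - diag(1, nrow(g$L))
}

# Chebyshev basis matrices T_0(Lt) .. T_{K-1}(Lt) for the scaled Laplacian.
cheb_basis <- function(g, K) {
  Lt <- scaled_laplacian(g)
  N <- nrow(Lt)
  Ts <- vector("list", K)
  Ts[[1]] <- diag(1, N)
  if (K >= 2) Ts[[2]] <- Lt
  if (K >= 3) for (k in 3:K) Ts[[k]] <- 2 * Lt %*% Ts[[k - 1]] - Ts[[k - 2]]
  Ts
}

#' Chebyshev polynomial graph filtering
#'
#' `y = sum_k theta_k T_k(Lt) x` with `Lt = 2L/lambda_max - I` and the
#' recurrence `T_0 = I`, `T_1 = Lt`, `T_k = 2 Lt T_{k-1} - T_{k-2}`. This is
#' the filtering the trainable layers use: cost is `O(K nnz(L) F)` and no
#' eigendecomposition is ever formed.
#'
#' @param x node-signal `[N]` or `[N x F]`.
#' @param theta coefficient vector (length `K`, constant term first).
#' @param g a `channel_graph` with Laplacian.
#' @return filtered signal, same shape as `x`.
#' @export
cheb_filter <- function(x, theta, g) {
  K <- length(theta)
  if (K < 1) stop_config("need at least one Chebyshev coefficient")
  x <- as.matrix(x)
  Lt <- scaled_laplacian(g)
  Tk_prev2 <- x                      # T_0 x
  y <- theta[1] * Tk_prev2
  if (K >= 2) {
    Tk_prev1 <- Lt %*% x             # T_1 x
    y <- y + theta[2] * Tk_prev1
    if (K >= 3) for (k in 3:K) {
      Tk <- 2 * Lt %*% Tk_prev1 - Tk_prev2
      y <- y + theta[k] * Tk
      Tk_prev2 <- Tk_prev1
      Tk_prev1 <- Tk
    }
  }
  y
}

#' Serialize / load a channel graph as JSON
#'
#' Matrices are stored both in decimal and in a base-16 float encoding
#' (`sprintf("%a")`) so the round trip is bit-exact.
#'
#' @param g a `channel_graph`; @param path JSON file path.
#' @return `path` / the restored `channel_graph`.
#' @export
write_graph_json <- function(g, path) {
  enc <- function(m) list(dim = dim(m), hex = sprintf("%a", as.numeric(m)))
  jsonlite::write_json(list(W = enc(g$W), tau = g$tau,
                            channels = rownames(g$W),
                            normalized = isTRUE(attr(g, "normalized"))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(e) {
    m <- matrix(as.numeric(strtoi_hexfloat(e$hex)), e$dim[1], e$dim[2])
    m
  }
  W <- dec(obj$W)
  dimnames(W) <- list(obj$channels, obj$channels)
  g <- structure(list(W = W, tau = obj$tau), class = "channel_graph")
  laplacian(g, normalized = isTRUE(obj$normalized))
}

# parse C99 hex-float literals written by sprintf("%a", .)
strtoi_hexfloat <- function(s) {
  vapply(s, function(z) as.numeric(sub("^\\+", "", z)), numeric(1),
         USE.NAMES = FALSE)
}
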