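random_graph <- function(N, seed) {
  set.seed(seed)
  W <- matrix(runif(N * N), N)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  laplacian(structure(list(W = W, tau = 0), class = "channel_graph"))
}

test_that("correlation adjacency is absolute Pearson with zero diagonal", {
  x <- rnorm(1000)
  sig <- rbind(x, x, rnorm(1000))
  g <- correlation_adjacency(sig)
  expect_equal(g$W[1, 2], 1)
  expect_equal(diag(g$W), c(0, 0, 0), ignore_attr = TRUE)
  # sine and cosine over whole periods are uncorrelated
  t <- seq(0, 1, length.out = 1001)[-1001]
  g2 <- correlation_adjacency(rbind(sin(2 * pi * 5 * t), cos(2 * pi * 5 * t),
                                    sin(2 * pi * 7 * t)))
  expect_lt(g2$W[1, 2], 1e-6)
  # naive covariance/sd loop oracle
  set.seed(30)
  sig3 <- matrix(rnorm(3 * 1000), 3)
  g3 <- correlation_adjacency(sig3)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    xi <- sig3[i, ]; xj <- sig3[j, ]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(g3$W[i, j], abs(r), tolerance = 1e-12)
  }
  expect_error(correlation_adjacency(matrix(1, 3, 1)), "2 samples")
  expect_warning(correlation_adjacency(rbind(rep(1, 10), rnorm(10), rnorm(10))),
                 "constant")
})

test_that("sparsify thresholds, preserves symmetry, and is idempotent", {
  W <- matrix(c(0, .2, .5, .2, 0, .9, .5, .9, 0), 3)
  expect_identical(sparsify(W, 0), W)
  expect_equal(sparsify(W, 0.4), matrix(c(0, 0, .5, 0, 0, .9, .5, .9, 0), 3))
  expect_equal(suppressWarnings(sparsify(W, 1)), matrix(0, 3, 3))
  for (tau in c(0.1, 0.3, 0.6)) {
    s1 <- suppressWarnings(sparsify(W, tau))
    expect_identical(suppressWarnings(sparsify(s1, tau)), s1)
    expect_identical(s1, t(s1))
  }
  expect_error(sparsify(W, 1.5), "tau")
  expect_warning(sparsify(W, 0.95), "isolated")
})

test_that("complete unit-weight 3-node graph has eigenvalues (0, 3, 3)", {
  W <- matrix(1, 3, 3); diag(W) <- 0
  g <- laplacian(structure(list(W = W, tau = 0), class = "channel_graph"))
  expect_equal(g$L, 3 * diag(3) - matrix(1, 3, 3) , ignore_attr = TRUE)
  expect_equal(g$lambda, c(0, 3, 3), tolerance = 1e-10)
  expect_equal(crossprod(g$U), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("empty graph has a zero Laplacian and zero spectrum", {
  g <- laplacian(structure(list(W = matrix(0, 3, 3), tau = 0),
                           class = "channel_graph"))
  expect_equal(g$L, matrix(0, 3, 3))
  expect_equal(g$lambda, c(0, 0, 0))
})

test_that("Laplacian identities hold on random graphs", {
  for (seed in 1:20) {
    g <- random_graph(sample(3:8, 1), seed)
    expect_equal(rowSums(g$L), rep(0, nrow(g$L)), tolerance = 1e-12)
    expect_equal(max(abs(crossprod(g$U) - diag(nrow(g$L)))), 0, tolerance = 1e-10)
    expect_true(all(diff(g$lambda) >= -1e-12))
    expect_lt(abs(g$lambda[1]), 1e-9)
    set.seed(seed + 100)
    for (r in 1:5) {
      x <- rnorm(nrow(g$L))
      expect_gte(drop(t(x) %*% g$L %*% x), -1e-10)
    }
  }
  expect_error(laplacian(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("graph Fourier transform inverts and preserves norms", {
  g <- random_graph(5, 77)
  expect_equal(gft(1:5, diag(5)), matrix(1:5), ignore_attr = TRUE)
  set.seed(78)
  q <- matrix(rnorm(5 * 4), 5)
  expect_equal(igft(gft(q, g), g), q, tolerance = 1e-10)
  expect_equal(sqrt(colSums(gft(q, g)^2)), sqrt(colSums(q^2)), tolerance = 1e-10)
  expect_error(gft(1:4, g), "mismatch")
})

test_that("exact spectral filter reproduces identity, zero and Laplacian action", {
  g <- random_graph(4, 79)
  set.seed(80)
  x <- matrix(rnorm(4 * 6), 4)
  expect_equal(spectral_filter(x, function(l) 1, g), x, tolerance = 1e-10)
  expect_equal(spectral_filter(x, function(l) 0, g), matrix(0, 4, 6))
  expect_equal(spectral_filter(x, function(l) l, g), g$L %*% x, tolerance = 1e-10)
})

test_that("Chebyshev base cases: K = 1 identity scaling and zero coefficients", {
  g <- random_graph(3, 81)
  x <- matrix(rnorm(3 * 5), 3)
  expect_equal(cheb_filter(x, 1, g), x)
  expect_equal(cheb_filter(x, c(0, 0, 0), g), matrix(0, 3, 5))
  expect_error(cheb_filter(x, numeric(0), g), "coefficient")
})

test_that("Chebyshev filtering equals exact spectral filtering for polynomial responses", {
  # Chebyshev polynomials evaluated at scalar u by the same recurrence
  cheb_eval <- function(theta, u) {
    K <- length(theta)
    t0 <- 1; acc <- theta[1]
    if (K >= 2) {
      t1 <- u; acc <- acc + theta[2] * u
      if (K >= 3) for (k in 3:K) {
        t2 <- 2 * u * t1 - t0
        acc <- acc + theta[k] * t2
        t0 <- t1; t1 <- t2
      }
    }
    acc
  }
  worst <- 0
  for (seed in 1:500) {
    N <- 3 + seed %% 6
    g <- random_graph(N, seed + 1000)
    K <- 1 + seed %% 4
    set.seed(seed)
    theta <- rnorm(K)
    x <- matrix(rnorm(N * 3), N)
    y_cheb <- cheb_filter(x, theta, g)
    resp <- function(l) cheb_eval(theta, 2 * l / g$lambda_max - 1)
    y_exact <- spectral_filter(x, resp, g)
    worst <- max(worst, max(abs(y_cheb - y_exact)))
  }
  expect_lt(worst, 1e-8)
})

test_that("graphs round-trip bit-exactly through JSON", {
  g <- build_channel_graph(matrix(rnorm(3 * 500), 3,
                                  dimnames = list(c("C3", "C4", "Pz"), NULL)),
                           tau = 0.1)
  f <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, f)
  g2 <- read_graph_json(f)
  expect_identical(unname(g2$W), unname(g$W))
  expect_identical(g2$lambda, g$lambda)
})
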