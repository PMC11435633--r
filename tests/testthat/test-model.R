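unit_graph <- function() {
  W <- matrix(c(0, .5, .6, .5, 0, .7, .6, .7, 0), 3)
  laplacian(structure(list(W = W, tau = 0), class = "channel_graph"))
}

test_that("forward pass has the contracted shapes and softmax rows", {
  g <- unit_graph()
  m <- build_model(model_config(), g, seed = 1)
  set.seed(50)
  X <- array(rnorm(4 * 3 * 125), c(4, 3, 125))
  sc <- dfcgn_forward(m, X)
  expect_equal(dim(sc), c(4L, 3L))
  expect_equal(rowSums(sc), rep(1, 4), tolerance = 1e-6)
  expect_true(all(sc > 0 & sc < 1))
  m2 <- build_model(model_config(n_classes = 2), g, seed = 1)
  expect_equal(dim(dfcgn_forward(m2, X)), c(4L, 2L))
  expect_error(dfcgn_forward(m, array(0, c(2, 3, 64))), "does not match")
})

test_that("feature widths follow the floor-halving chain 125 -> 62 -> 31 -> 15 -> 7", {
  cfg <- model_config()
  expect_equal(cfg$f_in, c(125L, 62L, 31L, 15L))
  expect_equal(cfg$f_final, 7L)
  expect_equal(cfg$n_nodes * cfg$f_final, 21L)
})

test_that("all-zero head yields uniform scores", {
  g <- unit_graph()
  m <- build_model(model_config(), g, seed = 2)
  m$params$head_W[] <- 0
  m$params$head_b[] <- 0
  sc <- dfcgn_forward(m, array(rnorm(3 * 3 * 125), c(3, 3, 125)))
  expect_equal(sc, matrix(1 / 3, 3, 3), tolerance = 1e-12)
})

test_that("identical seeds give identical initial weights", {
  g <- unit_graph()
  m1 <- build_model(model_config(), g, seed = 7)
  m2 <- build_model(model_config(), g, seed = 7)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(model_config(), g, seed = 8)
  expect_false(identical(m1$params, m3$params))
})

test_that("parameter counts equal the shape products", {
  g <- unit_graph()
  m <- build_model(model_config(), g, seed = 1)
  # K * F_in * F_out + F_out per layer, plus the 21 -> 3 head
  expected <- sum(3 * c(125 * 125, 62 * 62, 31 * 31, 15 * 15) +
                  c(125, 62, 31, 15)) + 21 * 3 + 3
  expect_equal(count_parameters(m), expected)
  # single layer worked example: 3 * 125 * 125 + 125 cheb weights + bias
  m1 <- build_model(model_config(n_gconv_layers = 1, cheb_orders = 3), g, 1)
  expect_equal(count_parameters(m1),
               3 * 125 * 125 + 125 + (3 * 62) * 3 + 3)
})

test_that("eval-mode forward is a pure function", {
  g <- unit_graph()
  m <- build_model(model_config(), g, seed = 3)
  X <- array(rnorm(2 * 3 * 125), c(2, 3, 125))
  expect_identical(dfcgn_forward(m, X), dfcgn_forward(m, X))
})

test_that("node relabeling commutes with the network when weights follow", {
  g <- unit_graph()
  m <- build_model(model_config(), g, seed = 4)
  set.seed(51)
  X <- array(rnorm(2 * 3 * 125), c(2, 3, 125))
  sc <- dfcgn_forward(m, X)
  perm <- c(3, 1, 2)
  gp <- laplacian(structure(list(W = g$W[perm, perm], tau = 0),
                            class = "channel_graph"))
  mp <- build_model(model_config(), gp, seed = 4)
  mp$params <- m$params
  # eigen sign conventions do not matter here: filtering uses L only
  mp$Tk <- dfcgn:::cheb_basis(gp, 3)
  # permute the head rows: flatten layout is node-fastest
  headW <- m$params$head_W
  idx <- as.vector(outer(perm, (0:6) * 3, `+`))
  mp$params$head_W <- headW[idx, ]
  Xp <- X[, perm, , drop = FALSE]
  scp <- dfcgn_forward(mp, Xp)
  expect_equal(scp, sc, tolerance = 1e-10)
})

test_that("analytic gradients match numerical differentiation", {
  W <- matrix(c(0, .5, .6, .5, 0, .7, .6, .7, 0), 3)
  g <- laplacian(structure(list(W = W, tau = 0), class = "channel_graph"))
  mc <- model_config(n_gconv_layers = 2, cheb_orders = c(3, 2),
                     input_width = 12, dropout_rate = 0)
  m <- build_model(mc, g, seed = 5)
  set.seed(52)
  X <- array(rnorm(2 * 3 * 12), c(2, 3, 12))
  y <- c(1L, 3L)
  lossfn <- function(m) {
    sc <- dfcgn_forward(m, X)
    -mean(log(sc[cbind(1:2, y)]))
  }
  fw <- dfcgn_forward(m, X, with_cache = TRUE)
  lg <- dfcgn:::loss_and_grad(fw$scores, y, "cross_entropy")
  gr <- dfcgn:::dfcgn_backward(m, lg$dlogits, fw$cache)
  eps <- 1e-6
  for (nm in names(m$params)) {
    P <- m$params[[nm]]
    for (i in sample(length(P), min(20, length(P)))) {
      mp <- m; mp$params[[nm]][i] <- P[i] + eps
      mm <- m; mm$params[[nm]][i] <- P[i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      ana <- gr[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("misconfigured models are rejected", {
  g <- unit_graph()
  expect_error(model_config(dropout_rate = 1), "dropout")
  expect_error(model_config(cheb_orders = c(3, 3)), "per layer")
  expect_error(model_config(input_width = 8, n_gconv_layers = 4), "exhausts")
  expect_error(build_model(model_config(n_nodes = 4), g), "nodes")
})
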