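# Scaled Laplacian, Chebyshev filtering (recurrence vs explicit spectral
# oracle), convolution layers and the status-code encoder.

# explicit spectral-domain filter: U T_k(diag(lambda)) U' X
spectral_oracle <- function(Ls, X, K) {
  eg <- eigen(Ls, symmetric = TRUE)
  lapply(seq_len(K) - 1L, function(k) {
    tk <- cos(k * acos(pmin(pmax(eg$values, -1), 1)))
    eg$vectors %*% diag(tk, length(tk)) %*% t(eg$vectors) %*% X
  })
}

test_that("two-node unit-edge graph has the closed-form spectrum", {
  sp <- scaled_laplacian(matrix(c(0, 1, 1, 0), 2))
  expect_equal(sp$laplacian, matrix(c(1, -1, -1, 1), 2))
  expect_equal(sp$lambda_max, 2)
  expect_equal(sp$scaled_laplacian, matrix(c(0, -1, -1, 0), 2))
})

test_that("edgeless graph degenerates to L = 0 and scaled Laplacian -I", {
  sp <- scaled_laplacian(matrix(0, 3, 3))
  expect_equal(sp$laplacian, matrix(0, 3, 3))
  expect_equal(sp$lambda_max, 1e-6)
  expect_equal(sp$scaled_laplacian, -diag(3))
})

test_that("scaled Laplacian spectrum stays within [-1, 1]", {
  set.seed(12)
  for (i in 1:20) {
    A <- random_adjacency(sample(2:12, 1))
    sp <- scaled_laplacian(A)
    ev <- eigen(sp$scaled_laplacian, symmetric = TRUE, only.values = TRUE)
    expect_true(all(abs(ev$values) <= 1 + 1e-9))
  }
})

test_that("invalid adjacencies are rejected", {
  expect_error(scaled_laplacian(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(scaled_laplacian(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
  expect_error(scaled_laplacian(matrix(c(1, 0, 0, 1), 2)), "diagonal")
})

test_that("Chebyshev recurrence equals the spectral-domain oracle", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(2:10, 1)
    A <- random_adjacency(n)
    sp <- scaled_laplacian(A)
    X <- matrix(rnorm(n * 3), n)
    for (K in c(1, 3, 5)) {
      got <- chebyshev_basis(sp, X, K)
      want <- spectral_oracle(sp$scaled_laplacian, X, K)
      for (k in seq_len(K)) {
        expect_lt(max(abs(got[[k]] - want[[k]])), 1e-9)
      }
    }
  }
})

test_that("order-1 basis is the features; 2-node toy matches by hand", {
  sp <- scaled_laplacian(matrix(c(0, 1, 1, 0), 2))
  X <- matrix(c(1, 0), 2)
  expect_identical(chebyshev_basis(sp, X, 1), list(X))
  b <- chebyshev_basis(sp, X, 2)
  expect_equal(b[[2]], matrix(c(0, -1), 2))
})

test_that("convolution layer reduces to ReLU for identity theta, K=1", {
  set.seed(7)
  A <- random_adjacency(4)
  sp <- scaled_laplacian(A)
  X <- matrix(rnorm(8), 4)
  expect_equal(cheb_conv_layer(X, sp, list(matrix(0, 2, 3))),
               matrix(0, 4, 3))
  expect_equal(cheb_conv_layer(X, sp, list(diag(2))), pmax(X, 0))
})

test_that("two-term convolution matches the hand expansion", {
  A <- matrix(c(0, 1, 0, 1, 0, 0.5, 0, 0.5, 0), 3)
  sp <- scaled_laplacian(A)
  X <- matrix(c(1, -1, 2, 0, 1, 1), 3)
  th0 <- matrix(c(1, 0, 0, 1), 2)
  th1 <- matrix(c(0.5, -0.5, 0.25, 0), 2)
  want <- pmax(X %*% th0 + (sp$scaled_laplacian %*% X) %*% th1, 0)
  expect_equal(cheb_conv_layer(X, sp, list(th0, th1)), want,
               tolerance = 1e-12)
})

test_that("convolution layers are permutation equivariant (pre-FC)", {
  set.seed(41)
  n <- 6
  A <- random_adjacency(n)
  sp <- scaled_laplacian(A)
  X <- matrix(rnorm(n * 4), n)
  theta <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2),
                matrix(rnorm(8), 4, 2))
  p <- sample(n)
  out <- cheb_conv_layer(X, sp, theta)
  outp <- cheb_conv_layer(X[p, ], scaled_laplacian(A[p, p]), theta)
  expect_equal(outp, out[p, ], tolerance = 1e-9)
})

test_that("encoder emits an 18-value status code for 18-channel graphs", {
  cfg <- sim_config()
  seg <- generate_segment("pre_ictal", cfg, seed = 6)
  g <- segment_graph(seg)
  params <- encoder_params(seed = 13)
  s <- encode_status(g, params, window_index = 4L)
  expect_length(s, 18)
  expect_identical(attr(s, "window_index"), 4L)
})

test_that("zero node features with zero fc bias encode to zero", {
  cfg <- small_sim()
  seg <- generate_segment("pre_ictal", cfg, seed = 2)
  g <- segment_graph(seg)
  g$node_features <- matrix(0, 4, 16)
  params <- encoder_params(n_channels = 4, seed = 3)
  expect_equal(unname(as.numeric(encode_status(g, params))), rep(0, 4))
})

test_that("encode_status equals the composition of its layer primitives", {
  cfg <- small_sim()
  seg <- generate_segment("inter_ictal", cfg, seed = 17)
  g <- segment_graph(seg)
  params <- encoder_params(n_channels = 4, hidden = c(6, 5), order_K = 3,
                           seed = 19)
  sp <- scaled_laplacian(g$adjacency)
  O1 <- cheb_conv_layer(g$node_features, sp, params$theta1)
  O2 <- cheb_conv_layer(O1, sp, params$theta2)
  want <- drop(matrix(as.vector(O2), 1) %*% params$fc_w) + params$fc_b
  got <- encode_status(g, params)
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
})
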