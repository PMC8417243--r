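# Training loop: gradient correctness, batch/primitive consistency,
# determinism, and descent on separable data.

tiny_training_setup <- function() {
  cfg <- small_sim()
  segs <- make_dataset(cfg, 6, seed = 11)
  tc <- train_config(seq_len = 3, order_K = 3, hidden = c(5, 4),
                     gru_hidden = 6, mlp_hidden = 3, lambda_reg = 1e-3)
  fz <- featurize_segments(segs, tc)
  arch <- list(n_channels = fz$n_channels, in_dim = fz$in_dim,
               hidden = tc$hidden, order_K = tc$order_K,
               gru_hidden = tc$gru_hidden, mlp_hidden = tc$mlp_hidden)
  seqs <- seizecast:::.build_sequences(fz$labels, seq_along(segs), 3, 1)
  list(cfg = tc, fz = fz, arch = arch, seqs = seqs)
}

test_that("analytic gradients match numerical differentiation", {
  su <- tiny_training_setup()
  set.seed(5)
  P <- seizecast:::.init_params(su$arch)
  batch <- seizecast:::.assemble_batch(su$fz, su$seqs, c(1, 3, 6, 8),
                                       su$arch$order_K)
  fw <- seizecast:::.forward_batch(P, batch, su$arch, 1e-3)
  G <- seizecast:::.backward_batch(P, batch, su$arch, 1e-3, fw)
  g <- seizecast:::.flatten_params(G)
  th <- seizecast:::.flatten_params(P)
  f <- function(v) {
    seizecast:::.forward_batch(seizecast:::.unflatten_params(v, P), batch,
                               su$arch, 1e-3)$loss
  }
  set.seed(9)
  pick <- sample(length(th), 60)
  num <- vapply(pick, function(i) {
    e <- rep(0, length(th)); e[i] <- 1e-5
    (f(th + e) - f(th - e)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(num - g[pick]) / pmax(abs(num), 1e-4)), 1e-5)
})

test_that("the batched forward pass equals the layer primitives", {
  su <- tiny_training_setup()
  set.seed(6)
  P <- seizecast:::.init_params(su$arch)
  batch <- seizecast:::.assemble_batch(su$fz, su$seqs, c(2, 5),
                                       su$arch$order_K)
  fw <- seizecast:::.forward_batch(P, batch, su$arch, 0)

  enc <- structure(list(theta1 = P[paste0("th1_", 1:3)],
                        theta2 = P[paste0("th2_", 1:3)],
                        fc_w = P$fc_w, fc_b = P$fc_b, order_K = 3L,
                        n_channels = su$arch$n_channels,
                        in_dim = su$arch$in_dim, hidden = su$arch$hidden),
                   class = "encoder_params")
  names(enc$theta1) <- names(enc$theta2) <- NULL
  gru <- structure(c(P[c("W_r", "U_r", "W_z", "U_z", "W", "U")],
                     list(input_size = su$arch$n_channels,
                          hidden_size = su$arch$gru_hidden)),
                   class = "gru_params")
  mlp <- structure(list(W1 = P$W1m, b1 = P$b1m, W2 = P$W2m, b2 = P$b2m,
                        hidden_size = su$arch$gru_hidden,
                        mlp_hidden = su$arch$mlp_hidden),
                   class = "mlp_params")

  for (bi in 1:2) {
    sq <- su$seqs[[c(2, 5)[bi]]]
    codes <- lapply(sq$windows, function(w) {
      feat <- su$fz$features[[w]]
      g <- structure(list(adjacency = NULL, node_features = feat$X),
                     class = "channel_graph")
      # encode via primitives on the precomputed spectrum
      sp <- structure(list(scaled_laplacian = feat$L,
                           laplacian = NULL, lambda_max = NULL),
                      class = "graph_spectrum")
      O1 <- cheb_conv_layer(feat$X, sp, enc$theta1)
      O2 <- cheb_conv_layer(O1, sp, enc$theta2)
      drop(matrix(as.vector(O2), 1) %*% enc$fc_w) + enc$fc_b
    })
    state <- run_sequence(codes, gru)
    out <- mlp_predict(state, mlp)
    expect_equal(unname(out$probabilities),
                 unname(fw$Pr[bi, ]), tolerance = 1e-10)
  }
})

test_that("same seed reproduces the loss history exactly", {
  cfg <- small_sim()
  segs <- make_dataset(cfg, 8, seed = 20)
  tc <- train_config(epochs = 3, seq_len = 3, seed = 42,
                     hidden = c(8, 8), gru_hidden = 8, mlp_hidden = 4)
  m1 <- train_model(segs, tc)
  m2 <- train_model(segs, tc)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
})

test_that("training descends on separable synthetic data", {
  cfg <- small_sim()
  segs <- make_dataset(cfg, 20, seed = 30)
  tc <- train_config(epochs = 10, seq_len = 3, seed = 7,
                     hidden = c(8, 8), gru_hidden = 8, mlp_hidden = 4)
  m <- train_model(segs, tc)
  expect_length(m$loss_history, 10)
  expect_lt(m$loss_history[10], m$loss_history[1])
  ev <- evaluate_model(m)
  expect_equal(ev$counts$total, nrow(ev$predictions))
  expect_true(all(c("predictions", "counts", "metrics") %in% names(ev)))
})

test_that("sequence blocking keeps every window on one side of the split", {
  cfg <- small_sim()
  segs <- make_dataset(cfg, 10, seed = 40)
  tc <- train_config(epochs = 1, seq_len = 3, seed = 1, hidden = c(4, 4),
                     gru_hidden = 4, mlp_hidden = 3)
  m <- train_model(segs, tc)
  tr <- unique(unlist(lapply(m$train_sequences, `[[`, "windows")))
  te <- unique(unlist(lapply(m$test_sequences, `[[`, "windows")))
  expect_length(intersect(tr, te), 0)
})

test_that("single-class datasets are rejected", {
  cfg <- small_sim()
  segs <- lapply(1:6, function(i) generate_segment("pre_ictal", cfg, i))
  expect_error(train_model(segs, train_config(epochs = 1)), "both classes")
})
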