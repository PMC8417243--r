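# End-to-end training of the graph encoder + recurrent predictor.
#
# The per-window graph quantities never change during training, so
# featurization precomputes, per window, the node features X, the rescaled
# Laplacian, and the Chebyshev basis T_k(Ls) X of the first convolution
# layer. A training batch stacks B sequences x T windows into one tall node
# matrix; the windows' Laplacians become one sparse block-diagonal operator,
# so every layer is a handful of large matrix products. Gradients are
# hand-derived (verified against numerical differentiation in the test
# suite) and optimized with Adam on the flattened parameter vector.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.01).
#' @param lambda_reg L2 regularization strength on weight matrices (biases
#'   excluded; default 5e-4).
#' @param epochs Training epochs (default 50).
#' @param batch_size Sequences per batch (default 32).
#' @param seed Master seed for initialization and batch shuffling.
#' @param split_fraction Held-out fraction for evaluation (default 0.3).
#' @param seq_len Consecutive windows per prediction; the sequence label is
#'   the label of its last window (default 5).
#' @param seq_stride Stride between sequence starts within a labeled run
#'   (default 1).
#' @param order_K Chebyshev order (default 3).
#' @param hidden Convolution layer widths (default `c(32, 32)`).
#' @param gru_hidden GRU state width (default 32).
#' @param mlp_hidden MLP hidden width (default 16).
#' @param depth Wavelet-packet depth (default 4).
#' @param wavelet Wavelet name (default `"db4"`).
#' @param graph_mode Correlation input mode for [build_channel_graph()].
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, lambda_reg = 5e-4,
                         epochs = 50, batch_size = 32, seed = 1,
                         split_fraction = 0.3, seq_len = 5, seq_stride = 1,
                         order_K = 3, hidden = c(32, 32), gru_hidden = 32,
                         mlp_hidden = 16, depth = 4, wavelet = "db4",
                         graph_mode = "energy_vectors") {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, lambda_reg = lambda_reg,
                 epochs = epochs, batch_size = batch_size, seed = seed,
                 split_fraction = split_fraction, seq_len = seq_len,
                 seq_stride = seq_stride, order_K = order_K,
                 hidden = hidden, gru_hidden = gru_hidden,
                 mlp_hidden = mlp_hidden, depth = depth, wavelet = wavelet,
                 graph_mode = graph_mode),
            class = "train_config")
}

#' Precompute per-window graph features for training
#'
#' For each segment: relative band-energy node features, the rescaled
#' normalized Laplacian of its correlation graph, and the Chebyshev basis
#' applied to the node features.
#'
#' @param segments List of `eeg_segment` objects.
#' @param cfg A [train_config()].
#' @return List with `features` (per segment: `X`, `L`, `B`), `labels`,
#'   `n_channels`, `in_dim`.
#' @export
featurize_segments <- function(segments, cfg = train_config()) {
  feats <- lapply(segments, function(seg) {
    g <- segment_graph(seg, depth = cfg$depth, wavelet = cfg$wavelet,
                       mode = cfg$graph_mode)
    spec <- scaled_laplacian(g$adjacency)
    X <- unname(g$node_features)
    list(X = X, L = spec$scaled_laplacian,
         B = chebyshev_basis(spec, X, cfg$order_K))
  })
  labels <- vapply(segments, `[[`, "", "label")
  list(features = feats, labels = labels,
       n_channels = nrow(feats[[1]]$X), in_dim = ncol(feats[[1]]$X))
}

# Sequences of seq_len consecutive windows within runs of constant label,
# restricted to the given (ordered) segment indices.
.build_sequences <- function(labels, indices, seq_len, stride) {
  seqs <- list()
  if (length(indices) == 0) return(seqs)
  lab <- labels[indices]
  run_start <- 1L
  for (i in seq_along(indices)) {
    end_run <- i == length(indices) || lab[i + 1L] != lab[i]
    if (end_run) {
      run <- indices[run_start:i]
      if (length(run) >= seq_len) {
        starts <- seq(1L, length(run) - seq_len + 1L, by = stride)
        for (s0 in starts) {
          seqs[[length(seqs) + 1L]] <-
            list(windows = run[s0:(s0 + seq_len - 1L)], label = lab[i])
        }
      }
      run_start <- i + 1L
    }
  }
  seqs
}

.init_params <- function(arch) {
  K <- arch$order_K
  P <- list()
  for (k in seq_len(K)) P[[paste0("th1_", k)]] <- .glorot(arch$in_dim,
                                                          arch$hidden[1])
  for (k in seq_len(K)) P[[paste0("th2_", k)]] <- .glorot(arch$hidden[1],
                                                          arch$hidden[2])
  P$fc_w <- .glorot(arch$n_channels * arch$hidden[2], arch$n_channels)
  P$fc_b <- rep(0, arch$n_channels)
  P$W_r <- .glorot(arch$n_channels, arch$gru_hidden)
  P$U_r <- .glorot(arch$gru_hidden, arch$gru_hidden)
  P$W_z <- .glorot(arch$n_channels, arch$gru_hidden)
  P$U_z <- .glorot(arch$gru_hidden, arch$gru_hidden)
  P$W <- .glorot(arch$n_channels, arch$gru_hidden)
  P$U <- .glorot(arch$gru_hidden, arch$gru_hidden)
  P$W1m <- .glorot(arch$gru_hidden, arch$mlp_hidden)
  P$b1m <- rep(0, arch$mlp_hidden)
  P$W2m <- .glorot(arch$mlp_hidden, 2)
  P$b2m <- rep(0, 2)
  P
}

.bias_names <- c("fc_b", "b1m", "b2m")

# Stack a batch of sequences: window order is t-major (all sequences' step-1
# windows, then step-2, ...), matching the GRU's row blocks.
.assemble_batch <- function(fz, seqs, idx, K) {
  Tn <- length(seqs[[idx[1]]]$windows)
  worder <- unlist(lapply(seq_len(Tn), function(t) {
    vapply(idx, function(b) seqs[[b]]$windows[t], integer(1))
  }))
  feats <- fz$features
  Bstack <- lapply(seq_len(K), function(k) {
    do.call(rbind, lapply(worder, function(w) feats[[w]]$B[[k]]))
  })
  Lblk <- Matrix::bdiag(lapply(worder, function(w) feats[[w]]$L))
  y <- vapply(idx, function(b) {
    if (seqs[[b]]$label == "pre_ictal") 1L else 0L
  }, integer(1))
  list(Bstack = Bstack, Lblk = Lblk, y = y, B = length(idx), Tn = Tn,
       n = fz$n_channels)
}

.forward_batch <- function(P, batch, arch, lambda) {
  K <- arch$order_K
  n <- batch$n; Bn <- batch$B; Tn <- batch$Tn
  BT <- Bn * Tn
  H1 <- arch$hidden[1]; H2 <- arch$hidden[2]

  Z1 <- batch$Bstack[[1]] %*% P$th1_1
  if (K >= 2) for (k in 2:K) Z1 <- Z1 + batch$Bstack[[k]] %*%
      P[[paste0("th1_", k)]]
  A1 <- pmax(Z1, 0)

  C <- vector("list", K)
  C[[1]] <- A1
  if (K >= 2) C[[2]] <- as.matrix(batch$Lblk %*% A1)
  if (K >= 3) for (k in 3:K) {
    C[[k]] <- 2 * as.matrix(batch$Lblk %*% C[[k - 1]]) - C[[k - 2]]
  }
  Z2 <- C[[1]] %*% P$th2_1
  if (K >= 2) for (k in 2:K) Z2 <- Z2 + C[[k]] %*% P[[paste0("th2_", k)]]
  A2 <- pmax(Z2, 0)

  Fm <- matrix(aperm(array(A2, c(n, BT, H2)), c(2, 1, 3)), nrow = BT)
  S <- Fm %*% P$fc_w + matrix(P$fc_b, BT, n, byrow = TRUE)

  gh <- arch$gru_hidden
  Cst <- matrix(0, Bn, gh)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    St <- S[((t - 1L) * Bn + 1L):(t * Bn), , drop = FALSE]
    R <- .sigmoid(St %*% P$W_r + Cst %*% P$U_r)
    N <- .sigmoid(St %*% P$W_z + Cst %*% P$U_z)
    M <- Cst %*% P$U
    Ctil <- tanh(St %*% P$W + R * M)
    Cnew <- (1 - N) * Cst + N * Ctil
    steps[[t]] <- list(St = St, R = R, N = N, M = M, Ctil = Ctil,
                       C_prev = Cst)
    Cst <- Cnew
  }

  Zh <- Cst %*% P$W1m + matrix(P$b1m, Bn, arch$mlp_hidden, byrow = TRUE)
  Hh <- pmax(Zh, 0)
  logits <- Hh %*% P$W2m + matrix(P$b2m, Bn, 2, byrow = TRUE)
  lmax <- apply(logits, 1, max)
  ez <- exp(logits - lmax)
  Pr <- ez / rowSums(ez)

  ce <- -mean(log(pmax(Pr[cbind(seq_len(Bn), batch$y + 1L)], 1e-12)))
  l2 <- 0
  for (nm in names(P)) {
    if (is.matrix(P[[nm]]) && !(nm %in% .bias_names)) {
      l2 <- l2 + sum(P[[nm]]^2)
    }
  }
  loss <- ce + lambda / 2 * l2
  list(loss = loss, ce = ce, Pr = Pr,
       cache = list(Z1 = Z1, A1 = A1, C = C, Z2 = Z2, A2 = A2, Fm = Fm,
                    S = S, steps = steps, C_T = Cst, Zh = Zh, Hh = Hh,
                    logits = logits))
}

.backward_batch <- function(P, batch, arch, lambda, fw) {
  K <- arch$order_K
  n <- batch$n; Bn <- batch$B; Tn <- batch$Tn
  BT <- Bn * Tn
  H2 <- arch$hidden[2]
  ch <- fw$cache
  G <- list()

  Y <- matrix(0, Bn, 2)
  Y[cbind(seq_len(Bn), batch$y + 1L)] <- 1
  dlogits <- (fw$Pr - Y) / Bn
  G$W2m <- t(ch$Hh) %*% dlogits + lambda * P$W2m
  G$b2m <- colSums(dlogits)
  dH <- dlogits %*% t(P$W2m)
  dZh <- dH * (ch$Zh > 0)
  G$W1m <- t(ch$C_T) %*% dZh + lambda * P$W1m
  G$b1m <- colSums(dZh)
  dC <- dZh %*% t(P$W1m)

  gW_r <- 0 * P$W_r; gU_r <- 0 * P$U_r
  gW_z <- 0 * P$W_z; gU_z <- 0 * P$U_z
  gW <- 0 * P$W; gU <- 0 * P$U
  dS <- matrix(0, BT, n)
  for (t in rev(seq_len(Tn))) {
    st <- ch$steps[[t]]
    dN <- dC * (st$Ctil - st$C_prev)
    dCtil <- dC * st$N
    dZc <- dCtil * (1 - st$Ctil^2)
    dR <- dZc * st$M
    dM <- dZc * st$R
    dZr <- dR * st$R * (1 - st$R)
    dZn <- dN * st$N * (1 - st$N)
    gW <- gW + t(st$St) %*% dZc
    gU <- gU + t(st$C_prev) %*% dM
    gW_r <- gW_r + t(st$St) %*% dZr
    gU_r <- gU_r + t(st$C_prev) %*% dZr
    gW_z <- gW_z + t(st$St) %*% dZn
    gU_z <- gU_z + t(st$C_prev) %*% dZn
    dS[((t - 1L) * Bn + 1L):(t * Bn), ] <-
      dZc %*% t(P$W) + dZr %*% t(P$W_r) + dZn %*% t(P$W_z)
    dC <- dC * (1 - st$N) + dM %*% t(P$U) + dZr %*% t(P$U_r) +
      dZn %*% t(P$U_z)
  }
  G$W_r <- gW_r + lambda * P$W_r; G$U_r <- gU_r + lambda * P$U_r
  G$W_z <- gW_z + lambda * P$W_z; G$U_z <- gU_z + lambda * P$U_z
  G$W <- gW + lambda * P$W; G$U <- gU + lambda * P$U

  G$fc_w <- t(ch$Fm) %*% dS + lambda * P$fc_w
  G$fc_b <- colSums(dS)
  dFm <- dS %*% t(P$fc_w)
  dA2 <- matrix(aperm(array(dFm, c(BT, n, H2)), c(2, 1, 3)), nrow = n * BT)
  dZ2 <- dA2 * (ch$Z2 > 0)
  for (k in seq_len(K)) {
    G[[paste0("th2_", k)]] <- t(ch$C[[k]]) %*% dZ2 +
      lambda * P[[paste0("th2_", k)]]
  }
  # adjoint of the Chebyshev recurrence (Lblk symmetric)
  dCk <- lapply(seq_len(K), function(k) dZ2 %*% t(P[[paste0("th2_", k)]]))
  if (K >= 3) for (k in K:3) {
    dCk[[k - 1]] <- dCk[[k - 1]] + 2 * as.matrix(batch$Lblk %*% dCk[[k]])
    dCk[[k - 2]] <- dCk[[k - 2]] - dCk[[k]]
  }
  if (K >= 2) dCk[[1]] <- dCk[[1]] + as.matrix(batch$Lblk %*% dCk[[2]])
  dA1 <- dCk[[1]]
  dZ1 <- dA1 * (ch$Z1 > 0)
  for (k in seq_len(K)) {
    G[[paste0("th1_", k)]] <- t(batch$Bstack[[k]]) %*% dZ1 +
      lambda * P[[paste0("th1_", k)]]
  }
  G[names(P)]
}

.flatten_params <- function(P) unlist(P, use.names = FALSE)

.unflatten_params <- function(v, skeleton) {
  out <- skeleton
  pos <- 0L
  for (nm in names(skeleton)) {
    len <- length(skeleton[[nm]])
    chunk <- v[(pos + 1L):(pos + len)]
    if (is.matrix(skeleton[[nm]])) {
      out[[nm]] <- matrix(chunk, nrow(skeleton[[nm]]),
                          ncol(skeleton[[nm]]))
    } else {
      out[[nm]] <- chunk
    }
    pos <- pos + len
  }
  out
}

#' Train the encoder + predictor end to end
#'
#' Featurizes the segments, makes a stratified sequence-blocked train/test
#' split (all windows of a sequence fall on one side; within each class the
#' held-out block is the tail of the segment list), and minimizes the
#' cross-entropy + L2 loss with Adam. Deterministic given the configuration
#' seed.
#'
#' @param segments List of labeled `eeg_segment` objects (both classes
#'   required).
#' @param cfg A [train_config()].
#' @return Object of class `seizecast_model`: trained parameters, per-epoch
#'   loss history, the featurized windows and the train/test sequence
#'   split.
#' @export
train_model <- function(segments, cfg = train_config()) {
  labels <- vapply(segments, `[[`, "", "label")
  if (length(unique(labels)) < 2) {
    stop("dataset must contain both classes", call. = FALSE)
  }
  fz <- featurize_segments(segments, cfg)
  arch <- list(n_channels = fz$n_channels, in_dim = fz$in_dim,
               hidden = cfg$hidden, order_K = cfg$order_K,
               gru_hidden = cfg$gru_hidden, mlp_hidden = cfg$mlp_hidden)

  train_idx <- integer(0); test_idx <- integer(0)
  for (cl in unique(labels)) {
    ci <- which(labels == cl)
    n_tr <- floor((1 - cfg$split_fraction) * length(ci))
    train_idx <- c(train_idx, ci[seq_len(n_tr)])
    test_idx <- c(test_idx, ci[setdiff(seq_along(ci), seq_len(n_tr))])
  }
  train_idx <- sort(train_idx); test_idx <- sort(test_idx)
  train_seqs <- .build_sequences(fz$labels, train_idx, cfg$seq_len,
                                 cfg$seq_stride)
  test_seqs <- .build_sequences(fz$labels, test_idx, cfg$seq_len,
                                cfg$seq_stride)
  if (length(train_seqs) == 0) {
    stop("no training sequences: need at least seq_len (", cfg$seq_len,
         ") consecutive windows per class", call. = FALSE)
  }

  res <- .with_seed(cfg$seed, {
    P <- .init_params(arch)
    skel <- P
    theta <- .flatten_params(P)
    m <- v <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    history <- numeric(cfg$epochs)
    n_seq <- length(train_seqs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_seq)
      ep_loss <- 0; ep_n <- 0L
      for (b0 in seq(1L, n_seq, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n_seq)]
        batch <- .assemble_batch(fz, train_seqs, idx, cfg$order_K)
        P <- .unflatten_params(theta, skel)
        fw <- .forward_batch(P, batch, arch, cfg$lambda_reg)
        G <- .backward_batch(P, batch, arch, cfg$lambda_reg, fw)
        g <- .flatten_params(G)
        step <- step + 1L
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mh <- m / (1 - b1^step)
        vh <- v / (1 - b2^step)
        theta <- theta - cfg$learning_rate * mh / (sqrt(vh) + eps)
        ep_loss <- ep_loss + fw$loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      history[ep] <- ep_loss / ep_n
    }
    list(P = .unflatten_params(theta, skel), history = history)
  })

  structure(list(params = res$P, arch = arch, config = cfg,
                 loss_history = res$history, features = fz,
                 train_sequences = train_seqs, test_sequences = test_seqs),
            class = "seizecast_model")
}

#' @export
print.seizecast_model <- function(x, ...) {
  cat(sprintf(paste0("<seizecast_model: %d-channel graphs, K=%d, ",
                     "%d train / %d test sequences, final loss %.4f>\n"),
              x$arch$n_channels, x$arch$order_K,
              length(x$train_sequences), length(x$test_sequences),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

# Forward pass without loss, on an arbitrary sequence list.
.predict_sequences <- function(model, seqs) {
  if (length(seqs) == 0) {
    return(data.frame(p_inter = numeric(0), p_pre = numeric(0),
                      predicted = character(0), truth = character(0)))
  }
  batch <- .assemble_batch(model$features, seqs, seq_along(seqs),
                           model$arch$order_K)
  fw <- .forward_batch(model$params, batch, model$arch, 0)
  pred <- ifelse(fw$Pr[, 2] > fw$Pr[, 1], "pre_ictal", "inter_ictal")
  data.frame(p_inter = fw$Pr[, 1], p_pre = fw$Pr[, 2], predicted = pred,
             truth = vapply(seqs, `[[`, "", "label"),
             stringsAsFactors = FALSE)
}

#' Evaluate a trained model on its held-out sequences
#'
#' @param model A [train_model()] result.
#' @param sequences Sequence list to evaluate (default: the model's
#'   held-out test sequences).
#' @return List with `predictions` (data frame), `counts`
#'   ([confusion_counts()]) and `metrics` ([compute_metrics()]).
#' @export
evaluate_model <- function(model, sequences = model$test_sequences) {
  stopifnot(inherits(model, "seizecast_model"))
  preds <- .predict_sequences(model, sequences)
  if (nrow(preds) == 0) stop("no sequences to evaluate", call. = FALSE)
  counts <- confusion_counts(preds$predicted, preds$truth)
  list(predictions = preds, counts = counts,
       metrics = compute_metrics(counts))
}
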