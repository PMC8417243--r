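# Chebyshev spectral graph convolution encoder. The filter acts on the
# rescaled symmetric normalized Laplacian (spectrum in [-1, 1]) through the
# Chebyshev recurrence T_k = 2 x T_{k-1} - T_{k-2}, so no eigendecomposition
# is needed at filtering time; two stacked convolution layers with ReLU feed
# a fully connected layer that emits one status-code value per channel.

.check_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square", call. = FALSE)
  if (any(A < 0)) stop("adjacency must be nonnegative", call. = FALSE)
  if (max(abs(A - t(A))) > 1e-9) stop("adjacency must be symmetric",
                                      call. = FALSE)
  if (any(abs(diag(A)) > 1e-12)) stop("adjacency diagonal must be zero",
                                      call. = FALSE)
  A
}

#' Scaled normalized graph Laplacian and spectrum
#'
#' Computes the symmetric normalized Laplacian
#' `L = I - D^{-1/2} A D^{-1/2}`, its largest eigenvalue (by dense
#' eigendecomposition; channel graphs are small), and the rescaled form
#' `2 L / lambda_max - I` whose spectrum lies in `[-1, 1]`. Rows/columns of
#' isolated (degree-zero) nodes are zero, so an edgeless graph has `L = 0`;
#' `lambda_max` is floor-clamped at `1e-6`, making the rescaled Laplacian
#' `-I` in that degenerate case.
#'
#' @param adjacency Symmetric nonnegative matrix with zero diagonal.
#' @return Object of class `graph_spectrum`: list with `laplacian`,
#'   `lambda_max`, `scaled_laplacian`.
#' @export
scaled_laplacian <- function(adjacency) {
  A <- .check_adjacency(adjacency)
  d <- rowSums(A)
  dm <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -(dm %o% dm) * A
  diag(L) <- ifelse(d > 0, 1, 0)
  lam <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  lam <- max(lam, 1e-6)
  Ls <- (2 / lam) * L
  diag(Ls) <- diag(Ls) - 1
  structure(list(laplacian = L, lambda_max = lam, scaled_laplacian = Ls),
            class = "graph_spectrum")
}

#' Chebyshev polynomial basis applied to node features
#'
#' Returns `T_k(Ls) X` for `k = 0 .. order_K - 1` via the recurrence
#' `T_0 X = X`, `T_1 X = Ls X`, `T_k X = 2 Ls T_{k-1} X - T_{k-2} X`, where
#' `Ls` is the rescaled Laplacian.
#'
#' @param spec A [scaled_laplacian()] result.
#' @param X Node-feature matrix (nodes x features).
#' @param order_K Number of polynomial terms (>= 1).
#' @return List of `order_K` matrices, each the shape of `X`.
#' @export
chebyshev_basis <- function(spec, X, order_K) {
  stopifnot(inherits(spec, "graph_spectrum"))
  X <- as.matrix(X)
  if (nrow(X) != nrow(spec$scaled_laplacian)) {
    stop("X row count must equal graph size", call. = FALSE)
  }
  if (order_K < 1) stop("order_K must be >= 1", call. = FALSE)
  out <- vector("list", order_K)
  out[[1]] <- X
  if (order_K >= 2) out[[2]] <- spec$scaled_laplacian %*% X
  if (order_K >= 3) {
    for (k in 3:order_K) {
      out[[k]] <- 2 * (spec$scaled_laplacian %*% out[[k - 1]]) - out[[k - 2]]
    }
  }
  out
}

#' One Chebyshev graph convolution layer with ReLU
#'
#' Computes `ReLU(sum_k T_k(Ls) X theta_k)`: a learnable mixing matrix per
#' polynomial order.
#'
#' @param X Node features (nodes x in_width).
#' @param spec A [scaled_laplacian()] result.
#' @param theta List of `K` matrices, each in_width x out_width.
#' @return Activated output matrix (nodes x out_width).
#' @export
cheb_conv_layer <- function(X, spec, theta) {
  if (!is.list(theta) || length(theta) < 1) {
    stop("theta must be a nonempty list of mixing matrices", call. = FALSE)
  }
  K <- length(theta)
  basis <- chebyshev_basis(spec, X, K)
  if (ncol(basis[[1]]) != nrow(theta[[1]])) {
    stop("theta rows (", nrow(theta[[1]]), ") must match feature width (",
         ncol(basis[[1]]), ")", call. = FALSE)
  }
  O <- basis[[1]] %*% theta[[1]]
  if (K >= 2) for (k in 2:K) O <- O + basis[[k]] %*% theta[[k]]
  pmax(O, 0)
}

.glorot <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

#' Initialize graph state encoder parameters
#'
#' Two Chebyshev convolution layers followed by a fully connected layer
#' mapping the flattened node representation to one value per channel
#' (the status code). Glorot-uniform initialization.
#'
#' @param n_channels Graph size and status-code length (default 18).
#' @param in_dim Node-feature width (default 16 sub-bands).
#' @param hidden Widths of the two convolution layers (default `c(32, 32)`).
#' @param order_K Chebyshev order (default 3).
#' @param seed Optional seed (draws from the current RNG stream if `NULL`).
#' @return Object of class `encoder_params`.
#' @export
encoder_params <- function(n_channels = 18, in_dim = 16,
                           hidden = c(32, 32), order_K = 3, seed = NULL) {
  if (order_K < 1) stop("order_K must be >= 1", call. = FALSE)
  build <- function() {
    list(theta1 = lapply(seq_len(order_K),
                         function(k) .glorot(in_dim, hidden[1])),
         theta2 = lapply(seq_len(order_K),
                         function(k) .glorot(hidden[1], hidden[2])),
         fc_w = .glorot(n_channels * hidden[2], n_channels),
         fc_b = rep(0, n_channels),
         order_K = as.integer(order_K), n_channels = n_channels,
         in_dim = in_dim, hidden = hidden)
  }
  p <- if (is.null(seed)) build() else .with_seed(seed, build())
  structure(p, class = "encoder_params")
}

#' Encode a channel graph into a status code
#'
#' Applies the two convolution layers and the fully connected layer,
#' producing one value per channel for the window.
#'
#' @param g A [build_channel_graph()] result.
#' @param params An [encoder_params()] object.
#' @param window_index Chronological index attached to the code.
#' @return Numeric status-code vector of length `params$n_channels`, with
#'   attribute `window_index`.
#' @export
encode_status <- function(g, params, window_index = 1L) {
  stopifnot(inherits(g, "channel_graph"), inherits(params, "encoder_params"))
  X <- g$node_features
  if (nrow(X) != params$n_channels || ncol(X) != params$in_dim) {
    stop("graph sized ", nrow(X), "x", ncol(X), " does not match encoder (",
         params$n_channels, "x", params$in_dim, ")", call. = FALSE)
  }
  spec <- scaled_laplacian(g$adjacency)
  O1 <- cheb_conv_layer(X, spec, params$theta1)
  O2 <- cheb_conv_layer(O1, spec, params$theta2)
  s <- drop(matrix(as.vector(O2), nrow = 1) %*% params$fc_w) + params$fc_b
  attr(s, "window_index") <- as.integer(window_index)
  s
}
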