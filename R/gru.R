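# Gated recurrent unit over chronologically ordered status codes, with an
# MLP head emitting class probabilities. Gate algebra (row-vector
# convention, no bias terms):
#   R_t = sigmoid(s_t W_r + C_{t-1} U_r)          (reset gate)
#   N_t = sigmoid(s_t W_z + C_{t-1} U_z)          (update gate)
#   Ctil_t = tanh(s_t W + R_t * (C_{t-1} U))      (candidate state)
#   C_t = (1 - N_t) * C_{t-1} + N_t * Ctil_t
# "*" is elementwise; the reset gate modulates the recurrent term of the
# candidate.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize GRU parameters
#'
#' Six Glorot-uniform weight matrices: input and recurrent weights for the
#' reset gate, the update gate, and the candidate state.
#'
#' @param input_size Status-code length (default 18).
#' @param hidden_size Hidden-state width (default 32).
#' @param seed Optional seed (draws from the current RNG stream if `NULL`).
#' @return Object of class `gru_params`.
#' @export
gru_params <- function(input_size = 18, hidden_size = 32, seed = NULL) {
  build <- function() {
    list(W_r = .glorot(input_size, hidden_size),
         U_r = .glorot(hidden_size, hidden_size),
         W_z = .glorot(input_size, hidden_size),
         U_z = .glorot(hidden_size, hidden_size),
         W = .glorot(input_size, hidden_size),
         U = .glorot(hidden_size, hidden_size),
         input_size = input_size, hidden_size = hidden_size)
  }
  p <- if (is.null(seed)) build() else .with_seed(seed, build())
  structure(p, class = "gru_params")
}

#' One GRU step
#'
#' @param s_t Status-code vector (length `input_size`).
#' @param state Previous state: list with `C` (hidden vector) and `t` (step
#'   index), or `NULL` for the zero initial state.
#' @param params A [gru_params()] object.
#' @return Updated state: list with `C` and `t`.
#' @export
gru_step <- function(s_t, state, params) {
  stopifnot(inherits(params, "gru_params"))
  s_t <- as.numeric(s_t)
  if (length(s_t) != params$input_size) {
    stop("status code length ", length(s_t), " != input_size ",
         params$input_size, call. = FALSE)
  }
  if (is.null(state)) state <- list(C = rep(0, params$hidden_size), t = 0L)
  C_prev <- state$C
  if (length(C_prev) != params$hidden_size) {
    stop("state width ", length(C_prev), " != hidden_size ",
         params$hidden_size, call. = FALSE)
  }
  sv <- matrix(s_t, nrow = 1)
  cv <- matrix(C_prev, nrow = 1)
  R <- .sigmoid(drop(sv %*% params$W_r + cv %*% params$U_r))
  N <- .sigmoid(drop(sv %*% params$W_z + cv %*% params$U_z))
  Ctil <- tanh(drop(sv %*% params$W) + R * drop(cv %*% params$U))
  C <- (1 - N) * C_prev + N * Ctil
  list(C = C, t = state$t + 1L)
}

#' Run a GRU over an ordered status-code sequence
#'
#' Folds [gru_step()] over the codes from the zero initial state. Codes must
#' be in chronological order; if `window_index` attributes are present they
#' must be strictly increasing.
#'
#' @param codes A T x input_size matrix (rows = time steps) or a list of
#'   status-code vectors.
#' @param params A [gru_params()] object.
#' @return Final state (list with `C` and `t`).
#' @export
run_sequence <- function(codes, params) {
  if (is.matrix(codes)) codes <- lapply(seq_len(nrow(codes)),
                                        function(i) codes[i, ])
  if (!is.list(codes) || length(codes) == 0) {
    stop("codes must be a nonempty sequence", call. = FALSE)
  }
  idx <- vapply(codes, function(s) {
    w <- attr(s, "window_index")
    if (is.null(w)) NA_real_ else as.numeric(w)
  }, numeric(1))
  if (!anyNA(idx) && any(diff(idx) <= 0)) {
    stop("window indices must be strictly increasing (chronological order)",
         call. = FALSE)
  }
  state <- NULL
  for (s in codes) state <- gru_step(s, state, params)
  state
}

#' Initialize the MLP prediction head
#'
#' One hidden dense layer with ReLU, then a dense map to two logits.
#'
#' @param hidden_size GRU state width feeding the head (default 32).
#' @param mlp_hidden Hidden-layer width (default 16).
#' @param seed Optional seed.
#' @return Object of class `mlp_params`.
#' @export
mlp_params <- function(hidden_size = 32, mlp_hidden = 16, seed = NULL) {
  build <- function() {
    list(W1 = .glorot(hidden_size, mlp_hidden), b1 = rep(0, mlp_hidden),
         W2 = .glorot(mlp_hidden, 2), b2 = rep(0, 2),
         hidden_size = hidden_size, mlp_hidden = mlp_hidden)
  }
  p <- if (is.null(seed)) build() else .with_seed(seed, build())
  structure(p, class = "mlp_params")
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Class probabilities from a GRU state
#'
#' @param state A GRU state (list with `C`) or a plain hidden vector.
#' @param head_params An [mlp_params()] object.
#' @return Object of class `predictor_output`: list with `probabilities`
#'   (named vector over `inter_ictal`, `pre_ictal`, summing to 1) and
#'   `predicted_label`.
#' @export
mlp_predict <- function(state, head_params) {
  stopifnot(inherits(head_params, "mlp_params"))
  C <- if (is.list(state)) state$C else as.numeric(state)
  if (length(C) != head_params$hidden_size) {
    stop("state width ", length(C), " != head input ",
         head_params$hidden_size, call. = FALSE)
  }
  h <- pmax(drop(matrix(C, 1) %*% head_params$W1) + head_params$b1, 0)
  logits <- drop(matrix(h, 1) %*% head_params$W2) + head_params$b2
  p <- .softmax(logits)
  names(p) <- c("inter_ictal", "pre_ictal")
  structure(list(probabilities = p,
                 predicted_label = names(p)[which.max(p)]),
            class = "predictor_output")
}

#' Cross-entropy + L2 training loss
#'
#' Cross-entropy of the predicted distribution against the one-hot true
#' label (probabilities floored at 1e-12) plus
#' `lambda_reg / 2 * sum(w^2)` over the supplied weight matrices (biases
#' are the caller's responsibility to exclude).
#'
#' @param out A [mlp_predict()] result, or a bare probability 2-vector
#'   ordered `(inter_ictal, pre_ictal)`.
#' @param true_label `"pre_ictal"` or `"inter_ictal"`.
#' @param weights List of numeric weight matrices entering the L2 term
#'   (may be empty or `NULL`).
#' @param lambda_reg Nonnegative regularization strength.
#' @return Scalar loss.
#' @export
predictor_loss <- function(out, true_label, weights = NULL, lambda_reg = 0) {
  if (lambda_reg < 0) stop("lambda_reg must be >= 0", call. = FALSE)
  p <- if (inherits(out, "predictor_output")) out$probabilities
       else as.numeric(out)
  if (length(p) != 2 || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop("invalid probability vector", call. = FALSE)
  }
  true_label <- match.arg(true_label, c("pre_ictal", "inter_ictal"))
  idx <- if (true_label == "inter_ictal") 1L else 2L
  ce <- -log(max(p[idx], 1e-12))
  l2 <- 0
  if (!is.null(weights) && length(weights) > 0) {
    l2 <- sum(vapply(weights, function(w) sum(w^2), numeric(1)))
  }
  unname(ce + lambda_reg / 2 * l2)
}
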