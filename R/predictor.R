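# The nonlinear functional H mapping a flattened latent matrix U to the
# condition indicators: a small fully-connected network with tanh hidden
# units, squared-error or softmax cross-entropy loss, and exact gradients
# with respect to both the parameters and the input.
#
# Latent matrices are flattened column-major (R's native vec()); the input
# gradient dU is reshaped with the same convention.

#' Describe a predictor architecture
#'
#' @param input_dim Flattened latent dimension (`J^2`, or `J_e * J_c`).
#' @param hidden Integer vector of hidden-layer widths; `integer(0)` gives a
#'   purely affine predictor.
#' @param output_dim Number of indicators (regression) or classes
#'   (classification).
#' @param loss `"squared"` (sum of squared errors) or `"softmax"`
#'   (softmax cross entropy on pre-softmax scores).
#' @return Object of class `"predictor_spec"`.
#' @export
predictor_spec <- function(input_dim, hidden = 10L, output_dim = 1L,
                           loss = c("squared", "softmax")) {
  loss <- match.arg(loss)
  hidden <- as.integer(hidden)
  if (any(c(input_dim, hidden, output_dim) < 1)) {
    stop("all layer widths must be >= 1")
  }
  structure(list(input_dim = as.integer(input_dim), hidden = hidden,
                 output_dim = as.integer(output_dim), loss = loss),
            class = "predictor_spec")
}

layer_dims <- function(spec) {
  widths <- c(spec$input_dim, spec$hidden, spec$output_dim)
  lapply(seq_len(length(widths) - 1),
         function(l) c(out = widths[l + 1], "in" = widths[l]))
}

#' Initialize predictor parameters
#'
#' Weights are drawn `N(0, 1/fan_in)` (standard normal scaled by
#' `1/sqrt(fan_in)`) and biases start at zero. With `scale = "raw"` the
#' entries are plain `N(0,1)` draws, the convention used for ground-truth
#' generative networks in the synthetic benchmarks.
#'
#' @param spec A [predictor_spec()].
#' @param seed Optional integer seed.
#' @param scale `"fan_in"` (default) or `"raw"`.
#' @return List of layers, each `list(W, b)` with `W` of shape
#'   `out x in`.
#' @export
init_predictor <- function(spec, seed = NULL, scale = c("fan_in", "raw")) {
  scale <- match.arg(scale)
  if (!is.null(seed)) set.seed(seed)
  lapply(layer_dims(spec), function(d) {
    sd <- if (scale == "fan_in") 1 / sqrt(d[["in"]]) else 1
    W <- matrix(stats::rnorm(d[["out"]] * d[["in"]], sd = sd),
                d[["out"]], d[["in"]])
    b <- if (scale == "fan_in") numeric(d[["out"]]) else stats::rnorm(d[["out"]])
    list(W = W, b = b)
  })
}

# Batched forward pass. X: n x input_dim. Returns list(out = n x output_dim,
# acts = list of layer activations including X itself).
mlp_forward <- function(params, X) {
  X <- as.matrix(X)
  acts <- vector("list", length(params) + 1)
  acts[[1]] <- X
  A <- X
  L <- length(params)
  for (l in seq_len(L)) {
    A <- A %*% t(params[[l]]$W) +
      matrix(params[[l]]$b, nrow(A), length(params[[l]]$b), byrow = TRUE)
    if (l < L) A <- tanh(A)
    acts[[l + 1]] <- A
  }
  list(out = A, acts = acts)
}

#' Evaluate the predictor on one latent matrix
#'
#' Deterministic forward pass of `H[U]`; classification outputs are
#' pre-softmax scores.
#'
#' @param spec A [predictor_spec()].
#' @param params Parameters from [init_predictor()] or a fitted model.
#' @param U Latent matrix (flattened column-major internally) or an
#'   already-flattened vector of length `input_dim`.
#' @return Numeric vector of length `output_dim`.
#' @export
predict_indicators <- function(spec, params, U) {
  x <- as.numeric(U)
  if (length(x) != spec$input_dim) {
    stop("flattened U has length ", length(x), ", expected ", spec$input_dim)
  }
  drop(mlp_forward(params, matrix(x, 1))$out)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Loss and exact gradients of the predictor
#'
#' Computes the total loss over a batch together with the gradient with
#' respect to every parameter tensor (summed over the batch) and with
#' respect to each input row. Squared-error loss is
#' `sum_i (y_i - yhat_i)^2` per row; softmax cross entropy takes `Y` as a
#' 0/1 one-hot matrix (or a vector of class indices).
#'
#' @param spec A [predictor_spec()].
#' @param params Parameter list.
#' @param X `n x input_dim` matrix of flattened latents.
#' @param Y `n x output_dim` target matrix (one-hot for classification; an
#'   integer class vector is also accepted).
#' @return `list(loss, grads, dX)`: `loss` is the batch total, `grads`
#'   mirrors `params` with batch-summed gradients, `dX` is `n x input_dim`
#'   with per-row input gradients.
#' @export
predictor_loss_grads <- function(spec, params, X, Y) {
  X <- as.matrix(X)
  fw <- mlp_forward(params, X)
  out <- fw$out
  if (!all(is.finite(out))) stop("non-finite predictor output")
  if (spec$loss == "softmax" && !is.matrix(Y) && length(Y) == nrow(X)) {
    Yh <- matrix(0, nrow(X), spec$output_dim)
    Yh[cbind(seq_len(nrow(X)), as.integer(Y))] <- 1
    Y <- Yh
  }
  Y <- as.matrix(Y)
  if (spec$loss == "squared") {
    R <- out - Y
    loss <- sum(R * R)
    delta <- 2 * R
  } else {
    P <- softmax_rows(out)
    loss <- -sum(Y * log(pmax(P, 1e-300)))
    delta <- P - Y
  }
  L <- length(params)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    A_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = crossprod(delta, A_prev), b = colSums(delta))
    delta <- delta %*% params[[l]]$W
    if (l > 1) delta <- delta * (1 - fw$acts[[l]]^2)
  }
  list(loss = loss, grads = grads, dX = delta)
}

#' Train a predictor on fixed inputs
#'
#' Full-batch Adam on the predictor loss; used to fit the downstream
#' networks of the reconstruction-first baselines, where the latent inputs
#' are frozen.
#'
#' @param spec A [predictor_spec()].
#' @param X `n x input_dim` inputs.
#' @param Y Targets as in [predictor_loss_grads()].
#' @param epochs,lr Optimization budget and Adam step size.
#' @param seed Seed for the parameter initialization.
#' @param params Optional warm-start parameters.
#' @return `list(params, history)` with the per-epoch mean loss.
#' @export
train_predictor <- function(spec, X, Y, epochs = 2000, lr = 1e-3,
                            seed = 1L, params = NULL) {
  if (is.null(params)) params <- init_predictor(spec, seed = seed)
  n <- nrow(as.matrix(X))
  opt <- adam_state(params)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    lg <- predictor_loss_grads(spec, params, X, Y)
    grads <- lapply(lg$grads, function(g) list(W = g$W / n, b = g$b / n))
    upd <- adam_step(opt, params, grads, lr)
    params <- upd$params; opt <- upd$state
    history[e] <- lg$loss / n
  }
  list(params = params, history = history)
}
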