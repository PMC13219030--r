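# Comparison methods: TuckerNN (reconstruction-only shared-basis
# factorization of the stacked graph tensor followed by a predictor on the
# frozen latents), and PCANN / LDANN for the single-effect-variable case
# where each graph is a plain vector.

tucker_objective <- function(graphs, C) {
  mean(vapply(graphs, function(W) {
    fro2(W) - fro2(crossprod(C, W %*% C))
  }, numeric(1)))
}

#' Fit the TuckerNN baseline
#'
#' Stage 1 learns a single orthonormal basis `C` minimizing the mean
#' reconstruction error `(1/K) sum_k ||W_k - C U_k C'||^2` with
#' `U_k = C'W_kC`: initialized at the top-`J` eigenvectors of
#' `(1/K) sum_k (W_kW_k' + W_k'W_k)` and refined by fixed-point alternation
#' (each proposal is accepted only if it lowers the objective, so the stage-1
#' trace is non-increasing). Stage 2 trains a predictor on the frozen
#' latents.
#'
#' @param family A square [graph_family()].
#' @param indicators Matching [indicator_table()]; the first group is used
#'   unless `mechanism` selects another.
#' @param J Latent dimension.
#' @param config A [trip_config()]; predictor architecture and training
#'   budget are shared with TRIP for comparability.
#' @param mechanism Indicator group to predict.
#' @return Object of class `"baseline_model"` with `kind = "tucker"`,
#'   the basis `C`, `stage1_objective` trace, and the fitted predictor.
#' @export
fit_tucker_nn <- function(family, indicators, J, config = trip_config(),
                          mechanism = 1L) {
  graphs <- family$graphs
  K <- length(graphs)
  M <- Reduce(`+`, lapply(graphs, function(W) W %*% t(W) + t(W) %*% W)) / K
  C <- eigen(M, symmetric = TRUE)$vectors[, seq_len(J), drop = FALSE]
  obj <- tucker_objective(graphs, C)
  trace_obj <- obj
  for (it in seq_len(200L)) {
    G <- Reduce(`+`, lapply(graphs, function(W) {
      WC <- W %*% C; WtC <- crossprod(W, C)
      tcrossprod(WC) + tcrossprod(WtC)
    })) / K
    C_new <- eigen(G, symmetric = TRUE)$vectors[, seq_len(J), drop = FALSE]
    obj_new <- tucker_objective(graphs, C_new)
    if (obj_new < obj - 1e-10 * max(1, obj)) {
      C <- C_new; obj <- obj_new
      trace_obj <- c(trace_obj, obj)
    } else break
  }
  task <- indicators$task[mechanism]
  Y <- mechanism_targets(indicators, indicators$groups[[mechanism]], task)
  X <- t(vapply(graphs, function(W) as.numeric(crossprod(C, W %*% C)),
                numeric(J^2)))
  spec <- predictor_spec(J^2, hidden = config$hidden,
                         output_dim = ncol(as.matrix(Y)),
                         loss = if (task == "classification") "softmax"
                         else "squared")
  tp <- train_predictor(spec, X, Y, epochs = config$epochs, lr = config$lr,
                        seed = config$seed)
  structure(list(kind = "tucker", C = C, stage1_objective = trace_obj,
                 spec = spec, params = tp$params, task = task,
                 mechanism = mechanism),
            class = "baseline_model")
}

#' Fit the PCANN baseline
#'
#' Projects vector observations onto their top-`J` (centered) principal
#' components and trains a predictor on the scores.
#'
#' @param X `K x I` matrix of observations (e.g. `1 x I` graphs stacked as
#'   rows).
#' @param y Targets: numeric vector (regression) or class labels
#'   (classification).
#' @param J Number of components.
#' @param config A [trip_config()] for the predictor stage.
#' @param task `"regression"` or `"classification"`.
#' @return `"baseline_model"` with the projection (`rotation`, `center`).
#' @export
fit_pca_nn <- function(X, y, J, config = trip_config(),
                       task = c("classification", "regression")) {
  task <- match.arg(task)
  X <- as.matrix(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (J > ncol(pc$rotation) || pc$sdev[J] < 1e-12) {
    stop("requested J = ", J, " exceeds the rank of the data")
  }
  rot <- pc$rotation[, seq_len(J), drop = FALSE]
  scores <- pc$x[, seq_len(J), drop = FALSE]
  fit_projected_nn(scores, y, task, config,
                   list(kind = "pca", rotation = rot, center = pc$center))
}

#' Fit the LDANN baseline
#'
#' Projects onto linear discriminant axes and trains a predictor on the
#' scores. Classic LDA yields at most `classes - 1` axes; when more are
#' requested the projection is completed with the leading principal
#' components of the within-class residuals so that the predictor sees the
#' same input dimension as the other methods.
#'
#' @param X `K x I` observation matrix.
#' @param y Class labels.
#' @param J Projection dimension.
#' @param config A [trip_config()] for the predictor stage.
#' @return `"baseline_model"` with the projection matrix and centering.
#' @export
fit_lda_nn <- function(X, y, J, config = trip_config()) {
  X <- as.matrix(X)
  y <- as.factor(y)
  ld <- MASS::lda(X, grouping = y, tol = 1e-12)
  axes <- ld$scaling
  if (ncol(axes) > J) axes <- axes[, seq_len(J), drop = FALSE]
  if (ncol(axes) < J) {
    centered <- X
    for (lev in levels(y)) {
      idx <- y == lev
      centered[idx, ] <- scale(X[idx, , drop = FALSE], scale = FALSE)
    }
    resid <- centered - centered %*% axes %*% MASS::ginv(axes)
    pc <- stats::prcomp(resid, center = FALSE)
    extra <- pc$rotation[, seq_len(J - ncol(axes)), drop = FALSE]
    axes <- cbind(axes, extra)
  }
  center <- colMeans(X)
  scores <- sweep(X, 2, center) %*% axes
  fit_projected_nn(scores, as.integer(y), "classification", config,
                   list(kind = "lda", rotation = axes, center = center))
}

fit_projected_nn <- function(scores, y, task, config, proto) {
  if (task == "classification") {
    lev <- sort(unique(as.integer(as.factor(y))))
    yi <- as.integer(as.factor(y))
    Y <- matrix(0, length(yi), length(lev))
    Y[cbind(seq_along(yi), yi)] <- 1
    spec <- predictor_spec(ncol(scores), hidden = config$hidden,
                           output_dim = length(lev), loss = "softmax")
  } else {
    Y <- matrix(as.numeric(y), ncol = 1)
    spec <- predictor_spec(ncol(scores), hidden = config$hidden,
                           output_dim = 1, loss = "squared")
  }
  tp <- train_predictor(spec, scores, Y, epochs = config$epochs,
                        lr = config$lr, seed = config$seed)
  structure(c(proto, list(spec = spec, params = tp$params, task = task,
                          history = tp$history)),
            class = "baseline_model")
}

#' Predict with a fitted baseline
#'
#' @param model A `"baseline_model"`.
#' @param newdata A [graph_family()] (tucker) or `K x I` matrix (pca/lda).
#' @return Regression predictions, or a list with `class` and `scores` for
#'   classification.
#' @export
predict_baseline <- function(model, newdata) {
  if (model$kind == "tucker") {
    J <- ncol(model$C)
    X <- t(vapply(newdata$graphs,
                  function(W) as.numeric(crossprod(model$C, W %*% model$C)),
                  numeric(J^2)))
  } else {
    X <- sweep(as.matrix(newdata), 2, model$center) %*% model$rotation
  }
  out <- mlp_forward(model$params, X)$out
  if (model$task == "classification") {
    list(class = max.col(out, ties.method = "first"), scores = out)
  } else {
    out
  }
}

#' Score a baseline on held-out data
#'
#' @param model A `"baseline_model"`.
#' @param newdata As in [predict_baseline()].
#' @param y True targets (numeric or class labels).
#' @return RMSE (regression) or accuracy (classification).
#' @export
evaluate_baseline <- function(model, newdata, y) {
  pred <- predict_baseline(model, newdata)
  if (model$task == "classification") {
    mean(pred$class == as.integer(as.factor(y)))
  } else {
    sqrt(mean((as.numeric(pred) - as.numeric(y))^2))
  }
}
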