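# Joint inference of the orthonormal mechanism bases and the nonlinear
# indicator predictors from a family of graphs: the TRIP objective, its
# exact gradient assembly through the Stiefel parameterization, and the
# training loop.
#
# For S mechanisms all bases are sliced out of ONE stacked Stiefel point of
# shape I x sum(J_s); this enforces C_s'C_t = 0 for s != t exactly, the
# no-direct-interaction assumption of the model. In bipartite mode the
# effect-side basis is the identity and the stacked point parameterizes the
# cause-side bases D_s.

#' Fitting configuration for [trip_fit()]
#'
#' @param latent_dim Integer vector: latent dimension `J_s` per fitted
#'   mechanism.
#' @param beta Trade-off weight of the truncated-reconstruction penalty;
#'   `beta = 0` fits the predictor alone, large `beta` approaches a
#'   reconstruction-only projection.
#' @param hidden Hidden-layer widths of every predictor.
#' @param epochs,lr Optimization budget and Adam step size.
#' @param lr_basis Optional separate step size for the free basis parameter
#'   `Z`; defaults to `lr`. A faster basis timescale lets the projection
#'   settle on high-variance structure before the predictor commits, which
#'   helps on strongly nonlinear problems where the predictor can otherwise
#'   memorize through an arbitrary projection.
#' @param warmup_epochs Predictor-only epochs run before joint training in
#'   each restart, with the basis frozen. A warmed-up predictor produces
#'   small, structured gradients when the basis is released, instead of the
#'   large arbitrary ones of an untrained network that can kick the basis
#'   off good subspaces.
#' @param restarts Number of random restarts; the restart with the smallest
#'   final training objective is returned (ties: lowest restart index).
#' @param batch_size Minibatch size; `NULL` (default) is full batch.
#' @param optimizer `"adam"` (default) or plain `"gd"`.
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @param bipartite Fit cause-side bases with identity effect basis.
#' @param mechanisms Names or indices of the indicator groups to fit;
#'   default all groups of the indicator table.
#' @return Object of class `"trip_config"`.
#' @export
trip_config <- function(latent_dim = 2L, beta = 1e-3, hidden = 10L,
                        epochs = 2000L, lr = 1e-3, lr_basis = NULL,
                        warmup_epochs = 0L, restarts = 10L,
                        batch_size = NULL, optimizer = c("adam", "gd"),
                        seed = 1L, bipartite = FALSE, mechanisms = NULL) {
  optimizer <- match.arg(optimizer)
  if (restarts < 1) stop("restarts must be >= 1")
  if (beta < 0) stop("beta must be >= 0")
  if (is.null(lr_basis)) lr_basis <- lr
  structure(list(latent_dim = as.integer(latent_dim), beta = beta,
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, lr_basis = lr_basis,
                 warmup_epochs = as.integer(warmup_epochs),
                 restarts = as.integer(restarts),
                 batch_size = batch_size, optimizer = optimizer,
                 seed = as.integer(seed), bipartite = isTRUE(bipartite),
                 mechanisms = mechanisms),
            class = "trip_config")
}

# Internal: build targets for one mechanism from an indicator table.
mechanism_targets <- function(indicators, group, task) {
  Y <- indicators$values[, group, drop = FALSE]
  if (task == "classification") {
    if (ncol(Y) == 1) {
      lev <- sort(unique(as.numeric(Y)))
      Yh <- matrix(0, nrow(Y), length(lev))
      Yh[cbind(seq_len(nrow(Y)), match(as.numeric(Y), lev))] <- 1
      attr(Yh, "levels") <- lev
      Y <- Yh
    }
  }
  Y
}

basis_columns <- function(J) {
  ends <- cumsum(J)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(function(a, b) seq.int(a, b), starts, ends)
}

#' Extract a fitted mechanism basis
#'
#' @param model A fitted `trip_model`.
#' @param mechanism Mechanism index.
#' @return The orthonormal `I x J_s` basis of that mechanism (`C_s`, or the
#'   cause-side `D_s` in bipartite mode).
#' @export
trip_basis <- function(model, mechanism = 1L) {
  C <- orthonormalize(model$Z)
  C[, basis_columns(model$J)[[mechanism]], drop = FALSE]
}

# Core evaluation: objective and (optionally) gradients for a model state.
# family: graph_family; targets: list of per-mechanism target matrices.
trip_eval <- function(family, targets, model, want_grads = FALSE) {
  K <- length(family$graphs)
  point <- stiefel_point(model$Z)
  Cfull <- point$C
  cols <- basis_columns(model$J)
  S <- length(model$J)
  beta <- model$beta
  Ws <- family$graphs
  bip <- isTRUE(model$bipartite)
  Ie <- nrow(Ws[[1]])
  Wmat <- NULL
  if (bip && Ie == 1) {
    Wmat <- do.call(rbind, Ws)
  }
  normW2 <- sum(vapply(Ws, fro2, numeric(1)))

  E_pred <- 0
  sumU2 <- 0
  dC <- if (want_grads) matrix(0, nrow(Cfull), ncol(Cfull)) else NULL
  dtheta <- if (want_grads) vector("list", S) else NULL

  for (s in seq_len(S)) {
    Cs <- Cfull[, cols[[s]], drop = FALSE]
    Js <- model$J[s]
    spec <- model$predictors[[s]]$spec
    if (bip) {
      if (!is.null(Wmat)) {
        X <- Wmat %*% Cs                    # K x Js, rows = vec(U_k)
      } else {
        X <- t(vapply(Ws, function(W) as.numeric(W %*% Cs),
                      numeric(Ie * Js)))
      }
    } else {
      X <- t(vapply(Ws, function(W) as.numeric(crossprod(Cs, W %*% Cs)),
                    numeric(Js * Js)))
    }
    sumU2 <- sumU2 + sum(X * X)
    isc <- if (is.null(model$input_scale)) 1 else model$input_scale[s]
    lg <- predictor_loss_grads(spec, model$predictors[[s]]$params, X * isc,
                               targets[[s]])
    E_pred <- E_pred + lg$loss / K

    if (want_grads) {
      dtheta[[s]] <- lapply(lg$grads, function(g) {
        list(W = g$W / K, b = g$b / K)
      })
      # chain rule through the fixed input standardization, then the
      # reconstruction pull: rows are vec(G_k)
      G <- lg$dX * isc - 2 * beta * X
      if (bip) {
        if (!is.null(Wmat)) {
          dC[, cols[[s]]] <- crossprod(Wmat, G) / K
        } else {
          acc <- matrix(0, nrow(Cs), Js)
          for (k in seq_len(K)) {
            Gk <- matrix(G[k, ], Ie, Js)
            acc <- acc + crossprod(Ws[[k]], Gk)
          }
          dC[, cols[[s]]] <- acc / K
        }
      } else {
        acc <- matrix(0, nrow(Cs), Js)
        for (k in seq_len(K)) {
          Gk <- matrix(G[k, ], Js, Js)
          WC <- Ws[[k]] %*% Cs
          WtC <- crossprod(Ws[[k]], Cs)
          acc <- acc + WC %*% t(Gk) + WtC %*% Gk
        }
        dC[, cols[[s]]] <- acc / K
      }
    }
  }
  E_rec <- beta * (normW2 - sumU2) / K
  E <- E_pred + E_rec
  out <- list(objective = E, prediction = E_pred, reconstruction = E_rec)
  if (want_grads) {
    out$dZ <- stiefel_pullback(dC, point)
    out$dtheta <- dtheta
  }
  out
}

model_targets <- function(model, indicators) {
  lapply(seq_along(model$groups), function(s) {
    mechanism_targets(indicators, model$groups[[s]], model$tasks[s])
  })
}

#' TRIP objective value
#'
#' `E = (1/K) sum_k [ loss(y_k, H[U_k]) + beta * ||W_k - C U_k C'||_2^2 ]`
#' with `U_k = C'W_kC`, summed over mechanisms. The reconstruction term is
#' evaluated through the truncation identity
#' `||W_k||^2 - sum_s ||U_sk||^2`, which is exact because the stacked
#' mechanism bases are mutually orthogonal by construction.
#'
#' @param family A [graph_family()].
#' @param indicators An [indicator_table()] aligned with the family.
#' @param model A `trip_model` (fitted or freshly initialized).
#' @return Scalar objective; components are attached as attributes
#'   `"prediction"` and `"reconstruction"`.
#' @export
trip_objective <- function(family, indicators, model) {
  ev <- trip_eval(family, model_targets(model, indicators), model)
  structure(ev$objective, prediction = ev$prediction,
            reconstruction = ev$reconstruction)
}

#' TRIP gradients
#'
#' Assembles the exact gradient of the objective: predictor gradients by
#' backpropagation averaged over samples, and the basis gradient
#' `dE/dC = (1/K) sum_k [W_k C G_k' + W_k' C G_k]` with
#' `G_k = dloss/dU_k - 2 beta U_k`, pulled back to the free Stiefel
#' parameter `Z` through [stiefel_pullback()].
#'
#' @inheritParams trip_objective
#' @return `list(dZ, dtheta)`: gradient for the stacked free parameter and
#'   per-mechanism predictor gradients.
#' @export
trip_gradients <- function(family, indicators, model) {
  ev <- trip_eval(family, model_targets(model, indicators), model,
                  want_grads = TRUE)
  list(dZ = ev$dZ, dtheta = ev$dtheta)
}

init_trip_model <- function(family, indicators, config) {
  bip <- config$bipartite
  W1 <- family$graphs[[1]]
  I <- if (bip) ncol(W1) else nrow(W1)
  Ie <- nrow(W1)
  groups <- indicators$groups
  tasks <- indicators$task
  mech <- config$mechanisms
  if (is.null(mech)) mech <- seq_along(groups)
  if (is.character(mech)) mech <- match(mech, names(groups))
  J <- rep_len(config$latent_dim, length(mech))
  if (sum(J) > I) stop("total latent dimension exceeds ambient dimension")
  Z <- matrix(stats::rnorm(I * sum(J)), I, sum(J))
  predictors <- vector("list", length(mech))
  for (i in seq_along(mech)) {
    s <- mech[i]
    Ytmp <- mechanism_targets(indicators, groups[[s]], tasks[s])
    input_dim <- if (bip) Ie * J[i] else J[i]^2
    spec <- predictor_spec(input_dim, hidden = config$hidden,
                           output_dim = ncol(as.matrix(Ytmp)),
                           loss = if (tasks[s] == "classification")
                             "softmax" else "squared")
    predictors[[i]] <- list(spec = spec,
                            params = init_predictor(spec))
  }
  # fixed input standardization for the predictor stage: one scalar per
  # mechanism, set from the family itself so tanh units start in their
  # active range at any data scale
  Cfull <- orthonormalize(Z)
  colsets <- basis_columns(J)
  input_scale <- vapply(seq_along(J), function(i) {
    Cs <- Cfull[, colsets[[i]], drop = FALSE]
    X0 <- if (bip) {
      t(vapply(family$graphs, function(W) as.numeric(W %*% Cs),
               numeric(Ie * J[i])))
    } else {
      t(vapply(family$graphs, function(W) as.numeric(crossprod(Cs, W %*% Cs)),
               numeric(J[i]^2)))
    }
    s0 <- stats::sd(as.numeric(X0))
    if (!is.finite(s0) || s0 < 1e-12) 1 else 1 / s0
  }, numeric(1))
  structure(list(Z = Z, J = J, predictors = predictors, beta = config$beta,
                 bipartite = bip, groups = groups[mech],
                 tasks = tasks[mech], input_scale = input_scale,
                 config = config),
            class = "trip_model")
}

#' @export
print.trip_model <- function(x, ...) {
  cat(sprintf("<trip_model: %d mechanism(s), J = (%s), beta = %g%s>\n",
              length(x$J), paste(x$J, collapse = ", "), x$beta,
              if (x$bipartite) ", bipartite" else ""))
  invisible(x)
}

#' Fit latent mechanisms and predictors to a graph family
#'
#' Minimizes the TRIP objective jointly over the stacked orthonormal basis
#' (through its free Stiefel parameter) and the predictor parameters, using
#' Adam (default) or plain gradient descent, with random restarts. The
#' restart reaching the smallest final training objective wins.
#'
#' @param family A [graph_family()] with `K >= 2` graphs.
#' @param indicators Matching [indicator_table()].
#' @param config A [trip_config()].
#' @return A fitted `trip_model` with elements `history` (objective per
#'   epoch, length `epochs + 1`, for the winning restart) and
#'   `restart_objectives`.
#' @export
trip_fit <- function(family, indicators, config = trip_config()) {
  if (length(family$graphs) < 2) stop("need at least K = 2 graphs to fit")
  if (nrow(indicators$values) != length(family$graphs)) {
    stop("indicator table has ", nrow(indicators$values),
         " rows but the family has ", length(family$graphs), " graphs")
  }
  best <- NULL
  restart_obj <- numeric(config$restarts)
  for (r in seq_len(config$restarts)) {
    set.seed(config$seed + r - 1L)
    model <- init_trip_model(family, indicators, config)
    targets <- model_targets(model, indicators)
    res <- run_trip_restart(family, targets, model, config)
    restart_obj[r] <- res$final
    if (is.null(best) || res$final < best$final) {
      best <- res
      best$restart <- r
    }
  }
  if (!is.finite(best$final)) {
    stop("all restarts diverged to a non-finite objective")
  }
  model <- best$model
  model$history <- best$history
  model$restart <- best$restart
  model$restart_objectives <- restart_obj
  model
}

run_trip_restart <- function(family, targets, model, config) {
  K <- length(family$graphs)
  bs <- config$batch_size
  full_batch <- is.null(bs) || bs >= K
  pars <- list(Z = model$Z,
               theta = lapply(model$predictors, `[[`, "params"))
  optZ <- adam_state(pars$Z)
  optT <- adam_state(pars$theta)
  wu <- config$warmup_epochs
  if (is.null(wu)) wu <- 0L
  if (wu > 0) {
    # predictor-only warm-up at the frozen initial basis
    for (e in seq_len(wu)) {
      ev <- trip_eval(family, targets, model, want_grads = TRUE)
      if (!is.finite(ev$objective)) break
      if (config$optimizer == "adam") {
        uT <- adam_step(optT, pars$theta, ev$dtheta, config$lr)
        optT <- uT$state
        pars$theta <- uT$params
      } else {
        pars$theta <- sgd_step(pars$theta, ev$dtheta, config$lr)
      }
      model <- set_model_params(model, pars)
    }
    optT <- adam_state(pars$theta)
  }
  step <- function(grads) {
    if (config$optimizer == "adam") {
      uZ <- adam_step(optZ, pars$Z, grads$Z, config$lr_basis)
      uT <- adam_step(optT, pars$theta, grads$theta, config$lr)
      optZ <<- uZ$state; optT <<- uT$state
      list(Z = uZ$params, theta = uT$params)
    } else {
      list(Z = sgd_step(pars$Z, grads$Z, config$lr_basis),
           theta = sgd_step(pars$theta, grads$theta, config$lr))
    }
  }
  history <- numeric(config$epochs + 1L)
  ev <- trip_eval(family, targets, model)
  history[1] <- ev$objective
  for (e in seq_len(config$epochs)) {
    if (full_batch) {
      ev <- trip_eval(family, targets, model, want_grads = TRUE)
      if (!is.finite(ev$objective)) {
        history <- history[seq_len(e)]
        return(list(model = model, history = history, final = Inf))
      }
      pars <- step(list(Z = ev$dZ, theta = ev$dtheta))
      model <- set_model_params(model, pars)
      history[e + 1] <- ev$objective
    } else {
      idx <- sample.int(K)
      batches <- split(idx, ceiling(seq_along(idx) / bs))
      for (b in batches) {
        sub_fam <- list(graphs = family$graphs[b], bipartite = family$bipartite)
        sub_tgt <- lapply(targets, function(Y) Y[b, , drop = FALSE])
        ev <- trip_eval(sub_fam, sub_tgt, model, want_grads = TRUE)
        if (!is.finite(ev$objective)) {
          return(list(model = model, history = history[seq_len(e)],
                      final = Inf))
        }
        pars <- step(list(Z = ev$dZ, theta = ev$dtheta))
        model <- set_model_params(model, pars)
      }
      history[e + 1] <- trip_eval(family, targets, model)$objective
    }
  }
  final <- trip_eval(family, targets, model)$objective
  if (config$epochs > 0) history[length(history)] <- final
  list(model = model, history = history, final = final)
}

set_model_params <- function(model, pars) {
  model$Z <- pars$Z
  for (s in seq_along(model$predictors)) {
    model$predictors[[s]]$params <- pars$theta[[s]]
  }
  model
}

#' Evaluate a fitted model on a graph family
#'
#' @param model A fitted `trip_model`.
#' @param family Graph family to score.
#' @param indicators Matching indicator table.
#' @return A list with one entry per mechanism: RMSE (regression) or
#'   accuracy (classification), predictions, and the mean per-sample
#'   reconstruction gap of the model's stacked basis.
#' @export
trip_evaluate <- function(model, family, indicators) {
  targets <- model_targets(model, indicators)
  K <- length(family$graphs)
  Cfull <- orthonormalize(model$Z)
  cols <- basis_columns(model$J)
  out <- vector("list", length(model$J))
  for (s in seq_along(model$J)) {
    Cs <- Cfull[, cols[[s]], drop = FALSE]
    spec <- model$predictors[[s]]$spec
    if (model$bipartite) {
      X <- t(vapply(family$graphs, function(W) as.numeric(W %*% Cs),
                    numeric(nrow(family$graphs[[1]]) * model$J[s])))
    } else {
      X <- t(vapply(family$graphs,
                    function(W) as.numeric(crossprod(Cs, W %*% Cs)),
                    numeric(model$J[s]^2)))
    }
    isc <- if (is.null(model$input_scale)) 1 else model$input_scale[s]
    pred <- mlp_forward(model$predictors[[s]]$params, X * isc)$out
    Y <- as.matrix(targets[[s]])
    if (model$tasks[s] == "classification") {
      cls <- max.col(pred, ties.method = "first")
      truth <- max.col(Y, ties.method = "first")
      out[[s]] <- list(task = "classification",
                       accuracy = mean(cls == truth),
                       predicted_class = cls, scores = pred)
    } else {
      out[[s]] <- list(task = "regression",
                       rmse = sqrt(mean((pred - Y)^2)),
                       predictions = pred)
    }
  }
  gaps <- vapply(family$graphs, function(W) {
    if (model$bipartite) {
      fro2(W) - sum(vapply(seq_along(model$J), function(s) {
        fro2(W %*% Cfull[, cols[[s]], drop = FALSE])
      }, numeric(1)))
    } else {
      sum_u2 <- sum(vapply(seq_along(model$J), function(s) {
        Cs <- Cfull[, cols[[s]], drop = FALSE]
        fro2(crossprod(Cs, W %*% Cs))
      }, numeric(1)))
      fro2(W) - sum_u2
    }
  }, numeric(1))
  list(mechanisms = out, reconstruction_gap = gaps,
       mean_reconstruction_gap = mean(gaps))
}
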