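# Joint objective, gradient assembly, and the fitting loop.

make_model <- function(fam, ind, cfg) {
  set.seed(cfg$seed)
  tripnet:::init_trip_model(fam, ind, cfg)
}

test_that("objective matches an independent direct-form evaluation", {
  set.seed(40)
  tf <- tiny_family(I = 6, K = 4, seed = 40, p = 2)
  cfg <- trip_config(latent_dim = c(2, 2), beta = 0.07, hidden = 4,
                     restarts = 1, epochs = 0, seed = 9,
                     mechanisms = NULL)
  ind <- indicator_table(tf$indicators$values, groups = list(a = 1, b = 2))
  model <- make_model(tf$family, ind, cfg)
  E <- as.numeric(trip_objective(tf$family, ind, model))
  # direct form: explicit reconstruction residual + per-sample losses
  Cfull <- orthonormalize(model$Z)
  bases <- list(Cfull[, 1:2], Cfull[, 3:4])
  K <- length(tf$family$graphs)
  acc <- 0
  for (k in seq_len(K)) {
    W <- tf$family$graphs[[k]]
    Us <- lapply(bases, function(C) project_graph(W, C))
    recon <- reconstruct_graph(bases, Us)
    for (s in 1:2) {
      # the predictor stage includes the model's fixed input standardization
      yhat <- predict_indicators(model$predictors[[s]]$spec,
                                 model$predictors[[s]]$params,
                                 Us[[s]] * model$input_scale[s])
      acc <- acc + sum((ind$values[k, s] - yhat)^2)
    }
    acc <- acc + model$beta * sum((W - recon)^2)
  }
  expect_equal(E, acc / K, tolerance = 1e-10)
})

test_that("degenerate objectives vanish where they should", {
  set.seed(41)
  # K = 1, J = I, C spanning everything: reconstruction term is zero
  W <- matrix(rnorm(9), 3, 3)
  fam <- graph_family(list(W, W))
  ind <- indicator_table(matrix(c(0.3, 0.3), 2, 1))
  cfg <- trip_config(latent_dim = 3, beta = 5, hidden = 2, restarts = 1,
                     epochs = 0, seed = 2)
  model <- make_model(fam, ind, cfg)
  E <- trip_objective(fam, ind, model)
  expect_equal(as.numeric(attr(E, "reconstruction")), 0, tolerance = 1e-8)
  expect_equal(as.numeric(E), as.numeric(attr(E, "prediction")),
               tolerance = 1e-10)
})

test_that("gradients match finite differences (square, multi-mechanism)", {
  for (seed in c(50, 51, 52)) {
    tf <- tiny_family(I = 6, K = 3, seed = seed, p = 2)
    ind <- indicator_table(tf$indicators$values, groups = list(a = 1, b = 2))
    cfg <- trip_config(latent_dim = c(2, 2), beta = 0.05, hidden = 4,
                       restarts = 1, epochs = 0, seed = seed + 1)
    model <- make_model(tf$family, ind, cfg)
    gr <- trip_gradients(tf$family, ind, model)
    fZ <- function(Z) {
      m <- model; m$Z <- Z
      as.numeric(trip_objective(tf$family, ind, m))
    }
    expect_lt(rel_err(gr$dZ, fd_grad_matrix(fZ, model$Z)), 1e-4)
    fW1 <- function(Wl) {
      m <- model; m$predictors[[2]]$params[[1]]$W <- Wl
      as.numeric(trip_objective(tf$family, ind, m))
    }
    fdW <- fd_grad_matrix(fW1, model$predictors[[2]]$params[[1]]$W)
    expect_lt(rel_err(gr$dtheta[[2]][[1]]$W, fdW), 1e-4)
  }
})

test_that("gradients match finite differences (bipartite classification)", {
  for (seed in c(60, 61)) {
    set.seed(seed)
    K <- 5; Ic <- 7
    fam <- graph_family(lapply(1:K, function(k) matrix(rnorm(Ic), 1, Ic)),
                        bipartite = TRUE)
    ind <- indicator_table(matrix(sample(1:2, K, TRUE), ncol = 1),
                           groups = list(g = 1), task = "classification")
    cfg <- trip_config(latent_dim = 2, beta = 0.03, hidden = 4,
                       restarts = 1, epochs = 0, seed = seed,
                       bipartite = TRUE)
    model <- make_model(fam, ind, cfg)
    gr <- trip_gradients(fam, ind, model)
    fZ <- function(Z) {
      m <- model; m$Z <- Z
      as.numeric(trip_objective(fam, ind, m))
    }
    expect_lt(rel_err(gr$dZ, fd_grad_matrix(fZ, model$Z)), 1e-4)
  }
})

test_that("basis gradient vanishes when E does not depend on C", {
  # beta = 0 and an input-independent predictor (zero first layer)
  tf <- tiny_family(I = 5, K = 3, seed = 70)
  cfg <- trip_config(latent_dim = 2, beta = 0, hidden = 3, restarts = 1,
                     epochs = 0, seed = 8)
  model <- make_model(tf$family, tf$indicators, cfg)
  model$predictors[[1]]$params[[1]]$W[] <- 0
  gr <- trip_gradients(tf$family, tf$indicators, model)
  expect_equal(gr$dZ, model$Z * 0, tolerance = 1e-12)
})

test_that("zero-epoch fit returns the initialization with history length 1", {
  tf <- tiny_family(I = 5, K = 3, seed = 71)
  cfg <- trip_config(latent_dim = 2, beta = 0.01, hidden = 3, restarts = 1,
                     epochs = 0, seed = 5)
  fit <- trip_fit(tf$family, tf$indicators, cfg)
  expect_length(fit$history, 1)
  ref <- make_model(tf$family, tf$indicators, cfg)
  expect_equal(fit$Z, ref$Z)
})

test_that("fits are deterministic given the seed", {
  tf <- tiny_family(I = 5, K = 4, seed = 72)
  cfg <- trip_config(latent_dim = 2, beta = 0.01, hidden = 3, restarts = 2,
                     epochs = 30, seed = 13)
  f1 <- trip_fit(tf$family, tf$indicators, cfg)
  f2 <- trip_fit(tf$family, tf$indicators, cfg)
  expect_identical(f1$Z, f2$Z)
  expect_identical(f1$history, f2$history)
})

test_that("full-batch gradient descent is non-increasing at small steps", {
  tf <- tiny_family(I = 6, K = 5, seed = 73)
  lr <- 1e-3
  for (attempt in 1:4) {
    cfg <- trip_config(latent_dim = 2, beta = 0.05, hidden = 4,
                       restarts = 1, epochs = 50, seed = 3,
                       optimizer = "gd", lr = lr)
    fit <- trip_fit(tf$family, tf$indicators, cfg)
    ok <- all(diff(fit$history) <= 1e-10)
    if (ok) break
    lr <- lr / 2
  }
  expect_true(ok)
})

test_that("planted low-rank family with linear response is recovered", {
  set.seed(80)
  I <- 8; J <- 2; K <- 60
  C0 <- rand_orth(I, J)
  Us <- lapply(1:K, function(k) matrix(rnorm(J * J), J, J))
  graphs <- lapply(Us, function(U) C0 %*% U %*% t(C0))
  g <- rnorm(J * J)
  y <- vapply(Us, function(U) sum(g * as.numeric(U)), numeric(1))
  fam <- graph_family(graphs)
  ind <- indicator_table(matrix(y, ncol = 1))
  cfg <- trip_config(latent_dim = J, beta = 1e-1, hidden = 6,
                     restarts = 3, epochs = 800, lr = 1e-2, seed = 4)
  fit <- trip_fit(fam, ind, cfg)
  expect_gte(subspace_similarity(C0, trip_basis(fit, 1)), 1.9)
})

test_that("evaluation metrics behave at the extremes", {
  set.seed(81)
  tf <- tiny_family(I = 5, K = 6, seed = 81)
  cfg <- trip_config(latent_dim = 2, beta = 0, hidden = 3, restarts = 1,
                     epochs = 0, seed = 2)
  model <- make_model(tf$family, tf$indicators, cfg)
  # force a perfect predictor: constant output equal to constant targets
  ind_const <- indicator_table(matrix(1.25, 6, 1))
  model2 <- model
  model2$predictors[[1]]$params <- lapply(model2$predictors[[1]]$params,
                                          function(l) {
                                            list(W = l$W * 0, b = l$b * 0)
                                          })
  nl <- length(model2$predictors[[1]]$params)
  model2$predictors[[1]]$params[[nl]]$b <- 1.25
  ev <- trip_evaluate(model2, tf$family, ind_const)
  expect_equal(ev$mechanisms[[1]]$rmse, 0, tolerance = 1e-12)
  expect_true(all(ev$reconstruction_gap >= -1e-10))
})

test_that("restart bookkeeping picks the smallest final objective", {
  tf <- tiny_family(I = 5, K = 4, seed = 82)
  cfg <- trip_config(latent_dim = 2, beta = 0.01, hidden = 3, restarts = 3,
                     epochs = 20, seed = 21)
  fit <- trip_fit(tf$family, tf$indicators, cfg)
  expect_equal(tail(fit$history, 1), min(fit$restart_objectives),
               tolerance = 1e-12)
  expect_equal(fit$restart,
               which(fit$restart_objectives ==
                       min(fit$restart_objectives))[1])
})
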