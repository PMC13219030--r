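# The generative direction: loss evaluation oracles, DAG-constrained
# synthesis, and the unconstrained bipartite solver.

test_that("generation loss matches an independent direct evaluation", {
  prob <- tiny_problem(I = 5, S = 2, J = 2, m = 2, seed = 100)
  set.seed(101)
  W <- matrix(rnorm(25), 5, 5)
  got <- generation_loss(W, prob)
  acc <- prob$lambda * sum(abs(W))
  recon <- matrix(0, 5, 5)
  for (s in 1:2) {
    C <- prob$bases[[s]]
    U <- t(C) %*% W %*% C
    recon <- recon + C %*% U %*% t(C)
    yhat <- predict_indicators(prob$predictors[[s]]$spec,
                               prob$predictors[[s]]$params, U)
    acc <- acc + sum((prob$targets[[s]] - yhat)^2)
  }
  acc <- acc + prob$beta * sum((W - recon)^2)
  expect_equal(got, acc, tolerance = 1e-10)
})

test_that("with predictors switched off the loss reduces to the scaled gap", {
  set.seed(102)
  I <- 6; J <- 2
  C <- rand_orth(I, J)
  spec <- predictor_spec(J^2, hidden = 2, output_dim = 1)
  params <- init_predictor(spec, seed = 1)
  # zero all layers: predictor contributes a constant 0 with zero targets
  params <- lapply(params, function(l) list(W = l$W * 0, b = l$b * 0))
  prob <- generation_problem(list(C), list(list(spec = spec, params = params)),
                             list(0), beta = 0.37, lambda = 0)
  W <- matrix(rnorm(I * I), I, I)
  expect_equal(generation_loss(W, prob),
               0.37 * reconstruction_gap(W, C), tolerance = 1e-9)
})

test_that("generation smooth gradient matches finite differences", {
  prob <- tiny_problem(I = 4, S = 1, J = 2, m = 2, seed = 103, beta = 0.05)
  set.seed(104)
  W <- matrix(rnorm(16), 4, 4)
  sg <- tripnet:::generation_smooth(W, prob, want_grad = TRUE)
  fd <- fd_grad_matrix(function(Wx) {
    tripnet:::generation_smooth(Wx, prob)$value
  }, W)
  expect_lt(rel_err(sg$grad, fd), 1e-5)
})

test_that("targets reachable at zero give a (near-)zero DAG", {
  set.seed(105)
  I <- 4; J <- 2
  C <- rand_orth(I, J)
  spec <- predictor_spec(J^2, hidden = 2, output_dim = 1)
  params <- init_predictor(spec, seed = 6)
  y0 <- predict_indicators(spec, params, matrix(0, J, J))
  prob <- generation_problem(list(C), list(list(spec = spec, params = params)),
                             list(y0), beta = 1e-3, lambda = 0.02)
  W <- generate_graph(prob)
  expect_equal(max(abs(W)), 0)
  expect_equal(attr(W, "acyclicity"), 0)
})

test_that("solver matches a triangular brute-force oracle on I = 3", {
  # single mechanism, linear predictor; the oracle searches only
  # upper-triangular W (guaranteed DAGs) by direct numerical optimization
  set.seed(106)
  I <- 3; J <- 2
  C <- rand_orth(I, J)
  spec <- predictor_spec(J^2, hidden = integer(0), output_dim = 1)
  params <- list(list(W = matrix(rnorm(J^2), 1), b = 0.2))
  target <- 1.1
  prob <- generation_problem(list(C), list(list(spec = spec, params = params)),
                             list(target), beta = 1e-2, lambda = 0.01)
  W_hat <- generate_graph(prob)
  D_hat <- generation_loss(W_hat, prob)
  tri_loss <- function(v) {
    W <- matrix(0, I, I)
    W[upper.tri(W)] <- v
    generation_loss(W, prob)
  }
  best <- Inf
  for (s in 1:8) {
    o <- optim(rnorm(3, sd = 0.5), tri_loss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_lte(D_hat, best + 1e-3)
})

test_that("generated graphs are valid DAGs and beat the zero graph on fit", {
  prob_seed <- 107
  set.seed(prob_seed)
  I <- 8; S <- 1; J <- 2; m <- 3
  C <- rand_orth(I, J)
  spec <- predictor_spec(J^2, hidden = 6, output_dim = m)
  params <- init_predictor(spec, scale = "raw")
  preds <- list(list(spec = spec, params = params))
  rmse0 <- rmse_gen <- numeric(10)
  for (k in 1:10) {
    y <- runif(m, -4, 4)
    prob <- generation_problem(list(C), preds, list(y), beta = 1e-3,
                               lambda = 0.01)
    W <- generate_graph(prob)
    expect_lte(acyclicity(W), 1e-8)
    expect_equal(max(abs(diag(W))), 0)
    U <- project_graph(W, C)
    rmse_gen[k] <- sqrt(mean((predict_indicators(spec, params, U) - y)^2))
    rmse0[k] <- sqrt(mean((predict_indicators(spec, params,
                                              matrix(0, J, J)) - y)^2))
  }
  expect_lt(mean(rmse_gen), mean(rmse0))
})

test_that("bipartite generation matches the quadratic oracle when linear", {
  # linear predictor + squared loss + lambda 0: D(W) is an exact quadratic;
  # reconstruct it from loss evaluations alone and solve the normal equations
  set.seed(108)
  Ie <- 2; Ic <- 3; J <- 2
  C <- rand_orth(Ie, 1)
  D <- rand_orth(Ic, J)
  # full-rank linear map so the in-span directions are all pinned by the
  # prediction term and the quadratic is strictly convex
  spec <- predictor_spec(J, hidden = integer(0), output_dim = J)
  params <- list(list(W = matrix(rnorm(J * J), J) + 2 * diag(J), b = c(-0.4, 0.7)))
  prob <- generation_problem(list(C), list(list(spec = spec, params = params)),
                             list(c(2.2, -1)), beta = 0.15, lambda = 0,
                             cause_bases = list(D))
  n <- Ie * Ic
  f <- function(v) generation_loss(matrix(v, Ie, Ic), prob)
  # quadratic reconstruction: f(x) = c + b'x + x'Ax/2 from exact evaluations
  f0 <- f(numeric(n))
  e <- diag(n)
  bvec <- numeric(n); H <- matrix(0, n, n)
  for (i in 1:n) {
    fp <- f(e[i, ]); fm <- f(-e[i, ])
    bvec[i] <- (fp - fm) / 2
    H[i, i] <- fp + fm - 2 * f0
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    H[i, j] <- H[j, i] <-
      f(e[i, ] + e[j, ]) - f(e[i, ]) - f(e[j, ]) + f0 -
      0 # cross second difference
  }
  W_star <- matrix(solve(H, -bvec), Ie, Ic)
  W_hat <- generate_bipartite_graph(prob)
  expect_equal(W_hat[, ], W_star, tolerance = 1e-5)
  expect_lte(abs(generation_loss(W_hat, prob) - f(as.numeric(W_star))), 1e-6)
})

test_that("bipartite sparsity is monotone in the L1 weight", {
  set.seed(109)
  Ie <- 1; Ic <- 8; J <- 2
  D <- rand_orth(Ic, J)
  spec <- predictor_spec(J, hidden = 4, output_dim = 1)
  params <- init_predictor(spec, seed = 3)
  nnz <- integer(0)
  for (lam in c(0, 0.01, 0.1, 0.5)) {
    prob <- generation_problem(list(matrix(1, 1, 1)),
                               list(list(spec = spec, params = params)),
                               list(1.4), beta = 0.05, lambda = lam,
                               cause_bases = list(D))
    W <- suppressWarnings(generate_bipartite_graph(prob))
    nnz <- c(nnz, sum(abs(W) > 1e-8))
  }
  expect_true(all(diff(nnz) <= 0))
})
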