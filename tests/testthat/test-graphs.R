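# Core graph algebra: projection, reconstruction, the truncation identity,
# acyclicity, subspace similarity, thresholding.

test_that("project_graph matches the element-wise brute-force sum", {
  set.seed(10)
  W <- matrix(rnorm(16), 4, 4)
  C <- rand_orth(4, 2)
  U <- project_graph(W, C)
  # independent triple-loop oracle: u_ij = sum_ab c_ai w_ab c_bj
  U_oracle <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    acc <- 0
    for (a in 1:4) for (b in 1:4) acc <- acc + C[a, i] * W[a, b] * C[b, j]
    U_oracle[i, j] <- acc
  }
  expect_equal(U, U_oracle, tolerance = 1e-12)
  # zero and identity special cases
  expect_equal(project_graph(matrix(0, 4, 4), C), matrix(0, 2, 2))
  expect_equal(project_graph(W, diag(4)), W)
})

test_that("projection validates shapes and orthonormality", {
  W <- matrix(rnorm(16), 4, 4)
  expect_error(project_graph(W, rand_orth(5, 2)), "rows")
  expect_error(project_graph(W, matrix(rnorm(8), 4, 2)), "orthonormal")
})

test_that("bipartite projection uses the cause-side basis", {
  set.seed(11)
  W <- matrix(rnorm(3 * 6), 3, 6)
  C <- rand_orth(3, 2)
  D <- rand_orth(6, 2)
  expect_equal(project_graph(W, C, D), t(C) %*% W %*% D, tolerance = 1e-12)
})

test_that("reconstruct o project round-trips in the identity basis", {
  set.seed(12)
  W <- matrix(rnorm(25), 5, 5)
  expect_equal(reconstruct_graph(diag(5), project_graph(W, diag(5))), W)
  expect_equal(reconstruct_graph(rand_orth(5, 2), matrix(0, 2, 2)),
               matrix(0, 5, 5))
})

test_that("truncation identity: direct gap equals norm difference", {
  # ||W - sum_s C_s U_s C_s'||^2 == ||W||^2 - sum_s ||U_s||^2 for
  # pairwise-orthogonal orthonormal bases, on 100 random instances
  set.seed(13)
  for (rep in 1:100) {
    I <- sample(4:9, 1)
    O <- rand_orth(I, min(4, I))
    bases <- list(O[, 1:2, drop = FALSE],
                  O[, 3:min(4, I), drop = FALSE])
    W <- matrix(rnorm(I * I), I, I)
    direct <- reconstruction_gap(W, bases)
    Us <- lapply(bases, function(C) project_graph(W, C))
    identity_form <- sum(W^2) - sum(vapply(Us, function(U) sum(U^2),
                                           numeric(1)))
    expect_equal(direct, identity_form, tolerance = 1e-8)
  }
})

test_that("reconstruction gap handles span-contained and orthogonal cases", {
  set.seed(14)
  C <- rand_orth(6, 2)
  U <- matrix(rnorm(4), 2, 2)
  W_in <- C %*% U %*% t(C)
  expect_equal(reconstruction_gap(W_in, C), 0, tolerance = 1e-10)
  # support orthogonal to the basis span
  C2 <- diag(6)[, 1:2]
  W_out <- matrix(0, 6, 6)
  W_out[4:6, 4:6] <- matrix(rnorm(9), 3, 3)
  expect_equal(reconstruction_gap(W_out, C2), sum(W_out^2), tolerance = 1e-10)
  # non-orthogonal basis pair is rejected
  expect_error(reconstruction_gap(W_in, list(C, C)), "orthogonal")
})

test_that("projection is a contraction for orthonormal bases", {
  set.seed(15)
  for (rep in 1:20) {
    W <- matrix(rnorm(49), 7, 7)
    C <- rand_orth(7, 3)
    expect_lte(sqrt(sum(project_graph(W, C)^2)), sqrt(sum(W^2)) + 1e-12)
  }
})

test_that("acyclicity has the closed form 2cosh(ab) - 2 on a two-cycle", {
  W <- matrix(0, 2, 2)
  W[1, 2] <- 0.7; W[2, 1] <- -1.3
  expect_equal(acyclicity(W), 2 * cosh(0.7 * -1.3) - 2, tolerance = 1e-10)
  expect_equal(acyclicity(matrix(0, 3, 3)), 0, tolerance = 1e-12)
  # strictly triangular supports are nilpotent
  Wt <- matrix(rnorm(36), 6, 6)
  Wt[lower.tri(Wt, diag = TRUE)] <- 0
  expect_equal(acyclicity(Wt), 0, tolerance = 1e-8)
})

test_that("acyclicity separates DAGs from graphs with cycles", {
  set.seed(16)
  for (rep in 1:50) {
    I <- sample(4:8, 1)
    W <- matrix(rnorm(I * I), I, I)
    W[lower.tri(W, diag = TRUE)] <- 0
    perm <- sample(I)
    W_dag <- W[perm, perm]   # permuted triangle is still a DAG
    expect_lt(abs(acyclicity(W_dag)), 1e-8)
    W_cyc <- W_dag
    ij <- sample(I, 2)
    W_cyc[ij[1], ij[2]] <- 0.8
    W_cyc[ij[2], ij[1]] <- 0.9
    expect_gt(acyclicity(W_cyc), 1e-6)
  }
})

test_that("subspace similarity scores identical spans as J", {
  set.seed(17)
  C1 <- rand_orth(10, 2)
  expect_equal(subspace_similarity(C1, C1), 2, tolerance = 1e-10)
  R <- rand_rotation(2)
  expect_equal(subspace_similarity(C1, C1 %*% R), 2, tolerance = 1e-10)
  # orthogonal spans score 0
  O <- rand_orth(10, 4)
  expect_equal(subspace_similarity(O[, 1:2], O[, 3:4]), 0, tolerance = 1e-10)
})

test_that("subspace similarity is symmetric and rotation-invariant", {
  set.seed(18)
  for (rep in 1:10) {
    C1 <- rand_orth(8, 2); C2 <- rand_orth(8, 3)
    s <- subspace_similarity(C1, C2)
    expect_equal(subspace_similarity(C2, C1), s, tolerance = 1e-8)
    expect_equal(subspace_similarity(C1 %*% rand_rotation(2), C2), s,
                 tolerance = 1e-8)
    expect_equal(subspace_similarity(C1, C2 %*% rand_rotation(3)), s,
                 tolerance = 1e-8)
    expect_gte(s, -1e-12)
    expect_lte(s, 2 + 1e-12)
  }
})

test_that("threshold_graph zeroes strictly-below-tau entries only", {
  W <- matrix(c(0.1, -0.5, 0.3, 0), 2, 2)
  Wt <- threshold_graph(W, 0.3)
  expect_equal(as.numeric(Wt), c(0, -0.5, 0.3, 0))
  expect_equal(attr(Wt, "nnz"), 2L)
  expect_equal(threshold_graph(W, 0)[, ], W[, ])
  set.seed(19)
  Wr <- matrix(rnorm(25), 5, 5)
  expect_true(all(threshold_graph(Wr, max(abs(Wr)) + 1) == 0))
  expect_error(threshold_graph(Wr, -1), "non-negative")
})

test_that("family and indicator constructors validate their invariants", {
  g <- lapply(1:3, function(k) matrix(rnorm(9), 3, 3))
  fam <- graph_family(g)
  expect_length(fam, 3)
  expect_error(graph_family(list(g[[1]], matrix(0, 2, 2))), "share")
  expect_error(causal_graph(matrix(0, 2, 3)), "square")
  expect_error(causal_graph(matrix(c(1, Inf, 0, 0), 2, 2)), "finite")
  expect_error(indicator_table(matrix(0, 3, 2), groups = list(a = 5)),
               "unknown")
})
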