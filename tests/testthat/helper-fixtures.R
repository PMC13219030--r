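# Shared fixtures: small random instances built in code, plus independent
# numerical oracles (finite differences, brute-force sums) kept deliberately
# separate from the package's own computational paths.

rand_orth <- function(I, J, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(rnorm(I * J), I, J)))
}

rand_rotation <- function(J, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(J * J), J, J)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Central finite differences of scalar f over the entries of a matrix.
fd_grad_matrix <- function(f, X, h = 1e-6) {
  G <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xm <- X
    Xp[i] <- X[i] + h
    Xm[i] <- X[i] - h
    G[i] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(abs(b), 1e-12)
}

# Tiny random square family with matching regression indicators.
tiny_family <- function(I = 5, K = 3, seed = 1, p = 1) {
  set.seed(seed)
  fam <- graph_family(lapply(seq_len(K), function(k) {
    matrix(rnorm(I * I), I, I)
  }))
  ind <- indicator_table(matrix(rnorm(K * p), K, p),
                         groups = list(m1 = seq_len(p)))
  list(family = fam, indicators = ind)
}

# A fixed random generation problem for the graph-generation tests.
tiny_problem <- function(I = 5, S = 1, J = 2, m = 2, seed = 4,
                         beta = 1e-3, lambda = 0.01, hidden = 6) {
  set.seed(seed)
  bases <- lapply(seq_len(S), function(s) rand_orth(I, J))
  preds <- lapply(seq_len(S), function(s) {
    spec <- predictor_spec(J^2, hidden = hidden, output_dim = m)
    list(spec = spec, params = init_predictor(spec, scale = "raw"))
  })
  targets <- lapply(seq_len(S), function(s) runif(m, -2, 2))
  generation_problem(bases, preds, targets, beta = beta, lambda = lambda)
}
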