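# Post-hoc interpretation of a fitted nonlinear predictor: a bilinear
# surrogate y ~ g'Uh + b fitted by alternating least squares, a rotation
# that decorrelates the latent projections, two-dimensional latent
# coordinate tables, and edge-level contribution matrices.

as_latent_array <- function(latents) {
  if (is.list(latents)) {
    latents <- lapply(latents, as.matrix)
    d <- dim(latents[[1]])
    arr <- array(unlist(latents), dim = c(d[1], d[2], length(latents)))
  } else if (is.array(latents) && length(dim(latents)) == 3) {
    arr <- latents
  } else {
    stop("latents must be a list of matrices or a 3-d array")
  }
  arr
}

#' Fit a bilinear surrogate of the predictor
#'
#' Approximates indicator values by `y_k ~ g'U_k h + b` via alternating
#' least squares: with `h` fixed, `(g, b)` solve a linear regression on the
#' features `U_k h`; with `g` fixed, `(h, b)` solve one on `U_k'g`. Each
#' substep is an exact least-squares solve, so the objective is
#' non-increasing. The scale ambiguity `(g, h) -> (a g, h / a)` is fixed by
#' `||g|| = 1` with the first nonzero entry of `g` positive.
#'
#' @param latents List (or `Je x Jc x K` array) of latent matrices `U_k`.
#' @param y Numeric vector of `K` indicator values.
#' @param max_iter,tol ALS iteration cap and relative objective-change
#'   tolerance.
#' @return Object of class `"linear_surrogate"`: `g`, `h`, `b`, the
#'   squared-error `residual`, the per-iteration `objective` trace, and
#'   `degenerate` flag.
#' @export
fit_surrogate <- function(latents, y, max_iter = 1000L, tol = 1e-10) {
  arr <- as_latent_array(latents)
  K <- dim(arr)[3]
  if (length(y) != K) stop("y must have one value per latent matrix")
  Je <- dim(arr)[1]; Jc <- dim(arr)[2]
  if (K < Je * Jc) {
    warning("fewer samples (", K, ") than bilinear coefficients (", Je * Jc,
            "); the surrogate may be underdetermined")
  }
  if (all(arr == 0)) {
    return(structure(list(g = numeric(Je), h = numeric(Jc), b = mean(y),
                          residual = sum((y - mean(y))^2),
                          objective = sum((y - mean(y))^2),
                          degenerate = TRUE),
                     class = "linear_surrogate"))
  }
  # init: rank-1 direction of the y-weighted latent average
  M <- matrix(0, Je, Jc)
  for (k in seq_len(K)) M <- M + y[k] * arr[, , k]
  sv <- svd(M)
  g <- sv$u[, 1]
  h <- sv$v[, 1] * sv$d[1]
  b <- 0
  obj <- function(g, h, b) {
    pred <- vapply(seq_len(K), function(k) drop(crossprod(g, arr[, , k] %*% h)),
                   numeric(1))
    sum((y - pred - b)^2)
  }
  ls_step <- function(F) {
    # y ~ F coef + b
    fit <- stats::lm.fit(cbind(1, F), y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    co
  }
  o_prev <- obj(g, h, b)
  trace_obj <- o_prev
  for (it in seq_len(max_iter)) {
    Fg <- t(vapply(seq_len(K), function(k) drop(arr[, , k] %*% h),
                   numeric(Je)))
    co <- ls_step(Fg)
    b <- co[1]; g <- co[-1]
    Fh <- t(vapply(seq_len(K), function(k) drop(crossprod(arr[, , k], g)),
                   numeric(Jc)))
    co <- ls_step(Fh)
    b <- co[1]; h <- co[-1]
    o <- obj(g, h, b)
    trace_obj <- c(trace_obj, o)
    if (abs(o_prev - o) <= tol * max(1, o_prev)) break
    o_prev <- o
  }
  ng <- sqrt(sum(g^2))
  if (ng > 0) {
    h <- h * ng
    g <- g / ng
    nz <- which(g != 0)[1]
    if (!is.na(nz) && g[nz] < 0) {
      g <- -g; h <- -h
    }
  }
  structure(list(g = as.numeric(g), h = as.numeric(h), b = as.numeric(b),
                 residual = obj(g, h, b), objective = trace_obj,
                 degenerate = FALSE),
            class = "linear_surrogate")
}

sign_fix_columns <- function(R) {
  for (j in seq_len(ncol(R))) {
    nz <- which(R[, j] != 0)[1]
    if (!is.na(nz) && R[nz, j] < 0) R[, j] <- -R[, j]
  }
  R
}

#' Rotation decorrelating the latent projections
#'
#' Finds the orthogonal `R` that diagonalizes the sample covariance of the
#' cause-direction projections `p_k = U_k'g` (eigen-rotation, axes ordered
#' by descending variance, sign fixed by the first nonzero entry of each
#' column). Applying the same rotation to the basis and the latents leaves
#' the reconstructed graph unchanged.
#'
#' @param latents List (or array) of latent matrices `U_k`.
#' @param surrogate A fitted [fit_surrogate()] object.
#' @return `J x J` orthogonal matrix of class `"matrix"`.
#' @export
orthogonalizing_rotation <- function(latents, surrogate) {
  arr <- as_latent_array(latents)
  K <- dim(arr)[3]
  P <- t(vapply(seq_len(K), function(k) {
    drop(crossprod(arr[, , k], surrogate$g))
  }, numeric(dim(arr)[2])))
  V <- stats::cov(P)
  if (qr(V)$rank < ncol(V)) {
    warning("rank-deficient projection covariance; returning identity")
    return(diag(ncol(V)))
  }
  eg <- eigen(V, symmetric = TRUE)
  sign_fix_columns(eg$vectors)
}

#' Edge-level contribution matrix
#'
#' The rank-one matrix `C g h' C'` quantifying how each observed edge
#' contributes to the surrogate prediction of the indicator. Invariant
#' under a simultaneous rotation of `(C, g, h)`.
#'
#' @param C Mechanism basis (`I x J`; cause-side basis also accepted as
#'   `D` for bipartite problems).
#' @param surrogate A fitted [fit_surrogate()] object.
#' @param D Optional cause-side basis for bipartite problems; the result is
#'   then `C g h' D'`.
#' @return `I x I` (or `I_e x I_c`) contribution matrix.
#' @export
edge_contributions <- function(C, surrogate, D = NULL) {
  C <- as.matrix(C)
  if (is.null(D)) D <- C
  (C %*% surrogate$g) %*% crossprod(surrogate$h, t(as.matrix(D)))
}

#' Latent coordinates of each graph
#'
#' Projects every latent matrix onto the surrogate directions:
#' cause-direction coordinates `R'(U_k'g)` (causal-effect magnitude
#' aggregated over the effect dimension) and effect-direction coordinates
#' `R'(U_k h)`. The first cause-direction component is the axis most
#' aligned with the indicator.
#'
#' @param latents List (or array) of latent matrices.
#' @param surrogate A fitted [fit_surrogate()] object.
#' @param rotation Optional rotation from [orthogonalizing_rotation()];
#'   identity when omitted.
#' @return `list(cause, effect)` of `K x J` coordinate matrices.
#' @export
latent_coordinates <- function(latents, surrogate, rotation = NULL) {
  arr <- as_latent_array(latents)
  K <- dim(arr)[3]
  cause <- t(vapply(seq_len(K), function(k) {
    drop(crossprod(arr[, , k], surrogate$g))
  }, numeric(dim(arr)[2])))
  effect <- t(vapply(seq_len(K), function(k) {
    drop(arr[, , k] %*% surrogate$h)
  }, numeric(dim(arr)[1])))
  if (!is.null(rotation)) {
    cause <- cause %*% rotation
    Re <- if (nrow(rotation) == ncol(effect)) rotation else NULL
    if (!is.null(Re)) effect <- effect %*% Re
  }
  colnames(cause) <- paste0("cause", seq_len(ncol(cause)))
  colnames(effect) <- paste0("effect", seq_len(ncol(effect)))
  list(cause = cause, effect = effect)
}
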