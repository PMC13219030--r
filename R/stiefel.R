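# Unconstrained parameterization of orthonormal matrices: the basis C is the
# polar factor of a free matrix Z, obtained from the SVD Z = P S Q' as
# C = PQ', and gradients in C are pulled back to Z analytically.

#' Construct a Stiefel parameterization point
#'
#' Wraps a free `I x J` matrix `Z` together with its cached thin SVD
#' `Z = P diag(S) Q'`. The induced orthonormal basis is `C = PQ'`, the polar
#' factor of `Z`; optimizing over unconstrained `Z` therefore optimizes `C`
#' over the Stiefel manifold.
#'
#' @param Z Numeric `I x J` matrix of full column rank.
#' @return Object of class `"stiefel_point"` with elements `Z`, `P`, `S`,
#'   `Q` and the derived basis `C`.
#' @export
stiefel_point <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < ncol(Z)) stop("Z must be tall: I >= J")
  sv <- svd(Z)
  if (sv$d[length(sv$d)] <= 1e-10 * sv$d[1]) {
    stop("degenerate Stiefel parameter: Z is (near) rank-deficient; ",
         "re-initialize Z with full column rank")
  }
  structure(list(Z = Z, P = sv$u, S = sv$d, Q = sv$v,
                 C = sv$u %*% t(sv$v)),
            class = "stiefel_point")
}

#' Orthonormalize a free matrix via its polar factor
#'
#' Returns `C = PQ'` from the SVD `Z = P diag(S) Q'`. `C` has exactly
#' orthonormal columns and depends only on the polar part of `Z`
#' (`orthonormalize(Z D) = orthonormalize(Z)` for any symmetric positive
#' definite `D`, in particular positive column scalings).
#'
#' @param Z Numeric matrix of full column rank (or a `stiefel_point`).
#' @return Matrix `C` with `C'C = I`.
#' @export
orthonormalize <- function(Z) {
  if (inherits(Z, "stiefel_point")) return(Z$C)
  stiefel_point(Z)$C
}

#' Pull a gradient in C back to the free parameter Z
#'
#' Given `A = dE/dC` at a Stiefel point with SVD factors `(P, S, Q)`,
#' returns `dE/dZ` via
#' `phi(A, Z) = P[(P'AQ - Q'A'P) / (s_i + s_j)]Q' + (I - PP')A Q S^-1 Q'`,
#' where the division is elementwise against the outer-sum matrix of
#' singular values. This is the exact chain rule through `C = PQ'`.
#'
#' @param A Gradient with respect to `C` (same shape as `C`).
#' @param point A `stiefel_point` (or a raw `Z` matrix).
#' @return Matrix `dE/dZ`, same shape as `Z`.
#' @export
stiefel_pullback <- function(A, point) {
  if (!inherits(point, "stiefel_point")) point <- stiefel_point(point)
  A <- as.matrix(A)
  if (!identical(dim(A), dim(point$Z))) {
    stop("gradient shape ", paste(dim(A), collapse = "x"),
         " does not match Z shape ", paste(dim(point$Z), collapse = "x"))
  }
  P <- point$P; S <- point$S; Q <- point$Q
  denom <- outer(S, S, "+")
  if (any(denom < 1e-12)) {
    stop("degenerate Stiefel parameter: singular-value sums below 1e-12; ",
         "re-initialize Z")
  }
  PtAQ <- crossprod(P, A %*% Q)
  skew <- (PtAQ - t(PtAQ)) / denom
  term1 <- P %*% skew %*% t(Q)
  AQ <- A %*% Q
  term2 <- (AQ - P %*% crossprod(P, AQ)) %*% (t(Q) / S)
  term1 + term2
}
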