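# The generative direction: synthesize a graph W from fixed mechanism bases,
# predictors and target indicators by minimizing
#   D(W) = sum_s loss(y_s, H_s[U_s]) + beta ||W - sum_s C_s U_s C_s'||^2
#          + lambda ||W||_1,   U_s = C_s'WC_s,
# subject to acyclicity (square case; enforced by an augmented Lagrangian on
# h(W) = tr(exp(W*W)) - I), or unconstrained in the bipartite case.

#' Define a graph-generation problem
#'
#' @param bases List of effect-side bases `C_s` (a single matrix accepted).
#' @param predictors List per mechanism of `list(spec, params)` describing
#'   the fixed functional `H_s`.
#' @param targets List per mechanism of target indicator vectors `y_s`
#'   (one-hot rows for classification specs).
#' @param beta Reconstruction weight (`>= 0`).
#' @param lambda L1 weight on the entries of `W` (`>= 0`).
#' @param cause_bases Optional cause-side bases `D_s` for the bipartite
#'   case (`U_s = C_s'WD_s`).
#' @return Object of class `"generation_problem"`.
#' @export
generation_problem <- function(bases, predictors, targets, beta = 1e-3,
                               lambda = 0.01, cause_bases = NULL) {
  if (is.matrix(bases)) bases <- list(bases)
  if (!is.null(cause_bases) && is.matrix(cause_bases)) {
    cause_bases <- list(cause_bases)
  }
  if (beta < 0 || lambda < 0) stop("beta and lambda must be >= 0")
  S <- length(bases)
  if (length(predictors) != S || length(targets) != S) {
    stop("need one predictor and one target vector per mechanism")
  }
  for (s in seq_len(S)) check_orthonormal(bases[[s]], what = paste0("C_", s))
  if (!is.null(cause_bases)) {
    for (s in seq_len(S)) {
      check_orthonormal(cause_bases[[s]], what = paste0("D_", s))
    }
  }
  structure(list(bases = bases, predictors = predictors, targets = targets,
                 beta = beta, lambda = lambda, cause_bases = cause_bases),
            class = "generation_problem")
}

# Smooth part of the generation loss and its gradient in W.
generation_smooth <- function(W, problem, want_grad = FALSE) {
  bases <- problem$bases
  Db <- problem$cause_bases
  S <- length(bases)
  recon <- matrix(0, nrow(W), ncol(W))
  loss <- 0
  grad <- if (want_grad) matrix(0, nrow(W), ncol(W)) else NULL
  Us <- vector("list", S)
  for (s in seq_len(S)) {
    C <- bases[[s]]
    D <- if (is.null(Db)) C else Db[[s]]
    U <- crossprod(C, W %*% D)
    Us[[s]] <- U
    recon <- recon + C %*% U %*% t(D)
    spec <- problem$predictors[[s]]$spec
    lg <- predictor_loss_grads(spec, problem$predictors[[s]]$params,
                               matrix(as.numeric(U), 1),
                               matrix(problem$targets[[s]], 1))
    loss <- loss + lg$loss
    if (want_grad) {
      G <- matrix(lg$dX, nrow(U), ncol(U))
      grad <- grad + C %*% G %*% t(D)
    }
  }
  E <- W - recon
  loss <- loss + problem$beta * fro2(E)
  if (want_grad) {
    # adjoint of W -> W - sum_s P_s W P_s applied to E
    proj <- matrix(0, nrow(W), ncol(W))
    for (s in seq_len(S)) {
      C <- bases[[s]]
      D <- if (is.null(Db)) C else Db[[s]]
      proj <- proj + C %*% crossprod(C, E %*% D) %*% t(D)
    }
    grad <- grad + 2 * problem$beta * (E - proj)
  }
  list(value = loss, grad = grad, latents = Us)
}

#' Generation loss of a candidate graph
#'
#' `D(W) = sum_s loss(y_s, H_s[C_s'WC_s]) + beta ||W - sum_s C_sU_sC_s'||^2
#' + lambda ||W||_1`. The reconstruction term is evaluated in direct form,
#' so the bases need not be mutually orthogonal.
#'
#' @param W Candidate weight matrix.
#' @param problem A [generation_problem()].
#' @return Scalar loss.
#' @export
generation_loss <- function(W, problem) {
  W <- as.matrix(W)
  if (nrow(W) != nrow(problem$bases[[1]])) {
    stop("W rows do not match the effect-side basis")
  }
  generation_smooth(W, problem)$value + problem$lambda * sum(abs(W))
}

#' Solver configuration for graph generation
#'
#' @param h_tol Acyclicity target for the augmented Lagrangian.
#' @param rho_init,rho_max,outer_max Penalty schedule: `rho` is multiplied
#'   by 10 whenever `h` fails to shrink by 4x, up to `rho_max`, for at most
#'   `outer_max` outer iterations; the dual variable is updated as
#'   `alpha <- alpha + rho * h`.
#' @param inner_max,inner_tol Proximal-gradient budget and relative step
#'   tolerance of the inner solver.
#' @param final_threshold Entries with `|w|` below this are zeroed after
#'   optimization (h is monotone in `|w_ij|`, so thresholding can only
#'   reduce it).
#' @param jitter_sd,seed Optional Gaussian jitter on the `W = 0` start.
#' @return List of solver settings.
#' @export
gen_config <- function(h_tol = 1e-8, rho_init = 1, rho_max = 1e16,
                       outer_max = 100L, inner_max = 300L, inner_tol = 1e-7,
                       final_threshold = 0.01, jitter_sd = 0, seed = NULL) {
  list(h_tol = h_tol, rho_init = rho_init, rho_max = rho_max,
       outer_max = as.integer(outer_max), inner_max = as.integer(inner_max),
       inner_tol = inner_tol, final_threshold = final_threshold,
       jitter_sd = jitter_sd, seed = seed)
}

# L-BFGS-B minimization of smooth(W) + lambda ||W||_1 via the split
# W = Wpos - Wneg (both >= 0), which turns the L1 term into a linear one.
# zero_diag pins diag(W) to 0 by fixing those coordinates at zero.
lbfgsb_l1 <- function(W0, smooth_fn, lambda, maxit, zero_diag = FALSE) {
  d <- dim(W0)
  n <- length(W0)
  par0 <- c(pmax(W0, 0), pmax(-W0, 0))
  upper <- rep(Inf, 2 * n)
  if (zero_diag) {
    di <- seq(1, n, by = d[1] + 1)
    upper[di] <- 0
    upper[n + di] <- 0
    par0[c(di, n + di)] <- 0
  }
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$sg)
    W <- matrix(par[1:n] - par[(n + 1):(2 * n)], d[1], d[2])
    sg <- smooth_fn(W)
    cache$par <- par
    cache$sg <- sg
    sg
  }
  fn <- function(par) {
    sg <- eval_at(par)
    v <- sg$value + lambda * sum(par)
    if (!is.finite(v)) v <- .Machine$double.xmax
    v
  }
  gr <- function(par) {
    sg <- eval_at(par)
    g <- as.numeric(sg$grad)
    g[!is.finite(g)] <- 0
    c(g, -g) + lambda
  }
  res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = 0, upper = upper,
                      control = list(maxit = maxit, factr = 1e3))
  W <- matrix(res$par[1:n] - res$par[(n + 1):(2 * n)], d[1], d[2])
  if (zero_diag) diag(W) <- 0
  sg <- smooth_fn(W)
  list(W = W, value = sg$value + lambda * sum(abs(W)), grad = sg$grad,
       iterations = res$counts[1])
}

# Monotone proximal-gradient minimization of smooth(W) + lambda ||W||_1 with
# Barzilai-Borwein step and backtracking. zero_diag pins diag(W) to 0.
prox_gradient <- function(W, smooth_fn, lambda, max_iter, tol,
                          zero_diag = FALSE, t_init = 1) {
  soft <- function(A, q) sign(A) * pmax(abs(A) - q, 0)
  sg <- smooth_fn(W)
  f <- sg$value; g <- sg$grad
  if (zero_diag) diag(g) <- 0
  t_step <- t_init
  W_prev <- NULL; g_prev <- NULL
  for (it in seq_len(max_iter)) {
    if (!is.null(W_prev)) {
      dW <- W - W_prev; dG <- g - g_prev
      denom <- sum(dW * dG)
      if (denom > 0) t_step <- max(1e-12, min(1e12, sum(dW * dW) / denom))
    }
    repeat {
      W_new <- soft(W - t_step * g, t_step * lambda)
      if (zero_diag) diag(W_new) <- 0
      sg_new <- smooth_fn(W_new)
      dW <- W_new - W
      if (is.finite(sg_new$value) &&
          sg_new$value <= f + sum(g * dW) + fro2(dW) / (2 * t_step) + 1e-12) {
        break
      }
      t_step <- t_step / 2
      if (t_step < 1e-15) {
        W_new <- W
        sg_new <- list(value = f, grad = g)
        break
      }
    }
    step_norm <- sqrt(fro2(W_new - W))
    W_prev <- W; g_prev <- g
    W <- W_new; f <- sg_new$value; g <- sg_new$grad
    if (zero_diag) diag(g) <- 0
    if (step_norm <= tol * max(1, sqrt(fro2(W)))) break
  }
  list(W = W, value = f, grad = g, iterations = it)
}

#' Generate a DAG-constrained graph from fixed mechanisms
#'
#' Minimizes the generation loss subject to acyclicity via the standard
#' augmented-Lagrangian scheme on `h(W) = tr(exp(W*W)) - I`: inner proximal
#' gradient on the smooth part plus the L1 prox, the diagonal pinned to
#' zero, the penalty escalated until `h` reaches tolerance, and a final hard
#' threshold on tiny entries.
#'
#' @param problem A [generation_problem()] with square bases.
#' @param config A [gen_config()].
#' @return The generated `I x I` weight matrix with attributes
#'   `"acyclicity"`, `"loss"` and `"trace"` (per-outer-iteration log).
#' @export
generate_graph <- function(problem, config = gen_config()) {
  I <- nrow(problem$bases[[1]])
  if (!is.null(problem$cause_bases)) {
    stop("generate_graph is for the square case; use ",
         "generate_bipartite_graph for cause/effect-separated problems")
  }
  W <- matrix(0, I, I)
  if (config$jitter_sd > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    W <- matrix(stats::rnorm(I * I, sd = config$jitter_sd), I, I)
    diag(W) <- 0
  }
  rho <- config$rho_init
  alpha <- 0
  h_prev <- Inf
  trace_log <- list()
  for (outer in seq_len(config$outer_max)) {
    # re-solve at increasing rho (same dual) until h shrinks by 4x
    repeat {
      smooth_fn <- function(Wc) {
        base <- generation_smooth(Wc, problem, want_grad = TRUE)
        hg <- acyclicity_grad(Wc)
        mult <- alpha + rho * hg$h
        list(value = base$value + alpha * hg$h + 0.5 * rho * hg$h^2,
             grad = base$grad + mult * hg$grad)
      }
      sol <- lbfgsb_l1(W, smooth_fn, problem$lambda, config$inner_max,
                       zero_diag = TRUE)
      h_new <- acyclicity(sol$W)
      if (h_new > h_prev / 4 && rho < config$rho_max) {
        rho <- rho * 10
      } else break
    }
    W <- sol$W
    h_prev <- h_new
    alpha <- alpha + rho * h_new
    trace_log[[outer]] <- c(outer = outer, rho = rho, alpha = alpha,
                            h = h_new, inner = sol$iterations)
    if (h_new <= config$h_tol) break
  }
  W <- threshold_graph(W, config$final_threshold)
  attr(W, "nnz") <- NULL
  diag(W) <- 0
  h_final <- acyclicity(W)
  if (h_final > 1e-8) {
    cond <- structure(
      class = c("tripnet_convergence_error", "error", "condition"),
      list(message = sprintf(
        "generated graph failed the acyclicity tolerance (h = %.3g)", h_final),
        call = sys.call(-1), W_best = W))
    stop(cond)
  }
  attr(W, "acyclicity") <- h_final
  attr(W, "loss") <- generation_loss(W, problem)
  attr(W, "trace") <- do.call(rbind, trace_log)
  W
}

#' Generate a bipartite graph (no acyclicity constraint)
#'
#' In the cause/effect-separated case the graph needs no DAG constraint, so
#' the generation loss plus L1 penalty is minimized by plain proximal
#' gradient descent.
#'
#' @param problem A [generation_problem()] with `cause_bases` supplied.
#' @param config A [gen_config()]; only the inner-solver settings are used.
#' @return The generated `I_e x I_c` weight matrix with attributes
#'   `"loss"` and `"stationarity"` (max violation of the first-order
#'   conditions on the smooth part).
#' @export
generate_bipartite_graph <- function(problem, config = gen_config()) {
  if (is.null(problem$cause_bases)) {
    stop("bipartite generation needs cause_bases in the problem")
  }
  Ie <- nrow(problem$bases[[1]])
  Ic <- nrow(problem$cause_bases[[1]])
  W <- matrix(0, Ie, Ic)
  if (config$jitter_sd > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    W <- matrix(stats::rnorm(Ie * Ic, sd = config$jitter_sd), Ie, Ic)
  }
  smooth_fn <- function(Wc) {
    sg <- generation_smooth(Wc, problem, want_grad = TRUE)
    list(value = sg$value, grad = sg$grad)
  }
  sol <- prox_gradient(W, smooth_fn, problem$lambda,
                       max_iter = 20L * config$inner_max,
                       tol = config$inner_tol / 10)
  W <- sol$W
  g <- sol$grad
  lam <- problem$lambda
  viol <- ifelse(W != 0, abs(g + lam * sign(W)), pmax(abs(g) - lam, 0))
  stat <- max(viol)
  if (stat > 1e-5) {
    warning(sprintf(
      "bipartite generation stopped with stationarity %.3g (> 1e-5)", stat))
  }
  attr(W, "loss") <- generation_loss(W, problem)
  attr(W, "stationarity") <- stat
  W
}
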