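# Small optimizer utilities shared by the fitting routines. Parameter
# containers are arbitrarily nested lists of numeric arrays; gradients must
# mirror their structure.

flatten_params <- function(p) {
  if (is.numeric(p)) return(list(p))
  unlist(lapply(p, flatten_params), recursive = FALSE)
}

map_params <- function(f, ...) {
  args <- list(...)
  if (is.numeric(args[[1]])) return(do.call(f, args))
  out <- vector("list", length(args[[1]]))
  names(out) <- names(args[[1]])
  for (i in seq_along(out)) {
    out[[i]] <- do.call(map_params, c(list(f), lapply(args, `[[`, i)))
  }
  out
}

adam_state <- function(params) {
  zero <- function(x) x * 0
  list(m = map_params(zero, params), v = map_params(zero, params), t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- map_params(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr) {
  map_params(function(p, g) p - lr * g, params, grads)
}

# Central finite differences of a scalar function over a parameter list;
# used by tests but exported nowhere.
numeric_gradient <- function(f, params, h = 1e-6) {
  map_params_indexed <- function(p, path) {
    if (is.numeric(p)) {
      g <- p * 0
      for (i in seq_along(p)) {
        pp <- p; pp[i] <- p[i] + h
        pm <- p; pm[i] <- p[i] - h
        g[i] <- (f(assign_path(params, path, pp)) -
                   f(assign_path(params, path, pm))) / (2 * h)
      }
      return(g)
    }
    out <- vector("list", length(p)); names(out) <- names(p)
    for (i in seq_along(p)) out[[i]] <- map_params_indexed(p[[i]], c(path, i))
    out
  }
  map_params_indexed(params, integer(0))
}

assign_path <- function(params, path, value) {
  if (length(path) == 0) return(value)
  params[[path[1]]] <- assign_path(params[[path[1]]], path[-1], value)
  params
}
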