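# Optimizers over the nested layer/parameter structure. State (momentum
# buffers) lives in the optimizer's environment, mirroring the layer tree.

# Recursively walk layers/grads/state in parallel; f(p, g, s, name) must
# return list(p = updated param, s = updated state).
opt_walk <- function(layer, grad, state, f) {
  if (!is.null(layer$sub)) {
    if (is.null(state)) state <- list()
    for (nm in names(layer$sub)) {
      if (is.null(grad[[nm]])) next
      r <- opt_walk(layer$sub[[nm]], grad[[nm]], state[[nm]], f)
      layer$sub[[nm]] <- r$layer
      state[[nm]] <- r$state
    }
  } else if (length(layer$params)) {
    if (is.null(state)) state <- list()
    for (nm in names(layer$params)) {
      g <- grad[[nm]]
      if (is.null(g)) next
      r <- f(layer$params[[nm]], g, state[[nm]], nm)
      layer$params[[nm]] <- r$p
      state[[nm]] <- r$s
    }
  }
  list(layer = layer, state = state)
}

# Normalization affines and biases are excluded from LARS trust-ratio
# adaptation and from weight decay (standard LARS practice).
is_adapted_param <- function(name) name == "w" || name %in% c("theta", "phi", "g", "wz")

#' Create an optimizer
#'
#' `"sgd"` is momentum SGD with L2 weight decay folded into the gradient
#' (the convention of mainstream deep-learning frameworks). `"lars"` wraps the
#' same update with a per-parameter-tensor trust ratio
#' `||p|| / (||g|| + wd * ||p|| + eps)`, scaled by `trust_coef`; biases and
#' group-norm affines are excluded from both adaptation and decay.
#'
#' @param type `"sgd"` or `"lars"`.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param trust_coef LARS trust coefficient.
#' @return An optimizer object with a `$step(layers, grads, lr)` method that
#'   returns the updated layers.
#' @export
make_optimizer <- function(type = c("sgd", "lars"), momentum = 0.9,
                           weight_decay = 0, trust_coef = 0.01) {
  type <- match.arg(type)
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  eps <- 1e-9

  update_fun <- function(lr) {
    function(p, g, s, name) {
      if (type == "sgd") {
        geff <- g + weight_decay * p
        scale <- lr
      } else if (is_adapted_param(name)) {
        geff <- g + weight_decay * p
        pn <- sqrt(sum(p * p))
        gn <- sqrt(sum(geff * geff))
        trust <- if (pn > 0 && gn > 0) trust_coef * pn / (gn + eps) else 1
        scale <- lr * trust
      } else {
        geff <- g
        scale <- lr
      }
      v <- if (is.null(s)) scale * geff else momentum * s + scale * geff
      list(p = p - v, s = v)
    }
  }

  step <- function(layers, grads, lr) {
    if (is.null(env$state)) env$state <- vector("list", length(layers))
    f <- update_fun(lr)
    for (i in seq_along(layers)) {
      if (is.null(grads[[i]])) next
      r <- opt_walk(layers[[i]], grads[[i]], env$state[[i]], f)
      layers[[i]] <- r$layer
      env$state[i] <- list(r$state)  # may be NULL: keep list length
    }
    layers
  }

  structure(list(type = type, momentum = momentum,
                 weight_decay = weight_decay, trust_coef = trust_coef,
                 step = step, env = env),
            class = "usv_optimizer")
}

#' Cosine-annealed learning rate
#'
#' `eta_t = eta_min + 0.5 * (eta0 - eta_min) * (1 + cos(pi * t / t_max))`.
#'
#' @param t Current epoch (0-based).
#' @param t_max Total number of epochs.
#' @param eta0 Initial learning rate.
#' @param eta_min Floor learning rate.
#' @return The learning rate at epoch `t`.
#' @export
cosine_lr <- function(t, t_max, eta0, eta_min = 0) {
  eta_min + 0.5 * (eta0 - eta_min) * (1 + cos(pi * t / t_max))
}

# Elementwise combination of two grad trees (accumulation across microbatches).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- grads_add(a[[i]], b[[i]])
    a
  } else a + b
}

# Scale every leaf of a grad tree.
grads_scale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) {
    for (i in seq_along(g)) g[[i]] <- grads_scale(g[[i]], s)
    g
  } else g * s
}
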