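# Temporal aggregator: a cascade of shared per-frame linear+Tanh layers
# produces T x m attention logits; softmax across the frame axis (per feature
# dimension) gives a column-stochastic attention matrix; the aggregated
# video-level feature is the per-dimension convex combination of the frame
# features. Uniform logits reduce the module exactly to average pooling, and
# a hard per-dimension one-hot drives it toward max pooling.

#' Attention cascade configuration
#'
#' @param num_layers Cascade depth `L` (>= 1); every layer maps m -> m.
#' @param final_activation `"tanh"` (the literal cascade, logits bounded in
#'   (-1, 1)) or `"none"` (unbounded final logits; required to realize the
#'   max-pooling limit exactly).
#' @return An `attention_config` list.
#' @export
attention_config <- function(num_layers = 2L,
                             final_activation = c("tanh", "none")) {
  if (num_layers < 1) stop("attention_config: num_layers must be >= 1")
  structure(list(num_layers = as.integer(num_layers),
                 final_activation = match.arg(final_activation)),
            class = "attention_config")
}

#' Build attention cascade weights
#'
#' @param m Feature dimension; all layers are `m x m`.
#' @param config An [attention_config()].
#' @param seed Integer seed for initialization (Xavier for the Tanh cascade).
#' @return A `usv_attention` weight set.
#' @export
build_attention <- function(m, config = attention_config(), seed = 0L) {
  with_seed(seed, {
    layers <- lapply(seq_len(config$num_layers), function(l) {
      list(w = matrix(stats::rnorm(m * m, sd = sqrt(1 / m)), m, m),
           b = numeric(m))
    })
    structure(list(m = as.integer(m), config = config, layers = layers),
              class = "usv_attention")
  })
}

check_features <- function(features) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (!all(is.finite(features))) {
    stop("attention: features contain non-finite values")
  }
  features
}

#' Attention logits for a frame-feature sequence
#'
#' Applies the cascade `E_l = sigma(W_l E_{l-1} + b_l)` (shared weights across
#' frames, no cross-frame mixing) to each frame feature; `E_0` is the feature
#' itself.
#'
#' @param features `T x m` matrix, one row per frame.
#' @param weights A `usv_attention` from [build_attention()].
#' @return `T x m` logits matrix (entries in (-1, 1) under the Tanh default).
#' @export
attention_logits <- function(features, weights) {
  features <- check_features(features)
  if (ncol(features) != weights$m) {
    stop("attention_logits: features have width ", ncol(features),
         " but weights expect ", weights$m)
  }
  attention_cascade_fw(features, weights)$logits
}

attention_cascade_fw <- function(features, weights) {
  L <- weights$config$num_layers
  acts <- vector("list", L + 1)
  acts[[1]] <- features
  E <- features
  for (l in seq_len(L)) {
    Z <- E %*% t(weights$layers[[l]]$w)
    Z <- sweep(Z, 2, weights$layers[[l]]$b, "+")
    E <- if (l < L || weights$config$final_activation == "tanh") tanh(Z) else Z
    acts[[l + 1]] <- E
  }
  list(logits = E, acts = acts)
}

#' Attention weights from logits
#'
#' Per feature dimension `i`, a softmax over the frame axis:
#' `A[t, i] = exp(e[t, i]) / sum_j exp(e[j, i])`; every column of the result
#' sums to 1. Computed with per-dimension max subtraction for stability.
#'
#' @param logits `T x m` matrix of finite reals.
#' @return `T x m` attention matrix with unit column sums.
#' @export
attention_weights <- function(logits) {
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1)
  if (!all(is.finite(logits))) {
    stop("attention_weights: logits must be finite")
  }
  e <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

#' Aggregate frame features under an attention matrix
#'
#' `F_bar[i] = sum_t A[t, i] * F[t, i]` -- the elementwise (bitwise) product
#' summed over frames. With uniform attention this is exactly the frame mean.
#'
#' @param features `T x m` frame features.
#' @param attention `T x m` attention matrix (column sums 1).
#' @return Aggregated feature vector of length `m`.
#' @export
aggregate <- function(features, attention) {
  features <- check_features(features)
  if (!is.matrix(attention)) attention <- matrix(attention, nrow = 1)
  if (!all(dim(features) == dim(attention))) {
    stop("aggregate: features are ", paste(dim(features), collapse = "x"),
         " but attention is ", paste(dim(attention), collapse = "x"))
  }
  colSums(features * attention)
}

#' Attention pooling: logits -> softmax -> aggregate
#'
#' The full temporal aggregation operator. It accepts any number of frames
#' without reconfiguration and is invariant to frame order.
#'
#' @inheritParams attention_logits
#' @return Aggregated feature vector of length `m`.
#' @export
attention_pool <- function(features, weights) {
  features <- check_features(features)
  aggregate(features, attention_weights(attention_logits(features, weights)))
}

#' Average and max pooling baselines
#'
#' The two degenerate cases of attention pooling: uniform weights (average)
#' and the limit of per-dimension one-hot weights (max).
#'
#' @param features `T x m` matrix of frame features.
#' @return Vector of length `m`.
#' @export
average_pool <- function(features) {
  features <- check_features(features)
  colMeans(features)
}

#' @rdname average_pool
#' @export
max_pool <- function(features) {
  features <- check_features(features)
  apply(features, 2, max)
}

# Forward with cache for training.
attention_pool_fw <- function(features, weights) {
  cas <- attention_cascade_fw(features, weights)
  A <- attention_weights(cas$logits)
  list(y = colSums(features * A), A = A, acts = cas$acts)
}

# Backward: dout is an m-vector; returns gradient wrt features and weights.
attention_pool_bw <- function(features, weights, cache, dout) {
  Tn <- nrow(features)
  m <- ncol(features)
  A <- cache$A
  Dm <- matrix(dout, Tn, m, byrow = TRUE)
  dX <- A * Dm
  dA <- features * Dm
  # columnwise softmax backward
  dE <- A * sweep(dA, 2, colSums(dA * A))
  L <- weights$config$num_layers
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    El <- cache$acts[[l + 1]]
    dZ <- if (l < L || weights$config$final_activation == "tanh") {
      dE * (1 - El * El)
    } else dE
    grads[[l]] <- list(w = t(dZ) %*% cache$acts[[l]], b = colSums(dZ))
    dE <- dZ %*% weights$layers[[l]]$w
  }
  list(dfeatures = dX + dE, grads = grads)
}
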