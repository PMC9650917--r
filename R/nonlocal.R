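# Non-local block: embedded-Gaussian self-attention over spatial positions,
# added residually. For a map with P = H*W positions, each position's response
# is a softmax-weighted sum over all P positions of a bottlenecked (C/2)
# embedding, projected back to C channels by an output weight that is
# zero-initialized so the block starts as the identity.

nonlocal_layer <- function(channels, zero_init_out = TRUE) {
  if (channels %% 2 != 0) {
    stop("non_local: channel count must be even (bottleneck C/2), got ",
         channels)
  }
  ch <- channels %/% 2
  sd <- sqrt(2 / channels)
  list(
    type = "nonlocal",
    params = list(
      theta = matrix(stats::rnorm(channels * ch, sd = sd), channels, ch),
      phi   = matrix(stats::rnorm(channels * ch, sd = sd), channels, ch),
      g     = matrix(stats::rnorm(channels * ch, sd = sd), channels, ch),
      wz    = if (zero_init_out) matrix(0, ch, channels) else
                matrix(stats::rnorm(ch * channels, sd = sqrt(2 / ch)),
                       ch, channels)
    )
  )
}

row_softmax <- function(s) {
  s <- exp(s - apply(s, 1, max))
  s / rowSums(s)
}

nonlocal_fw <- function(layer, x) {
  p <- layer$params
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  P <- H * W
  y <- x
  cache <- vector("list", N)
  for (n in seq_len(N)) {
    X <- x[, , , n, drop = FALSE]
    dim(X) <- c(P, C)
    Th <- X %*% p$theta
    Ph <- X %*% p$phi
    G  <- X %*% p$g
    A <- row_softmax(tcrossprod(Th, Ph))
    Y <- A %*% G
    Z <- Y %*% p$wz
    y[, , , n] <- array(y[, , , n, drop = FALSE] + as.numeric(Z),
                        dim = c(H, W, C))
    cache[[n]] <- list(X = X, Th = Th, Ph = Ph, G = G, A = A, Y = Y)
  }
  list(y = y, cache = list(per = cache, d = d))
}

nonlocal_bw <- function(layer, cache, dy) {
  p <- layer$params
  d <- cache$d
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  P <- H * W
  dx <- dy
  dth <- matrix(0, C, ncol(p$theta))
  dph <- dth
  dg <- dth
  dwz <- matrix(0, ncol(p$theta), C)
  for (n in seq_len(N)) {
    cc <- cache$per[[n]]
    dZ <- dy[, , , n, drop = FALSE]
    dim(dZ) <- c(P, C)
    dwz <- dwz + crossprod(cc$Y, dZ)
    dY <- tcrossprod(dZ, p$wz)
    dA <- tcrossprod(dY, cc$G)
    dG <- crossprod(cc$A, dY)
    dS <- cc$A * (dA - rowSums(dA * cc$A))
    dTh <- dS %*% cc$Ph
    dPh <- crossprod(dS, cc$Th)
    dX <- tcrossprod(dTh, p$theta) + tcrossprod(dPh, p$phi) +
      tcrossprod(dG, p$g)
    dth <- dth + crossprod(cc$X, dTh)
    dph <- dph + crossprod(cc$X, dPh)
    dg <- dg + crossprod(cc$X, dG)
    dx[, , , n] <- array(dx[, , , n, drop = FALSE] + as.numeric(dX),
                         dim = c(H, W, C))
  }
  list(dx = dx, grads = list(theta = dth, phi = dph, g = dg, wz = dwz))
}

#' Create weights for a standalone non-local block
#'
#' @param channels Number of input channels `C`; must be even (the pairwise
#'   embeddings use a `C/2` bottleneck).
#' @param zero_init_out If `TRUE` (default) the output projection is zero, so
#'   the block computes the identity until trained.
#' @param seed Optional integer seed for the embedding weights.
#' @return A weight set accepted by [non_local()].
#' @export
non_local_weights <- function(channels, zero_init_out = TRUE, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  nonlocal_layer(channels, zero_init_out)
}

#' Apply a non-local self-attention block to a feature map
#'
#' Every spatial position's response is a softmax-normalized weighted sum of
#' the (bottlenecked) features at all positions -- the embedded-Gaussian
#' pairwise form -- added residually: `out = x + Wz %*% y(x)`. With the output
#' projection zero-initialized the block is exactly the identity.
#'
#' @param x Numeric array `(C, H, W)` (single map) or `(H, W, C, N)` batch.
#' @param weights Weights from [non_local_weights()].
#' @return Array of the same shape as `x`.
#' @examples
#' w <- non_local_weights(4, seed = 1)
#' x <- array(rnorm(4 * 5 * 5), dim = c(4, 5, 5))
#' stopifnot(all(abs(non_local(x, w) - x) < 1e-12))
#' @export
non_local <- function(x, weights) {
  d <- dim(x)
  chw <- length(d) == 3
  if (chw) {
    # single map given channel-first: transpose to internal (H, W, C, 1)
    x <- aperm(x, c(2, 3, 1))
    dim(x) <- c(d[2], d[3], d[1], 1L)
  }
  C <- dim(x)[3]
  if (nrow(weights$params$theta) != C) {
    stop("non_local: weights built for ", nrow(weights$params$theta),
         " channels, input has ", C)
  }
  y <- nonlocal_fw(weights, x)$y
  if (chw) {
    dim(y) <- d[c(2, 3, 1)]
    y <- aperm(y, c(3, 1, 2))
  }
  y
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's RNG.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  force(code)
}
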