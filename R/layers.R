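# Primitive differentiable layers. Tensors are R arrays in (H, W, C, N)
# layout; feature matrices are (features x batch). Each layer is a list with
# $type, hyperparameters, and $params (named numeric arrays). Forward passes
# return list(y, cache); backward passes take (layer, cache, dy) and return
# list(dx, grads) with grads mirroring $params.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

conv_layer <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  list(
    type = "conv", stride = as.integer(stride), pad = as.integer(pad),
    params = list(
      w = he_init(c(kh, kw, cin, cout), fan_in = kh * kw * cin),
      b = numeric(cout)
    )
  )
}

conv_fw <- function(layer, x) {
  y <- cpp_conv2d_fw(x, layer$params$w, layer$params$b, layer$stride, layer$pad)
  list(y = y, cache = x)
}

conv_bw <- function(layer, cache, dy) {
  g <- cpp_conv2d_bw(cache, layer$params$w, dy, layer$stride, layer$pad)
  list(dx = g$dx, grads = list(w = g$dw, b = g$db))
}

# Effective group count: the largest divisor of `channels` not exceeding
# `groups` that divides evenly; gcd covers the narrow-layer presets.
effective_groups <- function(groups, channels) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  if (channels %% groups == 0) groups else g(groups, channels)
}

gn_layer <- function(channels, groups = 32L, eps = 1e-5) {
  list(
    type = "gn", groups = as.integer(effective_groups(groups, channels)),
    eps = eps,
    params = list(gamma = rep(1, channels), beta = numeric(channels))
  )
}

gn_fw_core <- function(x, groups, eps, gamma, beta) {
  if (dim(x)[3] %% groups != 0) {
    stop("group_normalize: groups (", groups, ") must divide channels (",
         dim(x)[3], ")")
  }
  r <- cpp_gn_fw(x, as.integer(groups), eps, gamma, beta)
  list(y = r$y, cache = list(xhat = r$xhat, istd = r$istd, gamma = gamma,
                             groups = groups))
}

gn_fw <- function(layer, x) {
  gn_fw_core(x, layer$groups, layer$eps, layer$params$gamma, layer$params$beta)
}

gn_bw <- function(layer, cache, dy) {
  r <- cpp_gn_bw(cache$xhat, cache$istd, cache$gamma, dy,
                 as.integer(cache$groups))
  list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

relu_layer <- function() list(type = "relu", params = list())

# cache is the output itself: the mask dy needs is just y > 0
relu_fw <- function(layer, x) {
  y <- cpp_relu_fw(x)
  list(y = y, cache = y)
}

relu_bw <- function(layer, cache, dy) {
  list(dx = cpp_relu_bw(dy, cache), grads = list())
}

maxpool_layer <- function(k = 3L, stride = 2L, pad = 1L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), params = list())
}

maxpool_fw <- function(layer, x) {
  r <- cpp_maxpool_fw(x, layer$k, layer$stride, layer$pad)
  list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)))
}

maxpool_bw <- function(layer, cache, dy) {
  list(dx = cpp_maxpool_bw(dy, cache$argmax, as.integer(cache$xdim)),
       grads = list())
}

# Global average pool: (H, W, C, N) -> (C, N)
gap_layer <- function() list(type = "gap", params = list())

gap_fw <- function(layer, x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  y <- matrix(colMeans(xm), d[3], d[4])
  list(y = y, cache = d)
}

gap_bw <- function(layer, cache, dy) {
  d <- cache
  HW <- d[1] * d[2]
  dx <- array(rep(as.numeric(dy) / HW, each = HW), dim = d)
  list(dx = dx, grads = list())
}

# Dense layer on (in x batch) matrices: y = W x + b
linear_layer <- function(d_in, d_out, init_sd = sqrt(2 / d_in)) {
  list(
    type = "linear",
    params = list(
      w = matrix(stats::rnorm(d_out * d_in, sd = init_sd), d_out, d_in),
      b = numeric(d_out)
    )
  )
}

linear_fw <- function(layer, x) {
  list(y = layer$params$w %*% x + layer$params$b, cache = x)
}

linear_bw <- function(layer, cache, dy) {
  list(
    dx = crossprod(layer$params$w, dy),
    grads = list(w = tcrossprod(dy, cache), b = rowSums(dy))
  )
}

# Basic ResNet block, batch-norm replaced by group norm throughout.
resblock_layer <- function(cin, cout, stride, groups) {
  sub <- list(
    conv1 = conv_layer(3, 3, cin, cout, stride = stride, pad = 1),
    gn1 = gn_layer(cout, groups),
    conv2 = conv_layer(3, 3, cout, cout, stride = 1, pad = 1),
    gn2 = gn_layer(cout, groups)
  )
  if (stride != 1 || cin != cout) {
    sub$down_conv <- conv_layer(1, 1, cin, cout, stride = stride, pad = 0)
    sub$down_gn <- gn_layer(cout, groups)
  }
  list(type = "resblock", sub = sub, params = list())
}

resblock_fw <- function(layer, x) {
  s <- layer$sub
  c1 <- conv_fw(s$conv1, x)
  g1 <- gn_fw(s$gn1, c1$y)
  r1 <- relu_fw(NULL, g1$y)
  c2 <- conv_fw(s$conv2, r1$y)
  g2 <- gn_fw(s$gn2, c2$y)
  if (!is.null(s$down_conv)) {
    dc <- conv_fw(s$down_conv, x)
    dg <- gn_fw(s$down_gn, dc$y)
    short <- dg$y
    down_cache <- list(dc = dc$cache, dg = dg$cache)
  } else {
    short <- x
    down_cache <- NULL
  }
  y <- cpp_relu_fw(cpp_add(g2$y, short))
  list(y = y, cache = list(
    c1 = c1$cache, g1 = g1$cache, r1 = r1$cache,
    c2 = c2$cache, g2 = g2$cache, down = down_cache, mask = y
  ))
}

resblock_bw <- function(layer, cache, dy) {
  s <- layer$sub
  dpre <- cpp_relu_bw(dy, cache$mask)
  bg2 <- gn_bw(s$gn2, cache$g2, dpre)
  bc2 <- conv_bw(s$conv2, cache$c2, bg2$dx)
  br1 <- relu_bw(NULL, cache$r1, bc2$dx)
  bg1 <- gn_bw(s$gn1, cache$g1, br1$dx)
  bc1 <- conv_bw(s$conv1, cache$c1, bg1$dx)
  grads <- list(conv1 = bc1$grads, gn1 = bg1$grads,
                conv2 = bc2$grads, gn2 = bg2$grads)
  if (!is.null(cache$down)) {
    bdg <- gn_bw(s$down_gn, cache$down$dg, dpre)
    bdc <- conv_bw(s$down_conv, cache$down$dc, bdg$dx)
    grads$down_conv <- bdc$grads
    grads$down_gn <- bdg$grads
    dx <- bc1$dx + bdc$dx
  } else {
    dx <- bc1$dx + dpre
  }
  list(dx = dx, grads = grads)
}

layer_fw <- function(layer, x) {
  switch(layer$type,
    conv = conv_fw(layer, x),
    gn = gn_fw(layer, x),
    relu = relu_fw(layer, x),
    maxpool = maxpool_fw(layer, x),
    gap = gap_fw(layer, x),
    linear = linear_fw(layer, x),
    resblock = resblock_fw(layer, x),
    nonlocal = nonlocal_fw(layer, x),
    stop("unknown layer type: ", layer$type)
  )
}

layer_bw <- function(layer, cache, dy) {
  switch(layer$type,
    conv = conv_bw(layer, cache, dy),
    gn = gn_bw(layer, cache, dy),
    relu = relu_bw(layer, cache, dy),
    maxpool = maxpool_bw(layer, cache, dy),
    gap = gap_bw(layer, cache, dy),
    linear = linear_bw(layer, cache, dy),
    resblock = resblock_bw(layer, cache, dy),
    nonlocal = nonlocal_bw(layer, cache, dy),
    stop("unknown layer type: ", layer$type)
  )
}

# Sequential forward/backward over a list of layers.
seq_fw <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fw(layers[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

seq_bw <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bw(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

#' Group normalization
#'
#' Standardizes a feature map per sample within channel groups (mean 0,
#' variance 1 up to `eps`), then applies the per-channel affine transform
#' `gamma * xhat + beta`. Unlike batch normalization the statistics never mix
#' samples, so the operation is independent of batch size -- the property that
#' matters for video batches, where frames of one clip are highly correlated.
#'
#' @param x Numeric array, either `(H, W, C)` for a single feature map or
#'   `(H, W, C, N)` for a batch.
#' @param groups Number of channel groups; must divide `C`.
#' @param eps Variance floor for numerical stability.
#' @param gamma,beta Per-channel affine parameters (default identity).
#' @return Array with the same dimensions as `x`.
#' @examples
#' x <- array(rnorm(4 * 4 * 8), dim = c(4, 4, 8))
#' y <- group_normalize(x, groups = 4)
#' @export
group_normalize <- function(x, groups, eps = 1e-5, gamma = NULL, beta = NULL) {
  d <- dim(x)
  squeeze <- length(d) == 3
  if (squeeze) dim(x) <- c(d, 1L)
  C <- dim(x)[3]
  if (C %% groups != 0) {
    stop("group_normalize: groups (", groups, ") must divide channels (",
         C, ")")
  }
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- numeric(C)
  y <- gn_fw_core(x, groups, eps, gamma, beta)$y
  if (squeeze) dim(y) <- d
  y
}
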