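# Multi-dimension temporal attention pooling.

test_that("attention logits follow the Tanh cascade contract", {
  m <- 6
  att <- zero_attention(m)
  Fmat <- matrix(rnorm(4 * m), 4, m)
  expect_equal(attention_logits(Fmat, att), matrix(0, 4, m))
  # arbitrary weights: strictly inside (-1, 1)
  att2 <- build_attention(m, seed = 2)
  lg <- attention_logits(Fmat * 10, att2)
  expect_true(all(lg > -1 & lg < 1))
  # single layer with identity weights = elementwise tanh of the features
  att1 <- build_attention(m, attention_config(num_layers = 1), seed = 1)
  att1$layers[[1]]$w <- diag(m)
  att1$layers[[1]]$b <- numeric(m)
  expect_equal(attention_logits(Fmat, att1), tanh(Fmat), tolerance = 1e-12)
  expect_error(attention_logits(matrix(0, 3, m + 1), att), "width")
})

test_that("attention weights are a per-dimension softmax over frames", {
  expect_equal(attention_weights(matrix(1.7, 4, 3)),
               matrix(0.25, 4, 3), tolerance = 1e-12)
  expect_equal(attention_weights(matrix(rnorm(5), 1, 5)),
               matrix(1, 1, 5))
  w <- attention_weights(matrix(c(0, log(3)), 2, 1))
  expect_equal(as.numeric(w), c(0.25, 0.75), tolerance = 1e-12)
  expect_error(attention_weights(matrix(c(1, NaN), 2, 1)), "finite")
})

test_that("aggregation is the attention-weighted per-dimension sum", {
  Fmat <- matrix(c(1, 2, 3, 4), 2, 2)  # T = 2, m = 2
  A <- matrix(c(1, 0, 0, 1), 2, 2)     # per-dimension one-hot
  expect_equal(aggregate(Fmat, A), c(1, 4))
  expect_equal(aggregate(Fmat, matrix(0.5, 2, 2)), colMeans(Fmat))
  expect_equal(aggregate(Fmat[1, , drop = FALSE], matrix(1, 1, 2)), Fmat[1, ])
  expect_error(aggregate(Fmat, matrix(1, 3, 2)), "3x2")
})

test_that("uniform attention degenerates exactly to average pooling", {
  set.seed(20)
  for (i in 1:100) {
    Tn <- sample(1:32, 1)
    m <- sample(1:64, 1)
    Fmat <- matrix(rnorm(Tn * m, sd = 3), Tn, m)
    out <- attention_pool(Fmat, zero_attention(m))
    expect_lt(max(abs(out - colMeans(Fmat))), 1e-6)
    expect_equal(out, average_pool(Fmat), tolerance = 1e-6)
  }
})

test_that("attention columns always sum to one", {
  set.seed(21)
  att_by_m <- new.env()
  for (i in 1:100) {
    Tn <- sample(1:64, 1)
    m <- sample(1:512, 1)
    key <- as.character(m)
    if (is.null(att_by_m[[key]])) {
      att_by_m[[key]] <- build_attention(m, seed = m)
    }
    lg <- attention_logits(matrix(rnorm(Tn * m), Tn, m), att_by_m[[key]])
    A <- attention_weights(lg)
    expect_true(all(abs(colSums(A) - 1) < 1e-6))
    expect_true(all(A >= 0 & A <= 1))
  }
})

test_that("forward is permutation-invariant and length-agnostic", {
  m <- 16
  att <- build_attention(m, seed = 5)
  set.seed(22)
  for (Tn in c(1, 16, 64)) {
    Fmat <- matrix(rnorm(Tn * m), Tn, m)
    out <- attention_pool(Fmat, att)
    expect_length(out, m)
    pi <- sample(Tn)
    expect_lt(max(abs(out - attention_pool(Fmat[pi, , drop = FALSE], att))),
              1e-5)
    # convexity: each component within the frame-wise min/max
    expect_true(all(out >= apply(Fmat, 2, min) - 1e-9))
    expect_true(all(out <= apply(Fmat, 2, max) + 1e-9))
  }
})

test_that("a hard per-dimension one-hot drives pooling to the max", {
  # Tanh-bounded logits cannot reach the max-pooling limit (weight ratios are
  # capped at e^2); with the unbounded final activation, beta-scaled one-hot
  # logits recover max pooling.
  set.seed(23)
  m <- 8
  Tn <- 6
  Fmat <- matrix(rnorm(Tn * m), Tn, m)
  beta <- 50
  onehot <- apply(Fmat, 2, function(col) {
    z <- numeric(Tn)
    z[which.max(col)] <- 1
    z
  })
  out <- aggregate(Fmat, attention_weights(beta * onehot))
  expect_lt(max(abs(out - max_pool(Fmat))), 1e-4)
  # the "none" final activation exposes unbounded logits end to end
  att <- build_attention(m, attention_config(num_layers = 1,
                                             final_activation = "none"),
                         seed = 1)
  att$layers[[1]]$w <- diag(m) * beta
  att$layers[[1]]$b <- numeric(m)
  lg <- attention_logits(Fmat, att)
  expect_true(any(abs(lg) > 1))
  expect_equal(lg, beta * Fmat, tolerance = 1e-10)
})

test_that("attention backward matches numerical gradients", {
  set.seed(24)
  m <- 5
  Tn <- 4
  att <- build_attention(m, seed = 3)
  Fmat <- matrix(rnorm(Tn * m), Tn, m)
  dout <- rnorm(m)
  fw <- usvid:::attention_pool_fw(Fmat, att)
  bw <- usvid:::attention_pool_bw(Fmat, att, fw, dout)
  gF <- num_grad(function(v) {
    sum(attention_pool(matrix(v, Tn, m), att) * dout)
  }, as.numeric(Fmat))
  expect_lt(max(abs(bw$dfeatures - matrix(gF, Tn, m))), 1e-6)
  for (l in 1:2) {
    gW <- num_grad(function(v) {
      a2 <- att
      a2$layers[[l]]$w <- matrix(v, m, m)
      sum(attention_pool(Fmat, a2) * dout)
    }, as.numeric(att$layers[[l]]$w))
    expect_lt(max(abs(bw$grads[[l]]$w - matrix(gW, m, m))), 1e-6)
  }
})
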