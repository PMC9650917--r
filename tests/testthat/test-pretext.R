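# Contrastive pretext: augmentation family, batch sampling, projection,
# NT-Xent loss, and the scaled-down pretraining loop.

test_that("augmentation with everything disabled is the identity", {
  fr <- matrix(runif(32 * 32), 32, 32)
  cfg <- augment_config(enabled = c(flip = FALSE, crop = FALSE, scale = FALSE,
                                    elastic = FALSE, brightness = FALSE,
                                    contrast = FALSE))
  expect_identical(augment(fr, cfg, seed = 1), fr)
})

test_that("augmentation is seeded, shape/range-preserving, and varied", {
  set.seed(30)
  fr <- generate_clip(clip_params(n_frames = 1, height = 32, width = 32,
                                  seed = 4))$frames[[1]]
  cfg <- augment_config()
  expect_identical(augment(fr, cfg, seed = 42), augment(fr, cfg, seed = 42))
  outs <- lapply(1:100, function(s) augment(fr, cfg, seed = s))
  expect_true(all(vapply(outs, function(o) {
    all(dim(o) == dim(fr)) && all(o >= 0 & o <= 1)
  }, logical(1))))
  expect_gt(length(unique(lapply(outs, function(o) round(o, 10)))), 1)
  expect_error(augment_config(crop_scale_range = c(0.9, 0.5)), "ordered")
})

test_that("pretext batches pair two views per frame via an involution", {
  vids <- tiny_videos(n = 8, n_frames = 4, size = 8)
  b <- sample_pretext_batch(vids, n_clips = 2, frames_per_clip = 3, seed = 1)
  expect_length(b$views, 12)
  expect_equal(sum(b$pair_index[b$pair_index] != seq_len(12)), 0)
  expect_true(all(b$pair_index != seq_len(12)))
  expect_equal(nrow(b$meta), 6 * 2)
  b2 <- sample_pretext_batch(vids, n_clips = 2, frames_per_clip = 3, seed = 1)
  expect_equal(b$meta, b2$meta)
  expect_identical(b$views, b2$views)
  expect_error(sample_pretext_batch(vids, n_clips = 9, frames_per_clip = 1,
                                    seed = 1), "exceeds")
  # frames sampled with replacement when the clip is short
  b3 <- sample_pretext_batch(vids, n_clips = 1, frames_per_clip = 6, seed = 2)
  expect_length(b3$views, 12)
})

test_that("repeated seeded draws cover every clip", {
  vids <- tiny_videos(n = 8, n_frames = 2, size = 8)
  cfg <- augment_config(enabled = c(flip = FALSE, crop = FALSE, scale = FALSE,
                                    elastic = FALSE, brightness = FALSE,
                                    contrast = FALSE))
  seen <- integer(0)
  for (s in 1:200) {
    b <- sample_pretext_batch(vids, n_clips = 4, frames_per_clip = 1,
                              config = cfg, seed = s)
    seen <- union(seen, unique(b$meta$clip))
  }
  expect_setequal(seen, 1:8)
})

test_that("projection embeds onto the unit sphere with a zero guard", {
  head <- build_projection_head(16, hidden = 16, d = 8, seed = 1)
  e <- project(rnorm(16), head)
  expect_length(e, 8)
  expect_equal(sqrt(sum(e^2)), 1, tolerance = 1e-6)
  # batch form: unit columns
  eb <- project(matrix(rnorm(16 * 5), 16, 5), head)
  expect_equal(sqrt(colSums(eb^2)), rep(1, 5), tolerance = 1e-6)
  # zero weights: epsilon-guarded normalization, finite output
  hz <- build_projection_head(4, hidden = 4, d = 3, seed = 1)
  hz$lin1$params$w[] <- 0
  hz$lin2$params$w[] <- 0
  ez <- project(rnorm(4), hz)
  expect_true(all(is.finite(ez)))
  expect_error(project(rnorm(5), head), "does not match")
})

test_that("NT-Xent matches its closed forms", {
  # all embeddings identical: every similarity equal -> -log(1/(2K-1))
  emb <- matrix(rep(c(1, 0, 0), each = 4), 4, 3)
  pair <- c(2L, 1L, 4L, 3L)
  expect_equal(nt_xent_loss(emb, pair, temperature = 0.3), log(3),
               tolerance = 1e-12)
  expect_equal(nt_xent_loss(emb, pair, temperature = 5), log(3),
               tolerance = 1e-12)
  # identical positives, orthogonal cross pairs, tau = 0.5:
  # loss = log(1 + 2 e^{-2})
  emb2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(nt_xent_loss(emb2, pair, temperature = 0.5),
               log(1 + 2 * exp(-2)), tolerance = 1e-12)
  expect_error(nt_xent_loss(emb2, pair, temperature = 0), "temperature")
  expect_error(nt_xent_loss(emb2, c(1L, 2L, 3L, 4L), 0.5), "involution")
})

test_that("NT-Xent equals the double-loop oracle and is pair-symmetric", {
  set.seed(31)
  for (K in c(2, 5, 8)) {
    B <- 2 * K
    emb <- matrix(rnorm(B * 6), B, 6)
    emb <- emb / sqrt(rowSums(emb^2))
    pair <- as.integer(sapply(1:B, function(i) if (i %% 2) i + 1 else i - 1))
    l <- nt_xent_loss(emb, pair, 0.5)
    expect_equal(l, nt_xent_bruteforce(emb, pair, 0.5), tolerance = 1e-6)
    # permuting views while preserving pairs leaves the loss unchanged
    perm <- sample(B)
    inv <- integer(B)
    inv[perm] <- seq_len(B)
    expect_equal(nt_xent_loss(emb[perm, ], inv[pair[perm]], 0.5), l,
                 tolerance = 1e-10)
    # lower bound for unit vectors: cosine similarities are >= -1
    expect_gte(l, log(1 + (B - 2) * exp(-2 / 0.5)))
  }
})

test_that("the analytic NT-Xent gradient matches finite differences", {
  set.seed(32)
  B <- 6
  emb <- matrix(rnorm(B * 4), B, 4)
  emb <- emb / sqrt(rowSums(emb^2))
  pair <- c(2L, 1L, 4L, 3L, 6L, 5L)
  g <- usvid:::nt_xent_grad(emb, pair, 0.5)
  gn <- num_grad(function(v) nt_xent_loss(matrix(v, B, 4), pair, 0.5),
                 as.numeric(emb))
  expect_lt(max(abs(g$de - matrix(gn, B, 4))), 1e-6)
  expect_equal(g$loss, nt_xent_loss(emb, pair, 0.5), tolerance = 1e-12)
})

test_that("the cosine schedule follows its closed form", {
  expect_equal(cosine_lr(0, 10, 0.1), 0.1)
  expect_equal(cosine_lr(10, 10, 0.1), 0)
  expect_equal(cosine_lr(5, 10, 0.1, 0.01), 0.01 + 0.5 * 0.09)
  tt <- 0:20
  lrs <- cosine_lr(tt, 20, 9e-3)
  expect_equal(lrs, 0 + 0.5 * 9e-3 * (1 + cos(pi * tt / 20)))
  expect_lt(lrs[21], lrs[1])
})

test_that("scaled-down pretraining descends the loss deterministically", {
  vids <- tiny_videos(n = 8, n_frames = 3, size = 32)
  enc <- build_encoder(encoder_config(base_width = 8, nl_stages = 3:4),
                       seed = 1)
  cfg <- pretrain_config(n_clips = 4, frames_per_clip = 2, epochs = 5,
                         learning_rate = 0.05, optimizer = "sgd",
                         steps_per_epoch = 3, seed = 7)
  r1 <- pretrain(vids, enc, cfg)
  expect_equal(nrow(r1$history), 5)
  expect_lt(tail(r1$history$loss, 1), r1$history$loss[1])
  r2 <- pretrain(vids, enc, cfg)
  expect_identical(r1$history, r2$history)
  # LARS path also runs and records the cosine-annealed learning rate
  cfg_lars <- pretrain_config(n_clips = 4, frames_per_clip = 1, epochs = 2,
                              learning_rate = 0.1, optimizer = "lars",
                              steps_per_epoch = 2, seed = 8)
  r3 <- pretrain(vids, enc, cfg_lars)
  expect_equal(r3$history$lr, cosine_lr(0:1, 2, 0.1))
  expect_true(all(is.finite(r3$history$loss)))
})

test_that("same-video positive pairing is available", {
  vids <- tiny_videos(n = 4, n_frames = 4, size = 8)
  b <- sample_pretext_batch(vids, n_clips = 2, frames_per_clip = 2, seed = 3,
                            positive_mode = "same_video")
  expect_length(b$views, 8)
  # both views of a pair come from the same clip
  for (k in unique(b$meta$pair)) {
    expect_length(unique(b$meta$clip[b$meta$pair == k]), 1)
  }
})
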