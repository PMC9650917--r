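# Contrastive pretraining of the frame encoder: two independent augmentations
# of each sampled frame form a positive pair; all other views in the batch are
# negatives. Embeddings come from a two-layer projection head on top of the
# encoder feature and are L2-normalized; the NT-Xent loss pulls positives
# together on the unit sphere.

#' Augmentation family configuration
#'
#' Transforms applied (in order): horizontal flip, random crop-then-resize,
#' zoom, elastic deformation, brightness offset, contrast scaling. All are
#' seeded and preserve the frame size; output values are clipped to `[0, 1]`.
#'
#' @param flip_prob Probability of a horizontal flip.
#' @param crop_scale_range Area fraction range `(low, high)` of the random
#'   crop (crop is resized back to the input size).
#' @param scale_range Zoom factor range.
#' @param brightness_delta Maximum additive brightness offset.
#' @param contrast_range Multiplicative contrast range (about the frame mean).
#' @param elastic_alpha,elastic_sigma Elastic-deformation displacement
#'   amplitude (px, on a 64 px basis -- scaled with frame size) and Gaussian
#'   smoothness (px) of the displacement field.
#' @param enabled Named logical vector switching individual transforms.
#' @return An `augment_config` list.
#' @export
augment_config <- function(flip_prob = 0.5, crop_scale_range = c(0.6, 1.0),
                           scale_range = c(0.9, 1.1), brightness_delta = 0.2,
                           contrast_range = c(0.8, 1.25), elastic_alpha = 20,
                           elastic_sigma = 4,
                           enabled = c(flip = TRUE, crop = TRUE, scale = TRUE,
                                       elastic = TRUE, brightness = TRUE,
                                       contrast = TRUE)) {
  if (flip_prob < 0 || flip_prob > 1) {
    stop("augment_config: flip_prob must lie in [0, 1]")
  }
  for (nm in c("crop_scale_range", "scale_range", "contrast_range")) {
    r <- get(nm)
    if (length(r) != 2 || r[2] < r[1]) {
      stop("augment_config: ", nm, " must be an ordered (low, high) pair")
    }
  }
  if (crop_scale_range[1] <= 0 || crop_scale_range[2] > 1) {
    stop("augment_config: crop_scale_range must lie in (0, 1]")
  }
  full <- c(flip = TRUE, crop = TRUE, scale = TRUE, elastic = TRUE,
            brightness = TRUE, contrast = TRUE)
  full[names(enabled)] <- enabled
  structure(list(flip_prob = flip_prob, crop_scale_range = crop_scale_range,
                 scale_range = scale_range, brightness_delta = brightness_delta,
                 contrast_range = contrast_range, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma, enabled = full),
            class = "augment_config")
}

# Bilinear resize to h x w.
resize_frame <- function(img, h, w) {
  rows <- matrix(seq(1, nrow(img), length.out = h), h, w)
  cols <- matrix(seq(1, ncol(img), length.out = w), h, w, byrow = TRUE)
  bilinear_sample(img, rows, cols)
}

# Bilinear sampling of img at fractional (row, col) coordinate matrices,
# clamped to the border.
bilinear_sample <- function(img, rows, cols) {
  H <- nrow(img)
  W <- ncol(img)
  r <- pmin(pmax(rows, 1), H)
  c <- pmin(pmax(cols, 1), W)
  r0 <- floor(r)
  c0 <- floor(c)
  r1 <- pmin(r0 + 1, H)
  c1 <- pmin(c0 + 1, W)
  fr <- r - r0
  fc <- c - c0
  v00 <- img[cbind(as.vector(r0), as.vector(c0))]
  v10 <- img[cbind(as.vector(r1), as.vector(c0))]
  v01 <- img[cbind(as.vector(r0), as.vector(c1))]
  v11 <- img[cbind(as.vector(r1), as.vector(c1))]
  out <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  matrix(out, nrow(rows), ncol(rows))
}

#' Apply the augmentation family to one frame
#'
#' A pure function of `(frame, config, seed)`: the same seed reproduces the
#' same augmented view bit for bit.
#'
#' @param frame `H x W` matrix in `[0, 1]`.
#' @param config An [augment_config()].
#' @param seed Integer seed.
#' @return Augmented `H x W` matrix in `[0, 1]`.
#' @export
augment <- function(frame, config = augment_config(), seed = 0L) {
  H <- nrow(frame)
  W <- ncol(frame)
  en <- config$enabled
  with_seed(seed, {
    x <- frame
    if (en[["flip"]] && runif(1) < config$flip_prob) {
      x <- x[, rev(seq_len(W)), drop = FALSE]
    }
    grid_r <- matrix(seq_len(H), H, W)
    grid_c <- matrix(seq_len(W), H, W, byrow = TRUE)
    resample <- FALSE
    rows <- grid_r
    cols <- grid_c
    if (en[["crop"]]) {
      area <- runif(1, config$crop_scale_range[1], config$crop_scale_range[2])
      side <- sqrt(area)
      ch <- side * H
      cw <- side * W
      top <- runif(1, 0, H - ch)
      left <- runif(1, 0, W - cw)
      rows <- top + (rows - 1) * (ch - 1) / max(H - 1, 1) + 1
      cols <- left + (cols - 1) * (cw - 1) / max(W - 1, 1) + 1
      resample <- TRUE
    }
    if (en[["scale"]]) {
      z <- runif(1, config$scale_range[1], config$scale_range[2])
      rows <- (rows - (H + 1) / 2) / z + (H + 1) / 2
      cols <- (cols - (W + 1) / 2) / z + (W + 1) / 2
      resample <- TRUE
    }
    if (en[["elastic"]]) {
      sc <- min(H, W) / 64
      dr <- gaussian_blur(matrix(runif(H * W, -1, 1), H, W),
                          config$elastic_sigma * max(sc, 0.5))
      dc <- gaussian_blur(matrix(runif(H * W, -1, 1), H, W),
                          config$elastic_sigma * max(sc, 0.5))
      amp <- config$elastic_alpha * sc
      rows <- rows + amp * dr / max(abs(range(dr)))
      cols <- cols + amp * dc / max(abs(range(dc)))
      resample <- TRUE
    }
    if (resample) x <- bilinear_sample(x, rows, cols)
    if (en[["brightness"]]) {
      x <- x + runif(1, -config$brightness_delta, config$brightness_delta)
    }
    if (en[["contrast"]]) {
      cmul <- runif(1, config$contrast_range[1], config$contrast_range[2])
      mu <- mean(x)
      x <- mu + cmul * (x - mu)
    }
    pmin(pmax(x, 0), 1)
  })
}

#' Sample an augmented-view batch for contrastive pretraining
#'
#' Draws `n_clips` clips (without replacement), `frames_per_clip` frames from
#' each (without replacement when the clip is long enough, otherwise with),
#' and produces two independently augmented views per sampled frame. In
#' `"same_video"` mode the two views of a pair come from two (possibly
#' different) frames of the same clip instead.
#'
#' @param videos List of `usv_video` objects.
#' @param n_clips,frames_per_clip Batch composition (`N` clips, `M` frames
#'   per clip; `2 * N * M` views).
#' @param config An [augment_config()].
#' @param seed Integer seed.
#' @param positive_mode `"augmented_frame"` (strict SimCLR pairing, default)
#'   or `"same_video"`.
#' @return List with `views` (list of frames), `pair_index` (fixed-point-free
#'   involution: `pair_index[i]` is the positive partner of view `i`), and
#'   `meta` (tibble of clip/frame provenance per view).
#' @export
sample_pretext_batch <- function(videos, n_clips, frames_per_clip,
                                 config = augment_config(), seed = 0L,
                                 positive_mode = c("augmented_frame",
                                                   "same_video")) {
  positive_mode <- match.arg(positive_mode)
  if (n_clips > length(videos)) {
    stop("sample_pretext_batch: n_clips (", n_clips,
         ") exceeds dataset size (", length(videos), ")")
  }
  with_seed(seed, {
    clip_idx <- sample(length(videos), n_clips)
    views <- list()
    meta <- list()
    k <- 0L
    for (ci in clip_idx) {
      v <- videos[[ci]]
      Tn <- length(v$frames)
      f_idx <- if (Tn >= frames_per_clip) {
        sample(Tn, frames_per_clip)
      } else {
        sample(Tn, frames_per_clip, replace = TRUE)
      }
      for (fi in f_idx) {
        k <- k + 1L
        if (positive_mode == "augmented_frame") {
          fr1 <- fr2 <- v$frames[[fi]]
          fj <- fi
        } else {
          fj <- sample(Tn, 1)
          fr1 <- v$frames[[fi]]
          fr2 <- v$frames[[fj]]
        }
        s1 <- sample.int(.Machine$integer.max, 1)
        s2 <- sample.int(.Machine$integer.max, 1)
        views[[2 * k - 1]] <- augment(fr1, config, s1)
        views[[2 * k]] <- augment(fr2, config, s2)
        meta[[k]] <- tibble::tibble(pair = k, clip = ci,
                                    frame = c(fi, fj),
                                    view = c(2 * k - 1, 2 * k))
      }
    }
    n_pairs <- k
    pair_index <- as.integer(sapply(seq_len(2 * n_pairs), function(i) {
      if (i %% 2 == 1) i + 1L else i - 1L
    }))
    list(views = views, pair_index = pair_index,
         meta = dplyr::bind_rows(meta))
  })
}

#' Build a projection head
#'
#' Two-layer MLP `m -> hidden -> d` with a ReLU between, used only during
#' contrastive pretraining; embeddings are L2-normalized downstream.
#'
#' @param m Encoder feature dimension.
#' @param hidden Hidden width (default `m`).
#' @param d Output dimension (default 128).
#' @param seed Integer seed.
#' @return A `usv_projection_head`.
#' @export
build_projection_head <- function(m, hidden = m, d = 128L, seed = 0L) {
  with_seed(seed, {
    structure(list(lin1 = linear_layer(m, hidden), lin2 = linear_layer(hidden, d)),
              class = "usv_projection_head")
  })
}

PROJ_NORM_EPS <- 1e-12

#' Project an encoder feature into the contrastive embedding space
#'
#' @param feature Numeric vector of length `m`, or an `m x B` matrix of
#'   features in columns.
#' @param head A [build_projection_head()] object.
#' @return Unit-norm embedding vector (or `d x B` matrix of unit columns).
#'   A zero pre-normalization vector is guarded with an epsilon (1e-12)
#'   denominator rather than erroring.
#' @export
project <- function(feature, head) {
  vec <- !is.matrix(feature)
  x <- if (vec) matrix(feature, ncol = 1) else feature
  if (nrow(x) != ncol(head$lin1$params$w)) {
    stop("project: feature length ", nrow(x), " does not match head input ",
         ncol(head$lin1$params$w))
  }
  h <- cpp_relu_fw(head$lin1$params$w %*% x + head$lin1$params$b)
  z <- head$lin2$params$w %*% h + head$lin2$params$b
  nrm <- sqrt(colSums(z * z))
  e <- sweep(z, 2, pmax(nrm, PROJ_NORM_EPS), "/")
  if (vec) drop(e) else e
}

# Projection forward with cache (x: m x B) and backward (de: d x B).
project_fw <- function(x, head) {
  a <- head$lin1$params$w %*% x + head$lin1$params$b
  h <- cpp_relu_fw(a)
  z <- head$lin2$params$w %*% h + head$lin2$params$b
  nrm <- pmax(sqrt(colSums(z * z)), PROJ_NORM_EPS)
  e <- sweep(z, 2, nrm, "/")
  list(e = e, cache = list(x = x, h = h, z = z, nrm = nrm, e = e))
}

project_bw <- function(head, cache, de) {
  # through normalization: dz = (de - e * colSums(e * de)) / nrm
  dz <- sweep(de - sweep(cache$e, 2, colSums(cache$e * de), "*"),
              2, cache$nrm, "/")
  g2 <- list(w = tcrossprod(dz, cache$h), b = rowSums(dz))
  dh <- crossprod(head$lin2$params$w, dz)
  da <- cpp_relu_bw(dh, cache$h)
  g1 <- list(w = tcrossprod(da, cache$x), b = rowSums(da))
  dx <- crossprod(head$lin1$params$w, da)
  list(dx = dx, grads = list(lin1 = g1, lin2 = g2))
}

#' NT-Xent contrastive loss
#'
#' Normalized temperature-scaled cross entropy over cosine similarities: the
#' mean over all `2K` views of
#' `-log( exp(sim(i, p(i)) / tau) / sum_{k != i} exp(sim(i, k) / tau) )`.
#'
#' @param embeddings `2K x d` matrix of unit-norm view embeddings (rows).
#' @param pair_index Fixed-point-free involution giving each view's positive.
#' @param temperature Positive temperature `tau`.
#' @return Scalar loss.
#' @export
nt_xent_loss <- function(embeddings, pair_index, temperature = 0.5) {
  if (temperature <= 0) {
    stop("nt_xent_loss: temperature must be > 0, got ", temperature)
  }
  B <- nrow(embeddings)
  if (length(pair_index) != B || any(pair_index == seq_len(B)) ||
      any(pair_index[pair_index] != seq_len(B))) {
    stop("nt_xent_loss: pair_index must be a fixed-point-free involution")
  }
  s <- tcrossprod(embeddings) / temperature
  diag(s) <- -Inf
  mx <- apply(s, 1, max)
  lse <- mx + log(rowSums(exp(s - mx)))
  pos <- s[cbind(seq_len(B), pair_index)]
  mean(lse - pos)
}

# Loss + gradient wrt embeddings (rows), for training.
nt_xent_grad <- function(embeddings, pair_index, temperature) {
  B <- nrow(embeddings)
  s <- tcrossprod(embeddings) / temperature
  diag(s) <- -Inf
  mx <- apply(s, 1, max)
  p <- exp(s - mx)
  p <- p / rowSums(p)
  loss <- mean((mx + log(rowSums(exp(s - mx)))) -
                 s[cbind(seq_len(B), pair_index)])
  g <- p
  g[cbind(seq_len(B), pair_index)] <-
    g[cbind(seq_len(B), pair_index)] - 1
  g <- g / (B * temperature)
  de <- (g + t(g)) %*% embeddings
  list(loss = loss, de = de)
}

#' Pretraining configuration
#'
#' Defaults mirror the published pretext settings (LARS, cosine-annealed
#' learning rate 9e-3, weight decay 1e-6, 8192 epochs, 64-view batches);
#' CPU-scale experiments should pass far smaller `epochs` and batch sizes.
#'
#' @param n_clips,frames_per_clip Batch composition (N clips, M frames each;
#'   the effective view batch is `2 * N * M`).
#' @param temperature NT-Xent temperature.
#' @param projection_hidden,projection_dim Projection-head widths (hidden
#'   defaults to the feature dimension at build time when `NULL`).
#' @param epochs,learning_rate,weight_decay,momentum Optimization schedule;
#'   the learning rate is cosine-annealed over `epochs`.
#' @param optimizer `"lars"` (default) or `"sgd"`.
#' @param steps_per_epoch Batches per epoch; `NULL` means `floor(n_videos /
#'   n_clips)`.
#' @param view_size Optional side length: augmented views are bilinearly
#'   resized to `view_size x view_size` before encoding (smaller views make
#'   CPU pretraining far cheaper; the encoder is size-agnostic).
#' @param augment An [augment_config()].
#' @param positive_mode See [sample_pretext_batch()].
#' @param seed Integer seed.
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(n_clips = 16L, frames_per_clip = 2L,
                            temperature = 0.5, projection_hidden = NULL,
                            projection_dim = 128L, epochs = 8192L,
                            learning_rate = 9e-3, weight_decay = 1e-6,
                            momentum = 0.9,
                            optimizer = c("lars", "sgd"),
                            steps_per_epoch = NULL, view_size = NULL,
                            augment = augment_config(),
                            positive_mode = c("augmented_frame", "same_video"),
                            seed = 0L) {
  if (temperature <= 0) stop("pretrain_config: temperature must be > 0")
  structure(list(
    n_clips = as.integer(n_clips),
    frames_per_clip = as.integer(frames_per_clip),
    temperature = temperature, projection_hidden = projection_hidden,
    projection_dim = as.integer(projection_dim), epochs = as.integer(epochs),
    learning_rate = learning_rate, weight_decay = weight_decay,
    momentum = momentum, optimizer = match.arg(optimizer),
    steps_per_epoch = steps_per_epoch,
    view_size = if (is.null(view_size)) NULL else as.integer(view_size),
    augment = augment,
    positive_mode = match.arg(positive_mode), seed = as.integer(seed)
  ), class = "pretrain_config")
}

#' Contrastively pretrain a frame encoder
#'
#' SimCLR-style pretraining on frames sampled from the given clips. Every
#' epoch draws `steps_per_epoch` batches, each of `n_clips` clips and
#' `frames_per_clip` frames per clip, augments each frame twice, and descends
#' the NT-Xent loss through the projection head and encoder. Fully seeded.
#'
#' @param videos List of `usv_video` clips.
#' @param encoder A `usv_encoder` (its weights are the starting point).
#' @param config A [pretrain_config()].
#' @param state Optional checkpoint state from a previous [pretrain()] call
#'   (fields `encoder`, `head`, `epochs_done`) to resume from.
#' @return List with `encoder` (trained), `head`, and `history` (tibble with
#'   one row per epoch: `epoch`, `loss`, `lr`).
#' @export
pretrain <- function(videos, encoder, config = pretrain_config(),
                     state = NULL) {
  if (length(videos) == 0) stop("pretrain: dataset is empty")
  m <- encoder$config$feature_dim
  hidden <- if (is.null(config$projection_hidden)) m else config$projection_hidden
  if (!is.null(state)) {
    encoder <- state$encoder
    head <- state$head
    epoch0 <- state$epochs_done
  } else {
    head <- build_projection_head(m, hidden, config$projection_dim,
                                  seed = config$seed + 1L)
    epoch0 <- 0L
  }
  steps <- if (is.null(config$steps_per_epoch)) {
    max(1L, length(videos) %/% config$n_clips)
  } else config$steps_per_epoch
  opt <- make_optimizer(config$optimizer, momentum = config$momentum,
                        weight_decay = config$weight_decay)
  history <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    lr <- cosine_lr(ep - 1, config$epochs, config$learning_rate)
    losses <- numeric(steps)
    for (st in seq_len(steps)) {
      bseed <- derive_seed(config$seed, (epoch0 + ep) * 10000L + st)
      batch <- sample_pretext_batch(videos, config$n_clips,
                                    config$frames_per_clip, config$augment,
                                    seed = bseed,
                                    positive_mode = config$positive_mode)
      views <- batch$views
      if (!is.null(config$view_size)) {
        views <- lapply(views, resize_frame, config$view_size,
                        config$view_size)
      }
      x <- frames_to_batch(views)
      ef <- encoder_fw(encoder, x)
      pf <- project_fw(ef$y, head)
      ng <- nt_xent_grad(t(pf$e), batch$pair_index, config$temperature)
      losses[st] <- ng$loss
      if (!is.finite(ng$loss)) {
        stop("pretrain: non-finite loss at epoch ", epoch0 + ep,
             " (step ", st, ")")
      }
      pb <- project_bw(head, pf$cache, t(ng$de))
      eb <- encoder_bw(encoder, ef$caches, pb$dx)
      all_layers <- c(encoder$layers, list(head$lin1, head$lin2))
      all_grads <- c(eb$grads, list(pb$grads$lin1, pb$grads$lin2))
      all_layers <- opt$step(all_layers, all_grads, lr)
      nl <- length(encoder$layers)
      encoder$layers <- all_layers[seq_len(nl)]
      head$lin1 <- all_layers[[nl + 1]]
      head$lin2 <- all_layers[[nl + 2]]
    }
    history[[ep]] <- tibble::tibble(epoch = epoch0 + ep,
                                    loss = mean(losses), lr = lr)
  }
  list(encoder = encoder, head = head,
       history = dplyr::bind_rows(history), epochs_done = epoch0 + config$epochs)
}


#' Linear probe of a frozen encoder
#'
#' Freezes the encoder, represents each video by the mean of its frame
#' features, fits an L2-regularized logistic regression on the training
#' split, and reports balanced accuracy on the test split -- the standard
#' protocol for judging the quality of self-supervised representations.
#'
#' @param encoder A `usv_encoder` (random or pretrained).
#' @param videos Named list of `usv_video`.
#' @param index Index tibble with `video_id`, `label`, `split`.
#' @param lambda Ridge penalty for the logistic probe.
#' @param n_labeled Optional label budget: train the probe on only this many
#'   training videos (stratified, seeded) -- the low-label protocol that
#'   separates representation quality from raw class separability.
#' @param seed Seed for the label subset draw.
#' @return List with `balanced_accuracy`, `accuracy`, and the per-video
#'   `scores` tibble.
#' @export
linear_probe <- function(encoder, videos, index, lambda = 0.01,
                         n_labeled = NULL, seed = 0L) {
  feat_of <- function(ids) {
    t(vapply(ids, function(id) {
      rowMeans(encode_frames(videos[[id]], encoder))
    }, numeric(encoder$config$feature_dim)))
  }
  tr <- index$video_id[index$split == "train"]
  te <- index$video_id[index$split == "test"]
  if (!is.null(n_labeled)) {
    tr <- with_seed(derive_seed(seed, 271L), {
      lab <- index$label[match(tr, index$video_id)]
      unlist(lapply(c("benign", "malignant"), function(lb) {
        sample(tr[lab == lb], max(1, round(n_labeled / 2)))
      }))
    })
  }
  ytr <- label_to_int(index$label[match(tr, index$video_id)])
  yte <- label_to_int(index$label[match(te, index$video_id)])
  fit <- glmnet::glmnet(feat_of(tr), factor(ytr, levels = 0:1),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  p <- as.numeric(predict(fit, feat_of(te), type = "response"))
  pred <- as.integer(p >= 0.5)
  sens <- mean(pred[yte == 1] == 1)
  spec <- mean(pred[yte == 0] == 0)
  list(balanced_accuracy = (sens + spec) / 2, accuracy = mean(pred == yte),
       scores = tibble::tibble(video_id = te, truth = yte,
                               malignant_score = p))
}

#' Tiny pretext preset sized for a CPU
#'
#' Micro-batch contrastive pretraining: 12 clips x 2 frames per batch
#' (48 views), 48 px views, plain momentum SGD at 0.05 (the LARS trust
#' ratio is tuned for large-batch regimes and stalls at this scale),
#' cosine-annealed.
#'
#' @param epochs,seed Overridable scaled-down defaults.
#' @return A `pretrain_config`.
#' @export
pretrain_config_tiny <- function(epochs = 12L, seed = 0L) {
  pretrain_config(n_clips = 12L, frames_per_clip = 2L, epochs = epochs,
                  learning_rate = 0.05, optimizer = "sgd",
                  steps_per_epoch = 8L, view_size = 48L, seed = seed)
}
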