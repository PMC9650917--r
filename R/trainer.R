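# Supervised video-level training: frame encoder -> temporal attention
# pooling -> linear classifier (m -> 2), cross-entropy on the video label.
# Training subsamples each clip to `sample_length` frames; inference uses the
# full sequence (the aggregator is length-agnostic).

CLASS_LEVELS <- c("benign", "malignant")

#' Supervised training configuration
#'
#' Defaults encode the published schedule: SGD, 320 epochs, learning rate
#' 1e-4, momentum 0.9, weight decay 5e-4, sample length `T = 16`, batch size
#' 8, cross-entropy loss. CPU-scale experiments pass smaller values (see
#' [train_config_tiny()]).
#'
#' @param epochs Number of passes over the training split.
#' @param learning_rate,momentum,weight_decay SGD hyperparameters.
#' @param sample_length Frames sampled per clip during training (`T`).
#' @param batch_size Clips per gradient step.
#' @param frame_sampling `"evenly_spaced"` or `"random_jitter"`.
#' @param class_weights If `TRUE`, weight the loss by inverse class frequency.
#' @param augment Optional [augment_config()] applied to each sampled frame
#'   during training (regularization against speckle memorization); `NULL`
#'   disables.
#' @param eval_every Evaluate test metrics every this many epochs (0 = only
#'   at the end).
#' @param seed Integer seed for shuffling and frame sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 320L, learning_rate = 1e-4, momentum = 0.9,
                         weight_decay = 5e-4, sample_length = 16L,
                         batch_size = 8L,
                         frame_sampling = c("evenly_spaced", "random_jitter"),
                         class_weights = FALSE, eval_every = 0L, seed = 0L,
                         augment = NULL) {
  if (sample_length < 1) stop("train_config: sample_length must be >= 1")
  if (learning_rate <= 0 || weight_decay < 0 || batch_size < 1) {
    stop("train_config: rates and batch size must be positive")
  }
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, weight_decay = weight_decay,
                 sample_length = as.integer(sample_length),
                 batch_size = as.integer(batch_size), optimizer = "sgd",
                 frame_sampling = match.arg(frame_sampling),
                 class_weights = class_weights,
                 eval_every = as.integer(eval_every), seed = as.integer(seed),
                 augment = augment),
            class = "train_config")
}

#' Tiny supervised preset sized for a CPU
#' @param epochs,learning_rate,seed Overridable scaled-down defaults.
#' @return A `train_config`.
#' @export
train_config_tiny <- function(epochs = 12L, learning_rate = 0.01, seed = 0L) {
  train_config(epochs = epochs, learning_rate = learning_rate,
               sample_length = 8L, batch_size = 8L, seed = seed,
               frame_sampling = "random_jitter",
               augment = augment_config(crop_scale_range = c(0.7, 1),
                                        brightness_delta = 0.1,
                                        elastic_alpha = 10))
}

#' Subsample a clip to a fixed number of frames
#'
#' `"evenly_spaced"` picks indices `round(k * (len - 1) / (T - 1))`,
#' `k = 0 .. T-1` (with replacement implied when `len < T`; the single index
#' 0 when `T = 1`). `"random_jitter"` splits `[0, len)` into `T` equal bins
#' and draws one frame uniformly from each.
#'
#' @param video A `usv_video` (or list of frames).
#' @param n_frames Target frame count `T`.
#' @param mode Sampling mode.
#' @param seed Seed for `"random_jitter"`.
#' @return A `usv_video` of exactly `n_frames` frames.
#' @export
sample_frames <- function(video, n_frames,
                          mode = c("evenly_spaced", "random_jitter"),
                          seed = 0L) {
  mode <- match.arg(mode)
  if (n_frames < 1) stop("sample_frames: n_frames must be >= 1")
  frames <- if (inherits(video, "usv_video")) video$frames else video
  len <- length(frames)
  if (len < 1) stop("sample_frames: sequence is empty")
  idx <- if (mode == "evenly_spaced") {
    if (n_frames == 1) 0L
    else round((seq_len(n_frames) - 1) * (len - 1) / (n_frames - 1))
  } else {
    with_seed(seed, {
      lo <- floor((seq_len(n_frames) - 1) * len / n_frames)
      hi <- pmax(ceiling(seq_len(n_frames) * len / n_frames) - 1, lo)
      mapply(function(a, b) if (a == b) a else sample(a:b, 1), lo, hi)
    })
  }
  out <- frames[idx + 1]
  if (inherits(video, "usv_video")) {
    structure(list(id = video$id, frames = out, label = video$label),
              class = "usv_video")
  } else out
}

label_to_int <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("labels must be benign/malignant or 0/1")
    as.integer(labels)
  } else {
    if (!all(labels %in% CLASS_LEVELS)) {
      stop("unknown label(s): ",
           paste(setdiff(unique(labels), CLASS_LEVELS), collapse = ", "))
    }
    as.integer(labels == "malignant")
  }
}

# Forward the full video model on a list of clips (already frame-sampled).
# Returns per-clip malignant probability, loss pieces, and caches if train.
model_forward_batch <- function(encoder, attention, classifier, clips,
                                keep_cache = FALSE) {
  Ts <- vapply(clips, function(v) length(v$frames), integer(1))
  x <- frames_to_batch(unlist(lapply(clips, `[[`, "frames"), recursive = FALSE))
  ef <- encoder_fw(encoder, x)
  feats <- ef$y  # m x sum(Ts)
  offs <- c(0L, cumsum(Ts))
  agg <- matrix(0, nrow(feats), length(clips))
  acaches <- vector("list", length(clips))
  for (i in seq_along(clips)) {
    Fi <- t(feats[, (offs[i] + 1):offs[i + 1], drop = FALSE])  # T x m
    pf <- attention_pool_fw(Fi, attention)
    agg[, i] <- pf$y
    if (keep_cache) acaches[[i]] <- c(pf, list(features = Fi))
  }
  logits <- classifier$params$w %*% agg + classifier$params$b  # 2 x B
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  probs <- sweep(ex, 2, colSums(ex), "/")  # row 1 benign, row 2 malignant
  list(probs = probs, agg = agg, ef = if (keep_cache) ef else NULL,
       acaches = acaches, offs = offs, logits = logits)
}

#' Train the video classifier
#'
#' Optimizes encoder + attention aggregator + linear classifier end to end
#' with cross-entropy on the video label, subsampling `sample_length` frames
#' per clip each step. The run is a pure function of the data, initial
#' weights, and `config$seed`.
#'
#' @param videos Named list of `usv_video` clips.
#' @param index Dataset index tibble with `video_id`, `label`, `split`
#'   columns (from [generate_dataset()] / [read_dataset()]).
#' @param encoder Initial `usv_encoder` (random or contrastively pretrained).
#' @param config A [train_config()].
#' @param attention_cfg An [attention_config()].
#' @param test_videos Evaluate on the `"test"` split rows of `index` when
#'   `config$eval_every > 0` and at the end.
#' @return A `usv_model` with fields `encoder`, `attention`, `classifier`,
#'   `history` (tibble: epoch, train_loss, lr, and test metrics where
#'   evaluated), `metrics` (final test metrics, if a test split exists).
#' @export
train_classifier <- function(videos, index, encoder,
                             config = train_config_tiny(),
                             attention_cfg = attention_config(),
                             test_videos = TRUE) {
  train_ids <- index$video_id[index$split == "train"]
  test_ids <- index$video_id[index$split == "test"]
  if (length(train_ids) == 0) stop("train_classifier: empty training split")
  train_labels <- label_to_int(index$label[match(train_ids, index$video_id)])
  if (length(unique(train_labels)) < 2) {
    stop("train_classifier: training split must contain both classes")
  }
  m <- encoder$config$feature_dim
  attention <- build_attention(m, attention_cfg, seed = config$seed + 17L)
  classifier <- with_seed(config$seed + 29L, linear_layer(m, 2L, init_sd = 0.01))
  cw <- if (isTRUE(config$class_weights)) {
    n <- table(factor(train_labels, levels = 0:1))
    w <- as.numeric(length(train_labels) / (2 * n))
    w / mean(w)
  } else c(1, 1)
  opt <- make_optimizer("sgd", momentum = config$momentum,
                        weight_decay = config$weight_decay)
  nl <- length(encoder$layers)
  La <- attention$config$num_layers
  history <- list()
  for (ep in seq_len(config$epochs)) {
    lr <- cosine_lr(ep - 1, config$epochs, config$learning_rate)
    order_ids <- with_seed(derive_seed(config$seed, ep), sample(train_ids))
    ep_loss <- 0
    n_seen <- 0
    batches <- split(order_ids, ceiling(seq_along(order_ids) / config$batch_size))
    for (bi in seq_along(batches)) {
      ids <- batches[[bi]]
      clips <- lapply(seq_along(ids), function(j) {
        sj <- derive_seed(config$seed, ep * 100000L + bi * 100L + j)
        cl <- sample_frames(videos[[ids[j]]], config$sample_length,
                            config$frame_sampling, seed = sj)
        if (!is.null(config$augment)) {
          cl$frames <- lapply(seq_along(cl$frames), function(t) {
            augment(cl$frames[[t]], config$augment,
                    seed = derive_seed(sj, t))
          })
        }
        cl
      })
      y <- label_to_int(index$label[match(ids, index$video_id)])
      fwd <- model_forward_batch(encoder, attention, classifier, clips,
                                 keep_cache = TRUE)
      B <- length(ids)
      wvec <- cw[y + 1]
      pick <- cbind(y + 1, seq_len(B))
      losses <- -log(pmax(fwd$probs[pick], 1e-12)) * wvec
      loss <- sum(losses) / sum(wvec)
      if (!is.finite(loss)) {
        stop("train_classifier: non-finite loss at epoch ", ep)
      }
      ep_loss <- ep_loss + sum(losses)
      n_seen <- n_seen + sum(wvec)
      # softmax cross-entropy backward
      dlogits <- fwd$probs
      dlogits[pick] <- dlogits[pick] - 1
      dlogits <- sweep(dlogits, 2, wvec / sum(wvec), "*")
      cgrads <- list(w = tcrossprod(dlogits, fwd$agg), b = rowSums(dlogits))
      dagg <- crossprod(classifier$params$w, dlogits)  # m x B
      dfeats <- matrix(0, m, fwd$offs[length(fwd$offs)])
      agrads <- NULL
      for (i in seq_len(B)) {
        ab <- attention_pool_bw(fwd$acaches[[i]]$features, attention,
                                fwd$acaches[[i]], dagg[, i])
        dfeats[, (fwd$offs[i] + 1):fwd$offs[i + 1]] <- t(ab$dfeatures)
        agrads <- grads_add(agrads, ab$grads)
      }
      eb <- encoder_bw(encoder, fwd$ef$caches, dfeats)
      att_layers <- lapply(attention$layers, function(l) {
        list(type = "linear", params = l)
      })
      all_layers <- c(encoder$layers, att_layers, list(classifier))
      all_grads <- c(eb$grads, agrads, list(cgrads))
      all_layers <- opt$step(all_layers, all_grads, lr)
      encoder$layers <- all_layers[seq_len(nl)]
      for (l in seq_len(La)) attention$layers[[l]] <- all_layers[[nl + l]]$params
      classifier <- all_layers[[nl + La + 1]]
    }
    row <- tibble::tibble(epoch = ep, train_loss = ep_loss / n_seen, lr = lr)
    do_eval <- test_videos && length(test_ids) > 0 && config$eval_every > 0 &&
      (ep %% config$eval_every == 0 || ep == config$epochs)
    if (do_eval) {
      mdl <- structure(list(encoder = encoder, attention = attention,
                            classifier = classifier, threshold = 0.5),
                       class = "usv_model")
      ev <- evaluate_model(mdl, videos, index, split = "test")
      row$test_accuracy <- ev$metrics$accuracy
      row$test_auc <- ev$metrics$auc
    }
    history[[ep]] <- row
  }
  model <- structure(
    list(encoder = encoder, attention = attention, classifier = classifier,
         threshold = 0.5, config = config,
         history = dplyr::bind_rows(history), metrics = NULL),
    class = "usv_model"
  )
  if (test_videos && length(test_ids) > 0) {
    ev <- evaluate_model(model, videos, index, split = "test")
    model$metrics <- ev$metrics
    model$test_scores <- ev$scores
  }
  model
}

#' Predict the class of one video
#'
#' Uses the full frame sequence (no subsampling): the aggregator accepts any
#' length, and the prediction is invariant to frame order.
#'
#' @param object A `usv_model`.
#' @param video A `usv_video` or list of frames.
#' @param ... Unused.
#' @return A one-row tibble: `video_id`, `label`, `malignant_score`,
#'   `benign_score`.
#' @export
predict.usv_model <- function(object, video, ...) {
  if (!inherits(video, "usv_video")) {
    video <- structure(list(id = "video", frames = video, label = NA),
                       class = "usv_video")
  }
  fwd <- model_forward_batch(object$encoder, object$attention,
                             object$classifier, list(video))
  ms <- fwd$probs[2, 1]
  tibble::tibble(
    video_id = video$id,
    label = ifelse(ms >= object$threshold, "malignant", "benign"),
    malignant_score = ms, benign_score = fwd$probs[1, 1]
  )
}

#' Score a set of videos and compute the six metrics
#'
#' @param model A `usv_model`.
#' @param videos Named list of `usv_video`.
#' @param index Index tibble (`video_id`, `label`, optionally `split`).
#' @param split Restrict to this split (`NULL` = all rows).
#' @return List with `scores` (tibble: video_id, label, malignant_score) and
#'   `metrics` (a `usv_metrics` object).
#' @export
evaluate_model <- function(model, videos, index, split = "test") {
  rows <- if (!is.null(split) && "split" %in% names(index)) {
    index[index$split == split, ]
  } else index
  scores <- purrr::map_dfr(rows$video_id, function(id) {
    p <- predict(model, videos[[id]])
    p$video_id <- id
    p
  })
  scores$truth <- rows$label[match(scores$video_id, rows$video_id)]
  metrics <- compute_metrics(scores$malignant_score,
                             label_to_int(scores$truth),
                             threshold = model$threshold)
  list(scores = scores, metrics = metrics)
}

#' @export
print.usv_model <- function(x, ...) {
  cat(sprintf("<usv_model: %d-d features, %d attention layers, trained %d epochs>\n",
              x$encoder$config$feature_dim, x$attention$config$num_layers,
              if (is.null(x$history)) 0L else max(x$history$epoch)))
  if (!is.null(x$metrics)) {
    cat(sprintf("  test: accuracy %.3f, AUC %.3f\n",
                x$metrics$accuracy, x$metrics$auc))
  }
  invisible(x)
}
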