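# Independent oracles and tiny fixtures shared across tests. Oracles are
# deliberately naive (double loops, whole-tensor formulas, external packages)
# so they stay independent of the implementation paths they check.

# Central-difference numerical gradient of scalar f at x.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# NT-Xent by explicit double loop over anchors and candidates.
nt_xent_bruteforce <- function(emb, pair_index, temperature) {
  B <- nrow(emb)
  total <- 0
  for (i in seq_len(B)) {
    num <- exp(sum(emb[i, ] * emb[pair_index[i], ]) / temperature)
    den <- 0
    for (k in seq_len(B)) {
      if (k != i) den <- den + exp(sum(emb[i, ] * emb[k, ]) / temperature)
    }
    total <- total - log(num / den)
  }
  total / B
}

# Whole-tensor standardization (the groups = 1 case of group norm).
standardize_bruteforce <- function(x, eps = 1e-5) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  (x - mu) / sqrt(v + eps)
}

# Lesion boundary irregularity (perimeter^2 / (4 pi area)) measured from the
# clip itself: average frames, smooth, Otsu-threshold, largest filled
# component, EBImage shape features. Knows nothing of the generator.
lesion_irregularity_oracle <- function(video) {
  m <- Reduce(`+`, video$frames) / length(video$frames)
  img <- EBImage::gblur(EBImage::Image(t(m)), sigma = 1.5)
  mask <- EBImage::fillHull(EBImage::bwlabel(img < EBImage::otsu(img)))
  ft <- EBImage::computeFeatures.shape(mask)
  if (is.null(ft) || nrow(ft) == 0) return(NA_real_)
  k <- which.max(ft[, "s.area"])
  unname(ft[k, "s.perimeter"]^2 / (4 * pi * ft[k, "s.area"]))
}

# Attention cascade with all weights and biases zeroed: uniform logits.
zero_attention <- function(m, num_layers = 2L) {
  att <- build_attention(m, attention_config(num_layers = num_layers), seed = 1)
  for (l in seq_along(att$layers)) {
    att$layers[[l]]$w[] <- 0
    att$layers[[l]]$b[] <- 0
  }
  att
}

# Small clips for smoke tests (32 px is the encoder's minimum input side).
tiny_videos <- function(n = 8, n_frames = 4, size = 32, seed = 1) {
  vids <- lapply(seq_len(n), function(i) {
    generate_clip(clip_params(
      n_frames = n_frames, height = size, width = size,
      class_label = if (i %% 2 == 0) "malignant" else "benign",
      seed = seed * 1000 + i
    ), id = sprintf("clip_%03d", i))
  })
  names(vids) <- vapply(vids, `[[`, "", "id")
  vids
}

tiny_index <- function(videos, test_fraction = 0.25) {
  labs <- vapply(videos, `[[`, "", "label")
  n <- length(videos)
  idx <- tibble::tibble(
    video_id = names(videos), label = unname(labs),
    n_frames = vapply(videos, function(v) length(v$frames), integer(1)),
    split = rep("train", n)
  )
  for (lb in unique(labs)) {
    members <- which(labs == lb)
    idx$split[members[seq_len(max(1, round(test_fraction * length(members))))]] <- "test"
  }
  idx
}
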