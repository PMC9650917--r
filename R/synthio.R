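# Synthetic ultrasound-like video clips. Each clip shows a dark lesion on a
# multiplicative-speckle background; benign lesions have a smooth elliptical
# boundary, malignant lesions a spiculated star-convex boundary. Consecutive
# frames differ by a bounded random-walk translation, slow zoom, and a
# brightness offset, mimicking probe handling during acquisition.

#' Parameters for one synthetic clip
#'
#' @param n_frames Number of frames `T`.
#' @param height,width Frame size in pixels (>= 8).
#' @param class_label `"benign"` or `"malignant"`.
#' @param lesion_radius_frac Lesion radius as a fraction of `min(height,
#'   width)`; must lie in (0, 0.5).
#' @param irregularity Spiculation amplitude (>= 0): the per-vertex radial
#'   perturbation of the lesion boundary, as a fraction of the radius. The
#'   class-dependent default (benign 0.06, malignant 0.45) encodes the
#'   smooth-versus-spiculated clinical cue.
#' @param speckle_scale Dispersion of the multiplicative speckle noise (> 0).
#' @param drift_px_per_frame Bound on the per-frame random-walk translation of
#'   the lesion, in pixels (>= 0).
#' @param brightness_jitter Bound on the per-frame additive brightness offset
#'   (>= 0).
#' @param seed Integer seed; the clip is a pure function of these parameters.
#' @return A `clip_params` list.
#' @export
clip_params <- function(n_frames = 16L, height = 64L, width = 64L,
                        class_label = c("benign", "malignant"),
                        lesion_radius_frac = 0.22, irregularity = NULL,
                        speckle_scale = 0.35, drift_px_per_frame = 1,
                        brightness_jitter = 0.05, seed = 0L) {
  class_label <- match.arg(class_label)
  bad <- function(field, why) {
    stop("clip_params: invalid `", field, "`: ", why, call. = FALSE)
  }
  if (!is.numeric(n_frames) || n_frames < 1) bad("n_frames", "must be >= 1")
  if (!is.numeric(height) || height < 8) bad("height", "must be >= 8")
  if (!is.numeric(width) || width < 8) bad("width", "must be >= 8")
  if (!is.numeric(lesion_radius_frac) || lesion_radius_frac <= 0 ||
      lesion_radius_frac >= 0.5) {
    bad("lesion_radius_frac", "must lie in (0, 0.5)")
  }
  irregularity_default <- is.null(irregularity)
  if (irregularity_default) {
    irregularity <- if (class_label == "malignant") 0.45 else 0.06
  }
  if (!is.numeric(irregularity) || irregularity < 0) {
    bad("irregularity", "must be >= 0")
  }
  if (!is.numeric(speckle_scale) || speckle_scale <= 0) {
    bad("speckle_scale", "must be > 0")
  }
  if (!is.numeric(drift_px_per_frame) || drift_px_per_frame < 0) {
    bad("drift_px_per_frame", "must be >= 0")
  }
  if (!is.numeric(brightness_jitter) || brightness_jitter < 0) {
    bad("brightness_jitter", "must be >= 0")
  }
  structure(
    list(n_frames = as.integer(n_frames), height = as.integer(height),
         width = as.integer(width), class_label = class_label,
         lesion_radius_frac = lesion_radius_frac, irregularity = irregularity,
         speckle_scale = speckle_scale,
         drift_px_per_frame = drift_px_per_frame,
         brightness_jitter = brightness_jitter, seed = as.integer(seed),
         irregularity_default = irregularity_default),
    class = "clip_params"
  )
}

# Separable Gaussian blur (sigma in px) with edge renormalization.
gaussian_blur <- function(x, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  band <- function(n) {
    m <- matrix(0, n, n)
    for (o in -r:r) {
      idx <- seq_len(n - abs(o))
      if (o >= 0) m[cbind(idx, idx + o)] <- k[o + r + 1]
      else m[cbind(idx - o, idx)] <- k[o + r + 1]
    }
    m / rowSums(m)
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

# Boundary radius at query angles, piecewise-linearly interpolated from
# per-vertex radii (star-convex polygon).
interp_radius <- function(theta, vertex_theta, vertex_r) {
  n <- length(vertex_theta)
  th <- theta %% (2 * pi)
  i <- findInterval(th, vertex_theta)
  i[i == 0] <- n  # wrap below first vertex
  j <- i %% n + 1
  t0 <- vertex_theta[i]
  span <- (vertex_theta[j] - t0) %% (2 * pi)
  span[span == 0] <- 2 * pi
  w <- ((th - t0) %% (2 * pi)) / span
  vertex_r[i] * (1 - w) + vertex_r[j] * w
}

# Soft (anti-aliased) lesion mask: 1 inside, 0 outside, linear ramp of
# `shape$edge` px at the boundary (sharp for circumscribed benign margins,
# wide for the ill-defined malignant ones). Radius is direction-dependent.
lesion_mask <- function(H, W, cx, cy, shape, scale = 1) {
  px <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  py <- matrix(seq_len(H), H, W) - cy
  d <- sqrt(px^2 + py^2)
  th <- atan2(py, px)
  B <- if (shape$kind == "ellipse") {
    a <- shape$a * scale
    b <- shape$b * scale
    tr <- th - shape$angle
    (a * b) / sqrt((b * cos(tr))^2 + (a * sin(tr))^2)
  } else {
    interp_radius(th - shape$angle, shape$vertex_theta,
                  shape$vertex_r * scale)
  }
  pmin(pmax((B - d) / shape$edge + 0.5, 0), 1)
}

# Draw the per-clip lesion geometry and echo pattern, following the standard
# sonographic cues. Benign (fibroadenoma-like): smooth ellipse, circumscribed
# (sharp ~1.5 px margin), moderately hypoechoic (0.4x background). Malignant:
# spiculated star-convex polygon (per-vertex radius r * (1 + irregularity*u)),
# ill-defined margin (wide ramp), markedly hypoechoic, posterior shadowing.
draw_lesion_shape <- function(class_label, r, irregularity) {
  angle <- runif(1, 0, 2 * pi)
  if (class_label == "benign") {
    ecc <- runif(1, 0.05, 0.25) + irregularity
    list(kind = "ellipse", a = r * (1 + ecc), b = r * (1 - ecc),
         angle = angle, edge = 1.5, hypo = 0.6, shadow = 0)
  } else {
    nv <- 14L
    vt <- sort(runif(nv, 0, 2 * pi))
    vr <- r * (1 + irregularity * runif(nv, -1, 1))
    list(kind = "polygon", vertex_theta = vt, vertex_r = pmax(vr, 1),
         angle = angle, edge = 3.5, hypo = 0.78,
         shadow = runif(1, 0.15, 0.3))
  }
}

#' Generate one synthetic ultrasound clip
#'
#' Renders `n_frames` grayscale frames: a speckle-textured background with a
#' darker lesion (0.4x background intensity at the core), whose boundary is a
#' smooth ellipse for benign clips and a spiculated star-convex polygon for
#' malignant clips. Frames drift, zoom, and change brightness slowly; speckle
#' is drawn fresh per frame and Gaussian-smoothed (sigma = 1 px) to mimic the
#' spatial correlation of ultrasound texture. The output is a pure function of
#' `params` (including its `seed`).
#'
#' @param params A [clip_params()] object.
#' @param id Identifier stored on the clip.
#' @return A `usv_video`: list with `id`, `frames` (list of `H x W` matrices
#'   in `[0, 1]`), and `label`.
#' @export
generate_clip <- function(params, id = "clip") {
  if (!inherits(params, "clip_params")) {
    params <- do.call(clip_params, params)
  }
  H <- params$height
  W <- params$width
  with_seed(params$seed, {
    r <- params$lesion_radius_frac * min(H, W)
    shape <- draw_lesion_shape(params$class_label, r, params$irregularity)
    cx0 <- W / 2 + runif(1, -0.1, 0.1) * W
    cy0 <- H / 2 + runif(1, -0.1, 0.1) * H
    # slow vertical attenuation gradient, as in real B-mode images
    bg <- 0.62 - 0.1 * matrix(seq_len(H) / H, H, W)
    drift <- params$drift_px_per_frame
    dx <- cumsum(runif(params$n_frames, -drift, drift))
    dy <- cumsum(runif(params$n_frames, -drift, drift))
    zoom <- pmin(1.03, pmax(0.97, 1 + cumsum(runif(params$n_frames, -0.01, 0.01))))
    bright <- runif(params$n_frames, -params$brightness_jitter,
                    params$brightness_jitter)
    frames <- vector("list", params$n_frames)
    for (t in seq_len(params$n_frames)) {
      mask <- lesion_mask(H, W, cx0 + dx[t], cy0 + dy[t], shape, zoom[t])
      clean <- bg * (1 - shape$hypo * mask)
      if (shape$shadow > 0) {
        # posterior acoustic shadowing: attenuation below the lesion
        clean <- clean * (1 - shape$shadow * apply(mask, 2, cummax))
      }
      speckled <- clean * (1 + params$speckle_scale * matrix(rnorm(H * W), H, W))
      fr <- gaussian_blur(speckled, 1) + bright[t]
      frames[[t]] <- pmin(pmax(fr, 0), 1)
    }
    structure(list(id = id, frames = frames, label = params$class_label),
              class = "usv_video")
  })
}

#' @export
print.usv_video <- function(x, ...) {
  cat(sprintf("<usv_video %s: %d frames %dx%d, label=%s>\n", x$id,
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$label))
  invisible(x)
}

# Derive a per-clip seed from the dataset seed; kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `<out_dir>/<video_id>/frame_0000.png ...` (8-bit grayscale PNG),
#' an `index.csv` with columns `(video_id, label, n_frames, relative_path)`,
#' and `splits.json` mapping each video to `"train"` or `"test"`. The
#' train/test split is stratified by class: `round(test_fraction * n)` clips
#' of each class go to the test set, drawn with the given seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_benign,n_malignant Number of clips per class (>= 1).
#' @param params_template A [clip_params()] used for every clip; its
#'   `class_label`, `seed`, and (if left at the class default) `irregularity`
#'   are overridden per clip.
#' @param test_fraction Fraction of each class assigned to the test split,
#'   in (0, 1).
#' @param seed Integer seed for clip generation and the split.
#' @return The dataset index as a tibble (`video_id`, `label`, `n_frames`,
#'   `relative_path`, `split`), invisibly classed `usv_index`.
#' @export
generate_dataset <- function(out_dir, n_benign, n_malignant,
                             params_template = clip_params(),
                             test_fraction = 0.4, seed = 1L) {
  if (n_benign < 1 || n_malignant < 1) {
    stop("generate_dataset: class counts must be >= 1")
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("generate_dataset: test_fraction must lie in (0, 1)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("generate_dataset: cannot create output directory ", out_dir)
  }
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  ids <- c(sprintf("benign_%03d", seq_len(n_benign)),
           sprintf("malignant_%03d", seq_len(n_malignant)))
  # default irregularity is class-dependent: re-resolve it per clip
  template_default_irr <- isTRUE(params_template$irregularity_default) ||
    is.null(params_template$irregularity)
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- params_template
    p$class_label <- labels[i]
    p$seed <- derive_seed(seed, i)
    if (template_default_irr) {
      p$irregularity <- if (labels[i] == "malignant") 0.45 else 0.06
    }
    clip <- generate_clip(p, id = ids[i])
    vdir <- file.path(out_dir, ids[i])
    dir.create(vdir, showWarnings = FALSE)
    for (t in seq_along(clip$frames)) {
      png::writePNG(clip$frames[[t]],
                    file.path(vdir, sprintf("frame_%04d.png", t - 1)))
    }
    records[[i]] <- tibble::tibble(
      video_id = ids[i], label = labels[i],
      n_frames = length(clip$frames), relative_path = ids[i]
    )
  }
  index <- dplyr::bind_rows(records)
  split <- with_seed(derive_seed(seed, 0L), {
    s <- setNames(rep("train", nrow(index)), index$video_id)
    for (lb in c("benign", "malignant")) {
      members <- index$video_id[index$label == lb]
      n_test <- round(test_fraction * length(members))
      s[sample(members, n_test)] <- "test"
    }
    s
  })
  index$split <- unname(split[index$video_id])
  readr::write_csv(index[, c("video_id", "label", "n_frames",
                             "relative_path")],
                   file.path(out_dir, "index.csv"))
  jsonlite::write_json(as.list(split), file.path(out_dir, "splits.json"),
                       auto_unbox = TRUE)
  class(index) <- c("usv_index", class(index))
  invisible(index)
}

#' Read a dataset written by [generate_dataset()]
#'
#' @param index_path Path to `index.csv` (or the dataset directory).
#' @return A list with `videos` (list of `usv_video`) and `index` (tibble,
#'   including the `split` column when `splits.json` is present).
#' @export
read_dataset <- function(index_path) {
  if (dir.exists(index_path)) index_path <- file.path(index_path, "index.csv")
  if (!file.exists(index_path)) {
    stop("read_dataset: index file not found: ", index_path)
  }
  root <- dirname(index_path)
  index <- readr::read_csv(index_path, col_types = readr::cols(
    video_id = readr::col_character(), label = readr::col_character(),
    n_frames = readr::col_integer(), relative_path = readr::col_character()
  ))
  if (nrow(index) > 0 && !all(index$label %in% c("benign", "malignant"))) {
    bad <- setdiff(unique(index$label), c("benign", "malignant"))
    stop("read_dataset: unknown label string(s): ", paste(bad, collapse = ", "))
  }
  split_path <- file.path(root, "splits.json")
  if (file.exists(split_path)) {
    sp <- unlist(jsonlite::read_json(split_path))
    index$split <- unname(sp[index$video_id])
  }
  videos <- vector("list", nrow(index))
  for (i in seq_len(nrow(index))) {
    vdir <- file.path(root, index$relative_path[i])
    frames <- vector("list", index$n_frames[i])
    for (t in seq_len(index$n_frames[i])) {
      fp <- file.path(vdir, sprintf("frame_%04d.png", t - 1))
      if (!file.exists(fp)) {
        stop("read_dataset: missing frame file for video_id `",
             index$video_id[i], "`: ", fp)
      }
      px <- png::readPNG(fp)
      if (length(dim(px)) == 3) px <- px[, , 1]
      frames[[t]] <- px
    }
    videos[[i]] <- structure(
      list(id = index$video_id[i], frames = frames, label = index$label[i]),
      class = "usv_video"
    )
  }
  names(videos) <- index$video_id
  class(index) <- c("usv_index", class(index))
  list(videos = videos, index = index)
}

#' Generate a labeled synthetic dataset in memory
#'
#' Identical clip generation and stratified-split logic to
#' [generate_dataset()], but keeps the clips in memory instead of writing
#' PNG files; the same `(counts, template, fraction, seed)` produce the same
#' clips either way.
#'
#' @inheritParams generate_dataset
#' @return A list with `videos` (named list of `usv_video`) and `index`
#'   (tibble with `video_id`, `label`, `n_frames`, `split`).
#' @export
generate_dataset_memory <- function(n_benign, n_malignant,
                                    params_template = clip_params(),
                                    test_fraction = 0.4, seed = 1L) {
  if (n_benign < 1 || n_malignant < 1) {
    stop("generate_dataset_memory: class counts must be >= 1")
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("generate_dataset_memory: test_fraction must lie in (0, 1)")
  }
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  ids <- c(sprintf("benign_%03d", seq_len(n_benign)),
           sprintf("malignant_%03d", seq_len(n_malignant)))
  template_default_irr <- isTRUE(params_template$irregularity_default) ||
    is.null(params_template$irregularity)
  videos <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- params_template
    p$class_label <- labels[i]
    p$seed <- derive_seed(seed, i)
    if (template_default_irr) {
      p$irregularity <- if (labels[i] == "malignant") 0.45 else 0.06
    }
    videos[[i]] <- generate_clip(p, id = ids[i])
  }
  names(videos) <- ids
  index <- tibble::tibble(video_id = ids, label = labels,
                          n_frames = params_template$n_frames)
  split <- with_seed(derive_seed(seed, 0L), {
    s <- setNames(rep("train", length(ids)), ids)
    for (lb in c("benign", "malignant")) {
      members <- ids[labels == lb]
      s[sample(members, round(test_fraction * length(members)))] <- "test"
    }
    s
  })
  index$split <- unname(split[index$video_id])
  class(index) <- c("usv_index", class(index))
  list(videos = videos, index = index)
}
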