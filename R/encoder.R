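# Frame encoder: a ResNet-18-style backbone for grayscale input, with every
# batch normalization replaced by group normalization and one non-local block
# appended to each of the selected stages. Global average pooling yields an
# m-vector per frame, m = 8 * base_width.

#' Encoder configuration
#'
#' @param base_width Channel multiplier; stages use `base_width * c(1, 2, 4, 8)`
#'   channels. The default 64 gives a 512-dimensional feature; the `"tiny"`
#'   preset (`base_width = 16`) gives 128 and is sized for CPU experiments.
#' @param gn_groups Group-normalization group count; reduced to the largest
#'   common divisor when a layer has fewer channels than groups.
#' @param nl_stages Integer stages (subset of 1:4) that receive a non-local
#'   block after their last residual block.
#' @param in_channels Number of input image channels (1 for ultrasound).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(base_width = 64L, gn_groups = 32L,
                           nl_stages = c(3L, 4L), in_channels = 1L) {
  if (!all(nl_stages %in% 1:4)) {
    stop("encoder_config: nl_stages must be a subset of 1:4")
  }
  if (base_width < 2) stop("encoder_config: base_width must be >= 2")
  structure(
    list(base_width = as.integer(base_width),
         gn_groups = as.integer(gn_groups),
         nl_stages = as.integer(sort(unique(nl_stages))),
         in_channels = as.integer(in_channels),
         feature_dim = as.integer(8 * base_width)),
    class = "encoder_config"
  )
}

#' Tiny encoder preset for CPU-scale experiments
#' @return An `encoder_config` with `base_width = 16` (128-d features).
#' @export
encoder_config_tiny <- function() encoder_config(base_width = 16L)

#' Build a frame encoder
#'
#' Constructs the backbone with randomly initialized weights (He init for
#' convolutions, identity affine for group norm, zero output projection in
#' non-local blocks so they start as identities).
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed controlling the weight initialization.
#' @return A `usv_encoder` object.
#' @export
build_encoder <- function(config = encoder_config(), seed = 0L) {
  w0 <- config$base_width
  g <- config$gn_groups
  widths <- w0 * c(1L, 2L, 4L, 8L)
  layers <- with_seed(seed, {
    ll <- list(
      conv_layer(7, 7, config$in_channels, w0, stride = 2, pad = 3),
      gn_layer(w0, g),
      relu_layer(),
      maxpool_layer(3, 2, 1)
    )
    cin <- w0
    for (stage in 1:4) {
      cout <- widths[stage]
      stride <- if (stage == 1) 1L else 2L
      ll <- c(ll, list(resblock_layer(cin, cout, stride, g),
                       resblock_layer(cout, cout, 1L, g)))
      if (stage %in% config$nl_stages) {
        ll <- c(ll, list(nonlocal_layer(cout, zero_init_out = TRUE)))
      }
      cin <- cout
    }
    c(ll, list(gap_layer()))
  })
  structure(list(config = config, layers = layers), class = "usv_encoder")
}

# Minimum input side: stem (stride 2) + maxpool (stride 2) + 3 strided stages
# need at least 32 px to keep every map non-empty.
ENCODER_MIN_SIDE <- 32L

check_frame_size <- function(H, W) {
  if (H < ENCODER_MIN_SIDE || W < ENCODER_MIN_SIDE) {
    stop("encoder requires frames of at least ", ENCODER_MIN_SIDE, "x",
         ENCODER_MIN_SIDE, " pixels, got ", H, "x", W)
  }
}

# Forward over a batch array (H, W, 1, N) -> list(y = m x N, caches)
encoder_fw <- function(encoder, x) {
  seq_fw(encoder$layers, x)
}

encoder_bw <- function(encoder, caches, dfeat) {
  seq_bw(encoder$layers, caches, dfeat)
}

frames_to_batch <- function(frames) {
  if (is.matrix(frames)) frames <- list(frames)
  H <- nrow(frames[[1]])
  W <- ncol(frames[[1]])
  x <- array(unlist(frames, use.names = FALSE), dim = c(H, W, 1L, length(frames)))
  x
}

#' Encode one frame to an m-dimensional feature vector
#'
#' @param frame Numeric `H x W` matrix with values in `[0, 1]`.
#' @param encoder A `usv_encoder` from [build_encoder()].
#' @param mode `"eval"` (deterministic) or `"train"`; the backbone has no
#'   stochastic layers, so both give identical outputs -- the mode is kept for
#'   interface symmetry with training code.
#' @return Numeric vector of length `encoder$config$feature_dim`.
#' @export
encode_frame <- function(frame, encoder, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  check_frame_size(nrow(frame), ncol(frame))
  drop(encoder_fw(encoder, frames_to_batch(frame))$y)
}

#' Encode an ordered set of frames
#'
#' @param frames A list of `H x W` matrices (all the same size), or a
#'   `usv_video` object.
#' @param encoder A `usv_encoder`.
#' @param mode See [encode_frame()].
#' @return An `m x T` matrix; column `t` is the feature of frame `t`.
#' @export
encode_frames <- function(frames, encoder, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (inherits(frames, "usv_video")) frames <- frames$frames
  check_frame_size(nrow(frames[[1]]), ncol(frames[[1]]))
  encoder_fw(encoder, frames_to_batch(frames))$y
}
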