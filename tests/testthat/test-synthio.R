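# Synthetic clip generator and on-disk dataset format.

test_that("generated clips honor the shape/range/determinism contract", {
  p <- clip_params(n_frames = 8, height = 64, width = 64,
                   class_label = "benign", seed = 7)
  v <- generate_clip(p)
  expect_s3_class(v, "usv_video")
  expect_length(v$frames, 8)
  expect_true(all(vapply(v$frames, function(f) {
    is.matrix(f) && all(dim(f) == c(64, 64)) && all(is.finite(f)) &&
      all(f >= 0) && all(f <= 1)
  }, logical(1))))
  expect_identical(generate_clip(p)$frames, v$frames)
  # consecutive frames are related but not identical (drift/zoom/brightness)
  d <- mapply(function(a, b) mean(abs(a - b)), v$frames[-8], v$frames[-1])
  expect_true(all(d > 0) && all(d < 0.2))
})

test_that("invalid clip parameters are rejected naming the offending field", {
  expect_error(clip_params(n_frames = 0), "n_frames")
  expect_error(clip_params(height = 4), "height")
  expect_error(clip_params(lesion_radius_frac = 0.7), "lesion_radius_frac")
  expect_error(clip_params(irregularity = -1), "irregularity")
  expect_error(clip_params(speckle_scale = 0), "speckle_scale")
  expect_error(clip_params(drift_px_per_frame = -1), "drift_px_per_frame")
  expect_error(clip_params(brightness_jitter = -0.1), "brightness_jitter")
})

test_that("malignant clips are measurably more irregular than benign", {
  skip_if_not_installed("EBImage")
  irr <- vapply(0:99, function(s) {
    c(lesion_irregularity_oracle(generate_clip(clip_params(
        n_frames = 2, class_label = "benign", seed = s))),
      lesion_irregularity_oracle(generate_clip(clip_params(
        n_frames = 2, class_label = "malignant", seed = s))))
  }, numeric(2))
  benign <- irr[1, ]
  malignant <- irr[2, ]
  expect_true(mean(malignant, na.rm = TRUE) > mean(benign, na.rm = TRUE))
  p <- stats::wilcox.test(malignant, benign, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("dataset writing produces a stratified split with round(f*n) per class", {
  td <- withr::local_tempdir()
  idx <- generate_dataset(file.path(td, "d1"), 5, 5,
                          clip_params(n_frames = 2, height = 32, width = 32),
                          test_fraction = 0.4, seed = 1)
  expect_equal(nrow(idx), 10)
  expect_equal(sum(idx$split == "test"), 4)
  expect_equal(sum(idx$split == "test" & idx$label == "benign"), 2)
  # the published cohort scaled down ~1/8: 19 benign / 15 malignant
  idx2 <- generate_dataset(file.path(td, "d2"), 19, 15,
                           clip_params(n_frames = 1, height = 32, width = 32),
                           test_fraction = 0.4, seed = 2)
  tab <- table(idx2$split, idx2$label)
  expect_equal(unname(tab["test", "benign"]), round(0.4 * 19))
  expect_equal(unname(tab["test", "malignant"]), round(0.4 * 15))
})

test_that("dataset write is deterministic and read round-trips exactly", {
  td <- withr::local_tempdir()
  p <- clip_params(n_frames = 3, height = 32, width = 32)
  i1 <- generate_dataset(file.path(td, "a"), 3, 3, p, 0.4, seed = 5)
  i2 <- generate_dataset(file.path(td, "b"), 3, 3, p, 0.4, seed = 5)
  expect_equal(as.data.frame(i1), as.data.frame(i2))
  f <- function(root, rel) readBin(file.path(root, rel), "raw", 1e6)
  expect_identical(f(file.path(td, "a"), "index.csv"),
                   f(file.path(td, "b"), "index.csv"))
  expect_identical(f(file.path(td, "a"), "benign_001/frame_0000.png"),
                   f(file.path(td, "b"), "benign_001/frame_0000.png"))
  rd <- read_dataset(file.path(td, "a"))
  expect_length(rd$videos, 6)
  expect_equal(rd$index$split, i1$split)
  # pixels equal after 8-bit quantization
  orig <- generate_clip({
    q <- p; q$class_label <- "benign"
    q$seed <- usvid:::derive_seed(5, 1); q$irregularity <- 0.06
    q
  })
  expect_equal(rd$videos$benign_001$frames[[2]],
               round(orig$frames[[2]] * 255) / 255, tolerance = 1e-12)
})

test_that("read errors are descriptive and empty datasets read cleanly", {
  td <- withr::local_tempdir()
  generate_dataset(file.path(td, "d"), 2, 2,
                   clip_params(n_frames = 2, height = 32, width = 32),
                   0.5, seed = 1)
  file.remove(file.path(td, "d", "malignant_002", "frame_0001.png"))
  expect_error(read_dataset(file.path(td, "d")), "malignant_002")

  idx_path <- file.path(td, "d", "index.csv")
  bad <- readr::read_csv(idx_path, show_col_types = FALSE)
  bad$label[1] <- "suspicious"
  readr::write_csv(bad, idx_path)
  expect_error(read_dataset(idx_path), "suspicious")

  empty <- file.path(td, "empty")
  dir.create(empty)
  readr::write_csv(tibble::tibble(video_id = character(), label = character(),
                                  n_frames = integer(),
                                  relative_path = character()),
                   file.path(empty, "index.csv"))
  rd <- read_dataset(empty)
  expect_length(rd$videos, 0)
  expect_equal(nrow(rd$index), 0)
})
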