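# Frame sampling, metrics, ROC, prediction contracts, and the supervised
# training loop at smoke scale.

test_that("evenly spaced frame sampling matches the index arithmetic", {
  vid <- structure(list(id = "v", frames = as.list(1:32), label = "benign"),
                   class = "usv_video")
  s <- sample_frames(vid, 16, "evenly_spaced")
  oracle <- round((0:15) * 31 / 15)
  expect_equal(unlist(s$frames), oracle + 1)
  # len < T: sampling with replacement, every original frame appears
  vid5 <- structure(list(id = "v", frames = as.list(1:5), label = "benign"),
                    class = "usv_video")
  s5 <- sample_frames(vid5, 16, "evenly_spaced")
  expect_length(s5$frames, 16)
  expect_setequal(unlist(s5$frames), 1:5)
  # len == T: identity selection
  vid16 <- structure(list(id = "v", frames = as.list(1:16), label = "benign"),
                     class = "usv_video")
  expect_equal(unlist(sample_frames(vid16, 16, "evenly_spaced")$frames), 1:16)
  expect_equal(unlist(sample_frames(vid16, 1, "evenly_spaced")$frames), 1)
  expect_error(sample_frames(vid16, 0), "n_frames")
})

test_that("jittered sampling draws one frame per bin, seeded", {
  vid <- structure(list(id = "v", frames = as.list(1:32), label = "benign"),
                   class = "usv_video")
  s1 <- unlist(sample_frames(vid, 8, "random_jitter", seed = 5)$frames)
  s2 <- unlist(sample_frames(vid, 8, "random_jitter", seed = 5)$frames)
  expect_identical(s1, s2)
  bins <- findInterval(s1 - 1, (0:8) * 4)  # 8 bins of width 4
  expect_equal(bins, 1:8)
})

test_that("the six metrics reproduce the hand-computed confusion case", {
  # TP 9, FN 1, TN 8, FP 2 via scores at a 0.5 threshold
  scores <- c(rep(0.9, 9), 0.1, rep(0.2, 8), rep(0.8, 2))
  labels <- c(rep(1, 10), rep(0, 10))
  m <- compute_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$tp, 9)
  expect_equal(m$fn, 1)
  expect_equal(m$tn, 8)
  expect_equal(m$fp, 2)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 2 * (9 / 11) * 0.9 / ((9 / 11) + 0.9), tolerance = 1e-12)
  expect_equal(tidy(m)$value[1], 0.85)
})

test_that("ranking metrics honor perfect, degenerate and tied orderings", {
  y <- c(0, 0, 1, 1)
  perfect <- compute_metrics(c(0.1, 0.2, 0.8, 0.9), y)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$average_precision, 1)
  tied <- compute_metrics(rep(0.5, 4), y)
  expect_equal(tied$auc, 0.5)
  one_class <- compute_metrics(c(0.2, 0.8), c(1, 1))
  expect_false(one_class$auc_defined)
  expect_true(is.na(one_class$auc) && is.na(one_class$average_precision))
  expect_error(roc_curve(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("ROC trapezoid area equals Mann-Whitney AUC on random score sets", {
  skip_if_not_installed("pROC")
  set.seed(40)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    m <- compute_metrics(s, y)
    roc <- roc_curve(s, y)
    expect_lt(abs(usvid:::roc_auc_trapezoid(roc) - m$auc), 1e-9)
    # independent reference implementation
    pr <- suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                               direction = "<")))
    expect_equal(m$auc, as.numeric(pr), tolerance = 1e-9)
    # monotone staircase from (0,0) to (1,1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(tail(roc$fpr, 1), tail(roc$tpr, 1)), c(1, 1))
    # reversing scores flips the area
    expect_equal(compute_metrics(-s, y)$auc, 1 - m$auc, tolerance = 1e-9)
    # invariance under strictly monotone transforms
    expect_equal(compute_metrics(plogis(5 * s), y)$auc, m$auc,
                 tolerance = 1e-12)
    # accuracy consistent with recomputed confusion counts
    expect_equal(m$accuracy, (m$tp + m$tn) / n)
  }
  # perfect ranking passes through (0, 1)
  roc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
})

test_that("prediction is a softmax over two classes, order/length agnostic", {
  vids <- tiny_videos(n = 4, n_frames = 6, size = 32)
  enc <- build_encoder(encoder_config(base_width = 8), seed = 1)
  att <- build_attention(64, seed = 2)
  cls <- usvid:::linear_layer(64, 2)
  model <- structure(list(encoder = enc, attention = att, classifier = cls,
                          threshold = 0.5), class = "usv_model")
  p <- predict(model, vids[[1]])
  expect_true(p$malignant_score >= 0 && p$malignant_score <= 1)
  expect_equal(p$malignant_score + p$benign_score, 1, tolerance = 1e-6)
  expect_true(p$label %in% c("benign", "malignant"))
  expect_equal(p$label == "malignant", p$malignant_score >= 0.5)
  # frame-order shuffle leaves the prediction unchanged
  shuffled <- vids[[1]]
  shuffled$frames <- shuffled$frames[sample(length(shuffled$frames))]
  expect_equal(predict(model, shuffled)$malignant_score, p$malignant_score,
               tolerance = 1e-6)
  # T = 1 and T = 64 versions are both accepted by the same model
  one <- vids[[1]]
  one$frames <- one$frames[1]
  long <- vids[[1]]
  long$frames <- rep(long$frames, length.out = 64)
  expect_no_error(predict(model, one))
  expect_no_error(predict(model, long))
})

test_that("training validates its split and runs deterministically", {
  vids <- tiny_videos(n = 12, n_frames = 4, size = 32)
  idx <- tiny_index(vids)
  enc <- build_encoder(encoder_config(base_width = 8, nl_stages = 4), seed = 3)
  bad_idx <- idx
  bad_idx$label <- "benign"
  expect_error(train_classifier(vids, bad_idx, enc), "both classes")
  cfg <- train_config(epochs = 2, learning_rate = 0.01, sample_length = 3,
                      batch_size = 4, seed = 11)
  m1 <- train_classifier(vids, idx, enc, cfg)
  m2 <- train_classifier(vids, idx, enc, cfg)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 2)
  expect_s3_class(glance(m1), "tbl_df")
  expect_equal(nrow(tidy(m1)), 2)
})

test_that("a mean-pooling (zeroed-attention) model still trains and predicts", {
  vids <- tiny_videos(n = 8, n_frames = 3, size = 32)
  idx <- tiny_index(vids)
  enc <- build_encoder(encoder_config(base_width = 8, nl_stages = integer(0)),
                       seed = 4)
  cfg <- train_config(epochs = 1, learning_rate = 0.005, sample_length = 2,
                      batch_size = 4, seed = 12)
  model <- train_classifier(vids, idx, enc, cfg)
  model$attention <- zero_attention(64)
  p <- predict(model, vids[[1]])
  expect_true(is.finite(p$malignant_score))
  # with zeroed attention the pooled feature is exactly the frame mean
  feats <- t(encode_frames(vids[[1]], model$encoder))
  expect_equal(attention_pool(feats, model$attention), colMeans(feats),
               tolerance = 1e-9)
})

test_that("class weighting flips the loss balance for imbalanced data", {
  vids <- tiny_videos(n = 9, n_frames = 2, size = 32)
  labs <- vapply(vids, `[[`, "", "label")
  idx <- tiny_index(vids)
  cfg <- train_config(epochs = 1, learning_rate = 1e-3, sample_length = 2,
                      batch_size = 4, seed = 13, class_weights = TRUE)
  enc <- build_encoder(encoder_config(base_width = 8, nl_stages = integer(0)),
                       seed = 5)
  expect_no_error(train_classifier(vids, idx, enc, cfg))
})
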