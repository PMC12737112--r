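toy_features <- function(n = 120, k = 2, seed = 1) {
  # class j lives at mean 2j on feature j; only first k classes populated
  set.seed(seed)
  y <- sample(emotion_levels()[seq_len(k)], n, replace = TRUE)
  X <- matrix(rnorm(n * 24, 0, 0.4), n, 24)
  for (j in seq_len(k)) X[y == emotion_levels()[j], j] <-
      X[y == emotion_levels()[j], j] + 2 * j
  list(X = X, y = y)
}

test_that("fused features concatenate the four modalities in fixed order", {
  sec <- data.frame(session = "s", second = 0:3)
  mk <- function(v) cbind(sec, matrix(v, 4, 6, byrow = TRUE,
                                      dimnames = list(NULL, emotion_levels())))
  preds <- list(eda = mk(1:6 / 10), hr = mk(7:12 / 20), temp = mk(2:7 / 30))
  face <- mk(encode_onehot("sad"))
  labels <- cbind(sec, label = c("happy", "other", "sad", "angry"))
  ff <- build_fused_features(preds, face, labels)
  expect_equal(nrow(ff), 4)
  expect_equal(unname(unlist(ff[1, paste0("f", 1:24)])),
               c(1:6 / 10, 7:12 / 20, 2:7 / 30, encode_onehot("sad")),
               ignore_attr = TRUE)
  expect_equal(ff$valid, c(TRUE, FALSE, TRUE, TRUE))
  # coverage mismatch is an error naming missing seconds
  expect_error(build_fused_features(
    list(eda = preds$eda, hr = preds$hr[1:3, ], temp = preds$temp),
    face, labels), "hr")
})

test_that("logistic fusion separates a separable toy problem", {
  tf <- toy_features()
  fit <- fit_fusion_m1(tf$X, tf$y, lambda = 0.01)
  pred <- predict_fusion_m1(fit, tf$X)
  expect_equal(mean(pred$class == tf$y), 1)
  expect_equal(rowSums(pred$scores), rep(1, nrow(tf$X)), tolerance = 1e-9)
  expect_error(fit_fusion_m1(tf$X, rep("happy", nrow(tf$X))), "2 classes")
})

test_that("the unpenalized unweighted fit is invariant to duplication", {
  tf <- toy_features(n = 60, seed = 2)
  f1 <- fit_fusion_m1(tf$X, tf$y, lambda = 0, balanced = FALSE)
  f2 <- fit_fusion_m1(rbind(tf$X, tf$X), c(tf$y, tf$y), lambda = 0,
                      balanced = FALSE)
  expect_equal(predict_fusion_m1(f1, tf$X)$scores,
               predict_fusion_m1(f2, tf$X)$scores, tolerance = 1e-4)
})

test_that("balanced class weights neutralize majority-class duplication", {
  tf <- toy_features(n = 80, seed = 3)
  dup <- tf$y == "happy"
  f1 <- fit_fusion_m1(tf$X, tf$y, lambda = 0, balanced = TRUE)
  f2 <- fit_fusion_m1(rbind(tf$X, tf$X[dup, ]), c(tf$y, tf$y[dup]),
                      lambda = 0, balanced = TRUE)
  expect_equal(predict_fusion_m1(f1, tf$X)$scores,
               predict_fusion_m1(f2, tf$X)$scores, tolerance = 1e-3)
})

test_that("the multinomial fit matches an independent reference", {
  skip_if_not_installed("nnet")
  # overlapping classes keep the unpenalized MLE finite and unique
  set.seed(4)
  n <- 200
  y <- sample(emotion_levels()[1:3], n, replace = TRUE)
  X <- matrix(rnorm(n * 4), n, 4)
  X[, 1] <- X[, 1] + match(y, emotion_levels())
  fit <- fit_fusion_m1(X, y, lambda = 0, balanced = FALSE)
  df <- data.frame(y = factor(y, levels = emotion_levels()[1:3]), X)
  ref <- nnet::multinom(y ~ ., df, maxit = 1000, reltol = 1e-14,
                        trace = FALSE)
  pref <- predict(ref, df, type = "probs")
  got <- predict_fusion_m1(fit, X)$scores[, 1:3]
  expect_equal(unname(got), unname(pref), tolerance = 1e-6)
})

test_that("fusion predictions always name one of the six emotions", {
  null_model <- structure(
    list(coef = matrix(0, 25, 6,
                       dimnames = list(NULL, emotion_levels())),
         classes = emotion_levels()),
    class = "fusion_m1")
  X <- matrix(rnorm(10 * 24), 10, 24)
  pred <- predict_fusion_m1(null_model, X)
  expect_true(all(pred$scores == 1 / 6))
  expect_true(all(pred$class == "happy"))  # tie-break to class index 0
  expect_false(any(pred$class == "other"))
})

test_that("invalid frames carry no influence on the categorical fusion fit", {
  tf <- toy_features(n = 90, seed = 5)
  sec <- data.frame(session = "s", second = seq_len(90) - 1)
  ff <- cbind(sec, as.data.frame(tf$X))
  colnames(ff)[2 + (1:24)] <- paste0("f", 1:24)
  ff$label <- tf$y
  ff$label[1:20] <- "other"
  ff$valid <- ff$label != "other"
  class(ff) <- c("fused_features", "data.frame")
  fit1 <- fit_fusion_m1(ff)
  ff2 <- ff
  ff2[1:20, paste0("f", 1:24)] <- rnorm(20 * 24)   # perturb masked frames
  fit2 <- fit_fusion_m1(ff2)
  expect_identical(fit1$coef, fit2$coef)
})

test_that("the recurrent fusion model learns a copy-through mapping", {
  set.seed(6)
  n <- 160
  x <- array(runif(n * 4 * 24), c(n, 4, 24))
  targets <- x[, , 1:6]                 # copy the EDA block
  mask <- matrix(1, n, 4)
  fit <- fit_fusion_m2(x, targets, mask,
                       schedule = schedule_fusion_m2(epochs = 30L),
                       seed = 3)
  pred <- predict_fusion_m2(fit, x)
  expect_lt(masked_mse(targets, pred$frames, mask), 0.01)
  expect_true(all(pred$frames >= 0 & pred$frames <= 1))
  # determinism
  fit2 <- fit_fusion_m2(x, targets, mask,
                        schedule = schedule_fusion_m2(epochs = 30L),
                        seed = 3)
  expect_identical(fit$params, fit2$params)
  expect_error(fit_fusion_m2(x[0, , , drop = FALSE], targets, mask), "empty")
})

test_that("masked frames leave the recurrent fusion parameters unchanged", {
  set.seed(7)
  n <- 40
  x <- array(runif(n * 4 * 24), c(n, 4, 24))
  targets <- x[, , 7:12]
  mask <- matrix(rbinom(n * 4, 1, 0.6), n, 4)
  sched <- schedule_fusion_m2(epochs = 5L)
  f1 <- fit_fusion_m2(x, targets, mask, schedule = sched, seed = 1)
  targets2 <- targets
  targets2[, , ][rep(mask == 0, 6)] <- runif(sum(mask == 0) * 6)
  f2 <- fit_fusion_m2(x, targets2, mask, schedule = sched, seed = 1)
  expect_identical(f1$params, f2$params)
})

test_that("mapped fusion outputs give a categorical stream", {
  set.seed(8)
  n <- 30
  x <- array(runif(n * 4 * 24), c(n, 4, 24))
  fit <- fit_fusion_m2(x, x[, , 1:6], matrix(1, n, 4),
                       schedule = schedule_fusion_m2(epochs = 2L), seed = 2)
  pr <- predict_fusion_m2(fit, x)
  mapped <- dominant_from_distribution(matrix(pr$frames, ncol = 6))
  expect_true(all(mapped %in% c(emotion_levels(), "other")))
})
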