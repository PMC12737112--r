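easy_windows <- function(n_seconds = 60, subject = "m1", seed = 2L,
                         labels = NULL) {
  # strong signal: eda value directly encodes the class index
  set.seed(seed)
  if (is.null(labels)) {
    labels <- sample(emotion_levels(), n_seconds, replace = TRUE)
  }
  idx <- match(labels, emotion_levels())
  idx[is.na(idx)] <- 0
  tl <- make_timeline(eda = idx + rnorm(n_seconds, 0, 0.05),
                      hr = idx + rnorm(n_seconds, 0, 0.05),
                      temp = idx + rnorm(n_seconds, 0, 0.05),
                      face = labels,
                      votes = matrix(labels, n_seconds, 3),
                      subject = subject)
  extract_windows(zscore_subject(tl))
}

test_that("model specs pin the architectures and parameter counts", {
  s1 <- seq_model_spec("method1", "EDA")
  expect_equal(s1$bilstm, 128L)
  expect_equal(s1$dense, c(64L, 32L))
  expect_equal(s1$out_act, "softmax")
  expect_equal(n_params(s1),
               2L * 4L * 128L * (1L + 128L + 1L) +     # BiLSTM
                 257L * 64L + 65L * 32L + 33L * 6L)    # dense stack
  expect_equal(n_params(s1), 151846L)

  s2 <- seq_model_spec("method2", "TEMP")
  expect_equal(s2$dense, c(128L, 64L))
  expect_equal(s2$out_act, "sigmoid")
  expect_equal(n_params(s2), 133120L + 257L * 128L + 129L * 64L + 65L * 6L)

  sf <- seq_model_spec("method2", "FACE")
  expect_equal(sf$bilstm, 0L)  # no recurrence for the facial model
  expect_equal(n_params(sf), 7L * 64L + 65L * 6L)

  expect_error(seq_model_spec("method1", "FACE"), "fusion")

  # the built model carries exactly the advertised number of parameters
  m <- build_seq_model(s1, seed = 1)
  expect_equal(n_params(m), n_params(s1))
  mf <- build_seq_model(sf, seed = 1)
  expect_null(mf$params$bilstm)
})

test_that("model building is seed-deterministic", {
  a <- build_seq_model(seq_model_spec("method2", "FACE"), seed = 7)
  b <- build_seq_model(seq_model_spec("method2", "FACE"), seed = 7)
  d <- build_seq_model(seq_model_spec("method2", "FACE"), seed = 8)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, d$params))
})

test_that("masked losses match their closed forms", {
  n <- 2; Tn <- 4
  tg <- array(0, c(n, Tn, 6))
  for (i in 1:n) for (t in 1:Tn) tg[i, t, (i + t) %% 6 + 1] <- 1
  mask <- matrix(1, n, Tn)
  expect_equal(masked_categorical_crossentropy(tg, tg, mask), 0)
  # uniform scores, one valid frame: loss = ln 6
  uni <- array(1 / 6, c(n, Tn, 6))
  m1 <- matrix(0, n, Tn); m1[1, 2] <- 1
  expect_equal(masked_categorical_crossentropy(tg, uni, m1), log(6))
  # MSE: one-hot target vs zero scores over 6 channels = 1/6
  zero <- array(0, c(n, Tn, 6))
  expect_equal(masked_mse(tg, zero, m1), 1 / 6)
  expect_equal(masked_mse(tg, tg, mask), 0)
  # fully masked batch: 0 by convention
  expect_equal(masked_categorical_crossentropy(tg, uni, mask * 0), 0)
  expect_equal(masked_mse(tg, uni, mask * 0), 0)
})

test_that("losses are bit-invariant to predictions at masked frames", {
  set.seed(5)
  n <- 3; Tn <- 4
  tg <- array(runif(n * Tn * 6), c(n, Tn, 6))
  sc <- array(runif(n * Tn * 6, 0.1, 0.9), c(n, Tn, 6))
  mask <- matrix(rbinom(n * Tn, 1, 0.5), n, Tn)
  sc2 <- sc
  sc2[, , ][rep(mask == 0, 6)] <- runif(sum(mask == 0) * 6)
  expect_identical(masked_mse(tg, sc, mask), masked_mse(tg, sc2, mask))
  expect_identical(masked_categorical_crossentropy(tg, sc, mask),
                   masked_categorical_crossentropy(tg, sc2, mask))
})

test_that("analytic gradients match central finite differences", {
  ns <- asNamespace("emofuse")
  set.seed(42)
  for (case in list(c("softmax", 0), c("sigmoid", 1))) {
    p <- ns$nn_init(2L, 3L, c(4L), 6L, case[1], seed = 7)
    n <- 3; Tn <- 4
    x <- array(rnorm(n * Tn * 2), c(n, Tn, 2))
    tg <- array(runif(n * Tn * 6), c(n, Tn, 6))
    if (case[2] == "0") {
      for (i in 1:n) for (t in 1:Tn) {
        tg[i, t, ] <- 0; tg[i, t, sample(6, 1)] <- 1
      }
    }
    mask <- matrix(rbinom(n * Tn, 1, 0.7), n, Tn)
    arch <- ns$cpp_arch(p); xs <- ns$split_steps(x)
    ys <- ns$split_steps(tg); mv <- ns$mask_vec(mask)
    theta <- ns$pack_params(p)
    lt <- as.integer(case[2])
    g <- ns$cpp_net_grad(theta, arch, xs, ys, mv, lt)
    for (j in sample(length(theta), 25)) {
      h <- 1e-5
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      num <- (ns$cpp_net_grad(tp, arch, xs, ys, mv, lt)$loss -
                ns$cpp_net_grad(tm, arch, xs, ys, mv, lt)$loss) / (2 * h)
      expect_equal(g$grad[j], num, tolerance = 1e-4)
    }
  }
})

test_that("output shapes and normalization honor the scheme", {
  ws <- easy_windows(30)
  m <- build_seq_model(seq_model_spec("method1", "EDA"), seed = 3)
  sc <- predict_windows(m, ws)
  expect_equal(dim(sc), c(n_windows(ws), 4, 6))
  expect_equal(apply(sc, c(1, 2), sum),
               matrix(1, n_windows(ws), 4), tolerance = 1e-9)
  m2 <- build_seq_model(seq_model_spec("method2", "HR"), seed = 3)
  sc2 <- predict_windows(m2, ws)
  expect_true(all(sc2 >= 0 & sc2 <= 1))
})

test_that("training reduces loss on an easy fixture, deterministically", {
  ws <- easy_windows(120)
  sched <- schedule_method1(epochs = 6L, patience = 10L)
  m <- build_seq_model(seq_model_spec("method1", "EDA"), seed = 1)
  f1 <- train_seq_model(m, ws, schedule = sched, seed = 1)
  expect_true(all(diff(f1$history$train[1:5]) < 0))
  f2 <- train_seq_model(m, ws, schedule = sched, seed = 1)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  f3 <- train_seq_model(m, ws, schedule = sched, seed = 2)
  expect_false(identical(f1$history$train, f3$history$train))
  expect_error(train_seq_model(m, windows_subset(ws, integer())), "empty")
})

test_that("early stopping halts after the configured patience", {
  ws <- easy_windows(80)
  # a fully masked validation set keeps validation loss at 0 forever, so
  # no epoch after the first can improve it
  val <- easy_windows(20, subject = "mv", labels = rep("other", 20))
  m <- build_seq_model(seq_model_spec("method1", "EDA"), seed = 2)
  fit <- train_seq_model(m, ws, val,
                         schedule = schedule_method1(epochs = 50L,
                                                     patience = 5L),
                         seed = 2)
  expect_equal(nrow(fit$history), 1L + 5L)
  # fixed-epoch schedules ignore patience
  m2 <- build_seq_model(seq_model_spec("method2", "EDA"), seed = 2)
  fit2 <- train_seq_model(m2, ws, val,
                          schedule = schedule_method2(epochs = 7L), seed = 2)
  expect_equal(nrow(fit2$history), 7L)
})

test_that("per-second predictions average overlapping windows", {
  ws <- easy_windows(21)
  m <- build_seq_model(seq_model_spec("method1", "TEMP"), seed = 4)
  sc <- predict_windows(m, ws)
  pf <- predict_frames(m, ws)
  expect_true(all(abs(rowSums(as.matrix(pf[emotion_levels()])) - 1) < 1e-9))
  # a second covered by exactly one window passes through unchanged
  # (second 0 is only in the first window)
  expect_equal(unname(unlist(pf[pf$second == 0, emotion_levels()])),
               sc[1, 1, ], tolerance = 1e-12)
  # a second covered twice is the mean of the two frame scores
  i2 <- which(ws$start == 2)[1]
  expect_equal(unname(unlist(pf[pf$second == 2, emotion_levels()])),
               (sc[1, 3, ] + sc[i2, 1, ]) / 2, tolerance = 1e-12)
})
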