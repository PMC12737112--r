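test_that("the categorical report satisfies its identities", {
  set.seed(1)
  lv <- emotion_levels()
  truth <- sample(lv, 500, replace = TRUE, prob = c(40, 20, 15, 10, 10, 5))
  pred <- truth
  flip <- sample(500, 180)
  pred[flip] <- sample(lv, 180, replace = TRUE)
  r <- classification_report(truth, pred)
  expect_equal(r$f1_micro, r$accuracy)
  expect_equal(r$precision_micro, r$accuracy)
  expect_equal(r$balanced_accuracy, r$recall_macro)
  expect_equal(r$hamming_loss, 1 - r$accuracy)
  expect_equal(sum(r$per_class$support), 500)

  perfect <- classification_report(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$hamming_loss, 0)

  expect_error(classification_report(character(), character()), "empty")
  expect_error(classification_report(c("happy", "other"), c("sad", "sad")),
               "modeled")
})

test_that("per-class precision/recall/F1 match a hand computation", {
  r <- classification_report(c("happy", "happy", "sad"),
                             c("happy", "sad", "sad"))
  pc <- r$per_class
  expect_equal(pc$recall[pc$emotion == "happy"], 1 / 2)
  expect_equal(pc$precision[pc$emotion == "happy"], 1)
  expect_equal(pc$f1[pc$emotion == "happy"], 2 / 3)
  expect_equal(pc$recall[pc$emotion == "sad"], 1)
  expect_equal(pc$precision[pc$emotion == "sad"], 1 / 2)
  expect_equal(pc$f1[pc$emotion == "sad"], 2 / 3)
  expect_equal(r$accuracy, 2 / 3)
  # absent classes contribute recall 0 to the macro average
  expect_equal(r$balanced_accuracy, (0.5 + 1) / 6)
})

test_that("accuracy/Hamming pairs behave like the published convention", {
  set.seed(2)
  lv <- emotion_levels()
  truth <- sample(lv, 10000, replace = TRUE)
  pred <- truth
  wrong <- sample(10000, 10000 - 6792)
  pred[wrong] <- vapply(truth[wrong], function(t) sample(setdiff(lv, t), 1),
                        "")
  r <- classification_report(truth, pred)
  expect_equal(r$accuracy, 0.6792)
  expect_equal(r$hamming_loss, 0.3208)
})

test_that("the regression report averages the six per-emotion errors", {
  set.seed(3)
  n <- 200
  tr <- matrix(runif(n * 6), n, 6)
  pr <- tr + matrix(rnorm(n * 6, 0, 0.1), n, 6)
  mask <- rbinom(n, 1, 0.8)
  r <- regression_report(tr, pr, mask)
  expect_equal(r$mse_overall, mean(r$per_emotion$mse))
  expect_equal(r$mae_overall, mean(r$per_emotion$mae))
  expect_equal(r$n, sum(mask))
  # identity predictions
  rid <- regression_report(tr, tr)
  expect_equal(rid$per_emotion$mse, rep(0, 6))
  expect_equal(rid$per_emotion$cosine, rep(1, 6))
  expect_equal(rid$cosine_overall, 1)
})

test_that("2-frame regression toy matches hand computation", {
  tr <- rbind(c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0))
  pr <- rbind(c(0.5, 0.5, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0))
  r <- regression_report(tr, pr)
  expect_equal(r$per_emotion$mse[1], (0.25 + 0) / 2)
  expect_equal(r$per_emotion$mae[1], 0.25)
  expect_equal(r$per_emotion$mse[2], (0.25 + 0) / 2)
  # cosine for emotion 1: (1*0.5) / (1 * 0.5) = 1 (collinear series)
  expect_equal(r$per_emotion$cosine[1], 1)
  # zero-norm channels have undefined cosine
  expect_true(is.na(r$per_emotion$cosine[3]))
  expect_error(regression_report(tr, pr, c(0, 0)), "no valid frames")
})

test_that("published per-emotion errors average to the published overall", {
  mses <- c(0.249, 0.086, 0.076, 0.080, 0.097, 0.091)
  expect_equal(mean(mses), 0.1133, tolerance = 2e-3)
  set.seed(4)
  # realize each per-emotion MSE exactly with constant-offset predictions
  n <- 100
  tr <- matrix(runif(n * 6), n, 6)
  pr <- tr + rep(sqrt(mses), each = n)
  r <- regression_report(tr, pr)
  expect_equal(r$per_emotion$mse, mses)
  expect_equal(r$mse_overall, mean(mses))
})

test_that("confusion matrices row-normalize to percentages", {
  cm <- confusion_percent(c("happy", "happy", "happy"),
                          c("happy", "happy", "sad"))
  expect_equal(unname(cm$counts["happy", c("happy", "sad")]), c(2, 1))
  expect_equal(unname(cm$percent["happy", c("happy", "sad")]),
               c(66.66667, 33.33333), tolerance = 1e-5)
  expect_setequal(cm$empty_rows, setdiff(emotion_levels(), "happy"))
  set.seed(5)
  truth <- sample(emotion_levels(), 300, replace = TRUE)
  pred <- sample(emotion_levels(), 300, replace = TRUE)
  cm2 <- confusion_percent(truth, pred)
  expect_equal(unname(rowSums(cm2$percent)), rep(100, 6), tolerance = 1e-9)
  cm3 <- confusion_percent(truth, truth)
  expect_equal(unname(diag(cm3$percent)), rep(100, 6))
})

test_that("dominant-emotion mapping enables categorical evaluation", {
  set.seed(6)
  truth <- sample(emotion_levels(), 400, replace = TRUE)
  onehot <- encode_onehot(truth)
  m <- map_and_report(onehot, truth)
  expect_equal(m$report$accuracy, 1)
  # uniform predictions all map to the tie-break class (happy)
  mu <- map_and_report(matrix(1 / 6, 400, 6), truth)
  expect_equal(mu$report$accuracy, mean(truth == "happy"))
  expect_error(map_and_report(onehot[1:10, ], truth), "different frame")
})

test_that("mapped accuracy/Hamming reproduce the published pairing", {
  set.seed(7)
  lv <- emotion_levels()
  truth <- sample(lv, 10000, replace = TRUE)
  pred_lab <- truth
  wrong <- sample(10000, 10000 - 7846)
  pred_lab[wrong] <- vapply(truth[wrong], function(t) sample(setdiff(lv, t), 1),
                            "")
  m <- map_and_report(encode_onehot(pred_lab), truth)
  expect_equal(m$report$accuracy, 0.7846)
  expect_lt(abs(m$report$hamming_loss - 0.2153), 1.1e-4)
  expect_equal(m$report$balanced_accuracy, m$report$recall_macro)
})

test_that("reports and confusion matrices serialize to CSV", {
  r <- classification_report(c("happy", "sad"), c("happy", "sad"))
  p1 <- tempfile(fileext = ".csv")
  write_report_csv(r, p1)
  df <- read.csv(p1)
  expect_equal(df$value[df$metric == "accuracy"], 1)
  cm <- confusion_percent(c("happy", "sad"), c("happy", "sad"))
  p2 <- tempfile(fileext = ".csv")
  write_confusion_csv(cm, p2)
  expect_equal(unname(as.matrix(read.csv(p2, row.names = 1))["happy", "happy"]),
               100)
})
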