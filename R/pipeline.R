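#' Run configuration for the end-to-end experiments
#'
#' Bundles everything the two experiment drivers need: the cohort (a list
#' of `synthetic_session`s, `session_timeline`s, or a data directory
#' written by [write_cohort()]), the subject-disjoint split, per-model
#' schedules, and output options.
#'
#' The validation split drives early stopping and best-checkpoint
#' selection only.  Setting `fusion_train = "val"` instead fits the
#' decision-level fusion on validation-split predictions (held-out
#' stacking); the default `"train"` fits it on predictions for the
#' training sequences.
#'
#' @param sessions List of sessions/timelines, or `NULL` when `data_dir`
#'   is given.
#' @param data_dir Directory containing a `cohort.csv` manifest.
#' @param fractions Train/val/test fractions.
#' @param seed Master seed for split and training.
#' @param schedule1,schedule2,schedule_fusion Training schedules for
#'   Method I unimodal, Method II unimodal, and Method II fusion models.
#' @param lambda L2 strength of the Method I logistic fusion.
#' @param fusion_train `"train"` or `"val"`.
#' @param out_dir Optional run directory; when set, split manifest,
#'   reports, fused features and loss histories are persisted there.
#' @return A `run_config` list.
#' @export
run_config <- function(sessions = NULL, data_dir = NULL,
                       fractions = c(0.6, 0.2, 0.2), seed = 1L,
                       schedule1 = schedule_method1(),
                       schedule2 = schedule_method2(),
                       schedule_fusion = schedule_fusion_m2(),
                       lambda = 1, fusion_train = c("train", "val"),
                       out_dir = NULL) {
  stopifnot(!is.null(sessions) || !is.null(data_dir))
  structure(list(sessions = sessions, data_dir = data_dir,
                 fractions = fractions, seed = as.integer(seed),
                 schedule1 = schedule1, schedule2 = schedule2,
                 schedule_fusion = schedule_fusion, lambda = lambda,
                 fusion_train = match.arg(fusion_train),
                 out_dir = out_dir),
            class = "run_config")
}

load_timelines <- function(config) {
  if (!is.null(config$data_dir)) {
    info <- utils::read.csv(file.path(config$data_dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
    return(lapply(info$dir, read_session_bundle))
  }
  lapply(config$sessions, function(s) {
    if (inherits(s, "session_timeline")) s else session_to_timeline(s)
  })
}

# Standardize, window, split.  Shared by both experiment drivers.
prepare_data <- function(config) {
  timelines <- lapply(load_timelines(config), zscore_subject)
  names(timelines) <- vapply(timelines, `[[`, "", "session")
  ws <- extract_windows(timelines)
  subjects <- unique(ws$subject)
  weights <- as.vector(table(factor(ws$subject, levels = subjects)))
  split <- split_subjects(subjects, config$fractions, config$seed,
                          weights = weights)
  part <- split$partition[match(ws$subject, split$subject)]
  parts <- lapply(c(train = "train", val = "val", test = "test"),
                  function(p) windows_subset(ws, part == p))
  assert_subject_disjoint(parts)
  list(timelines = timelines, split = split, windows = parts)
}

assert_subject_disjoint <- function(parts) {
  subj <- lapply(parts, function(w) unique(w$subject))
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(subj[[i]], subj[[j]])) > 0L) {
      stop("subject-disjointness violated between partitions ",
           names(subj)[i], " and ", names(subj)[j])
    }
  }
  invisible(TRUE)
}

# Per-second truth/face tables for fusion features and evaluation.
cohort_frames <- function(timelines) {
  do.call(rbind, lapply(timelines, function(tl) {
    face <- encode_onehot(tl$face)
    colnames(face) <- emotion_levels()
    df <- data.frame(session = tl$session, subject = tl$subject,
                     second = seq_len(tl$n_seconds) - 1L,
                     label = tl$m1, face_label = tl$face,
                     stringsAsFactors = FALSE)
    m2 <- tl$m2
    colnames(m2) <- paste0("m2_", emotion_levels())
    cbind(df, as.data.frame(face), as.data.frame(m2))
  }))
}

#' Run the categorical (Method I) experiment end to end
#'
#' Executes the full two-stage pipeline: ingest/alignment, per-subject
#' standardization, windowing, subject-disjoint split, training-only
#' sequence filtering and native-rate minority upsampling, three unimodal
#' BiLSTM classifiers (EDA, HR, TEMP) under the masked categorical
#' cross-entropy, per-second prediction, logistic-regression fusion on
#' the 24-dim fused features (the facial block is the one-hot
#' forward-filled label), and test-set evaluation.
#'
#' @param config A [run_config()].
#' @return An `emorec_run` with the fused test `report` and `confusion`,
#'   per-modality unimodal reports, the fitted models, the split, and the
#'   fused feature tables.
#' @export
run_method1 <- function(config) {
  prep <- prepare_data(config)
  train_ws <- filter_sequences_m1(prep$windows$train)
  train_ws <- upsample_minority(train_ws, prep$timelines, "method1")
  modalities <- c("EDA", "HR", "TEMP")
  models <- list()
  for (k in seq_along(modalities)) {
    m <- build_seq_model(seq_model_spec("method1", modalities[k]),
                         seed = config$seed + k)
    models[[tolower(modalities[k])]] <-
      train_seq_model(m, train_ws, prep$windows$val,
                      schedule = config$schedule1, seed = config$seed + k)
  }
  frames <- cohort_frames(prep$timelines)
  fuse_ws <- if (config$fusion_train == "val") prep$windows$val
             else windows_subset(prep$windows$train,
                                 !prep$windows$train$augmented)
  # the fusion model is fitted on predictions for the (unaugmented)
  # training sequences; augmented samples only shape the unimodal models
  feats_fit <- m1_features(models, fuse_ws, frames)
  fusion <- fit_fusion_m1(feats_fit, lambda = config$lambda)
  feats_test <- m1_features(models, prep$windows$test, frames)
  valid <- feats_test$valid
  pred <- predict_fusion_m1(fusion, feats_test[valid, , drop = FALSE])
  report <- classification_report(feats_test$label[valid], pred$class)
  confusion <- confusion_percent(feats_test$label[valid], pred$class)
  unimodal <- m1_unimodal_reports(models, prep$windows$test, feats_test,
                                  frames)
  run <- structure(list(method = "method1", report = report,
                        confusion = confusion, unimodal = unimodal,
                        fusion = fusion, models = models,
                        split = prep$split, features_test = feats_test,
                        config = config),
                   class = "emorec_run")
  persist_run(run, feats_fit)
  run
}

m1_features <- function(models, ws, frames) {
  preds <- lapply(models, predict_frames, windows = ws)
  key <- paste(preds$eda$session, preds$eda$second)
  fidx <- match(key, paste(frames$session, frames$second))
  face_df <- cbind(frames[fidx, c("session", "second")],
                   frames[fidx, emotion_levels()])
  labels_df <- frames[fidx, c("session", "second", "label")]
  build_fused_features(preds, face_df, labels_df)
}

m1_unimodal_reports <- function(models, test_ws, feats_test, frames) {
  valid <- feats_test$valid
  truth <- feats_test$label[valid]
  out <- list()
  for (nm in names(models)) {
    pf <- predict_frames(models[[nm]], test_ws)
    key <- paste(pf$session, pf$second)
    idx <- match(paste(feats_test$session, feats_test$second)[valid], key)
    cls <- dominant_from_distribution(as.matrix(pf[idx, emotion_levels()]))
    cls[cls == "other"] <- emotion_levels()[1L]
    out[[nm]] <- classification_report(truth, cls)
  }
  # the facial stream enters fusion as a one-hot; its standalone report
  # uses the argmax of that one-hot (all-zero frames fall to the tie class)
  face_scores <- as.matrix(
    feats_test[valid, paste0("f", 19:24), drop = FALSE])
  cls <- dominant_from_distribution(face_scores)
  cls[cls == "other"] <- emotion_levels()[1L]
  out$face <- classification_report(truth, cls)
  out
}

#' Run the distribution (Method II) experiment end to end
#'
#' Same two-stage protocol as [run_method1()] for the proportional
#' annotation scheme: four unimodal sigmoid-output models (EDA, HR, TEMP
#' and the non-recurrent FACE model) trained with the masked MSE for a
#' fixed 40 epochs, per-window fused 4 x 24 sequences, the recurrent
#' weighted fusion network (50 epochs), and both test-set evaluation
#' views: the regression report against the proportional targets and the
#' categorical report after dominant-emotion mapping against the
#' majority-vote truth.
#'
#' @param config A [run_config()].
#' @return An `emorec_run` with `report` (regression), `mapped` (report +
#'   confusion), per-modality unimodal regression reports, models and
#'   split.
#' @export
run_method2 <- function(config) {
  prep <- prepare_data(config)
  train_ws <- filter_sequences_m2(prep$windows$train)
  train_ws <- upsample_minority(train_ws, prep$timelines, "method2")
  modalities <- c("EDA", "HR", "TEMP", "FACE")
  models <- list()
  for (k in seq_along(modalities)) {
    m <- build_seq_model(seq_model_spec("method2", modalities[k]),
                         seed = config$seed + 10L + k)
    models[[tolower(modalities[k])]] <-
      train_seq_model(m, train_ws, prep$windows$val,
                      schedule = config$schedule2,
                      seed = config$seed + 10L + k)
  }
  fuse_ws <- if (config$fusion_train == "val") prep$windows$val else train_ws
  fused_fit <- build_fused_sequences(
    lapply(models, predict_windows, windows = fuse_ws))
  val_ws <- prep$windows$val
  val_in <- if (n_windows(val_ws) > 0L) {
    list(x = build_fused_sequences(
           lapply(models, predict_windows, windows = val_ws)),
         targets = val_ws$m2, mask = val_ws$mask_m2)
  } else NULL
  fusion <- fit_fusion_m2(fused_fit, fuse_ws$m2, fuse_ws$mask_m2,
                          schedule = config$schedule_fusion, val = val_in,
                          seed = config$seed + 20L)
  test_ws <- prep$windows$test
  fused_test <- build_fused_sequences(
    lapply(models, predict_windows, windows = test_ws))
  pred <- predict_fusion_m2(fusion, fused_test, windows = test_ws)
  frames <- cohort_frames(prep$timelines)
  key <- paste(pred$seconds$session, pred$seconds$second)
  fidx <- match(key, paste(frames$session, frames$second))
  truth_m2 <- as.matrix(frames[fidx, paste0("m2_", emotion_levels())])
  pred_m2 <- as.matrix(pred$seconds[emotion_levels()])
  mask <- as.integer(rowSums(truth_m2) > 0)
  report <- regression_report(truth_m2, pred_m2, mask)
  m1_truth <- frames$label[fidx]
  m1_valid <- m1_truth %in% emotion_levels()
  mapped <- map_and_report(pred_m2[m1_valid, , drop = FALSE],
                           m1_truth[m1_valid])
  unimodal <- lapply(models, function(m) {
    pf <- predict_frames(m, test_ws)
    idx <- match(paste(pf$session, pf$second),
                 paste(frames$session, frames$second))
    tm <- as.matrix(frames[idx, paste0("m2_", emotion_levels())])
    regression_report(tm, as.matrix(pf[emotion_levels()]),
                      as.integer(rowSums(tm) > 0))
  })
  run <- structure(list(method = "method2", report = report,
                        mapped = mapped, unimodal = unimodal,
                        fusion = fusion, models = models,
                        split = prep$split, config = config),
                   class = "emorec_run")
  persist_run(run, NULL)
  run
}

persist_run <- function(run, feats_fit) {
  out_dir <- run$config$out_dir
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_split(run$split, file.path(out_dir, "split.csv"))
  if (run$method == "method1") {
    write_report_csv(run$report, file.path(out_dir, "report_fused.csv"))
    write_confusion_csv(run$confusion, file.path(out_dir, "confusion.csv"))
    if (!is.null(feats_fit)) {
      write_fused_features_csv(feats_fit,
                               file.path(out_dir, "fused_features.csv"))
    }
  } else {
    utils::write.csv(run$report$per_emotion,
                     file.path(out_dir, "report_regression.csv"),
                     row.names = FALSE)
    write_report_csv(run$mapped$report,
                     file.path(out_dir, "report_mapped.csv"))
    write_confusion_csv(run$mapped$confusion,
                        file.path(out_dir, "confusion_mapped.csv"))
  }
  for (nm in names(run$models)) {
    utils::write.csv(run$models[[nm]]$history,
                     file.path(out_dir, sprintf("history_%s.csv", nm)),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' @export
print.emorec_run <- function(x, ...) {
  cat(sprintf("End-to-end emotion recognition run (%s)\n", x$method))
  if (x$method == "method1") {
    print(x$report)
  } else {
    print(x$report)
    cat("Dominant-emotion mapped view:\n")
    print(x$mapped$report)
  }
  invisible(x)
}
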