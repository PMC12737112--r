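#' Unimodal sequence-model specification
#'
#' Fixes the architecture of a per-modality sequence labeler.  All models
#' consume 4-step windows and emit one 6-vector per timestep
#' (sequence-to-sequence output, so that per-frame masked losses and
#' per-frame fusion features are well defined).
#'
#' * `method1` signal models (EDA/HR/TEMP): BiLSTM with 128 units per
#'   direction, dense ReLU layers of 64 and 32 units, softmax output —
#'   trained with masked categorical cross-entropy.
#' * `method2` signal models: BiLSTM 128, dense ReLU 128 and 64, sigmoid
#'   output (six independent intensities) — trained with masked MSE.
#' * `method2` FACE model: no recurrence; a 64-unit ReLU layer applied to
#'   each timestep of the 6-dim one-hot facial input, sigmoid output.
#'
#' Under `method1` the facial stream is not modeled: the forward-filled
#' dominant-emotion label is one-hot encoded and fed to the fusion stage
#' directly, so `seq_model_spec("method1", "FACE")` is an error.
#'
#' @param scheme `"method1"` or `"method2"`.
#' @param modality One of `"EDA"`, `"HR"`, `"TEMP"`, `"FACE"`.
#' @return An object of class `"seq_model_spec"`.
#' @export
seq_model_spec <- function(scheme = c("method1", "method2"),
                           modality = c("EDA", "HR", "TEMP", "FACE")) {
  scheme <- match.arg(scheme)
  modality <- match.arg(modality)
  if (scheme == "method1" && modality == "FACE") {
    stop("method1 uses the one-hot facial label directly in fusion; ",
         "no FACE sequence model exists under method1")
  }
  spec <- if (scheme == "method1") {
    list(d_in = 1L, bilstm = 128L, dense = c(64L, 32L), out_act = "softmax",
         loss = "cce")
  } else if (modality == "FACE") {
    list(d_in = 6L, bilstm = 0L, dense = 64L, out_act = "sigmoid",
         loss = "mse")
  } else {
    list(d_in = 1L, bilstm = 128L, dense = c(128L, 64L), out_act = "sigmoid",
         loss = "mse")
  }
  spec$scheme <- scheme
  spec$modality <- modality
  spec$d_out <- 6L
  class(spec) <- "seq_model_spec"
  spec
}

#' Number of trainable parameters implied by a model spec
#'
#' A pure function of the architecture: the BiLSTM contributes
#' `2 * 4h(d + h + 1)` parameters, each dense layer `(d_in + 1) * width`.
#'
#' @param spec A [seq_model_spec()] (or fitted `seq_model`).
#' @return Integer parameter count.
#' @export
n_params <- function(spec) {
  if (inherits(spec, "seq_model")) return(nn_n_params(spec$params))
  d <- spec$d_in
  n <- 0L
  if (spec$bilstm > 0L) {
    h <- spec$bilstm
    n <- n + 2L * (4L * h * (d + h + 1L))
    d <- 2L * h
  }
  for (w in c(spec$dense, spec$d_out)) {
    n <- n + (d + 1L) * w
    d <- w
  }
  n
}

#' Build an untrained sequence model
#'
#' Initializes all weights reproducibly from `seed` (Glorot-uniform
#' matrices, zero biases, forget-gate bias 1).
#'
#' @param spec A [seq_model_spec()].
#' @param seed Integer seed controlling initialization.
#' @return An object of class `"seq_model"`.
#' @export
build_seq_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "seq_model_spec"))
  params <- nn_init(spec$d_in, spec$bilstm, spec$dense, spec$d_out,
                    spec$out_act, seed = seed)
  structure(list(spec = spec, params = params, seed = seed,
                 trained = FALSE, history = NULL),
            class = "seq_model")
}

#' @export
print.seq_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Sequence model [%s/%s]: %s-> dense(%s) -> 6 x %s\n",
              s$scheme, s$modality,
              if (s$bilstm > 0) sprintf("BiLSTM(%d) ", s$bilstm) else "",
              paste(s$dense, collapse = ", "), s$out_act))
  cat(sprintf("  %d parameters; %s\n", n_params(x),
              if (x$trained) sprintf("trained %d epochs (best val loss %.5f)",
                                     nrow(x$history), min(x$history$val))
              else "untrained"))
  invisible(x)
}

#' Training schedules
#'
#' Fixed hyper-parameters of the two training regimes: Adam (learning rate
#' `1e-3`), batch size 32.  Method I trains for up to 100 epochs with early
#' stopping at patience 10 on validation loss; Method II trains unimodal
#' models for a fixed 40 epochs and the recurrent fusion model for 50, in
#' both cases restoring the best-validation-loss parameters.
#'
#' @param epochs,patience,batch,lr Override individual values.
#' @return A list of class `"training_schedule"`.
#' @export
schedule_method1 <- function(epochs = 100L, patience = 10L, batch = 32L,
                             lr = 1e-3) {
  structure(list(epochs = epochs, patience = patience, batch = batch,
                 lr = lr), class = "training_schedule")
}

#' @rdname schedule_method1
#' @export
schedule_method2 <- function(epochs = 40L, batch = 32L, lr = 1e-3) {
  structure(list(epochs = epochs, patience = Inf, batch = batch, lr = lr),
            class = "training_schedule")
}

#' @rdname schedule_method1
#' @export
schedule_fusion_m2 <- function(epochs = 50L, batch = 32L, lr = 1e-3) {
  structure(list(epochs = epochs, patience = Inf, batch = batch, lr = lr),
            class = "training_schedule")
}

# Extract model inputs/targets/mask from a window set for one modality.
model_inputs <- function(windows, modality, scheme) {
  n <- length(windows$start)
  x <- switch(modality,
    EDA  = array(windows$x$eda,  c(n, 4L, 1L)),
    HR   = array(windows$x$hr,   c(n, 4L, 1L)),
    TEMP = array(windows$x$temp, c(n, 4L, 1L)),
    FACE = windows$x$face,
    stop("unknown modality ", modality))
  if (scheme == "method1") {
    tg <- array(0, c(n, 4L, 6L))
    for (t in 1:4) tg[, t, ] <- encode_onehot(windows$m1[, t])
    list(x = x, targets = tg, mask = windows$mask_m1)
  } else {
    list(x = x, targets = windows$m2, mask = windows$mask_m2)
  }
}

# Core trainer shared by unimodal models and the Method II fusion network.
# The parameter vector, Adam state and the per-batch work live in the C++
# kernel (cpp_train_epoch); R owns shuffling, validation loss, early
# stopping and best-checkpoint restoration.
nn_train <- function(params, loss, x, targets, mask, xv = NULL,
                     targets_v = NULL, mask_v = NULL, schedule, seed = 1L) {
  n <- dim(x)[1L]
  if (n == 0L) stop("empty training set")
  set.seed(seed + 1L)
  arch <- cpp_arch(params)
  loss_type <- if (loss == "cce") 0L else 1L
  theta <- pack_params(params)
  am <- numeric(length(theta)); av <- numeric(length(theta))
  adam_t <- 0L
  xs <- split_steps(x)
  ys <- split_steps(targets)
  storage.mode(mask) <- "double"
  have_val <- !is.null(xv) && dim(xv)[1L] > 0L
  if (have_val) xsv <- split_steps(xv)
  best <- list(loss = Inf, theta = theta)
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  wait <- 0L
  for (epoch in seq_len(schedule$epochs)) {
    idx <- sample.int(n) - 1L                 # 0-based for the kernel
    batches <- split(idx, ceiling(seq_along(idx) / schedule$batch))
    train_loss <- cpp_train_epoch(theta, am, av, adam_t, arch, xs, ys,
                                  mask, unname(batches), loss_type,
                                  schedule$lr)
    val_loss <- if (have_val) {
      fv <- cpp_net_forward(theta, arch, xsv)
      flat_loss(loss, fv, targets_v, mask_v)
    } else train_loss
    hist <- rbind(hist, data.frame(epoch = epoch, train = train_loss,
                                   val = val_loss))
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, theta = theta * 1)  # force a copy
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (is.finite(schedule$patience) && wait >= schedule$patience) break
    }
  }
  list(params = unpack_params(params, best$theta), history = hist)
}

# masked loss from the flat [(T*n), k] score matrix
flat_loss <- function(loss, flat, targets, mask) {
  tf <- flatten_frames(targets)
  m <- as.logical(mask_vec(mask))
  if (!any(m)) return(0)
  if (loss == "cce") {
    p <- rowSums(tf * flat)[m]
    -sum(log(pmax(p, 1e-7))) / sum(m)
  } else {
    mean((flat - tf)[m, , drop = FALSE]^2)
  }
}

#' Train a unimodal sequence model
#'
#' Runs seeded minibatch Adam with the scheme's masked loss (categorical
#' cross-entropy for `method1`, MSE for `method2`).  Validation loss is
#' evaluated after every epoch; the parameters achieving the lowest
#' validation loss are restored at the end.  Under a finite patience the
#' run stops once validation loss has not improved for that many epochs.
#' Training is deterministic given the seed and schedule.
#'
#' @param model A [build_seq_model()] object.
#' @param train_windows,val_windows `window_set` objects from
#'   [extract_windows()]; the two must come from disjoint subject sets.
#' @param schedule A training schedule; defaults to the scheme's standard
#'   schedule.
#' @param seed Integer seed for batch shuffling.
#' @return The trained `seq_model`, with a `history` data frame of
#'   per-epoch train/validation loss.
#' @export
train_seq_model <- function(model, train_windows, val_windows = NULL,
                            schedule = NULL, seed = 1L) {
  stopifnot(inherits(model, "seq_model"))
  spec <- model$spec
  if (is.null(schedule)) {
    schedule <- if (spec$scheme == "method1") schedule_method1()
                else schedule_method2()
  }
  tr <- model_inputs(train_windows, spec$modality, spec$scheme)
  va <- if (!is.null(val_windows) && length(val_windows$start) > 0L) {
    model_inputs(val_windows, spec$modality, spec$scheme)
  } else NULL
  fit <- nn_train(model$params, spec$loss, tr$x, tr$targets, tr$mask,
                  xv = va$x, targets_v = va$targets, mask_v = va$mask,
                  schedule = schedule, seed = seed)
  model$params <- fit$params
  model$history <- fit$history
  model$trained <- TRUE
  model$schedule <- schedule
  model
}

#' Per-window frame scores
#'
#' Applies a model to every window and returns the raw per-frame 6-vectors
#' as an `[n, 4, 6]` array (no cross-window aggregation).
#'
#' @param model A trained `seq_model` (or the Method II fusion model).
#' @param windows A `window_set`.
#' @return Numeric array `[n_windows, 4, 6]`.
#' @export
predict_windows <- function(model, windows) {
  inp <- model_inputs(windows, model$spec$modality, model$spec$scheme)
  nn_forward(model$params, inp$x)$scores
}

#' Per-second frame predictions
#'
#' Aggregates per-window frame scores to one prediction per covered second:
#' seconds inside several overlapping windows receive the arithmetic mean
#' of their per-window scores, renormalized to sum to 1 for `method1`
#' (softmax) models.  Augmented (upsampled) windows have no place on the
#' session clock and are skipped.
#'
#' @inheritParams predict_windows
#' @param scores Optional precomputed `[n, 4, 6]` score array (e.g. fusion
#'   outputs); when supplied, `model` may be `NULL` except for its scheme.
#' @param renormalize Renormalize averaged scores to sum to 1 (default:
#'   `TRUE` for `method1` models).
#' @return A data frame with columns `session`, `subject`, `second` and the
#'   six emotion scores.
#' @export
predict_frames <- function(model, windows, scores = NULL,
                           renormalize = NULL) {
  if (is.null(scores)) scores <- predict_windows(model, windows)
  if (is.null(renormalize)) {
    renormalize <- !is.null(model) && model$spec$out_act == "softmax"
  }
  aggregate_frame_scores(windows, scores, renormalize = renormalize)
}

# Shared per-second averaging of [n, 4, 6] window scores.
aggregate_frame_scores <- function(windows, scores, renormalize = FALSE) {
  keep <- !windows$augmented
  if (!any(keep)) stop("no real (non-augmented) windows to aggregate")
  idx <- which(keep)
  n <- length(idx)
  # one row per (window, frame), window-major with frames in order
  sec <- as.vector(t(outer(windows$start[idx], 0:3, `+`)))
  sess <- rep(windows$session[idx], each = 4L)
  subj <- rep(windows$subject[idx], each = 4L)
  acc <- matrix(aperm(scores[idx, , , drop = FALSE], c(2L, 1L, 3L)),
                ncol = 6L)
  key <- paste(sess, sec)
  grp <- factor(key, levels = unique(key))
  m <- rowsum(acc, grp, reorder = FALSE)
  cnt <- as.vector(table(grp)[levels(grp)])
  m <- m / cnt
  if (renormalize) {
    s <- rowSums(m)
    s[s <= 0] <- 1
    m <- m / s
  }
  first <- !duplicated(key)
  out <- data.frame(session = sess[first], subject = subj[first],
                    second = sec[first], stringsAsFactors = FALSE)
  colnames(m) <- emotion_levels()
  out <- cbind(out, as.data.frame(m))
  rownames(out) <- NULL
  out[order(out$session, out$second), , drop = FALSE]
}
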