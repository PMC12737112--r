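#' Per-second fused feature vectors (Method I)
#'
#' Concatenates the four modality 6-vectors — EDA, HR, TEMP, FACE, in this
#' fixed order — into one 24-dimensional feature per second.  For Method I
#' the FACE block is the one-hot encoding of the forward-filled facial
#' label; the other blocks are the per-second unimodal model predictions.
#' Frames whose true label is `other` (zero-vector truth) are flagged
#' invalid and excluded from fusion fitting.
#'
#' @param preds Named list with per-second prediction data frames (from
#'   [predict_frames()]) for `eda`, `hr`, `temp`; each has columns
#'   `session`, `second` and the six emotion scores.
#' @param face_input Data frame `session`, `second` + six columns of the
#'   facial one-hot (or facial model scores).
#' @param labels Data frame `session`, `second`, `label` of true Method I
#'   labels.
#' @return A `fused_features` data frame: `session`, `second`, `f1`..`f24`,
#'   `label`, `valid`.
#' @export
build_fused_features <- function(preds, face_input, labels) {
  stopifnot(all(c("eda", "hr", "temp") %in% names(preds)))
  lv <- emotion_levels()
  key <- function(df) paste(df$session, df$second)
  base_key <- key(preds$eda)
  blocks <- list(eda = preds$eda, hr = preds$hr, temp = preds$temp,
                 face = face_input)
  mats <- vector("list", 4L)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    idx <- match(base_key, key(b))
    if (anyNA(idx)) {
      missing <- preds$eda$second[is.na(idx)]
      stop("modality ", names(blocks)[k], " does not cover second(s) ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (sum(is.na(idx)) > 5L) " ..." else "")
    }
    mats[[k]] <- as.matrix(b[idx, lv, drop = FALSE])
  }
  feat <- do.call(cbind, mats)
  colnames(feat) <- paste0("f", 1:24)
  lab_idx <- match(base_key, key(labels))
  if (anyNA(lab_idx)) stop("labels do not cover all predicted seconds")
  lab <- as.character(labels$label)[lab_idx]
  out <- data.frame(session = preds$eda$session, second = preds$eda$second,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(feat))
  out$label <- lab
  out$valid <- lab != "other"
  class(out) <- c("fused_features", "data.frame")
  out
}

fused_matrix <- function(features) {
  as.matrix(features[paste0("f", 1:24)])
}

#' Multinomial logistic-regression fusion (Method I)
#'
#' Maximum-likelihood multinomial logistic regression on the 24-dim fused
#' features with an L2 (ridge) penalty on the non-intercept coefficients
#' and inverse-class-frequency ("balanced") sample weights:
#' `w_i = n / (K * n_{class(i)})`.  The fit minimizes the penalized
#' weighted negative log-likelihood with BFGS from a zero start and is
#' deterministic given the data.
#'
#' @param features A `fused_features` data frame (only `valid` rows are
#'   used) or a numeric `n x 24` matrix.
#' @param labels True labels (taken from `features$label` if omitted).
#' @param lambda L2 penalty strength (default 1).
#' @param balanced Use inverse-frequency class weights (default `TRUE`).
#' @return A `fusion_m1` model: softmax coefficients (25 x 6, intercept
#'   first).
#' @export
fit_fusion_m1 <- function(features, labels = NULL, lambda = 1,
                          balanced = TRUE) {
  if (inherits(features, "fused_features")) {
    keep <- features$valid
    X <- fused_matrix(features)[keep, , drop = FALSE]
    y <- features$label[keep]
  } else {
    X <- as.matrix(features)
    y <- as.character(labels)
  }
  lv <- emotion_levels()
  stopifnot(length(y) == nrow(X), all(y %in% lv))
  present <- lv[lv %in% unique(y)]
  if (length(present) < 2L) {
    stop("fusion fitting needs at least 2 classes among valid frames")
  }
  yi <- match(y, lv)
  n <- nrow(X); p <- ncol(X); K <- 6L
  w <- rep(1, n)
  if (balanced) {
    cnt <- table(factor(y, levels = lv))
    w <- n / (length(present) * as.vector(cnt)[yi])
  }
  Xd <- cbind(1, X)
  Y <- matrix(0, n, K); Y[cbind(1:n, yi)] <- 1
  obj <- function(par) {
    B <- matrix(par, p + 1L, K)
    Z <- Xd %*% B
    Z <- Z - apply(Z, 1L, max)
    P <- exp(Z); P <- P / rowSums(P)
    nll <- -sum(w * log(pmax(P[cbind(1:n, yi)], 1e-12)))
    nll + lambda / 2 * sum(B[-1L, ]^2)
  }
  grad <- function(par) {
    B <- matrix(par, p + 1L, K)
    Z <- Xd %*% B
    Z <- Z - apply(Z, 1L, max)
    P <- exp(Z); P <- P / rowSums(P)
    G <- crossprod(Xd, w * (P - Y))
    G[-1L, ] <- G[-1L, ] + lambda * B[-1L, ]
    as.vector(G)
  }
  fit <- stats::optim(numeric((p + 1L) * K), obj, grad, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-12))
  feat_names <- colnames(X)
  if (is.null(feat_names)) feat_names <- paste0("f", seq_len(p))
  coef <- matrix(fit$par, p + 1L, K,
                 dimnames = list(c("(Intercept)", feat_names), lv))
  structure(list(coef = coef, lambda = lambda, balanced = balanced,
                 classes = lv, value = fit$value,
                 convergence = fit$convergence),
            class = "fusion_m1")
}

#' @export
coef.fusion_m1 <- function(object, ...) object$coef

#' @export
print.fusion_m1 <- function(x, ...) {
  cat(sprintf(paste0("Multinomial logistic fusion model: 24 features -> 6",
                     " classes\n  lambda = %g, %s class weights\n"),
              x$lambda, if (x$balanced) "balanced" else "uniform"))
  invisible(x)
}

#' Predict with the Method I fusion model
#'
#' Softmax class scores and the argmax class per frame.  The system always
#' outputs one of the six emotions (ties break to the lowest class
#' index); it never outputs `other`.
#'
#' @param model A `fusion_m1` fit (or a model with user-set coefficients).
#' @param features A `fused_features` data frame or `n x 24` matrix.
#' @return List with `class` (character) and `scores` (`n x 6`, rows sum
#'   to 1).
#' @export
predict_fusion_m1 <- function(model, features) {
  X <- if (is.data.frame(features)) fused_matrix(features)
       else as.matrix(features)
  Z <- cbind(1, X) %*% model$coef
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z); P <- P / rowSums(P)
  colnames(P) <- model$classes
  list(class = model$classes[max.col(P, ties.method = "first")], scores = P)
}

#' @export
predict.fusion_m1 <- function(object, newdata, ...) {
  predict_fusion_m1(object, newdata)
}

#' Per-window fused input sequences (Method II)
#'
#' Stacks the four unimodal Method II models' per-window frame outputs —
#' EDA, HR, TEMP, FACE, in the fixed modality order — into `[n, 4, 24]`
#' input sequences for the recurrent fusion model.
#'
#' @param pred_list Named list of `[n, 4, 6]` score arrays (from
#'   [predict_windows()]) for `eda`, `hr`, `temp`, `face`.
#' @return Numeric array `[n, 4, 24]`.
#' @export
build_fused_sequences <- function(pred_list) {
  stopifnot(all(c("eda", "hr", "temp", "face") %in% names(pred_list)))
  ord <- c("eda", "hr", "temp", "face")
  n <- dim(pred_list$eda)[1L]
  out <- array(0, c(n, 4L, 24L))
  for (k in seq_along(ord)) {
    out[, , ((k - 1L) * 6L + 1L):(k * 6L)] <- pred_list[[ord[k]]]
  }
  out
}

#' Recurrent weighted fusion model (Method II)
#'
#' Trains the decision-level fusion network for the distribution scheme: a
#' bidirectional LSTM (64 units per direction) over the 4-step sequence of
#' 24-dim fused unimodal outputs, a 64-unit ReLU layer modeling
#' cross-modality interactions, and six sigmoid outputs per frame.
#' Optimized with Adam under the masked MSE loss for a fixed 50 epochs
#' (best-validation parameters restored); masked frames contribute no
#' gradient.  Deterministic given the seed.
#'
#' @param fused_sequences `[n, 4, 24]` array from
#'   [build_fused_sequences()].
#' @param target_dists `[n, 4, 6]` target distributions.
#' @param masks `[n, 4]` binary validity mask.
#' @param schedule Training schedule; defaults to [schedule_fusion_m2()].
#' @param val Optional list `(x, targets, mask)` of validation data.
#' @param seed Integer seed.
#' @param units BiLSTM width per direction.
#' @return A `fusion_m2` model.
#' @export
fit_fusion_m2 <- function(fused_sequences, target_dists, masks,
                          schedule = schedule_fusion_m2(), val = NULL,
                          seed = 1L, units = 64L) {
  if (length(fused_sequences) == 0L || dim(fused_sequences)[1L] == 0L) {
    stop("empty fusion training input")
  }
  params <- nn_init(24L, units, 64L, 6L, "sigmoid", seed = seed)
  fit <- nn_train(params, "mse", fused_sequences, target_dists, masks,
                  xv = val$x, targets_v = val$targets, mask_v = val$mask,
                  schedule = schedule, seed = seed)
  structure(list(params = fit$params, history = fit$history,
                 schedule = schedule, seed = seed, units = units),
            class = "fusion_m2")
}

#' @export
print.fusion_m2 <- function(x, ...) {
  cat(sprintf(paste0("Recurrent fusion model: BiLSTM(%d) over 4 x 24 fused",
                     " inputs -> 6 sigmoid outputs\n"), x$units))
  cat(sprintf("  trained %d epochs (best val loss %.5f)\n",
              nrow(x$history), min(x$history$val)))
  invisible(x)
}

#' Predict with the Method II fusion model
#'
#' Per-frame 6-vectors of independent sigmoid intensities in `[0, 1]` (not
#' normalized).  When the originating `window_set` is supplied, outputs of
#' overlapping windows are additionally averaged per second.
#'
#' @param model A `fusion_m2` model.
#' @param fused_sequences `[n, 4, 24]` input array.
#' @param windows Optional `window_set` the sequences came from; enables
#'   the per-second view.
#' @return List with `frames` (`[n, 4, 6]` array) and, when `windows` is
#'   given, `seconds` (per-second data frame as in [predict_frames()]).
#' @export
predict_fusion_m2 <- function(model, fused_sequences, windows = NULL) {
  scores <- nn_forward(model$params, fused_sequences)$scores
  out <- list(frames = scores)
  if (!is.null(windows)) {
    out$seconds <- aggregate_frame_scores(windows, scores,
                                          renormalize = FALSE)
  }
  out
}

#' Export fused features for audit
#'
#' @param features A `fused_features` data frame.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_fused_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
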