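#' Subject-disjoint train/validation/test split
#'
#' Assigns every subject to exactly one of train/val/test.  Assignment is
#' greedy on per-subject frame counts: subjects are processed in
#' decreasing weight (ties shuffled by the seed) and each goes to the
#' partition with the largest remaining deficit relative to its target
#' fraction, so realized frame fractions track the 60/20/20 targets even
#' when session lengths vary.  Deterministic under a fixed seed.
#'
#' @param subjects Character vector of subject ids.
#' @param fractions Target fractions for (train, val, test); must sum
#'   to 1.
#' @param seed Integer seed.
#' @param weights Optional per-subject frame counts (defaults to equal
#'   weights).
#' @return A `split_assignment`: data frame with columns `subject`,
#'   `partition`.
#' @export
split_subjects <- function(subjects, fractions = c(0.6, 0.2, 0.2),
                           seed = 1L, weights = NULL) {
  subjects <- as.character(subjects)
  stopifnot(!anyDuplicated(subjects), length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8)
  if (length(subjects) < 3L) {
    stop("need at least 3 subjects for a 3-way subject-disjoint split")
  }
  if (is.null(weights)) weights <- rep(1, length(subjects))
  stopifnot(length(weights) == length(subjects), all(weights > 0))
  set.seed(seed)
  ord <- sample.int(length(subjects))            # seed-shuffled tie order
  ord <- ord[order(weights[ord], decreasing = TRUE)]
  parts <- c("train", "val", "test")
  total <- sum(weights)
  assigned <- setNames(numeric(3), parts)
  out <- character(length(subjects))
  for (i in ord) {
    deficit <- fractions * total - assigned
    p <- parts[which.max(deficit)]
    out[i] <- p
    assigned[p] <- assigned[p] + weights[i]
  }
  structure(data.frame(subject = subjects, partition = out,
                       stringsAsFactors = FALSE),
            class = c("split_assignment", "data.frame"),
            fractions = fractions, seed = seed)
}

#' Write / read a split manifest
#'
#' @param split A `split_assignment`.
#' @param path CSV path.
#' @return The path (writer) or the assignment (reader), invisibly.
#' @export
write_split <- function(split, path) {
  utils::write.csv(split, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("split_assignment", "data.frame"))
}

#' Sequence filtering for Method I training data
#'
#' Drops training windows dominated by the majority labels: a window is
#' kept iff it contains at least one frame with a minority emotion (any
#' label outside `other`/`happy`), or its `happy` count is exactly one
#' (fewer than two but at least one).  Windows of only `other`/`happy`
#' frames with two or more `happy` frames are excluded.
#'
#' @param windows A `window_set`.
#' @return The retained `window_set` (surviving windows are unaltered).
#' @export
filter_sequences_m1 <- function(windows) {
  minority <- apply(windows$m1, 1L, function(r) any(!r %in% c("other", "happy")))
  n_happy <- rowSums(windows$m1 == "happy")
  windows_subset(windows, minority | n_happy == 1L)
}

#' Sequence filtering for Method II training data
#'
#' Drops windows whose frames are all zero vectors (exclusively `other`)
#' and windows carrying mass only on `happy` while also containing at
#' least one zero-vector frame (`other`-and-`happy`-only segments).
#' Windows labeled solely with `happy` — every frame carrying happy mass —
#' are retained, as is any window with mass on a non-happy emotion.
#'
#' @param windows A `window_set`.
#' @return The retained `window_set`.
#' @export
filter_sequences_m2 <- function(windows) {
  happy_i <- match("happy", emotion_levels())
  keep <- vapply(seq_len(n_windows(windows)), function(i) {
    d <- matrix(windows$m2[i, , ], 4L, 6L)
    frame_mass <- rowSums(d)
    if (all(frame_mass == 0)) return(FALSE)           # exclusively other
    if (any(d[, -happy_i] > 0)) return(TRUE)          # minority mass present
    !any(frame_mass == 0)                             # all-happy kept
  }, logical(1))
  windows_subset(windows, keep)
}

#' Native-rate minority-class upsampling (training split only)
#'
#' For every distinct training-frame second whose dominant emotion is
#' `disgusted`, `surprised` or `angry`, appends exactly one augmented
#' 4-frame sample built from the original physiological data at its
#' native rate: the four 4 Hz EDA and TEMP samples of that second, the
#' 1 Hz HR value repeated across the four frames, and the facial label and
#' annotation targets copied to all four frames.  Augmented samples exist
#' only in the training partition; validation and test data are never
#' resampled.
#'
#' @param train_windows A `window_set` from the training partition.
#' @param timelines List of standardized `session_timeline`s (named or
#'   searchable by session id) providing the native 4 Hz arrays.
#' @param scheme `"method1"` (dominance = majority label) or `"method2"`
#'   (dominance = argmax of the target distribution).
#' @return The `window_set` with augmented samples appended.
#' @export
upsample_minority <- function(train_windows, timelines,
                              scheme = c("method1", "method2")) {
  scheme <- match.arg(scheme)
  minority <- c("disgusted", "surprised", "angry")
  tl_by_session <- timelines
  names(tl_by_session) <- vapply(timelines, `[[`, character(1), "session")
  real <- windows_subset(train_windows, !train_windows$augmented)
  # distinct (session, second) frames covered by the training windows
  nw <- n_windows(real)
  if (nw == 0L) return(train_windows)
  sess <- rep(real$session, each = 4L)
  subj <- rep(real$subject, each = 4L)
  sec <- as.vector(t(outer(real$start, 0:3, `+`)))
  lab <- if (scheme == "method1") {
    as.vector(t(real$m1))
  } else {
    dominant_from_distribution(matrix(aperm(real$m2, c(2L, 1L, 3L)),
                                      ncol = 6L))
  }
  frames <- data.frame(session = sess, subject = subj, second = sec,
                       label = lab, stringsAsFactors = FALSE)
  frames <- frames[!duplicated(frames[c("session", "second")]), ]
  frames <- frames[frames$label %in% minority, , drop = FALSE]
  if (nrow(frames) == 0L) return(train_windows)
  aug <- new_window_set(nrow(frames))
  keep <- logical(nrow(frames))
  for (i in seq_len(nrow(frames))) {
    tl <- tl_by_session[[frames$session[i]]]
    s <- frames$second[i]
    nat_idx <- (4L * s + 1L):(4L * s + 4L)
    eda4 <- tl$eda_native[nat_idx]
    temp4 <- tl$temp_native[nat_idx]
    if (anyNA(eda4) || anyNA(temp4) || is.na(tl$hr[s + 1L])) {
      warning(sprintf(
        "native data missing for %s second %d; frame skipped",
        frames$session[i], s))
      next
    }
    keep[i] <- TRUE
    aug$x$eda[i, ] <- eda4
    aug$x$temp[i, ] <- temp4
    aug$x$hr[i, ] <- rep(tl$hr[s + 1L], 4L)
    aug$x$face[i, , ] <- matrix(encode_onehot(tl$face[s + 1L]), 4L, 6L,
                                byrow = TRUE)
    aug$m1[i, ] <- rep(tl$m1[s + 1L], 4L)
    aug$m2[i, , ] <- matrix(tl$m2[s + 1L, ], 4L, 6L, byrow = TRUE)
  }
  aug$subject <- frames$subject
  aug$session <- frames$session
  aug$start <- as.integer(frames$second)
  aug$augmented <- rep(TRUE, nrow(frames))
  aug <- build_masks(windows_subset(aug, keep))
  bind_windows(list(train_windows, aug))
}
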