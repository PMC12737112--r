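#' Per-subject z-score standardization
#'
#' Standardizes each biosignal channel as `Z = (X - mu) / sigma`, where
#' `mu` and `sigma` are the mean and (population, divide-by-N) standard
#' deviation of that channel over the subject's own recording, computed on
#' the non-missing seconds of the 1 Hz aligned stream.  The retained
#' native 4 Hz arrays are standardized with the same parameters so that
#' upsampled training samples live on the same scale.  A constant channel
#' (`sigma = 0`) maps to all zeros with a warning.
#'
#' @param timeline A `session_timeline` from [align_session()].
#' @return The timeline with standardized signals; the fitted parameters
#'   are stored in its `standardization` field (per channel `mu`,
#'   `sigma`).
#' @export
zscore_subject <- function(timeline) {
  if (!is.null(timeline$standardization)) {
    stop("timeline is already standardized")
  }
  params <- list(subject = timeline$subject)
  for (ch in c("eda", "hr", "temp")) {
    x <- timeline[[ch]]
    ok <- !is.na(x)
    if (sum(ok) < 2L) {
      stop(sprintf("channel %s has %d non-missing seconds; >= 2 required",
                   toupper(ch), sum(ok)))
    }
    mu <- mean(x[ok])
    sigma <- sqrt(mean((x[ok] - mu)^2))
    if (sigma == 0) {
      warning(sprintf("channel %s is constant for subject %s; standardized ",
                      toupper(ch), timeline$subject),
              "values set to 0")
      timeline[[ch]][ok] <- 0
      z <- function(v) ifelse(is.na(v), NA_real_, 0)
    } else {
      z <- function(v) (v - mu) / sigma
      timeline[[ch]] <- z(x)
    }
    if (ch %in% c("eda", "temp")) {
      nat <- paste0(ch, "_native")
      timeline[[nat]] <- z(timeline[[nat]])
    }
    params[[ch]] <- list(mu = mu, sigma = sigma)
  }
  timeline$standardization <- params
  timeline
}

#' Extract fixed-length windows from a timeline
#'
#' Slides a 4-second window with a 2-second stride (50% overlap) over the
#' standardized 1 Hz timeline, starting at seconds 0, 2, 4, ...  Windows
#' containing any missing biosignal second are dropped (no imputation is
#' performed).  Loss masks for both annotation schemes are attached via
#' [build_masks()].
#'
#' @param timeline A standardized `session_timeline`, or a list of them.
#' @param length,stride Window length and stride in seconds.
#' @return A `window_set` holding, per window: the subject/session, the
#'   start second, per-frame signal values, the one-hot facial
#'   distribution, both label streams and both masks.
#' @export
extract_windows <- function(timeline, length = 4L, stride = 2L) {
  if (!inherits(timeline, "session_timeline")) {
    return(bind_windows(lapply(timeline, extract_windows,
                               length = length, stride = stride)))
  }
  stopifnot(length == 4L)  # the model input unit is fixed at 4 frames
  n <- timeline$n_seconds
  starts <- if (n >= length) seq(0L, n - length, by = stride) else integer()
  keep <- vapply(starts, function(s) {
    idx <- (s + 1L):(s + length)
    !anyNA(timeline$eda[idx]) && !anyNA(timeline$hr[idx]) &&
      !anyNA(timeline$temp[idx])
  }, logical(1))
  starts <- starts[keep]
  nw <- base::length(starts)
  ws <- new_window_set(nw)
  if (nw == 0L) return(ws)
  for (i in seq_len(nw)) {
    idx <- (starts[i] + 1L):(starts[i] + length)
    ws$x$eda[i, ] <- timeline$eda[idx]
    ws$x$hr[i, ] <- timeline$hr[idx]
    ws$x$temp[i, ] <- timeline$temp[idx]
    ws$x$face[i, , ] <- encode_onehot(timeline$face[idx])
    ws$m1[i, ] <- timeline$m1[idx]
    ws$m2[i, , ] <- timeline$m2[idx, ]
  }
  ws$subject <- rep(timeline$subject, nw)
  ws$session <- rep(timeline$session, nw)
  ws$start <- as.integer(starts)
  ws$augmented <- rep(FALSE, nw)
  build_masks(ws)
}

new_window_set <- function(n) {
  structure(list(
    subject = character(n), session = character(n), start = integer(n),
    augmented = logical(n),
    x = list(eda = matrix(0, n, 4L), hr = matrix(0, n, 4L),
             temp = matrix(0, n, 4L), face = array(0, c(n, 4L, 6L))),
    m1 = matrix("other", n, 4L), m2 = array(0, c(n, 4L, 6L)),
    mask_m1 = matrix(0L, n, 4L), mask_m2 = matrix(0L, n, 4L)
  ), class = "window_set")
}

#' Attach per-frame loss masks to windows
#'
#' A frame is masked (mask 0) for Method I when its majority-vote label is
#' `other`, and for Method II when its target distribution is the all-zero
#' vector.  Masked frames stay in the input sequences — only the loss
#' ignores them — so signal data is never altered.
#'
#' @param windows A `window_set`.
#' @return The `window_set` with `mask_m1` and `mask_m2` set.
#' @export
build_masks <- function(windows) {
  windows$mask_m1 <- matrix(as.integer(windows$m1 != "other"),
                            nrow(windows$m1), 4L)
  tot <- apply(windows$m2, c(1L, 2L), sum)
  windows$mask_m2 <- matrix(as.integer(tot > 0), nrow(windows$m1), 4L)
  windows
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("Window set: %d windows (%d augmented) from %d session(s)\n",
              length(x$start), sum(x$augmented),
              length(unique(x$session))))
  cat(sprintf("  valid frames: method I %d / %d, method II %d / %d\n",
              sum(x$mask_m1), length(x$mask_m1),
              sum(x$mask_m2), length(x$mask_m2)))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) length(ws$start)

#' Subset a window set
#'
#' @param ws A `window_set`.
#' @param i Logical or integer index over windows.
#' @return The subsetted `window_set`.
#' @export
windows_subset <- function(ws, i) {
  out <- ws
  out$subject <- ws$subject[i]; out$session <- ws$session[i]
  out$start <- ws$start[i]; out$augmented <- ws$augmented[i]
  out$x$eda <- ws$x$eda[i, , drop = FALSE]
  out$x$hr <- ws$x$hr[i, , drop = FALSE]
  out$x$temp <- ws$x$temp[i, , drop = FALSE]
  out$x$face <- ws$x$face[i, , , drop = FALSE]
  out$m1 <- ws$m1[i, , drop = FALSE]
  out$m2 <- ws$m2[i, , , drop = FALSE]
  out$mask_m1 <- ws$mask_m1[i, , drop = FALSE]
  out$mask_m2 <- ws$mask_m2[i, , drop = FALSE]
  out
}

#' Concatenate window sets
#'
#' @param ws_list List of `window_set` objects.
#' @return A single combined `window_set`.
#' @export
bind_windows <- function(ws_list) {
  ws_list <- Filter(function(w) n_windows(w) > 0L, ws_list)
  if (length(ws_list) == 0L) return(new_window_set(0L))
  out <- new_window_set(sum(vapply(ws_list, n_windows, integer(1))))
  out$subject <- unlist(lapply(ws_list, `[[`, "subject"))
  out$session <- unlist(lapply(ws_list, `[[`, "session"))
  out$start <- unlist(lapply(ws_list, `[[`, "start"))
  out$augmented <- unlist(lapply(ws_list, `[[`, "augmented"))
  out$x$eda <- do.call(rbind, lapply(ws_list, function(w) w$x$eda))
  out$x$hr <- do.call(rbind, lapply(ws_list, function(w) w$x$hr))
  out$x$temp <- do.call(rbind, lapply(ws_list, function(w) w$x$temp))
  out$x$face <- abind3(lapply(ws_list, function(w) w$x$face))
  out$m1 <- do.call(rbind, lapply(ws_list, `[[`, "m1"))
  out$m2 <- abind3(lapply(ws_list, `[[`, "m2"))
  out$mask_m1 <- do.call(rbind, lapply(ws_list, `[[`, "mask_m1"))
  out$mask_m2 <- do.call(rbind, lapply(ws_list, `[[`, "mask_m2"))
  out
}

# rbind for [n, 4, k] arrays
abind3 <- function(arrs) {
  ns <- vapply(arrs, function(a) dim(a)[1L], integer(1))
  out <- array(0, c(sum(ns), dim(arrs[[1L]])[2L], dim(arrs[[1L]])[3L]))
  at <- 0L
  for (a in arrs) {
    if (dim(a)[1L] > 0L) out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Dump windows to a columnar CSV for inspection
#'
#' One row per (window, frame) with signals, labels, distribution targets
#' and both masks.
#'
#' @param windows A `window_set`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  n <- n_windows(windows)
  rows <- lapply(seq_len(n), function(i) {
    m2 <- matrix(windows$m2[i, , ], 4L, 6L)
    colnames(m2) <- paste0("m2_", emotion_levels())
    cbind(data.frame(window = i, subject = windows$subject[i],
                     session = windows$session[i],
                     start = windows$start[i], frame = 1:4,
                     augmented = windows$augmented[i],
                     eda = windows$x$eda[i, ], hr = windows$x$hr[i, ],
                     temp = windows$x$temp[i, ], m1 = windows$m1[i, ],
                     mask_m1 = windows$mask_m1[i, ],
                     mask_m2 = windows$mask_m2[i, ]),
          as.data.frame(m2))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
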