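#' Read a wristband biosignal channel
#'
#' Parses the common wristband CSV dialect: line 1 is the recording start
#' time (UTC epoch seconds), line 2 the sample rate in Hz, and every
#' following line one sample.  EDA (microsiemens) and TEMP (degrees C) are
#' recorded at 4 Hz, HR (beats per minute) at 1 Hz; a file whose declared
#' rate does not match its kind is rejected.
#'
#' @param path Path to the channel file (e.g. `EDA.csv`).
#' @param kind One of `"EDA"`, `"TEMP"`, `"HR"`.
#' @return A `signal_channel`: list with `kind`, `start_epoch`, `rate`,
#'   `samples`.
#' @export
read_wristband_channel <- function(path, kind = c("EDA", "TEMP", "HR")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) {
    stop(sprintf("%s: need a start-epoch line, a rate line and >= 1 sample",
                 path))
  }
  start_epoch <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(start_epoch)) {
    stop(sprintf("%s line 1: malformed start epoch %s", path,
                 sQuote(lines[1L])))
  }
  rate <- suppressWarnings(as.numeric(lines[2L]))
  if (is.na(rate)) {
    stop(sprintf("%s line 2: malformed sample rate %s", path,
                 sQuote(lines[2L])))
  }
  expected <- expected_rate(kind)
  if (rate != expected) {
    stop(sprintf("%s line 2: %s declares rate %g, expected %g Hz",
                 path, kind, rate, expected))
  }
  samples <- suppressWarnings(as.numeric(lines[-(1:2)]))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1L] + 2L
    stop(sprintf("%s line %d: non-numeric sample %s", path, bad,
                 sQuote(lines[bad])))
  }
  new_signal_channel(kind, start_epoch, rate, samples)
}

expected_rate <- function(kind) if (kind == "HR") 1 else 4

new_signal_channel <- function(kind, start_epoch, rate, samples) {
  if (rate != expected_rate(kind)) {
    stop(sprintf("%s channels must be sampled at %g Hz", kind,
                 expected_rate(kind)))
  }
  stopifnot(length(samples) >= 1L, all(is.finite(samples)))
  structure(list(kind = kind, start_epoch = start_epoch, rate = rate,
                 samples = as.numeric(samples)),
            class = "signal_channel")
}

#' Resample a channel onto the 1 Hz session clock
#'
#' Second `t` of the session covers the half-open real-time interval
#' `[session_start + t, session_start + t + 1)`.  For 4 Hz channels the
#' per-second value is the arithmetic mean of the samples falling in that
#' bin; 1 Hz channels pass their native value through.  Seconds with no
#' samples are `NA` (missing).
#'
#' @param channel A `signal_channel`.
#' @param session_start Session anchor (UTC epoch seconds).
#' @param n_seconds Session length in seconds.
#' @return Numeric vector of length `n_seconds`, `NA` where no samples
#'   fall.
#' @export
bin_to_1hz <- function(channel, session_start, n_seconds) {
  ts <- channel$start_epoch + (seq_along(channel$samples) - 1L) / channel$rate
  bin <- floor(ts - session_start)
  keep <- bin >= 0 & bin < n_seconds
  if (!any(keep)) {
    stop(sprintf("channel %s has no overlap with the session interval",
                 channel$kind))
  }
  out <- rep(NA_real_, n_seconds)
  if (channel$rate == 1) {
    # native pass-through: the (single) sample of each covered second
    first <- !duplicated(bin[keep])
    out[bin[keep][first] + 1L] <- channel$samples[keep][first]
  } else {
    grp <- factor(bin[keep], levels = sort(unique(bin[keep])))
    m <- rowsum(channel$samples[keep], grp) / as.vector(table(grp))
    out[as.integer(levels(grp)) + 1L] <- m
  }
  out
}

# Native-rate view aligned on quarter-second bins of the session clock;
# length 4 * n_seconds, NA where no sample falls.
native_4hz <- function(channel, session_start, n_seconds) {
  stopifnot(channel$rate == 4)
  ts <- channel$start_epoch + (seq_along(channel$samples) - 1L) / channel$rate
  bin <- floor((ts - session_start) * 4)
  keep <- bin >= 0 & bin < 4 * n_seconds
  out <- rep(NA_real_, 4L * n_seconds)
  first <- !duplicated(bin[keep])
  out[bin[keep][first] + 1L] <- channel$samples[keep][first]
  out
}

#' Forward-fill a dominant-emotion event log to 1 Hz
#'
#' The facial-analysis tool logs only change points of the dominant
#' emotion, irregularly in time.  Each second receives the label of the
#' latest event at or before it; seconds before the first event (no face
#' seen yet) are `other`.
#'
#' @param events Data frame with columns `time_s` (strictly increasing
#'   offsets from session start) and `label`.
#' @param n_seconds Session length.
#' @return Character vector of per-second labels.
#' @export
forward_fill_face <- function(events, n_seconds) {
  if (is.null(events) || nrow(events) == 0L) {
    return(rep("other", n_seconds))
  }
  if (is.unsorted(events$time_s, strictly = TRUE)) {
    stop("face events must be strictly increasing in time")
  }
  assert_labels(events$label)
  idx <- findInterval(seq_len(n_seconds) - 1L, events$time_s)
  out <- rep("other", n_seconds)
  out[idx > 0L] <- as.character(events$label)[idx[idx > 0L]]
  normalize_vote(out)
}

#' Read a facial dominant-emotion event log
#'
#' CSV with columns `time_s` and `dominant_emotion`.
#'
#' @param path File path.
#' @return Data frame with `time_s`, `label`.
#' @export
read_face_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "dominant_emotion") %in% names(df))) {
    stop(path, ": expected columns time_s, dominant_emotion")
  }
  data.frame(time_s = as.numeric(df$time_s),
             label = assert_labels(df$dominant_emotion),
             stringsAsFactors = FALSE)
}

#' Read per-second annotator votes
#'
#' BORIS-style export: CSV with columns `time_s`, `annotator_id`,
#' `behavior`, one row per (second, annotator) on which that annotator
#' selected an emotion.  Seconds with no row for an annotator are that
#' annotator's `other` (no emotion selected).
#'
#' @param path File path.
#' @param n_seconds Session length.
#' @return An `n_seconds x 3` character matrix of votes, columns ordered
#'   by annotator id.
#' @export
read_annotations <- function(path, n_seconds) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "annotator_id", "behavior") %in% names(df))) {
    stop(path, ": expected columns time_s, annotator_id, behavior")
  }
  votes_from_annotations(df, n_seconds)
}

votes_from_annotations <- function(df, n_seconds) {
  ann <- sort(unique(as.character(df$annotator_id)))
  if (length(ann) > 3L) {
    stop("expected at most 3 annotators, found ", length(ann))
  }
  if (length(ann) < 3L) ann <- c(ann, paste0(".absent", seq_len(3L - length(ann))))
  votes <- matrix("other", n_seconds, 3L, dimnames = list(NULL, ann))
  if (nrow(df) > 0L) {
    assert_labels(df$behavior)
    sec <- as.integer(df$time_s)
    keep <- sec >= 0L & sec < n_seconds
    votes[cbind(sec[keep] + 1L,
                match(as.character(df$annotator_id)[keep], ann))] <-
      as.character(df$behavior)[keep]
  }
  votes
}

#' Align all streams of one session on a common 1 Hz clock
#'
#' Anchors the wristband channels (absolute epochs from their metadata),
#' the facial event log and the three annotation tracks (session-relative
#' seconds) on the session start, and produces the co-sampled timeline:
#' per-second EDA/HR/TEMP (missing where a channel has no samples), the
#' forward-filled facial label, the majority-vote label and the
#' proportional distribution, plus the retained native 4 Hz EDA/TEMP
#' arrays used by the balancing stage.  The timeline ends at the earliest
#' end of any biosignal stream (never exceeding `duration`); channels
#' starting late are carried as missing for their uncovered leading
#' seconds.
#'
#' @param channels Named list with elements `eda`, `temp`, `hr`
#'   (`signal_channel`s).
#' @param events Face event log (data frame `time_s`, `label`), or `NULL`.
#' @param votes `n x 3` character vote matrix (see [read_annotations()]).
#' @param session_start Session anchor, UTC epoch seconds.
#' @param duration Nominal session duration in seconds.
#' @param subject,session Identifiers.
#' @return A `session_timeline` object.
#' @export
align_session <- function(channels, events, votes, session_start, duration,
                          subject = "s1", session = subject) {
  stopifnot(all(c("eda", "temp", "hr") %in% names(channels)))
  ends <- vapply(channels, function(ch) {
    ch$start_epoch + length(ch$samples) / ch$rate - session_start
  }, numeric(1))
  n_seconds <- floor(min(duration, ends))
  if (n_seconds <= 0L) {
    stop("empty intersection of stream coverage; offending stream: ",
         names(channels)[which.min(ends)])
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (ch$start_epoch >= session_start + n_seconds) {
      stop("empty intersection of stream coverage; offending stream: ", nm)
    }
  }
  votes <- votes[seq_len(min(nrow(votes), n_seconds)), , drop = FALSE]
  if (nrow(votes) < n_seconds) {
    votes <- rbind(votes, matrix("other", n_seconds - nrow(votes), 3L))
  }
  votes <- matrix(normalize_vote(votes), n_seconds, 3L)
  m2 <- method2_distribution(votes)
  if (!is.matrix(m2)) m2 <- matrix(m2, 1L, 6L)
  tl <- structure(list(
    subject = subject,
    session = session,
    start_epoch = session_start,
    n_seconds = as.integer(n_seconds),
    eda = bin_to_1hz(channels$eda, session_start, n_seconds),
    temp = bin_to_1hz(channels$temp, session_start, n_seconds),
    hr = bin_to_1hz(channels$hr, session_start, n_seconds),
    face = forward_fill_face(events, n_seconds),
    votes = votes,
    m1 = method1_label(votes),
    m2 = m2,
    eda_native = native_4hz(channels$eda, session_start, n_seconds),
    temp_native = native_4hz(channels$temp, session_start, n_seconds),
    standardization = NULL
  ), class = "session_timeline")
  validate_timeline(tl)
  tl
}

validate_timeline <- function(tl) {
  n <- tl$n_seconds
  stopifnot(
    length(tl$eda) == n, length(tl$temp) == n, length(tl$hr) == n,
    length(tl$face) == n, nrow(tl$votes) == n, length(tl$m1) == n,
    nrow(tl$m2) == n, ncol(tl$m2) == 6L,
    length(tl$eda_native) == 4L * n, length(tl$temp_native) == 4L * n
  )
  invisible(tl)
}

#' @export
print.session_timeline <- function(x, ...) {
  cat(sprintf("Session timeline %s (subject %s): %d s%s\n", x$session,
              x$subject, x$n_seconds,
              if (!is.null(x$standardization)) ", standardized" else ""))
  miss <- vapply(x[c("eda", "hr", "temp")], function(v) sum(is.na(v)),
                 numeric(1))
  cat(sprintf("  missing seconds: EDA %d, HR %d, TEMP %d\n",
              miss[1], miss[3], miss[2]))
  cat("  majority labels: ")
  print(table(x$m1))
  invisible(x)
}

#' Per-second frame table of a timeline
#'
#' Convenience view for inspection and round-trip tests: one row per
#' second with signals, facial label, majority label and the distribution
#' columns.
#'
#' @param tl A `session_timeline`.
#' @return A data frame with `n_seconds` rows.
#' @export
timeline_frames <- function(tl) {
  out <- data.frame(session = tl$session, subject = tl$subject,
                    second = seq_len(tl$n_seconds) - 1L,
                    eda = tl$eda, hr = tl$hr, temp = tl$temp,
                    face = tl$face, m1 = tl$m1, stringsAsFactors = FALSE)
  m2 <- tl$m2
  colnames(m2) <- paste0("m2_", emotion_levels())
  cbind(out, as.data.frame(m2))
}
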