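#' Synthetic session generator configuration
#'
#' All knobs of the synthetic cohort simulator, which emulates the data
#' structure of wristband-plus-video therapy sessions: a latent per-second
#' emotion track with geometric dwell times, three imperfect annotators,
#' a facial-analysis change-point event log with detection gaps, and
#' emotion-conditioned biosignals at native rates (EDA/TEMP 4 Hz, HR
#' 1 Hz).  The default label distribution is heavily skewed toward
#' `happy` and `other` (about 45% / 35%, minority emotions 4% each),
#' qualitatively mirroring the strongly imbalanced label distributions of
#' real child-therapy recordings.
#'
#' Per-emotion effect profiles (in canonical emotion order): `eda_amp` is
#' the amplitude in microsiemens of an exponentially decaying phasic bump
#' added at each episode onset (time constant `eda_tau` seconds);
#' `hr_offset` an additive heart-rate offset in bpm while the emotion is
#' active; `temp_target` a skin-temperature setpoint offset in degrees C
#' toward which the signal drifts at relative rate `temp_rate` (1/s).
#' The `other` state carries no effect.  Channel noise is AR(1) with
#' coefficient `ar_phi` and innovation standard deviation `ar_sd`.
#'
#' @param n_subjects Number of subjects (one session each).
#' @param session_seconds Session length in seconds.
#' @param stationary Named 7-vector of stationary state probabilities over
#'   the six emotions plus `other`; must sum to 1.
#' @param mean_dwell Mean emotional-episode duration in seconds.
#' @param agreement Probability that an annotator's vote equals the latent
#'   state.
#' @param contempt_rate Probability that a confused vote is `contempt`
#'   (remaining confusion mass is uniform over the other non-latent
#'   labels); the default `1/7` makes confusion uniform over all 7
#'   non-latent labels.
#' @param face_detect Per-second probability that a face is detected.
#' @param face_confusion Probability that a detected face is perceived as
#'   a uniformly random non-latent label.
#' @param eda_amp,hr_offset,temp_target Length-6 per-emotion effect
#'   profiles (canonical order).
#' @param eda_tau,temp_rate Phasic decay constant (s) and temperature
#'   drift rate (1/s).
#' @param eda_base,hr_base,temp_base Length-2 subject baseline ranges
#'   (uniform draws).
#' @param ar_phi,ar_sd Named (eda, hr, temp) AR(1) coefficients and
#'   innovation SDs.
#' @param shuffle_effect_labels If `TRUE`, biosignals are generated from a
#'   seeded permutation of the latent track while labels keep the original
#'   track — a label-permutation null in which signals carry no emotion
#'   information.
#' @param start_epoch UTC epoch of the first session.
#' @param seed Master seed; every draw derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_subjects = 12L,
    session_seconds = 600L,
    stationary = c(happy = 0.45, sad = 0.04, scared = 0.04,
                   disgusted = 0.04, surprised = 0.04, angry = 0.04,
                   other = 0.35),
    mean_dwell = 8,
    agreement = 0.8,
    contempt_rate = 1 / 7,
    face_detect = 0.85,
    face_confusion = 0.1,
    eda_amp = c(0.3, 0.6, 1, 1.5, 2, 2.5),
    hr_offset = c(5, -5, 10, -10, 15, -15),
    temp_target = c(0.3, -0.3, 0.6, -0.6, 1, -1),
    eda_tau = 3,
    temp_rate = 0.05,
    eda_base = c(1, 8),
    hr_base = c(70, 110),
    temp_base = c(31, 34),
    ar_phi = c(eda = 0.9, hr = 0.7, temp = 0.95),
    ar_sd = c(eda = 0.05, hr = 1, temp = 0.03),
    shuffle_effect_labels = FALSE,
    start_epoch = 1.6e9,
    seed = 1L) {
  states <- c(emotion_levels(), "other")
  stationary <- stationary[states]
  stopifnot(!anyNA(stationary), abs(sum(stationary) - 1) < 1e-8,
            all(stationary >= 0), agreement >= 0, agreement <= 1,
            contempt_rate >= 0, contempt_rate <= 1,
            face_detect >= 0, face_detect <= 1,
            length(eda_amp) == 6L, length(hr_offset) == 6L,
            length(temp_target) == 6L)
  cfg <- list(n_subjects = as.integer(n_subjects),
              session_seconds = as.integer(session_seconds),
              stationary = stationary, mean_dwell = mean_dwell,
              agreement = agreement, contempt_rate = contempt_rate,
              face_detect = face_detect, face_confusion = face_confusion,
              eda_amp = stats::setNames(eda_amp, emotion_levels()),
              hr_offset = stats::setNames(hr_offset, emotion_levels()),
              temp_target = stats::setNames(temp_target, emotion_levels()),
              eda_tau = eda_tau, temp_rate = temp_rate,
              eda_base = eda_base, hr_base = hr_base, temp_base = temp_base,
              ar_phi = ar_phi, ar_sd = ar_sd,
              shuffle_effect_labels = isTRUE(shuffle_effect_labels),
              start_epoch = start_epoch, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Preset configurations for synthetic experiments
#'
#' `recovery_config()` is the idealized parameter-recovery setting:
#' perfect annotators (`agreement = 1`, no contempt), perfect face
#' detection, strongly separated per-emotion effect profiles on every
#' channel, low noise, and a moderately skewed latent distribution (happy
#' 30%, other 20%, minorities 10% each) over 12 subjects x 600 s.  The
#' EDA phasic decay is episode-scale (`eda_tau = 10` s) so the amplitude
#' profile stays informative across a whole emotional episode — the
#' meaning of a "strong" planted EDA effect at 1 Hz.
#'
#' `complementary_config()` splits class information across modalities: the
#' EDA phasic amplitude separates sad from scared, skin temperature
#' separates disgusted from surprised, heart rate separates happy from
#' angry, and the face stream is absent (detection 0) — no single modality
#' can solve the 6-class task, so fusion must integrate them.
#'
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
recovery_config <- function(...) {
  defaults <- list(
    n_subjects = 12L, session_seconds = 600L,
    stationary = c(happy = 0.3, sad = 0.1, scared = 0.1, disgusted = 0.1,
                   surprised = 0.1, angry = 0.1, other = 0.2),
    agreement = 1, contempt_rate = 0,
    face_detect = 1, face_confusion = 0,
    eda_amp = c(0.5, 1, 2, 3, 4, 5),
    eda_tau = 10,
    hr_offset = c(10, -10, 25, -25, 40, -40),
    temp_target = c(0.5, -0.5, 1.5, -1.5, 3, -3),
    temp_rate = 0.1,
    ar_sd = c(eda = 0.02, hr = 0.5, temp = 0.02))
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

#' @rdname recovery_config
#' @export
complementary_config <- function(...) {
  defaults <- list(
    n_subjects = 9L, session_seconds = 400L,
    stationary = c(happy = 0.18, sad = 0.144, scared = 0.144,
                   disgusted = 0.144, surprised = 0.144, angry = 0.144,
                   other = 0.1),
    agreement = 1, contempt_rate = 0,
    face_detect = 0, face_confusion = 0,
    eda_amp = c(0, 4, 1.5, 0, 0, 0),       # separates sad vs scared
    hr_offset = c(25, 0, 0, 0, 0, -25),    # separates happy vs angry
    temp_target = c(0, 0, 0, 2, -2, 0),    # separates disgusted vs surprised
    temp_rate = 0.15,
    ar_sd = c(eda = 0.02, hr = 0.5, temp = 0.02))
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

#' Simulate a latent per-second emotion track
#'
#' Semi-Markov chain over the six emotions plus `other`: episode dwell
#' times are geometric, the next state is drawn from the stationary law
#' excluding the current state.  The per-state mean dwell is
#' `mean_dwell / (1 - pi_state)`, which exactly compensates the
#' exclude-current embedded chain so that long-run state frequencies
#' converge to the configured stationary distribution.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Character vector of length `session_seconds`.
#' @export
simulate_latent <- function(config, seed = config$seed) {
  set.seed(seed)
  states <- names(config$stationary)
  pi <- config$stationary
  n <- config$session_seconds
  if (any(pi >= 1 - 1e-12)) {
    return(rep(states[which.max(pi)], n))
  }
  out <- character(0)
  cur <- sample(states, 1L, prob = pi)
  while (length(out) < n) {
    m <- config$mean_dwell / (1 - pi[[cur]])
    dwell <- stats::rgeom(1L, prob = min(1, 1 / m)) + 1L
    out <- c(out, rep(cur, dwell))
    nxt <- pi; nxt[cur] <- 0
    cur <- sample(states, 1L, prob = nxt)
  }
  out[seq_len(n)]
}

#' Simulate three annotator vote tracks
#'
#' Each annotator votes the latent state with probability `agreement`;
#' otherwise the vote is a confusion draw: `contempt` with probability
#' `contempt_rate`, else uniform over the remaining non-latent labels.
#' Annotators are independent given the latent track.
#'
#' @param latent Latent track from [simulate_latent()].
#' @param config A [generator_config()].
#' @param seed Integer seed (each annotator derives its own stream).
#' @return An `n x 3` character vote matrix.
#' @export
simulate_annotators <- function(latent, config, seed = config$seed) {
  n <- length(latent)
  votes <- matrix("other", n, 3L)
  all_labels <- annotation_levels()
  for (a in 1:3) {
    set.seed(seed_mix(seed, 13L + a))
    agree <- stats::runif(n) < config$agreement
    votes[, a] <- latent
    for (t in which(!agree)) {
      if (stats::runif(1) < config$contempt_rate && latent[t] != "contempt") {
        votes[t, a] <- "contempt"
      } else {
        pool <- setdiff(all_labels, c(latent[t], "contempt"))
        votes[t, a] <- sample(pool, 1L)
      }
    }
  }
  votes
}

#' Simulate a facial dominant-emotion change-point log
#'
#' Per second, a face is detected with probability `face_detect`; when
#' detected, the perceived label is the latent state, confused with
#' probability `face_confusion` into a uniformly random other label (over
#' the six emotions plus `other`).  The log records only change points of
#' the perceived stream; undetected stretches emit no events, which the
#' forward-fill bridging reproduces downstream.
#'
#' @inheritParams simulate_annotators
#' @return Data frame `time_s`, `label` with strictly increasing times.
#' @export
simulate_face_log <- function(latent, config, seed = config$seed) {
  set.seed(seed_mix(seed, 17L))
  n <- length(latent)
  labels7 <- c(emotion_levels(), "other")
  times <- integer(0); labs <- character(0)
  last <- NA_character_
  for (t in seq_len(n)) {
    if (stats::runif(1) >= config$face_detect) next
    perceived <- latent[t]
    if (config$face_confusion > 0 &&
        stats::runif(1) < config$face_confusion) {
      perceived <- sample(setdiff(labels7, latent[t]), 1L)
    }
    if (is.na(last) || perceived != last) {
      times <- c(times, t - 1L)
      labs <- c(labs, perceived)
      last <- perceived
    }
  }
  data.frame(time_s = as.numeric(times), label = labs,
             stringsAsFactors = FALSE)
}

# derive a distinct, valid 32-bit seed from (seed, stream)
seed_mix <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483629)
}

ar1_noise <- function(n, phi, sd) {
  e <- stats::rnorm(n, 0, sd)
  stats::filter(e, phi, method = "recursive") |> as.numeric()
}

#' Simulate emotion-conditioned biosignal channels
#'
#' Generates the three wristband channels at native rates from a latent
#' track: EDA (4 Hz) as subject baseline plus an exponentially decaying
#' phasic bump at each episode onset plus AR(1) noise; HR (1 Hz) as
#' baseline plus the active emotion's additive offset plus AR(1) noise;
#' TEMP (4 Hz) as a first-order drift toward the active emotion's setpoint
#' plus AR(1) noise.  The `other` state carries no effect.
#'
#' @inheritParams simulate_annotators
#' @param start_epoch Channel start time (UTC epoch seconds).
#' @return Named list of `signal_channel`s: `eda`, `temp`, `hr`.
#' @export
simulate_biosignals <- function(latent, config, seed = config$seed,
                                start_epoch = config$start_epoch) {
  set.seed(seed_mix(seed, 19L))
  n <- length(latent)
  eda_base <- stats::runif(1, config$eda_base[1], config$eda_base[2])
  hr_base <- stats::runif(1, config$hr_base[1], config$hr_base[2])
  temp_base <- stats::runif(1, config$temp_base[1], config$temp_base[2])
  eff <- function(profile, s) ifelse(s == "other", 0, profile[s])
  lat4 <- rep(latent, each = 4L)

  # EDA: phasic bumps at episode onsets, decaying with time constant tau
  eda <- rep(eda_base, 4L * n)
  onsets <- which(latent != c("", latent[-n]) & latent != "other")
  tq <- (seq_len(4L * n) - 1L) / 4
  for (o in onsets) {
    amp <- config$eda_amp[[latent[o]]]
    if (amp == 0) next
    t0 <- o - 1L
    idx <- which(tq >= t0)
    eda[idx] <- eda[idx] + amp * exp(-(tq[idx] - t0) / config$eda_tau)
  }
  eda <- eda + ar1_noise(4L * n, config$ar_phi[["eda"]],
                         config$ar_sd[["eda"]])

  # HR: additive per-emotion offset
  hr <- hr_base + eff(config$hr_offset, latent) +
    ar1_noise(n, config$ar_phi[["hr"]], config$ar_sd[["hr"]])

  # TEMP: first-order drift toward the active setpoint
  temp <- numeric(4L * n)
  cur <- temp_base
  dt <- 0.25
  for (k in seq_len(4L * n)) {
    target <- temp_base + eff(config$temp_target, lat4[k])
    cur <- cur + config$temp_rate * dt * (target - cur)
    temp[k] <- cur
  }
  temp <- temp + ar1_noise(4L * n, config$ar_phi[["temp"]],
                           config$ar_sd[["temp"]])

  list(eda = new_signal_channel("EDA", start_epoch, 4, eda),
       temp = new_signal_channel("TEMP", start_epoch, 4, temp),
       hr = new_signal_channel("HR", start_epoch, 1, hr))
}

#' Simulate one complete session
#'
#' Draws the latent track, the three annotator tracks, the facial event
#' log and the biosignal channels for one subject.  Under
#' `shuffle_effect_labels` the biosignals are generated from a seeded
#' permutation of the latent track (label-permutation null).
#'
#' @param config A [generator_config()].
#' @param subject Subject identifier.
#' @param seed Integer seed for this session.
#' @param start_epoch Session start (UTC epoch seconds).
#' @return A `synthetic_session` list: identifiers, `latent`, `votes`,
#'   `face_events`, `channels`, `duration`.
#' @export
simulate_session <- function(config, subject = "s01", seed = config$seed,
                             start_epoch = config$start_epoch) {
  latent <- simulate_latent(config, seed)
  votes <- simulate_annotators(latent, config, seed)
  face <- simulate_face_log(latent, config, seed)
  bio_latent <- latent
  if (config$shuffle_effect_labels) {
    set.seed(seed_mix(seed, 23L))
    bio_latent <- sample(latent)
  }
  channels <- simulate_biosignals(bio_latent, config, seed,
                                  start_epoch = start_epoch)
  structure(list(subject = subject, session = subject,
                 start_epoch = start_epoch,
                 duration = config$session_seconds,
                 latent = latent, votes = votes, face_events = face,
                 channels = channels, seed = seed, config = config),
            class = "synthetic_session")
}

#' Simulate a cohort of sessions
#'
#' One session per subject; per-session seeds are drawn reproducibly from
#' the master seed.
#'
#' @param config A [generator_config()].
#' @return List of `synthetic_session` objects.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 10L, config$n_subjects)
  lapply(seq_len(config$n_subjects), function(i) {
    simulate_session(config, subject = sprintf("s%02d", i),
                     seed = seeds[i],
                     start_epoch = config$start_epoch + (i - 1L) * 1e5)
  })
}

#' Align a synthetic session into a timeline
#'
#' Runs the ingest alignment on the simulated streams, producing the same
#' `session_timeline` that reading a written bundle would.
#'
#' @param session A `synthetic_session`.
#' @return A `session_timeline`.
#' @export
session_to_timeline <- function(session) {
  align_session(session$channels, session$face_events, session$votes,
                session$start_epoch, session$duration,
                subject = session$subject, session = session$session)
}

#' Write a session bundle to disk
#'
#' Emits the on-disk formats the ingest module consumes: `EDA.csv`,
#' `TEMP.csv`, `HR.csv` in the wristband dialect (start epoch, rate, then
#' samples, full double precision), `face_events.csv`, a combined
#' BORIS-style `annotations.csv` (`other` votes are absent rows), and a
#' `manifest.json` holding identifiers, anchors and the ground-truth
#' latent track.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  for (nm in c("eda", "temp", "hr")) {
    ch <- session$channels[[nm]]
    writeLines(c(sprintf("%.6f", ch$start_epoch),
                 sprintf("%.6f", ch$rate),
                 sprintf("%.17g", ch$samples)),
               file.path(dir, paste0(ch$kind, ".csv")))
  }
  utils::write.csv(
    data.frame(time_s = session$face_events$time_s,
               dominant_emotion = session$face_events$label),
    file.path(dir, "face_events.csv"), row.names = FALSE)
  votes <- session$votes
  rows <- which(votes != "other", arr.ind = TRUE)
  ann <- data.frame(time_s = rows[, 1L] - 1L,
                    annotator_id = paste0("a", rows[, 2L]),
                    behavior = votes[rows])
  ann <- ann[order(ann$time_s, ann$annotator_id), ]
  utils::write.csv(ann, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(subject = session$subject, session = session$session,
         start_epoch = session$start_epoch, duration = session$duration,
         seed = session$seed, latent = session$latent),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session bundle from disk
#'
#' Counterpart of [write_session_bundle()]: parses the wristband channel
#' files, the face event log and the annotation export, and aligns them
#' into a `session_timeline` using the manifest's anchors.  The manifest
#' (including the ground-truth latent track) is attached as the
#' `"manifest"` attribute.
#'
#' @param dir Bundle directory.
#' @return A `session_timeline`.
#' @export
read_session_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  channels <- list(
    eda = read_wristband_channel(file.path(dir, "EDA.csv"), "EDA"),
    temp = read_wristband_channel(file.path(dir, "TEMP.csv"), "TEMP"),
    hr = read_wristband_channel(file.path(dir, "HR.csv"), "HR"))
  events <- read_face_log(file.path(dir, "face_events.csv"))
  votes <- read_annotations(file.path(dir, "annotations.csv"),
                            man$duration)
  tl <- align_session(channels, events, votes, man$start_epoch,
                      man$duration, subject = man$subject,
                      session = man$session)
  attr(tl, "manifest") <- man
  tl
}

#' Write a full synthetic cohort to disk
#'
#' One bundle directory per session plus a cohort manifest CSV.
#'
#' @param config A [generator_config()].
#' @param dir Output directory.
#' @return Data frame of session directories, invisibly.
#' @export
write_cohort <- function(config, dir) {
  sessions <- simulate_cohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- data.frame(subject = vapply(sessions, `[[`, "", "subject"),
                     dir = file.path(dir, vapply(sessions, `[[`, "",
                                                 "subject")))
  for (i in seq_along(sessions)) {
    write_session_bundle(sessions[[i]], info$dir[i])
  }
  utils::write.csv(info, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(info)
}
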