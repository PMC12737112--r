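test_that("latent tracks are seeded, degenerate-safe and stationary", {
  cfg <- generator_config(session_seconds = 100L)
  expect_identical(simulate_latent(cfg, 5L), simulate_latent(cfg, 5L))
  expect_false(identical(simulate_latent(cfg, 5L), simulate_latent(cfg, 6L)))

  cfg1 <- generator_config(
    stationary = c(happy = 1, sad = 0, scared = 0, disgusted = 0,
                   surprised = 0, angry = 0, other = 0),
    session_seconds = 50L)
  expect_identical(simulate_latent(cfg1, 1L), rep("happy", 50))

  # empirical frequencies approach the stationary law; the tolerance
  # reflects the episode-level (not per-second) effective sample size
  cfg2 <- generator_config(session_seconds = 10000L)
  tr <- simulate_latent(cfg2, 11L)
  freq <- table(factor(tr, levels = names(cfg2$stationary))) / length(tr)
  expect_lt(max(abs(as.vector(freq) - cfg2$stationary)), 0.04)
  # dwell structure: mean episode length close to the configured mean
  runs <- rle(tr)
  expect_gt(mean(runs$lengths), cfg2$mean_dwell * 0.7)
})

test_that("annotator noise follows the agreement model", {
  cfg <- generator_config(agreement = 1, contempt_rate = 0,
                          session_seconds = 200L)
  lat <- simulate_latent(cfg, 3L)
  v <- simulate_annotators(lat, cfg, 3L)
  expect_identical(method1_label(v), lat)

  cfg2 <- generator_config(agreement = 0.8, session_seconds = 10000L)
  lat2 <- simulate_latent(cfg2, 4L)
  v2 <- simulate_annotators(lat2, cfg2, 4L)
  # under uniform confusion over 7 labels: P(agree) = a^2 + (1 - a)^2 / 7
  expected <- 0.8^2 + 0.2^2 / 7
  pair <- c(mean(v2[, 1] == v2[, 2]), mean(v2[, 1] == v2[, 3]),
            mean(v2[, 2] == v2[, 3]))
  expect_lt(max(abs(pair - expected)), 0.02)
  # contempt shows up at the configured rate among confused votes
  expect_gt(sum(v2 == "contempt"), 0)
  expect_identical(simulate_annotators(lat2, cfg2, 4L), v2)
})

test_that("the face log records change points and honors detection gaps", {
  cfg <- generator_config(face_detect = 1, face_confusion = 0,
                          session_seconds = 300L)
  lat <- simulate_latent(cfg, 6L)
  log <- simulate_face_log(lat, cfg, 6L)
  expect_identical(forward_fill_face(log, 300L), lat)
  expect_true(all(diff(log$time_s) > 0))
  # no detection, no events
  cfg0 <- generator_config(face_detect = 0, session_seconds = 50L)
  expect_equal(nrow(simulate_face_log(simulate_latent(cfg0, 1L), cfg0, 1L)),
               0)
})

test_that("biosignals realize the configured effect profiles exactly", {
  base <- list(eda_base = c(3, 3), hr_base = c(80, 80),
               temp_base = c(33, 33))
  cfg <- do.call(generator_config, c(list(
    session_seconds = 120L,
    ar_sd = c(eda = 0, hr = 0, temp = 0),
    eda_amp = rep(0, 6), hr_offset = rep(0, 6),
    temp_target = rep(0, 6)), base))
  lat <- simulate_latent(cfg, 2L)
  ch <- simulate_biosignals(lat, cfg, 2L)
  expect_equal(ch$eda$samples, rep(3, 480))
  expect_equal(ch$hr$samples, rep(80, 120))
  expect_equal(ch$temp$samples, rep(33, 480))

  # additive HR offset: +10 bpm during sad, exactly
  cfg2 <- do.call(generator_config, c(list(
    session_seconds = 200L,
    ar_sd = c(eda = 0, hr = 0, temp = 0),
    eda_amp = rep(0, 6), hr_offset = c(0, 10, 0, 0, 0, 0),
    temp_target = rep(0, 6)), base))
  lat2 <- simulate_latent(cfg2, 7L)
  ch2 <- simulate_biosignals(lat2, cfg2, 7L)
  expect_equal(ch2$hr$samples, 80 + 10 * (lat2 == "sad"))

  # phasic EDA bump decays from each onset with time constant tau
  cfg3 <- do.call(generator_config, c(list(
    session_seconds = 60L, mean_dwell = 30,
    stationary = c(happy = 0.5, sad = 0.1, scared = 0.1, disgusted = 0.1,
                   surprised = 0.1, angry = 0.1, other = 0),
    ar_sd = c(eda = 0, hr = 0, temp = 0),
    eda_amp = c(2, 2, 2, 2, 2, 2), hr_offset = rep(0, 6),
    temp_target = rep(0, 6)), base))
  lat3 <- simulate_latent(cfg3, 8L)
  ch3 <- simulate_biosignals(lat3, cfg3, 8L)
  onset <- which(lat3 != c("", lat3[-length(lat3)]) & lat3 != "other")[1]
  k <- 4 * (onset - 1) + 1
  expect_gt(ch3$eda$samples[k], 3 + 1.9)   # bump lands at the onset
  # quarter-second decay factor exp(-0.25 / tau)
  expect_equal(ch3$eda$samples[k + 1] - 3,
               (ch3$eda$samples[k] - 3) * exp(-0.25 / cfg3$eda_tau),
               tolerance = 1e-9)
})

test_that("channel noise has the configured AR(1) autocorrelation", {
  cfg <- do.call(generator_config, list(
    session_seconds = 10000L,
    eda_amp = rep(0, 6), hr_offset = rep(0, 6), temp_target = rep(0, 6),
    ar_phi = c(eda = 0.8, hr = 0.6, temp = 0.9),
    ar_sd = c(eda = 0.05, hr = 1, temp = 0.03)))
  lat <- simulate_latent(cfg, 9L)
  ch <- simulate_biosignals(lat, cfg, 9L)
  resid <- ch$hr$samples - mean(ch$hr$samples)
  rho <- stats::cor(resid[-1], resid[-length(resid)])
  expect_lt(abs(rho - 0.6), 0.05)
  reda <- ch$eda$samples - mean(ch$eda$samples)
  expect_lt(abs(stats::cor(reda[-1], reda[-length(reda)]) - 0.8), 0.05)
})

test_that("cohort simulation and bundle writing are reproducible", {
  cfg <- generator_config(n_subjects = 3L, session_seconds = 30L, seed = 5L)
  ses1 <- simulate_cohort(cfg)
  ses2 <- simulate_cohort(cfg)
  expect_identical(lapply(ses1, `[[`, "latent"),
                   lapply(ses2, `[[`, "latent"))
  expect_equal(length(ses1), 3)
  # distinct subjects get distinct tracks
  expect_false(identical(ses1[[1]]$latent, ses1[[2]]$latent))

  dir <- tempfile()
  info <- write_cohort(cfg, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_equal(nrow(info), 3)
  tl <- read_session_bundle(info$dir[1])
  expect_identical(attr(tl, "manifest")$latent, ses1[[1]]$latent)
})

test_that("the label-permutation null decouples signals from labels", {
  cfg <- recovery_config(n_subjects = 1L, session_seconds = 200L,
                         shuffle_effect_labels = TRUE)
  ses <- simulate_session(cfg, seed = 10L)
  # labels keep the original latent track
  expect_identical(method1_label(ses$votes), ses$latent)
  # but HR no longer follows it: the strong offsets land elsewhere
  cfg_ref <- recovery_config(n_subjects = 1L, session_seconds = 200L)
  ses_ref <- simulate_session(cfg_ref, seed = 10L)
  expect_identical(ses_ref$latent, ses$latent)
  expect_false(identical(ses_ref$channels$hr$samples,
                         ses$channels$hr$samples))
})
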