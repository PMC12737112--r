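# Shared fixture builders; everything is generated in code.

# A session timeline built directly from given arrays (already "aligned");
# native arrays default to each 1 Hz value repeated 4x.
make_timeline <- function(eda, hr = eda, temp = eda,
                          face = rep("happy", length(eda)),
                          votes = NULL, subject = "s1", session = subject,
                          eda_native = rep(eda, each = 4L),
                          temp_native = rep(temp, each = 4L)) {
  n <- length(eda)
  if (is.null(votes)) votes <- matrix("happy", n, 3L)
  votes <- matrix(normalize_vote(votes), n, 3L)
  m2 <- method2_distribution(votes)
  if (!is.matrix(m2)) m2 <- matrix(m2, 1L, 6L)
  structure(list(subject = subject, session = session,
                 start_epoch = 0, n_seconds = as.integer(n),
                 eda = as.numeric(eda), temp = as.numeric(temp),
                 hr = as.numeric(hr), face = face, votes = votes,
                 m1 = method1_label(votes), m2 = m2,
                 eda_native = as.numeric(eda_native),
                 temp_native = as.numeric(temp_native),
                 standardization = NULL),
            class = "session_timeline")
}

# A standardized timeline with seeded noise signals and given per-second
# majority votes (all three annotators unanimous).
make_labeled_timeline <- function(labels, subject = "s1", seed = 1L) {
  set.seed(seed)
  n <- length(labels)
  tl <- make_timeline(eda = rnorm(n), hr = rnorm(n), temp = rnorm(n),
                      face = ifelse(labels == "other", "other", labels),
                      votes = matrix(labels, n, 3L), subject = subject)
  tl$eda_native <- rep(tl$eda, each = 4L) + rnorm(4L * n, 0, 0.01)
  tl$temp_native <- rep(tl$temp, each = 4L) + rnorm(4L * n, 0, 0.01)
  tl
}

# A wristband-dialect channel file written to a temp path.
write_channel_file <- function(samples, rate, start_epoch = 1000,
                               path = tempfile(fileext = ".csv")) {
  writeLines(c(sprintf("%.6f", start_epoch), sprintf("%.6f", rate),
               sprintf("%.17g", samples)), path)
  path
}

# Constant-valued channels covering [start, start + n_seconds).
make_channels <- function(n_seconds, start_epoch = 1000,
                          eda = 2, temp = 33, hr = 90,
                          hr_start = start_epoch) {
  list(eda = emofuse:::new_signal_channel("EDA", start_epoch, 4,
                                          rep(eda, 4 * n_seconds)),
       temp = emofuse:::new_signal_channel("TEMP", start_epoch, 4,
                                           rep(temp, 4 * n_seconds)),
       hr = emofuse:::new_signal_channel(
         "HR", hr_start, 1,
         rep(hr, n_seconds - (hr_start - start_epoch))))
}

# Brute-force oracles for the two label-aggregation schemes.
oracle_method1 <- function(votes) {
  votes <- normalize_vote(votes)
  tab <- table(votes)
  top <- names(tab)[tab >= 2]
  if (length(top) == 0) "other" else top[1]
}

oracle_method2 <- function(votes) {
  votes <- normalize_vote(votes)
  vapply(emotion_levels(), function(e) sum(votes == e) / 3, numeric(1))
}

all_norm_triples <- function() {
  lv <- c(emotion_levels(), "contempt", "other")
  as.matrix(expand.grid(lv, lv, lv, stringsAsFactors = FALSE))
}
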