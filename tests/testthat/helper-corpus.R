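# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

make_recording <- function(waveform, fs = 22050, baby_id = "X", sex = "F",
                           condition = "discomfort", sequence_id = "test") {
  structure(list(waveform = waveform, sample_rate = fs, baby_id = baby_id,
                 sex = sex, condition = condition, sequence_id = sequence_id,
                 duration = length(waveform) / fs),
            class = "cry_recording")
}

sine_recording <- function(freq, dur = 2, fs = 22050, amp = 1) {
  t <- seq(0, dur, by = 1 / fs)
  make_recording(amp * sin(2 * pi * freq * t), fs)
}

# harmonic stack with 1/h rolloff (used for MPS pitch-localization checks)
stack_recording <- function(f0, dur = 1.5, fs = 22050, n_harm = 12) {
  t <- seq(0, dur, by = 1 / fs)
  x <- 0
  for (h in seq_len(n_harm)) {
    if (h * f0 < 0.45 * fs) x <- x + sin(2 * pi * h * f0 * t) / h
  }
  make_recording(x / max(abs(x)), fs)
}

test_profile <- function(...) {
  modifyList(list(baby_id = "T01", sex = "F", f0_mean = 350, f0_mod_depth = 40,
                  f0_mod_rate = 4, F1 = 1100, F2 = 3300, am_rate = 5,
                  am_depth = 0.35, jitter_sd = 8),
             list(...))
}

# small corpus shared by feature/space/classifier tests (~70 cries, 3 s)
small_corpus <- function() {
  fixture("small_corpus", function() {
    generate_corpus(generator_config(
      n_babies = 8, discomfort_count_range = c(5L, 6L),
      duration_mean_s = 3, duration_sd_s = 0.4, seed = 42L))
  })
}

small_mps <- function() {
  fixture("small_mps", function() corpus_mps(small_corpus()))
}

# independent cepstral pitch oracle: peak quefrency of the real cepstrum
cepstral_f0 <- function(recording, f0_min = 150, f0_max = 1200,
                        frame_s = 0.033, hop_s = 0.010) {
  x <- recording$waveform
  fs <- recording$sample_rate
  n <- round(frame_s * fs)
  starts <- seq(1L, length(x) - n + 1L, by = round(hop_s * fs))
  nfft <- 2^ceiling(log2(2 * n))
  q_lo <- max(2L, floor(fs / f0_max))
  q_hi <- ceiling(fs / f0_min)
  vapply(starts, function(s) {
    fr <- x[s:(s + n - 1)]
    fr <- (fr - mean(fr)) * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
    if (sd(fr) < 1e-10) return(NA_real_)
    ceps <- Re(fft(log(Mod(fft(c(fr, numeric(nfft - n))))^2 + 1e-12),
                   inverse = TRUE))
    q <- q_lo:q_hi
    fs / q[which.max(ceps[q + 1L])]
  }, numeric(1))
}
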