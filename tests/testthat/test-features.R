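# The 22 predefined acoustic features.

test_that("amplitude envelope is flat for steady tones, zero in silence, and tracks AM", {
  env <- amplitude_envelope(sine_recording(440))
  mid <- env$amplitude[200:(nrow(env) - 200)]
  expect_lt(sd(mid) / mean(mid), 0.05)

  fs <- 22050
  burst <- c(numeric(fs / 2), sin(2 * pi * 500 * seq(0, 0.5, by = 1 / fs)),
             numeric(fs / 2))
  envb <- amplitude_envelope(make_recording(burst))
  silent <- envb$amplitude[envb$time < 0.4]
  expect_lt(max(silent), 0.05 * max(envb$amplitude))

  t <- seq(0, 2, by = 1 / fs)
  am <- make_recording(sin(2 * pi * 1000 * t) * (0.5 + 0.5 * sin(2 * pi * 4 * t)))
  enva <- amplitude_envelope(am)
  e <- enva$amplitude - mean(enva$amplitude)
  spec <- Mod(fft(e))[2:40]
  freqs <- (1:39) / (length(e) / 1000)
  expect_lt(abs(freqs[which.max(spec)] - 4), 0.3)
})

test_that("envelope summaries match closed forms on simple inputs", {
  s <- summarize_envelope(rep(2.5, 100))
  expect_equal(s$env_mean, 2.5)
  expect_equal(s$env_sd, 0)
  expect_equal(s$env_rms, 2.5)
  expect_equal(s$env_max, 2.5)
  expect_equal(s$env_entropy, 1)      # uniform distribution over time

  sym <- summarize_envelope(rep(c(1, 2, 3), 4))   # symmetric value distribution
  expect_lt(abs(sym$env_skew), 1e-10)

  expect_error(summarize_envelope(numeric(50)), "zero")
  expect_error(summarize_envelope(1), "length")
})

test_that("spectral summaries behave as distributions over frequency", {
  tone <- power_spectrum_summary(sine_recording(400))
  expect_lt(abs(tone$Q1 - 400), 5)
  expect_lt(abs(tone$Q2 - 400), 5)
  expect_lt(abs(tone$Q3 - 400), 5)

  set.seed(31)
  noise <- power_spectrum_summary(make_recording(rnorm(22050)))
  expect_lt(abs(noise$Q2 - 5512) / 5512, 0.05)

  t <- seq(0, 2, by = 1 / 22050)
  two <- power_spectrum_summary(
    make_recording(sin(2 * pi * 300 * t) + sin(2 * pi * 900 * t)))
  expect_lt(abs(two$spec_mean - 600), 15)

  expect_error(power_spectrum_summary(make_recording(numeric(22050))), "silent")
})

test_that("pitch tracking: tones, noise, chirps, and band validation", {
  pt <- track_pitch(sine_recording(400))
  expect_true(all(abs(pt$f0[pt$voiced] - 400) < 2))
  expect_gt(mean(pt$saliency[pt$voiced]), 0.95)
  expect_true(all(pt$saliency >= 0 & pt$saliency <= 1))

  set.seed(77)
  sal_noise <- vapply(1:10, function(i) {
    mean(track_pitch(make_recording(rnorm(22050)))$saliency)
  }, numeric(1))
  expect_lt(mean(sal_noise), 0.3)

  fs <- 22050
  t <- seq(0, 2, by = 1 / fs)
  ph <- 2 * pi * cumsum(seq(300, 500, length.out = length(t))) / fs
  ptc <- track_pitch(make_recording(sin(ph)))
  f0c <- ptc$f0[ptc$voiced]
  expect_true(all(diff(f0c) > -5))       # monotone up to frame noise
  expect_lt(abs(f0c[1] - 300), 10)
  expect_lt(abs(f0c[length(f0c)] - 500), 10)

  expect_error(track_pitch(sine_recording(400), f0_min = 800, f0_max = 400),
               "f0_min")
  expect_error(track_pitch(sine_recording(400), f0_max = 9000), "quarter")
})

test_that("pitch tracker agrees with an independent cepstral oracle", {
  errs <- vapply(1:20, function(s) {
    prof <- test_profile(f0_mean = 280 + 15 * s, f0_mod_depth = 25, jitter_sd = 5)
    r <- synthesize_cry(prof, "discomfort", 2, seed = s)
    pt <- track_pitch(r)
    med_acf <- median(pt$f0[pt$voiced])
    ceps <- cepstral_f0(r)
    med_cep <- median(ceps, na.rm = TRUE)
    abs(med_acf - med_cep) / med_cep
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("formant estimation recovers synthetic resonances and tracks changes", {
  prof <- test_profile(F1 = 1100, F2 = 3300)
  f <- estimate_formants(synthesize_cry(prof, "discomfort", 3, seed = 5))
  expect_lt(abs(f$F1 - 1100) / 1100, 0.15)
  expect_lt(abs(f$F2 - 3300) / 3300, 0.15)
  expect_lt(f$F1, f$F2)

  moved <- estimate_formants(
    synthesize_cry(test_profile(F1 = 1500, F2 = 3000), "discomfort", 3, seed = 5))
  expect_gt(moved$F1, f$F1)        # F1 moved up
  expect_lt(moved$F2, f$F2)        # F2 moved down

  expect_error(estimate_formants(sine_recording(400)), "formant")
})

test_that("the PAF vector has exactly 22 finite features plus a confidence flag", {
  r <- small_corpus()$recordings[[1]]
  pv <- paf_vector(r)
  expect_true(all(paf_feature_names() %in% names(pv)))
  expect_equal(length(paf_feature_names()), 22)
  expect_true(all(is.finite(unlist(pv[paf_feature_names()]))))
  expect_true(all(paf_subset10_names() %in% paf_feature_names()))
  expect_equal(length(paf_subset10_names()), 10)
  # ordering invariants
  expect_lte(pv$Q1, pv$Q2)
  expect_lte(pv$Q2, pv$Q3)
  expect_lte(pv$MinF0, pv$meanF0)
  expect_lte(pv$meanF0, pv$MaxF0)
  expect_gte(pv$cvF0, 0)
  expect_lt(pv$F1, pv$F2)
})

test_that("constant-pitch cries give near-zero pitch variation features", {
  prof <- test_profile(f0_mean = 400, f0_mod_depth = 0, jitter_sd = 0)
  r <- synthesize_cry(prof, "discomfort", 2, seed = 3, noise_floor_db = -70)
  pv <- paf_vector(r)
  expect_lt(pv$cvF0, 0.02)
  expect_lt(pv$MaxF0 - pv$MinF0, 0.05 * pv$meanF0)
})

test_that("scale-invariant features ignore amplitude; envelope stats scale linearly", {
  r <- small_corpus()$recordings[[2]]
  r_scaled <- r
  r_scaled$waveform <- r$waveform * 0.2
  a <- paf_vector(r)
  b <- paf_vector(r_scaled)
  invariant <- c("Q1", "Q2", "Q3", "meanF0", "MaxF0", "MinF0", "cvF0",
                 "mean_saliency", "F1", "F2", "spec_mean", "spec_sd",
                 "spec_skew", "spec_kurtosis", "spec_entropy")
  for (f in invariant) expect_equal(b[[f]], a[[f]], tolerance = 1e-6)
  for (f in c("env_mean", "env_sd", "env_rms", "env_max")) {
    expect_equal(b[[f]], 0.2 * a[[f]], tolerance = 1e-6)
  }
})

test_that("condition contrast model detects a true shift and is calibrated under the null", {
  simulate_table <- function(shift, seed) {
    set.seed(seed)
    n_babies <- 18
    rows <- do.call(rbind, lapply(seq_len(n_babies), function(b) {
      n_d <- 6; n_p <- 4
      baby_mean <- rnorm(1, 0, 2)
      data.frame(
        baby_id = sprintf("B%02d", b),
        sex = ifelse(b %% 2 == 0, "F", "M"),
        condition = c(rep("discomfort", n_d), rep("pain", n_p)),
        value = baby_mean + c(rnorm(n_d), rnorm(n_p, shift))
      )
    }))
    rows
  }
  null_z <- vapply(1:20, function(s) {
    fc <- feature_condition_contrast(simulate_table(0, s), "value")
    fc$coefficients$z[grepl("^condition", fc$coefficients$term) &
                        !grepl(":", fc$coefficients$term)]
  }, numeric(1))
  expect_gte(mean(abs(null_z) < 1.96), 0.9)

  power_p <- vapply(1:20, function(s) {
    fc <- feature_condition_contrast(simulate_table(2, s + 100), "value")
    i <- grepl("^condition", fc$coefficients$term) & !grepl(":", fc$coefficients$term)
    fc$coefficients$p[i]
  }, numeric(1))
  expect_gte(mean(power_p < 0.05), 0.8)

  tb <- simulate_table(0, 1)
  expect_error(feature_condition_contrast(tb[tb$condition == "discomfort", ],
                                          "value"), "condition")
})

test_that("pain condition lowers saliency and raises pitch variability in the corpus", {
  pafs <- fixture("small_pafs", function() paf_table(small_corpus()))
  sal <- feature_condition_contrast(pafs, "mean_saliency")
  expect_lt(sal$condition_effect, 0)
  cv <- feature_condition_contrast(pafs, "cvF0")
  expect_gt(cv$condition_effect, 0)
  expect_true(all(tidy(sal)$p > 0 & tidy(sal)$p <= 1))
  expect_error(feature_condition_contrast(pafs, "not_a_feature"), "unknown")
})
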