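# Predefined acoustic features (PAFs): 22 scalar descriptors per cry, built
# from the amplitude envelope (7), the power spectrum treated as a
# distribution over frequency (8), the autocorrelation pitch track (5), and
# linear-prediction formants (2).

#' Amplitude envelope of a recording
#'
#' Full-wave rectification followed by a zero-phase 20 Hz low-pass filter,
#' resampled to `env_rate` Hz.
#'
#' @param recording A `cry_recording` (or a list with `waveform` and
#'   `sample_rate`).
#' @param cutoff Low-pass cutoff in Hz.
#' @param env_rate Envelope sampling rate in Hz.
#' @return Tibble with columns `time` (s) and `amplitude` (>= 0), with the
#'   envelope rate stored in attribute `env_rate`.
#' @export
amplitude_envelope <- function(recording, cutoff = 20, env_rate = 1000) {
  x <- recording$waveform
  fs <- recording$sample_rate
  env <- fft_lowpass(abs(x), fs, cutoff)
  env <- pmax(env, 0)
  t_in <- (seq_along(env) - 1) / fs
  t_out <- seq(0, t_in[length(t_in)], by = 1 / env_rate)
  out <- approx(t_in, env, xout = t_out)$y
  structure(tibble(time = t_out, amplitude = out), env_rate = env_rate)
}

#' Summary statistics of an amplitude envelope
#'
#' The seven envelope descriptors: mean, SD, skewness, kurtosis, entropy
#' (Shannon entropy of the envelope normalized to a distribution over time,
#' scaled by `log(n)` to `[0, 1]`), RMS, and maximum.
#'
#' @param envelope Output of [amplitude_envelope()], or a non-negative
#'   numeric vector.
#' @return One-row tibble: `env_mean`, `env_sd`, `env_skew`, `env_kurtosis`,
#'   `env_entropy`, `env_rms`, `env_max`.
#' @export
summarize_envelope <- function(envelope) {
  e <- if (is.data.frame(envelope)) envelope$amplitude else envelope
  if (length(e) < 2) abort("envelope must have length >= 2")
  if (all(e == 0)) abort("cannot summarize an all-zero envelope")
  m <- mean(e); s <- sd(e)
  skew <- if (s > 0) mean((e - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((e - m)^4) / s^4 else 0
  tibble(
    env_mean = m, env_sd = s, env_skew = skew, env_kurtosis = kurt,
    env_entropy = norm_entropy(e / sum(e)),
    env_rms = sqrt(mean(e^2)), env_max = max(e)
  )
}

# Power spectral density on [0, Nyquist], Hann-windowed periodogram
# (zero-padded to a composite length for speed).
psd_estimate <- function(x, fs) {
  n0 <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n0 - 1) / (n0 - 1))
  n <- stats::nextn(n0)
  X <- fft(c((x - mean(x)) * w, numeric(n - n0)))
  half <- seq_len(floor(n / 2) + 1L)
  list(freq = (half - 1) * fs / n, power = Mod(X[half])^2)
}

#' Spectral summary statistics of a recording
#'
#' The normalized power spectral density is treated as a probability
#' distribution over frequency; reported are its mean, SD, skewness,
#' kurtosis, normalized entropy, and the 25/50/75% energy quantiles
#' (`Q1`, `Q2`, `Q3`, in Hz).
#'
#' @param recording A `cry_recording`.
#' @return One-row tibble: `spec_mean`, `spec_sd`, `spec_skew`,
#'   `spec_kurtosis`, `spec_entropy`, `Q1`, `Q2`, `Q3`.
#' @export
power_spectrum_summary <- function(recording) {
  x <- recording$waveform
  if (length(x) < 0.1 * recording$sample_rate) abort("recording shorter than 0.1 s")
  if (all(x == 0)) abort("cannot summarize a silent recording")
  ps <- psd_estimate(x, recording$sample_rate)
  p <- ps$power / sum(ps$power)
  mo <- dist_moments(ps$freq, p)
  qs <- dist_quantile(ps$freq, p, c(0.25, 0.5, 0.75))
  tibble(
    spec_mean = mo$mean, spec_sd = mo$sd, spec_skew = mo$skew,
    spec_kurtosis = mo$kurtosis, spec_entropy = norm_entropy(p),
    Q1 = qs[1], Q2 = qs[2], Q3 = qs[3]
  )
}

#' Autocorrelation pitch track with pitch saliency
#'
#' For each 33 ms frame (10 ms hop), the fundamental is the reciprocal of the
#' lag of the first prominent peak of the normalized autocorrelation within
#' the search band, refined by parabolic interpolation; pitch saliency is that
#' peak's amplitude relative to lag zero (length-bias corrected, clipped to
#' `[0, 1]`). Frames with saliency below `voicing_threshold` are marked
#' unvoiced.
#'
#' @param recording A `cry_recording`.
#' @param f0_min,f0_max Search band in Hz (`f0_max` must stay below half the
#'   Nyquist frequency).
#' @param frame_s Frame length in seconds.
#' @param hop_s Hop between frames in seconds.
#' @param voicing_threshold Saliency below which a frame is unvoiced.
#' @return Tibble with `time`, `f0` (NA where unvoiced), `saliency`, `voiced`.
#' @export
track_pitch <- function(recording, f0_min = 150, f0_max = 1200,
                        frame_s = 0.033, hop_s = 0.010,
                        voicing_threshold = 0.5) {
  fs <- recording$sample_rate
  if (f0_min >= f0_max) abort("f0_min must be below f0_max")
  if (f0_max >= fs / 4) abort("f0_max must be below a quarter of the sample rate")
  x <- recording$waveform
  n_frame <- round(frame_s * fs)
  hop <- round(hop_s * fs)
  starts <- seq(1L, length(x) - n_frame + 1L, by = hop)
  if (length(starts) == 0) abort("recording shorter than one analysis frame")
  lag_min <- max(2L, floor(fs / f0_max))
  lag_max <- min(n_frame - 2L, ceiling(fs / f0_min))
  nfft <- 2^ceiling(log2(n_frame + lag_max + 2L))
  # all frames at once: column-wise FFT autocorrelation
  idx <- outer(seq_len(n_frame) - 1L, starts, "+")
  frames <- matrix(x[idx], nrow = n_frame)
  frames <- sweep(frames, 2, colMeans(frames))
  Fm <- mvfft(rbind(frames, matrix(0, nfft - n_frame, ncol(frames))))
  ac <- Re(mvfft(Fm * Conj(Fm), inverse = TRUE)) / nfft
  n_frames <- ncol(ac)
  band <- (lag_min + 1L):(lag_max + 1L)     # ac is 1-indexed at lag 0
  lags <- 0:(lag_max + 1L)
  interp_freq <- function(r, lag0) {
    ym <- r[lag0]; yc <- r[lag0 + 1L]; yp <- r[lag0 + 2L]
    denom <- ym - 2 * yc + yp
    delta <- if (abs(denom) > 1e-12) 0.5 * (ym - yp) / denom else 0
    fs / (lag0 + max(min(delta, 0.5), -0.5))
  }
  # pass 1: all autocorrelation peaks per frame (candidate periods)
  cand <- vector("list", n_frames)
  for (j in seq_len(n_frames)) {
    a <- ac[, j]
    if (a[1] <= 0) next
    r <- a[1:(lag_max + 2L)] / a[1]
    # unbiased correction for the shrinking overlap at long lags, clamped at
    # 1 so a repeat at twice the period cannot outrank the period itself
    r <- pmin(r * n_frame / pmax(n_frame - lags, 1), 1)
    rb <- r[band]
    prev <- c(Inf, rb[-length(rb)])
    nxt <- c(rb[-1], Inf)
    pk <- which(rb > prev & rb >= nxt)
    if (length(pk) == 0) {
      cand[[j]] <- list(f = numeric(0), r = numeric(0),
                        best = max(0, min(1, max(rb))))
      next
    }
    f_pk <- vapply(band[pk] - 1L, function(l) interp_freq(r, l), numeric(1))
    cand[[j]] <- list(f = f_pk, r = pmax(0, pmin(1, rb[pk])), best = max(rb[pk]))
  }
  # initial choice: earliest peak nearly as high as the global one
  pick_first <- function(cc, margin = 0.9) {
    i <- which(cc$r >= margin * max(cc$r))[1]
    c(cc$f[i], cc$r[i])
  }
  f0 <- rep(NA_real_, n_frames)
  sal <- numeric(n_frames)
  for (j in seq_len(n_frames)) {
    cc <- cand[[j]]
    if (is.null(cc) || length(cc$f) == 0) {
      sal[j] <- if (is.null(cc)) 0 else cc$best
      next
    }
    p <- pick_first(cc)
    f0[j] <- p[1]; sal[j] <- p[2]
  }
  # pass 2: when one harmonic dominates a frame, every sub-lag peak is nearly
  # as high as the period's and pass 1 can lock onto a harmonic or a
  # subharmonic; re-snap such frames to the candidate nearest the track
  # median, which legitimate pitch modulation never strays this far from
  # the median comes from unambiguous frames only: those with a single
  # candidate within the 0.9 margin (harmonic-captured frames tie several)
  unambiguous <- vapply(cand, function(cc) {
    !is.null(cc) && length(cc$f) > 0 && sum(cc$r >= 0.9 * max(cc$r)) == 1L
  }, logical(1))
  strong <- which(!is.na(f0) & sal >= voicing_threshold & unambiguous)
  if (length(strong) < 5) strong <- which(!is.na(f0) & sal >= voicing_threshold)
  if (length(strong) >= 5) {
    f0_med <- stats::median(f0[strong])
    for (j in seq_len(n_frames)) {
      cc <- cand[[j]]
      if (is.null(cc) || length(cc$f) == 0 || is.na(f0[j])) next
      ratio <- f0[j] / f0_med
      if (ratio > 0.55 && ratio < 1.8) next
      ok <- which(cc$r >= 0.8 * max(cc$r) &
                    cc$f / f0_med > 0.55 & cc$f / f0_med < 1.8)
      if (length(ok) > 0) {
        i <- ok[which.min(abs(log(cc$f[ok] / f0_med)))]
        f0[j] <- cc$f[i]; sal[j] <- cc$r[i]
      }
    }
  }
  voiced <- !is.na(f0) & sal >= voicing_threshold
  f0[!voiced] <- NA_real_
  tibble(time = (starts - 1L + n_frame / 2) / fs, f0 = f0,
         saliency = sal, voiced = voiced)
}

#' Average frequencies of the first two formants
#'
#' Linear-prediction (Burg) analysis of order `order` on the recording
#' decimated to 10 kHz, per 33 ms voiced frame. Complex pole frequencies with
#' bandwidth below 500 Hz, lying above `max(400, 1.3 x median f0)` (so the
#' model cannot report the fundamental itself as a resonance), are the
#' candidates; per frame the lowest candidate and the next one at least
#' 600 Hz higher are taken as (F1, F2), and the per-frame values are combined
#' by the median, which is robust to frames whose poles lock onto individual
#' pitch harmonics. Infant formant estimation is intrinsically fragile; a
#' `confidence` field reports the fraction of voiced frames yielding a usable
#' pair.
#'
#' @param recording A `cry_recording`.
#' @param pitch Optional precomputed [track_pitch()] output.
#' @param order LPC order.
#' @return One-row tibble: `F1`, `F2` (Hz), `confidence` in `[0, 1]`.
#' @export
estimate_formants <- function(recording, pitch = NULL, order = 12L) {
  fs <- recording$sample_rate
  if (is.null(pitch)) pitch <- track_pitch(recording)
  if (!any(pitch$voiced)) abort("no voiced frames: cannot estimate formants")
  fs_d <- 10000
  x <- fft_lowpass(recording$waveform, fs, 4500)
  t_in <- (seq_along(x) - 1) / fs
  x <- approx(t_in, x, xout = seq(0, t_in[length(t_in)], by = 1 / fs_d))$y
  n_frame <- round(0.033 * fs_d)
  centers <- pitch$time[pitch$voiced]
  if (length(centers) > 60) {  # 60 frames are ample for a stable median
    centers <- centers[round(seq(1, length(centers), length.out = 60))]
  }
  voiced_t <- pitch$time[pitch$voiced]
  voiced_f0 <- pitch$f0[pitch$voiced]
  f0_at <- voiced_f0[vapply(centers, function(ct) which.min(abs(voiced_t - ct)),
                            integer(1))]
  min_freq <- max(400, 1.6 * stats::median(voiced_f0))
  pairs <- matrix(NA_real_, nrow = length(centers), ncol = 2)
  for (i in seq_along(centers)) {
    s <- round(centers[i] * fs_d - n_frame / 2)
    if (s < 1 || s + n_frame - 1 > length(x)) next
    fr <- x[s:(s + n_frame - 1)]
    fr <- fr - mean(fr)
    if (sd(fr) < 1e-9) next
    a <- tryCatch(stats::ar.burg(fr, aic = FALSE, order.max = order,
                                 demean = FALSE)$ar,
                  error = function(e) NULL)
    if (is.null(a) || length(a) == 0) next
    rts <- 1 / polyroot(c(1, -a))   # polynomial roots are inverse poles; invert
    rts <- rts[Im(rts) > 1e-8]
    freq <- Arg(rts) * fs_d / (2 * pi)
    bw <- -log(pmin(Mod(rts), 1 - 1e-9)) * fs_d / pi
    # broad poles are vocal-tract resonances; sharp poles sitting on a pitch
    # harmonic of this frame are source-locked and discarded (the resonance
    # stays put across frames while the harmonics sweep, so the median over
    # frames recovers it)
    harmonic_ratio <- freq / f0_at[i]
    on_harmonic <- abs(harmonic_ratio - round(harmonic_ratio)) < 0.12
    keep <- which(bw < 900 & !(bw < 120 & on_harmonic) &
                    freq > min_freq & freq < fs_d / 2 - 100)
    if (length(keep) < 2) next
    cand <- sort(freq[keep])
    f1 <- cand[1]
    f2 <- cand[cand > f1 + 600][1]  # resonances must be clearly separated
    if (is.na(f2)) next
    pairs[i, ] <- c(f1, f2)
  }
  ok <- stats::complete.cases(pairs)
  if (!any(ok)) abort("formant estimation failed on every voiced frame (no clear resonances)")
  F1 <- stats::median(pairs[ok, 1])
  F2 <- stats::median(pairs[ok, 2])
  # a genuine resonance carries power: reject pole pairs that sit in spectral
  # regions far below the peak (e.g. a pure tone has no formant structure)
  ps <- psd_estimate(x, fs_d)
  level <- function(f) {
    sel <- abs(ps$freq - f) < 150
    10 * log10(max(ps$power[sel]) / max(ps$power))
  }
  if (level(F1) < -55 || level(F2) < -55) {
    abort("no clear formant structure (estimated resonances carry negligible power)")
  }
  tibble(F1 = F1, F2 = F2, confidence = mean(ok))
}

#' The 22 predefined acoustic features of one cry
#'
#' Combines [summarize_envelope()], [power_spectrum_summary()],
#' fundamental-frequency statistics from [track_pitch()] (mean, max, min,
#' coefficient of variation over voiced frames, and mean saliency over all
#' frames), and [estimate_formants()].
#'
#' @param recording A `cry_recording`.
#' @param f0_min,f0_max Pitch search band (Hz).
#' @return One-row tibble with the 22 features plus `formant_confidence`.
#' @export
paf_vector <- function(recording, f0_min = 150, f0_max = 1200) {
  env <- summarize_envelope(amplitude_envelope(recording))
  spec <- power_spectrum_summary(recording)
  pt <- track_pitch(recording, f0_min = f0_min, f0_max = f0_max)
  f0v <- pt$f0[pt$voiced]
  if (length(f0v) == 0) {
    abort(paste0("no voiced frames in ", recording$sequence_id %||% "recording",
                 ": pitch features undefined"))
  }
  fmt <- estimate_formants(recording, pitch = pt)
  dplyr::bind_cols(
    env, spec,
    tibble(meanF0 = mean(f0v), MaxF0 = max(f0v), MinF0 = min(f0v),
           cvF0 = sd(f0v) / mean(f0v), mean_saliency = mean(pt$saliency)),
    tibble(F1 = fmt$F1, F2 = fmt$F2, formant_confidence = fmt$confidence)
  )
}

#' Names of the 22 features and of the 10-feature spectral subset
#' @rdname paf_vector
#' @export
paf_feature_names <- function() {
  c("env_mean", "env_sd", "env_skew", "env_kurtosis", "env_entropy",
    "env_rms", "env_max",
    "spec_mean", "spec_sd", "spec_skew", "spec_kurtosis", "spec_entropy",
    "Q1", "Q2", "Q3",
    "meanF0", "MaxF0", "MinF0", "cvF0", "mean_saliency", "F1", "F2")
}

#' @rdname paf_vector
#' @export
paf_subset10_names <- function() {
  c("Q1", "Q2", "Q3", "meanF0", "MaxF0", "MinF0", "cvF0",
    "mean_saliency", "F1", "F2")
}

#' Feature table for a whole corpus
#'
#' @param corpus A `cry_corpus`.
#' @param ... Passed to [paf_vector()].
#' @return Tibble: metadata columns followed by the 22 feature columns.
#' @export
paf_table <- function(corpus, ...) {
  stopifnot(inherits(corpus, "cry_corpus"))
  feats <- purrr::map(corpus$recordings, function(r) {
    tryCatch(paf_vector(r, ...), error = function(e) {
      abort(paste0("feature extraction failed for ", r$sequence_id, ": ",
                   conditionMessage(e)))
    })
  })
  dplyr::bind_cols(corpus$metadata, dplyr::bind_rows(feats))
}

#' Mixed-effects condition contrast for one acoustic feature
#'
#' Fits `feature ~ sex * condition + (1 | baby_id)` by REML and reports Wald
#' z statistics and two-sided normal p-values for the fixed effects, plus the
#' condition effect with a +/- 2 SE interval.
#'
#' @param feature_table Output of [paf_table()] (or any tibble with
#'   `baby_id`, `sex`, `condition` and the feature column).
#' @param feature_name Name of the feature column to model.
#' @return A `feature_contrast` object; see [tidy.feature_contrast()].
#' @export
feature_condition_contrast <- function(feature_table, feature_name) {
  if (!feature_name %in% names(feature_table)) {
    abort(paste0("unknown feature: ", feature_name))
  }
  if (length(unique(feature_table$condition)) < 2) {
    abort("both conditions must be present")
  }
  df <- data.frame(
    y = feature_table[[feature_name]],
    sex = factor(feature_table$sex),
    condition = factor(feature_table$condition,
                       levels = c("discomfort", "pain")),
    baby_id = factor(feature_table$baby_id)
  )
  fit <- lme4::lmer(y ~ sex * condition + (1 | baby_id), data = df, REML = TRUE)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ci <- which(grepl("^condition", names(est)) & !grepl(":", names(est)))
  structure(list(
    feature_name = feature_name,
    coefficients = tibble(term = names(est), estimate = unname(est),
                          std_error = unname(se), z = unname(z), p = unname(p)),
    random_intercept_var = vc$vcov[vc$grp == "baby_id"][1],
    condition_effect = unname(est[ci]),
    condition_effect_2se = 2 * unname(se[ci]),
    model = fit
  ), class = "feature_contrast")
}

#' @export
print.feature_contrast <- function(x, ...) {
  cat(sprintf("<feature_contrast> %s: condition effect %.4g +/- %.4g [2SE]\n",
              x$feature_name, x$condition_effect, x$condition_effect_2se))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a feature contrast
#'
#' @param x A `feature_contrast`.
#' @param ... Unused.
#' @return Tibble of fixed-effect terms with estimates, SEs, Wald z and p.
#' @export
tidy.feature_contrast <- function(x, ...) x$coefficients

#' @export
glance.feature_contrast <- function(x, ...) {
  tibble(feature = x$feature_name,
         condition_effect = x$condition_effect,
         condition_effect_2se = x$condition_effect_2se,
         condition_z = x$coefficients$z[grepl("^condition", x$coefficients$term) &
                                          !grepl(":", x$coefficients$term)],
         random_intercept_var = x$random_intercept_var)
}
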