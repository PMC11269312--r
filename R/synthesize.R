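# Synthetic infant-cry corpus generator.
#
# Each baby gets an idiosyncratic source (mean fundamental, pitch-modulation
# depth, amplitude-modulation rate) and filter (two vocal-tract resonances).
# A cry sequence is a train of expiratory bursts: a harmonic stack with
# time-varying f0 (sinusoidal modulation + jitter), shaped by the resonances,
# amplitude-modulated, and mixed with formant-shaped noise at a tonality-
# controlled ratio. The pain condition widens pitch modulation, deepens
# amplitude modulation, raises the noise mix (lower pitch saliency), and pulls
# each baby's parameters toward the population mean (between-baby shrinkage).

#' Pain-condition effect parameters
#'
#' Controls how the pain condition transforms a baby's cry relative to
#' discomfort: a multiplier on pitch-modulation depth (wider pitch range), a
#' drop in the tonal fraction of the source (lower pitch saliency), an
#' additive increase in amplitude-modulation depth, and a convex shrinkage of
#' the baby's identity parameters toward the population mean.
#'
#' @param pitch_range_multiplier Multiplier (>= 1) on f0 modulation depth.
#' @param saliency_drop Fraction in `[0, 1]` by which the tonal (periodic)
#'   energy fraction of the source is reduced.
#' @param am_depth_increase Additive increase in amplitude-modulation depth,
#'   in `[0, 1]`.
#' @param shrinkage Weight in `[0, 1]` pulling identity parameters toward the
#'   population mean before pain synthesis (0 = none, 1 = full convergence).
#' @return A list of class `pain_effect`.
#' @export
pain_effect <- function(pitch_range_multiplier = 2,
                        saliency_drop = 0.12,
                        am_depth_increase = 0.3,
                        shrinkage = 0.4) {
  stopifnot(pitch_range_multiplier >= 1,
            saliency_drop >= 0, saliency_drop <= 1,
            am_depth_increase >= 0, am_depth_increase <= 1,
            shrinkage >= 0, shrinkage <= 1)
  structure(list(pitch_range_multiplier = pitch_range_multiplier,
                 saliency_drop = saliency_drop,
                 am_depth_increase = am_depth_increase,
                 shrinkage = shrinkage),
            class = "pain_effect")
}

#' Configuration for the synthetic cry corpus generator
#'
#' Defaults emulate the study corpus: 22 babies, 4 pain sequences per baby,
#' 2-19 discomfort sequences per baby, sequence durations around 6.3 +/- 1.1 s.
#'
#' @param n_babies Number of babies.
#' @param pain_per_baby Pain cry sequences per baby.
#' @param discomfort_count_range Length-2 integer range; per-baby discomfort
#'   counts are drawn uniformly within it.
#' @param duration_mean_s,duration_sd_s Sequence duration distribution in
#'   seconds (normal, truncated at 2 s).
#' @param sample_rate Sampling rate in Hz (>= 8000).
#' @param identity_dispersion Named list of between-baby SDs for the identity
#'   parameters: `f0_mean`, `f0_mod_depth`, `F1`, `F2`, `am_rate`.
#' @param within_baby_frac Within-baby, across-sequence parameter variability
#'   as a fraction of the between-baby dispersion. Real cries vary from one
#'   sequence to the next; without this the identity signature would be
#'   implausibly clean.
#' @param pain_effect A [pain_effect()] object.
#' @param noise_floor_db Additive background-noise floor in dB relative to
#'   peak.
#' @param seed Integer seed; the corpus is a pure function of the config.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_babies = 22L,
                             pain_per_baby = 4L,
                             discomfort_count_range = c(2L, 19L),
                             duration_mean_s = 6.3,
                             duration_sd_s = 1.1,
                             sample_rate = 22050,
                             identity_dispersion = list(
                               f0_mean = 80, f0_mod_depth = 25,
                               F1 = 150, F2 = 300, am_rate = 1.5),
                             within_baby_frac = 0.5,
                             pain_effect = cryid::pain_effect(),
                             noise_floor_db = -45,
                             seed = 1L) {
  disp <- identity_dispersion
  needed <- c("f0_mean", "f0_mod_depth", "F1", "F2", "am_rate")
  if (!all(needed %in% names(disp))) {
    abort(paste0("identity_dispersion must name: ",
                 paste(needed, collapse = ", ")))
  }
  if (any(unlist(disp[needed]) < 0)) abort("identity dispersion SDs must be >= 0")
  stopifnot(within_baby_frac >= 0,
            n_babies >= 1, pain_per_baby >= 1,
            length(discomfort_count_range) == 2,
            discomfort_count_range[1] >= 1,
            discomfort_count_range[1] <= discomfort_count_range[2],
            duration_sd_s >= 0, sample_rate >= 8000)
  if (!inherits(pain_effect, "pain_effect")) abort("pain_effect must be a pain_effect() object")
  structure(list(
    n_babies = as.integer(n_babies),
    pain_per_baby = as.integer(pain_per_baby),
    discomfort_count_range = as.integer(discomfort_count_range),
    duration_mean_s = duration_mean_s,
    duration_sd_s = duration_sd_s,
    sample_rate = sample_rate,
    identity_dispersion = disp[needed],
    within_baby_frac = within_baby_frac,
    pain_effect = pain_effect,
    noise_floor_db = noise_floor_db,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Population-level parameter centers. Identity varies around these with the
# configured dispersions; f0_mean is kept inside the plausible infant band.
.profile_centers <- list(
  f0_mean = 425, f0_mean_range = c(250, 600),
  f0_mod_depth = 40, f0_mod_depth_range = c(5, 150),
  f0_mod_rate = 4,
  F1 = 1100, F1_range = c(700, 1600),
  F2 = 3300, F2_range = c(2400, 4200),
  am_rate = 5, am_rate_range = c(2, 10),
  am_depth = 0.35,
  jitter_sd = 8,
  tonal_fraction = 0.95
)

#' Draw per-baby vocal profiles
#'
#' @param config A [generator_config()].
#' @return Tibble with one row per baby: `baby_id`, `sex`, `f0_mean`,
#'   `f0_mod_depth`, `f0_mod_rate`, `F1`, `F2`, `am_rate`, `am_depth`,
#'   `jitter_sd`. Deterministic given the config seed; sexes balanced to
#'   within one.
#' @export
sample_baby_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_babies
  ctr <- .profile_centers
  d <- config$identity_dispersion
  with_seed(config$seed, {
    prof <- tibble(
      baby_id = sprintf("B%02d", seq_len(n)),
      sex = rep_len(c("F", "M"), n),
      f0_mean = rnorm_trunc(n, ctr$f0_mean, d$f0_mean,
                            ctr$f0_mean_range[1], ctr$f0_mean_range[2]),
      f0_mod_depth = rnorm_trunc(n, ctr$f0_mod_depth, d$f0_mod_depth,
                                 ctr$f0_mod_depth_range[1], ctr$f0_mod_depth_range[2]),
      f0_mod_rate = rep(ctr$f0_mod_rate, n),
      F1 = rnorm_trunc(n, ctr$F1, d$F1, ctr$F1_range[1], ctr$F1_range[2]),
      F2 = rnorm_trunc(n, ctr$F2, d$F2, ctr$F2_range[1], ctr$F2_range[2]),
      am_rate = rnorm_trunc(n, ctr$am_rate, d$am_rate,
                            ctr$am_rate_range[1], ctr$am_rate_range[2]),
      am_depth = rep(ctr$am_depth, n),
      jitter_sd = rep(ctr$jitter_sd, n)
    )
    bad <- prof$F1 >= prof$F2
    if (any(bad)) {  # keep resonances ordered even under extreme dispersion
      mid <- (prof$F1[bad] + prof$F2[bad]) / 2
      prof$F1[bad] <- mid * 0.7
      prof$F2[bad] <- mid * 1.3
    }
    prof
  })
}

# Convexly pull identity parameters toward the population mean.
shrink_profile <- function(profile, pop_mean, w) {
  for (p in c("f0_mean", "f0_mod_depth", "F1", "F2", "am_rate")) {
    profile[[p]] <- (1 - w) * profile[[p]] + w * pop_mean[[p]]
  }
  profile
}

#' Peak-normalize a waveform
#'
#' Scales so the maximum absolute amplitude is exactly 1.
#'
#' @param waveform Numeric vector, not all zero.
#' @return Rescaled waveform.
#' @export
normalize_amplitude <- function(waveform) {
  peak <- max(abs(waveform))
  if (!is.finite(peak) || peak == 0) abort("cannot normalize a silent (all-zero) waveform")
  waveform / peak
}

# Smoothed Tukey (tapered cosine) window.
tukey_window <- function(n, alpha = 0.3) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / edge - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + edge) / edge)))
  w
}

# Combined magnitude response of the two vocal-tract resonances plus a small
# broadband base so the spectrum is nonzero between formants. Bandwidths are
# broad, as typical of infant vocal tracts; narrow resonances would let a
# single harmonic dominate the source, which infant cries do not show.
formant_gain <- function(f, F1, F2, bw1 = 500, bw2 = 600) {
  1 / (1 + ((f - F1) / (bw1 / 2))^2) +
    1 / (1 + ((f - F2) / (bw2 / 2))^2) + 0.05
}

# One expiratory burst (all RNG from the caller's stream). The harmonic stack
# is built with a 1/h rolloff and shaped by the vocal-tract response with a
# single zero-phase FFT filter; harmonics that would exceed 0.48 Nyquist at
# the pitch excursion maximum are dropped to avoid aliasing.
synth_burst <- function(profile, dur, fs, tonal_fraction, n_harmonics = 20L) {
  n <- max(8L, round(dur * fs))
  t <- (0:(n - 1)) / fs
  # slow jitter: coarse gaussian track sampled at 100 Hz, linearly interpolated
  n_knots <- max(3L, ceiling(dur * 100) + 1L)
  knots <- rnorm(n_knots, 0, profile$jitter_sd)
  jit <- approx(seq(0, dur, length.out = n_knots), knots, xout = t)$y
  phase0 <- runif(1, 0, 2 * pi)
  f0_t <- profile$f0_mean +
    profile$f0_mod_depth * sin(2 * pi * profile$f0_mod_rate * t + phase0) + jit
  f0_t <- pmin(pmax(f0_t, 80), fs / 4)
  phi <- 2 * pi * cumsum(f0_t) / fs
  h_max <- max(1L, min(n_harmonics, floor(0.48 * fs / max(f0_t))))
  harm <- numeric(n)
  for (h in seq_len(h_max)) harm <- harm + sin(h * phi) / h
  gain_fun <- function(f) formant_gain(f, profile$F1, profile$F2)
  harm <- fft_shape(harm, fs, gain_fun)
  harm <- harm / max(sd(harm), 1e-12)
  noise <- fft_shape(rnorm(n), fs, gain_fun)
  noise <- noise / max(sd(noise), 1e-12)
  tf <- min(max(tonal_fraction, 0), 1)
  x <- sqrt(tf) * harm + sqrt(1 - tf) * noise
  phase_am <- runif(1, 0, 2 * pi)
  am <- 1 - profile$am_depth * (0.5 + 0.5 * sin(2 * pi * profile$am_rate * t + phase_am))
  x * am * tukey_window(n, 0.3)
}

#' Synthesize one cry sequence
#'
#' Builds a cry as 2-6 expiratory bursts separated by 150-400 ms silences.
#' With `condition = "pain"` the [pain_effect()] transform is applied to the
#' profile's modulation parameters and source tonality (parameter-level
#' shrinkage toward the population mean is applied upstream, in
#' [generate_corpus()]). With a neutral effect (multiplier 1, drops 0) the two
#' conditions produce identical waveforms for the same seed.
#'
#' @param profile One row of [sample_baby_profiles()] (data frame or list).
#' @param condition `"discomfort"` or `"pain"`.
#' @param duration_s Sequence duration in seconds (> 0.5).
#' @param seed Integer seed for this cry.
#' @param sample_rate Sampling rate in Hz.
#' @param effect A [pain_effect()]; used only when `condition = "pain"`.
#' @param noise_floor_db Background-noise floor in dB re. peak.
#' @return A `cry_recording`: list with `waveform` (peak-normalized),
#'   `sample_rate`, `baby_id`, `sex`, `condition`, `sequence_id`, `duration`.
#' @export
synthesize_cry <- function(profile, condition = c("discomfort", "pain"),
                           duration_s, seed = 1L,
                           sample_rate = 22050,
                           effect = pain_effect(),
                           noise_floor_db = -45) {
  condition <- match.arg(condition)
  profile <- as.list(profile)
  if (duration_s <= 0.5) abort("duration_s must exceed 0.5 s")
  if (profile$f0_mean >= sample_rate / 4) {
    abort("f0_mean must be below sample_rate / 4")
  }
  tf <- .profile_centers$tonal_fraction
  if (condition == "pain") {
    profile$f0_mod_depth <- profile$f0_mod_depth * effect$pitch_range_multiplier
    profile$am_depth <- min(1, profile$am_depth + effect$am_depth_increase)
    tf <- tf * (1 - effect$saliency_drop)
  }
  fs <- sample_rate
  wav <- with_seed(seed, {
    n_max <- max(2L, min(6L, floor(duration_s / 1.0)))
    n_bursts <- if (n_max == 2L) 2L else sample(2:n_max, 1L)
    gaps <- runif(n_bursts - 1L, 0.15, 0.40)
    voiced <- duration_s - sum(gaps)
    if (voiced < 0.3 * n_bursts) {  # very short sequence: shrink the silences
      gaps <- gaps * max(duration_s - 0.3 * n_bursts, 0.1) / sum(gaps)
      voiced <- duration_s - sum(gaps)
    }
    prop <- runif(n_bursts, 0.6, 1.4)
    burst_dur <- voiced * prop / sum(prop)
    pieces <- vector("list", 2L * n_bursts - 1L)
    for (b in seq_len(n_bursts)) {
      pieces[[2L * b - 1L]] <- synth_burst(profile, burst_dur[b], fs, tf)
      if (b < n_bursts) pieces[[2L * b]] <- numeric(round(gaps[b] * fs))
    }
    x <- unlist(pieces)
    x + rnorm(length(x)) * 10^(noise_floor_db / 20)
  })
  structure(list(
    waveform = normalize_amplitude(wav),
    sample_rate = fs,
    baby_id = profile$baby_id %||% "B01",
    sex = profile$sex %||% "F",
    condition = condition,
    sequence_id = NA_character_,
    duration = length(wav) / fs
  ), class = "cry_recording")
}

#' @export
print.cry_recording <- function(x, ...) {
  cat(sprintf("<cry_recording> %s  baby %s (%s)  %s  %.2f s @ %g Hz\n",
              x$sequence_id %||% "", x$baby_id, x$sex, x$condition,
              x$duration, x$sample_rate))
  invisible(x)
}

#' Generate a full synthetic cry corpus
#'
#' Draws baby profiles, per-baby discomfort counts (uniform in the configured
#' range) plus the fixed number of pain sequences, and synthesizes every
#' sequence. Pain sequences are synthesized from profiles convexly shrunk
#' toward the population parameter mean with the configured shrinkage weight.
#' The whole corpus is a pure function of the config (including its seed).
#'
#' @param config A [generator_config()].
#' @return A `cry_corpus`: list with `recordings` (list of `cry_recording`),
#'   `metadata` (tibble: `baby_id`, `sex`, `condition`, `sequence_id`,
#'   `duration`), `profiles`, and `config`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  profiles <- sample_baby_profiles(config)
  pop_mean <- as.list(colMeans(profiles[, c("f0_mean", "f0_mod_depth",
                                            "F1", "F2", "am_rate")]))
  eff <- config$pain_effect
  plan <- with_seed(config$seed + 1L, {
    rng <- config$discomfort_count_range[1]:config$discomfort_count_range[2]
    n_disc <- rng[sample.int(length(rng), config$n_babies, replace = TRUE)]
    purrr::map2(seq_len(config$n_babies), n_disc, function(b, nd) {
      tibble(baby = b,
             condition = c(rep("discomfort", nd), rep("pain", config$pain_per_baby)))
    }) %>% bind_rows() %>%
      mutate(duration = rnorm_trunc(dplyr::n(), config$duration_mean_s,
                                    config$duration_sd_s, lower = 2))
  })
  id_params <- c("f0_mean", "f0_mod_depth", "F1", "F2", "am_rate")
  # within-baby, across-sequence parameter wobble
  deltas <- with_seed(config$seed + 3L, {
    sds <- unlist(config$identity_dispersion[id_params]) * config$within_baby_frac
    matrix(rnorm(nrow(plan) * length(id_params), 0, rep(sds, each = nrow(plan))),
           nrow = nrow(plan), dimnames = list(NULL, id_params))
  })
  seeds <- derive_seeds(config$seed + 2L, nrow(plan))
  recs <- vector("list", nrow(plan))
  seq_counter <- integer(config$n_babies)
  for (i in seq_len(nrow(plan))) {
    b <- plan$baby[i]
    prof <- as.list(profiles[b, ])
    cond <- plan$condition[i]
    if (cond == "pain" && eff$shrinkage > 0) {
      prof <- shrink_profile(prof, pop_mean, eff$shrinkage)
    }
    for (p in id_params) prof[[p]] <- prof[[p]] + deltas[i, p]
    prof$f0_mean <- min(max(prof$f0_mean, 150), config$sample_rate / 4 - 1)
    prof$f0_mod_depth <- max(prof$f0_mod_depth, 0)
    prof$am_rate <- min(max(prof$am_rate, 1), 12)
    if (prof$F1 >= prof$F2 - 300) {  # keep resonances ordered and separated
      mid <- (prof$F1 + prof$F2) / 2
      prof$F1 <- mid - 200
      prof$F2 <- mid + 200
    }
    rec <- synthesize_cry(prof, cond, plan$duration[i], seed = seeds[i],
                          sample_rate = config$sample_rate, effect = eff,
                          noise_floor_db = config$noise_floor_db)
    seq_counter[b] <- seq_counter[b] + 1L
    rec$sequence_id <- sprintf("%s_%s_%02d", prof$baby_id, substr(cond, 1, 4),
                               seq_counter[b])
    recs[[i]] <- rec
  }
  metadata <- tibble(
    baby_id = purrr::map_chr(recs, "baby_id"),
    sex = purrr::map_chr(recs, "sex"),
    condition = purrr::map_chr(recs, "condition"),
    sequence_id = purrr::map_chr(recs, "sequence_id"),
    duration = purrr::map_dbl(recs, "duration")
  )
  structure(list(recordings = recs, metadata = metadata,
                 profiles = profiles, config = config),
            class = "cry_corpus")
}

#' @export
print.cry_corpus <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<cry_corpus> %d babies, %d sequences (%d discomfort, %d pain), %.1f Hz\n",
              length(unique(m$baby_id)), nrow(m),
              sum(m$condition == "discomfort"), sum(m$condition == "pain"),
              x$config$sample_rate))
  invisible(x)
}

#' Write a corpus to disk as WAV files plus a metadata CSV
#'
#' @param corpus A `cry_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "cry_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- corpus$metadata
  meta$wav_path <- paste0(meta$sequence_id, ".wav")
  for (i in seq_along(corpus$recordings)) {
    r <- corpus$recordings[[i]]
    write_wav(r$waveform, r$sample_rate, file.path(dir, meta$wav_path[i]))
  }
  out <- meta[, c("baby_id", "sex", "condition", "sequence_id", "wav_path", "duration")]
  names(out)[names(out) == "duration"] <- "duration_s"
  utils::write.csv(out, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a corpus from a directory of WAV files and a metadata CSV
#'
#' Every metadata row must reference a readable mono WAV; condition labels are
#' validated against `discomfort`/`pain` and sex against `F`/`M`.
#'
#' @param dir Directory written by [write_corpus()] (or with the same layout).
#' @return A `cry_corpus` (without generator profiles/config).
#' @export
load_corpus <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) abort(paste0("no metadata.csv in ", dir))
  meta <- as_tibble(utils::read.csv(meta_path, stringsAsFactors = FALSE))
  if ("duration_s" %in% names(meta)) {
    names(meta)[names(meta) == "duration_s"] <- "duration"
  }
  bad_cond <- setdiff(unique(meta$condition), c("discomfort", "pain"))
  if (length(bad_cond) > 0) {
    abort(paste0("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
                 "; allowed: discomfort, pain"))
  }
  bad_sex <- setdiff(unique(meta$sex), c("F", "M"))
  if (length(bad_sex) > 0) {
    abort(paste0("unknown sex label(s): ", paste(bad_sex, collapse = ", ")))
  }
  recs <- purrr::pmap(meta, function(baby_id, sex, condition, sequence_id,
                                     wav_path, duration, ...) {
    path <- file.path(dir, wav_path)
    if (!file.exists(path)) abort(paste0("missing WAV file: ", wav_path))
    w <- read_wav(path)
    if (w$n_channels != 1L) abort(paste0("stereo input not supported: ", wav_path))
    structure(list(waveform = w$waveform, sample_rate = w$sample_rate,
                   baby_id = baby_id, sex = sex, condition = condition,
                   sequence_id = sequence_id,
                   duration = length(w$waveform) / w$sample_rate),
              class = "cry_recording")
  })
  metadata <- meta %>%
    select("baby_id", "sex", "condition", "sequence_id", "duration")
  structure(list(recordings = recs, metadata = metadata,
                 profiles = NULL, config = NULL),
            class = "cry_corpus")
}
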