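# Modulation power spectrum (MPS): the amplitude of the 2D Fourier transform
# of the normalized log spectrogram, averaged over 1 s Gaussian windows. Axes
# are temporal modulation (Hz, signed) and spectral modulation (cycles/kHz,
# non-negative half kept; the map is Hermitian-symmetric). A harmonic stack
# with fundamental f0 concentrates spectral-modulation energy near 1/f0 (in
# kHz^-1), so pitch appears as a ridge at e.g. ~3 cyc/kHz for 330 Hz.

#' Narrow-band log spectrogram
#'
#' Gaussian-windowed short-time analysis with the window width specified in
#' the frequency domain: `freq_width_hz` = 6 standard deviations of the
#' spectral Gaussian (default 50 Hz). Log power is normalized so its maximum
#' is 0 dB and floored at `floor_db`, which makes the result (and everything
#' derived from it) invariant to the overall signal scale.
#'
#' @param recording A `cry_recording`.
#' @param freq_width_hz Frequency-domain window width (6 sd), Hz.
#' @param hop_s Frame hop in seconds.
#' @param max_freq Highest analysis frequency in Hz.
#' @param freq_step_hz Frequency sampling step in Hz.
#' @param floor_db Dynamic-range floor in dB (after 0 dB normalization).
#' @return A `cry_spectrogram`: `times` (s), `freq` (Hz), `db`
#'   (freq x time matrix, 0 dB max, floored), plus analysis parameters.
#' @export
narrowband_spectrogram <- function(recording, freq_width_hz = 50,
                                   hop_s = 0.004, max_freq = 11000,
                                   freq_step_hz = 40, floor_db = -50) {
  x <- recording$waveform
  fs <- recording$sample_rate
  if (length(x) < fs) abort("recording must last at least 1 s (one MPS window)")
  sigma_f <- freq_width_hz / 6
  sigma_t <- 1 / (2 * pi * sigma_f)
  L <- 2L * floor(3 * sigma_t * fs / 2) + 1L        # odd length, +/- 3 sd
  win <- exp(-0.5 * (((seq_len(L) - (L + 1) / 2) / fs) / sigma_t)^2)
  nfft <- round(fs / freq_step_hz)
  df <- fs / nfft
  n_keep <- floor(max_freq / df) + 1L
  hop <- max(1L, round(hop_s * fs))
  xp <- c(numeric((L - 1L) %/% 2L), x, numeric(L))
  centers <- seq(1L, length(x), by = hop)
  idx <- outer(seq_len(L) - 1L, centers, "+")
  fr <- matrix(xp[idx], nrow = L) * win
  # fold the windowed frames to nfft samples: this samples each frame's DTFT
  # on the coarse frequency grid without a full-length transform
  folded <- fr[seq_len(nfft), , drop = FALSE]
  r0 <- nfft
  while (r0 < L) {
    rows <- (r0 + 1L):min(r0 + nfft, L)
    folded[seq_along(rows), ] <- folded[seq_along(rows), , drop = FALSE] +
      fr[rows, , drop = FALSE]
    r0 <- r0 + nfft
  }
  X <- mvfft(folded)
  p_half <- Mod(X[seq_len(n_keep), , drop = FALSE])^2
  db <- 10 * log10(pmax(p_half, 1e-300))
  db <- db - max(db)
  db[db < floor_db] <- floor_db
  structure(list(
    times = (centers - 1L) / fs,
    freq = (seq_len(n_keep) - 1L) * df,
    db = db,
    hop_s = hop / fs, freq_step_hz = df,
    window_width_hz = freq_width_hz, floor_db = floor_db
  ), class = "cry_spectrogram")
}

#' Modulation power spectrum of a spectrogram
#'
#' The log spectrogram is weighted by 1 s Gaussian windows (1 s = 6 sd,
#' advanced by `1 - overlap` of the window), 2D Fourier transformed, and the
#' amplitudes averaged over windows. The result is cropped to
#' `|temporal modulation| <= tmod_max` Hz and
#' `0 <= spectral modulation <= smod_max` cyc/kHz.
#'
#' @param spgm A `cry_spectrogram`.
#' @param window_s MPS window length in seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @param tmod_max,smod_max Crop limits (Hz, cyc/kHz).
#' @param id Optional recording identifier for provenance.
#' @return A `cry_mps`: `temporal_modulations` (Hz), `spectral_modulations`
#'   (cyc/kHz), `amplitude` (spectral x temporal matrix), `provenance`.
#' @export
compute_mps <- function(spgm, window_s = 1, overlap = 0.5,
                        tmod_max = 100, smod_max = 10, id = NULL) {
  stopifnot(inherits(spgm, "cry_spectrogram"))
  hop_s <- spgm$hop_s
  n_t <- length(spgm$times)
  n_f <- length(spgm$freq)
  n_win <- round(window_s / hop_s)
  if (n_t < n_win) abort(sprintf("spectrogram spans %.2f s; at least %g s required",
                                 n_t * hop_s, window_s))
  sigma <- n_win / 6
  w <- exp(-0.5 * ((seq_len(n_win) - (n_win + 1) / 2) / sigma)^2)
  step <- max(1L, round(n_win * (1 - overlap)))
  starts <- seq(1L, n_t - n_win + 1L, by = step)
  acc <- matrix(0, n_f, n_win)
  for (s in starts) {
    seg <- spgm$db[, s:(s + n_win - 1L), drop = FALSE]
    seg <- sweep(seg, 2L, w, "*")
    acc <- acc + Mod(fft(seg))
  }
  amp <- acc / length(starts)
  tmod <- fft_freqs(n_win, d = hop_s)
  smod <- fft_freqs(n_f, d = spgm$freq_step_hz / 1000)
  keep_s <- which(smod >= 0 & smod <= smod_max)
  ord_t <- order(tmod)
  keep_t <- ord_t[abs(tmod[ord_t]) <= tmod_max]
  structure(list(
    temporal_modulations = tmod[keep_t],
    spectral_modulations = smod[keep_s],
    amplitude = amp[keep_s, keep_t, drop = FALSE],
    provenance = list(ids = id %||% character(0), n_windows = length(starts))
  ), class = "cry_mps")
}

#' One-call MPS of a recording
#'
#' @param recording A `cry_recording`.
#' @param ... Passed on to [narrowband_spectrogram()] and [compute_mps()].
#' @return A `cry_mps`.
#' @export
cry_mps <- function(recording, ...) {
  args <- list(...)
  sp_args <- args[names(args) %in% names(formals(narrowband_spectrogram))]
  mp_args <- args[names(args) %in% names(formals(compute_mps))]
  spgm <- do.call(narrowband_spectrogram, c(list(recording), sp_args))
  do.call(compute_mps, c(list(spgm), mp_args,
                         list(id = recording$sequence_id %||% "recording")))
}

check_mps_axes <- function(a, b) {
  if (!isTRUE(all.equal(a$temporal_modulations, b$temporal_modulations)) ||
      !isTRUE(all.equal(a$spectral_modulations, b$spectral_modulations))) {
    abort("MPS axes do not match")
  }
}

#' Element-wise average of several MPS objects
#'
#' @param mps_list List of `cry_mps` with identical axes.
#' @return A `cry_mps` whose amplitude is the element-wise mean; provenance
#'   concatenates the inputs'.
#' @export
average_mps <- function(mps_list) {
  stopifnot(length(mps_list) >= 1)
  ref <- mps_list[[1]]
  for (m in mps_list[-1]) check_mps_axes(ref, m)
  amp <- Reduce(`+`, lapply(mps_list, `[[`, "amplitude")) / length(mps_list)
  structure(list(
    temporal_modulations = ref$temporal_modulations,
    spectral_modulations = ref$spectral_modulations,
    amplitude = amp,
    provenance = list(
      ids = unlist(lapply(mps_list, function(m) m$provenance$ids)),
      n_windows = sum(vapply(mps_list, function(m) m$provenance$n_windows, 1))
    )
  ), class = "cry_mps")
}

#' Pairwise dB difference between two MPS maps
#'
#' `20 * log10(a / b)` element-wise; antisymmetric under operand swap.
#'
#' @param a,b `cry_mps` objects on identical axes.
#' @return A `cry_mps_diff` with `values` in dB.
#' @export
mps_difference <- function(a, b) {
  check_mps_axes(a, b)
  eps <- 1e-12
  structure(list(
    temporal_modulations = a$temporal_modulations,
    spectral_modulations = a$spectral_modulations,
    values = 20 * log10((a$amplitude + eps) / (b$amplitude + eps))
  ), class = "cry_mps_diff")
}

#' @export
print.cry_mps <- function(x, ...) {
  cat(sprintf("<cry_mps> %d x %d (spectral x temporal), tmod +/-%g Hz, smod 0-%g cyc/kHz, %d window(s)\n",
              nrow(x$amplitude), ncol(x$amplitude),
              max(abs(x$temporal_modulations)), max(x$spectral_modulations),
              x$provenance$n_windows))
  invisible(x)
}

#' @export
print.cry_spectrogram <- function(x, ...) {
  cat(sprintf("<cry_spectrogram> %d freqs x %d frames, %.2f s, df %.1f Hz, floor %g dB\n",
              length(x$freq), length(x$times),
              length(x$times) * x$hop_s, x$freq_step_hz, x$floor_db))
  invisible(x)
}

#' Flatten an MPS to a feature vector
#'
#' @param mps A `cry_mps`.
#' @return Numeric vector (column-major over the amplitude matrix).
#' @export
mps_to_vector <- function(mps) as.numeric(mps$amplitude)

#' MPS feature matrix for a whole corpus
#'
#' Computes the MPS of every recording and stacks the flattened amplitudes
#' into a matrix (one row per cry).
#'
#' @param corpus A `cry_corpus`.
#' @param ... Passed to [cry_mps()].
#' @return An `mps_set`: list with `X` (n_cries x n_bins matrix), `meta`
#'   (the corpus metadata tibble), and the two modulation axes.
#' @export
corpus_mps <- function(corpus, ...) {
  stopifnot(inherits(corpus, "cry_corpus"))
  mps_list <- purrr::map(corpus$recordings, cry_mps, ...)
  ref <- mps_list[[1]]
  for (m in mps_list[-1]) check_mps_axes(ref, m)
  X <- do.call(rbind, lapply(mps_list, mps_to_vector))
  rownames(X) <- corpus$metadata$sequence_id
  structure(list(X = X, meta = corpus$metadata,
                 temporal_modulations = ref$temporal_modulations,
                 spectral_modulations = ref$spectral_modulations),
            class = "mps_set")
}

#' @export
print.mps_set <- function(x, ...) {
  cat(sprintf("<mps_set> %d cries x %d MPS bins (%d spectral x %d temporal)\n",
              nrow(x$X), ncol(x$X),
              length(x$spectral_modulations), length(x$temporal_modulations)))
  invisible(x)
}

#' Per-baby, per-condition average MPS from an `mps_set`
#'
#' @param mps_set An `mps_set`.
#' @return An `mps_set` whose rows are baby x condition averages; its `meta`
#'   has `baby_id`, `sex`, `condition`, `n_cries`.
#' @export
baby_average_mps <- function(mps_set) {
  stopifnot(inherits(mps_set, "mps_set"))
  key <- paste(mps_set$meta$baby_id, mps_set$meta$condition, sep = "||")
  Xa <- rowsum(mps_set$X, key) / as.vector(table(key)[sort(unique(key))])
  parts <- do.call(rbind, strsplit(rownames(Xa), "||", fixed = TRUE))
  sex <- mps_set$meta$sex[match(parts[, 1], mps_set$meta$baby_id)]
  meta <- tibble(baby_id = parts[, 1], sex = sex, condition = parts[, 2],
                 n_cries = as.integer(table(key)[rownames(Xa)]))
  structure(list(X = Xa, meta = meta,
                 temporal_modulations = mps_set$temporal_modulations,
                 spectral_modulations = mps_set$spectral_modulations),
            class = "mps_set")
}

# Rebuild a cry_mps from one row of an mps_set (used by plots and averages).
mps_from_row <- function(mps_set, i) {
  ns <- length(mps_set$spectral_modulations)
  nt <- length(mps_set$temporal_modulations)
  structure(list(
    temporal_modulations = mps_set$temporal_modulations,
    spectral_modulations = mps_set$spectral_modulations,
    amplitude = matrix(mps_set$X[i, ], ns, nt),
    provenance = list(ids = rownames(mps_set$X)[i], n_windows = NA_integer_)
  ), class = "cry_mps")
}
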