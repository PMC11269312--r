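---
title: "Individual signatures and distress in infant cries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual signatures and distress in infant cries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cryid` studies a trade-off in infant vocal communication: a cry carries both
*static* information (which baby is crying — an individual vocal signature)
and *dynamic* information (how distressed the baby is). The package provides
an end-to-end, testable pipeline for quantifying how much identity
information survives in high-distress (pain) cries compared with mild
discomfort cries: acoustic feature extraction, modulation-spectrum analysis,
supervised identity classification under within- and cross-condition
schemes, acoustic-space shrinkage statistics, and a Bayesian model of
familiar-baby recognition by human listeners. Because the corresponding
recordings cannot be bundled, the package ships a synthetic cry generator
with known ground truth, so every downstream stage can be exercised and
validated without any download.

## The synthetic cry generator

A cry sequence is modeled as 2–6 expiratory bursts separated by 150–400 ms
silences. Each burst is a source–filter synthesis:

* **Source** — a harmonic stack (up to 20 harmonics, 1/h amplitude rolloff)
  on a time-varying fundamental
  $f_0(t) = \bar{f_0} + d \sin(2\pi r t + \phi) + j(t)$,
  where $d$ is the pitch-modulation depth, $r$ the modulation rate and
  $j(t)$ a slow Gaussian jitter track (100 Hz knots). Gaussian noise, shaped
  by the same vocal-tract response, is mixed in at a tonality-controlled
  ratio: the tonal fraction is 0.95 for discomfort cries. Nonlinear
  phenomena (chaos, subharmonics) are not modeled explicitly; noise + jitter
  are used as a surrogate that reproduces their measurable consequence — a
  lower pitch saliency — rather than their mechanism.
* **Filter** — two resonances (F1, F2) realized as Lorentzian magnitude
  responses with broad bandwidths (500 and 600 Hz), typical of infant vocal
  tracts. Narrow resonances would let a single harmonic dominate the
  source, which real cries do not show and which defeats any
  autocorrelation pitch tracker.
* **Amplitude** — sinusoidal amplitude modulation (rate and depth are baby
  parameters), a smoothed Tukey envelope per burst, a background-noise floor
  at −45 dB, and exact peak normalization of the final sequence.

Baby identity lives in five parameters (`f0_mean`, `f0_mod_depth`, `F1`,
`F2`, `am_rate`) drawn once per baby from truncated normal distributions
(e.g. mean fundamental in 250–600 Hz). Each *sequence* re-draws these
parameters around the baby's values with a within-baby standard deviation
equal to `within_baby_frac` times the between-baby dispersion: recordings of
one baby across sessions are similar, not identical. Without this
within-baby variability the identity signal would be implausibly clean and
every classifier would be perfect.

The **pain condition** applies four transformations, matching the reported
acoustics of pain cries: the pitch-modulation depth is multiplied
(`pitch_range_multiplier`, default 2 — a wider and more modulated pitch),
the amplitude-modulation depth is increased (+0.3), the tonal fraction of
the source is reduced (`saliency_drop`, default 0.12 — noisier, less tonal
cries), and the baby's identity parameters are convexly pulled toward the
population mean with weight `shrinkage` *before* synthesis. Parameter-level
shrinkage directly realizes the between-baby convergence that the acoustic
analyses then measure downstream; it is the generator's model of "identity
is sacrificed to distress".

Default study conditions mirror the corpus the pipeline was designed
around: 22 babies, 4 pain sequences per baby, 2–19 discomfort sequences per
baby (drawn uniformly), sequence durations Normal(6.3 s, 1.1 s) truncated
at 2 s, 22.05 kHz sampling (adequate for fundamentals below 600 Hz and
formants below 5 kHz at half the compute of 44.1 kHz). The recordings'
true sample rate and the internal silence/voicing structure of a sequence
are not documented for the original corpus; the values here are package
choices. The generator is a pure function of its configuration, including
the seed; two runs with the same config are byte-identical.

The free effect-size parameters (`shrinkage` = 0.4, `within_baby_frac`
= 0.5, `saliency_drop` = 0.12, `pitch_range_multiplier` = 2) were
calibrated once so that the default synthetic corpus reproduces the
documented quantitative regime of the real corpus — within-discomfort
identity classification near 56% correct at chance 1/18, pain-cry
identification small but reliably above chance and similar between the
within-pain and cross-condition regimes, a saliency contrast near −0.1,
and a significant but moderate contraction of the pain acoustic space —
and then frozen. In particular, `saliency_drop` is anchored to the
measured saliency contrast rather than chosen freely: a much larger drop
buries the pain cries' identity cues in noise and contradicts the regime
the generator is supposed to emulate. These parameters are dials for
designing *other* experiments, not values to be tuned per analysis.

## Acoustic features (22 PAFs)

Per cry, 22 predefined acoustic features:

* **Envelope (7)** — mean, SD, skewness, kurtosis, entropy, RMS, max of the
  amplitude envelope (full-wave rectification, zero-phase 20 Hz low-pass,
  1 kHz envelope rate). Entropy is the Shannon entropy of the envelope
  normalized to a distribution over time, divided by $\log n$ so a constant
  envelope scores 1 and a single spike scores 0. The envelope method and
  the entropy normalization are standard bioacoustic practice; the exact
  estimator conventions of the reference corpus are not public, so these
  defaults are documented substitutes.
* **Spectrum (8)** — mean, SD, skewness, kurtosis, normalized entropy of
  the power spectral density treated as a distribution over frequency, plus
  the 25/50/75% energy quantiles Q1–Q3 in Hz.
* **Fundamental (5)** — meanF0, MaxF0, MinF0, cvF0 (= SD/mean over voiced
  frames; voiced-only is a package choice) and mean pitch saliency over all
  frames. The tracker computes, per 33 ms frame (10 ms hop), the normalized
  autocorrelation; f0 is the reciprocal lag of the first prominent peak in
  the 150–1200 Hz search band (parabolic interpolation), and saliency is
  that peak's amplitude relative to lag zero — near 1 for tonal frames, low
  for noise. Frames with saliency below 0.5 are unvoiced. Two details
  matter in practice: the small-lag-bias correction is clamped at 1 so a
  repeat peak at twice the period cannot outrank the period, and a second
  pass re-snaps frames whose estimate sits outside 0.55–1.8 times the track
  median (computed from unambiguous frames) to the nearest in-range
  candidate. Without the second pass, frames in which a formant boosts one
  harmonic far above the rest are genuinely ambiguous and the tracker locks
  onto that harmonic.
* **Formants (2)** — F1 and F2 as medians over voiced frames of
  linear-prediction (Burg, order 12) pole frequencies at 10 kHz, keeping
  poles with bandwidth under 500 Hz, above max(400 Hz, 1.6 × median f0),
  and at least 600 Hz apart, and discarding sharp poles (< 120 Hz
  bandwidth) that sit on a pitch harmonic of their frame. Estimating
  formants in cries is intrinsically fragile: the fundamental is so high
  that very few harmonics sample each resonance. When the fundamental
  exceeds roughly 430 Hz the harmonics can straddle F1 entirely and the
  estimate degrades; a confidence field reports the fraction of usable
  frames, and a degenerate input with no formant structure (e.g. a pure
  tone) raises an error rather than returning a number.

Per-feature condition contrasts use a linear mixed-effects model
(`feature ~ sex * condition + (1 | baby_id)`, REML) with Wald z tests on
the fixed effects — the baby is the random unit, so pseudo-replication
across a baby's many sequences does not inflate the condition test.

## Modulation power spectrum

The MPS is the amplitude of the 2D Fourier transform of the normalized log
spectrogram, averaged over 1 s Gaussian windows (1 s = 6 sd, 50% overlap).
The spectrogram is narrow-band: Gaussian analysis window with a
frequency-domain width of 50 Hz (= 6 sd), log power normalized to a 0 dB
maximum and floored at −50 dB *before* the transform. The normalization
and floor make the MPS exactly invariant to the overall level of the
recording — a property the test suite asserts to machine precision.

Axes are temporal modulation (Hz, signed) and spectral modulation
(cycles/kHz). A harmonic stack with fundamental $f_0$ concentrates
spectral-modulation energy at $1/f_0$ kHz$^{-1}$: 330 Hz appears near
3 cyc/kHz. Analysis defaults: 4 ms frame hop and 40 Hz frequency sampling,
giving modulation Nyquists of ±125 Hz and 12.5 cyc/kHz — comfortably beyond
the retained analysis region (|temporal| ≤ 100 Hz, spectral ≤ 10 cyc/kHz,
which covers the pitch region and the ±20 Hz modulation structure of
interest). Finer sampling changes nothing inside the retained region and
multiplies compute severalfold; the hop and frequency step are configurable
for users who want the wider region. Cries shorter than the 1 s window are
rejected rather than zero-padded. Recordings are stored as amplitude MPS;
displays use dB, and pairwise difference maps are dB differences
(antisymmetric under operand swap).

## Acoustic space, shrinkage, and trajectories

MPS vectors are reduced by centered PCA with a fixed sign convention (the
largest-magnitude loading of each component is positive, making runs
reproducible). Two scopes are exposed and must not be conflated: a
*visualization* basis fitted on per-baby average discomfort MPS (used for
the PC1–PC2 acoustic map) and a *classification* basis fitted on the
training fold's per-cry MPS (20 components).

The shrinkage statistic: project each baby × condition average MPS onto
PC1–PC2, compute each baby's Euclidean distance to its condition centroid,
and compare conditions with a two-sided paired t test across babies. A
positive mean difference (discomfort minus pain) means pain cries are more
homogeneous across babies — the acoustic space has contracted. Distances
are invariant to rigid rotations of the plane, and a rotation of the
signature plane (as opposed to a true contraction) does not produce a
spurious positive result in the pain-fitted basis; both properties are
under test.

The condition-discriminant axis is a two-class linear discriminant on the
20-component scores, unit-normed and oriented so pain projects positively.
Trajectory statistics correlate per-baby positions along this axis with a
PC coordinate, separately for discomfort means, pain means, and their
pairwise differences (Pearson r with the standard t-based test; the
reference analysis labels these p-values "Fisher's exact test", which is
presumably a misnomer — this package reports the standard correlation test
and says so here rather than guessing which variant was meant).

## Identity classification

Four regimes: leave-one-out within discomfort, leave-one-out within a mixed
pool, leave-one-out within pain, and a single cross-condition split
(train on all discomfort, test on all pain). Eligibility mirrors the
reference design: at least 5 discomfort cries for training (plus 1 when
leave-one-out holds a discomfort cry out), at least 4 pain cries, at least
10 cries overall. Classifiers: LDA, a ridge-regularized QDA (plain QDA is
singular when a class has fewer exemplars than dimensions — pain classes
can have 3 training cries in 20 dimensions), and a 100-tree random forest.

In the MPS space, the 20-component PCA is refit on every leave-one-out
training fold — fitting it once on all data would leak the held-out cry
into its own representation. Whether the reference analysis refit per fold
is unknown; per-fold refitting is the conservative choice. The refit is
made cheap by computing fold PCAs from the precomputed Gram matrix of the
full MPS matrix (kernel-PCA identity), which the suite verifies against a
direct `prcomp` refit. PAF features are standardized on the training fold.
Posteriors over babies are aggregated into a confusion matrix of mean
posteriors by true baby; the headline number is the mean diagonal
posterior ± 2 SE across babies (the reference's ± 2 SE basis is unstated;
across-baby is the package's choice). Hard counts use the maximum
posterior, ties broken toward the lowest baby label. Performance
comparisons use the exact Fisher test on correct/total counts, and each
regime is compared against uniform chance (1/n babies) with an exact
upper-tail binomial test.

## Listener experiment

The psychoacoustic design: two training sessions of 5 discomfort cries
from one "familiar" baby, then 20 pain-cry test trials — 4 from the
familiar baby, 16 from four unknown babies (2 boys, 2 girls) — answering
"is this your baby?" per trial. Chance is 4/20 = 20%.

The cohort simulator is a generative stand-in for real listeners: 100
subjects (25 per sex × parental-status cell), Bernoulli responses from a
logistic model with population hit and false-alarm rates, optional group
offsets, and random intercepts and familiar-status slopes for subjects and
for assigned babies. The realized random effects are centred (their sample
mean is removed): with only nine assigned babies an uncentred draw shifts
the whole cohort's rates several points away from the configured targets,
which would make the simulator's nominal rates misleading.

The analysis model is the Bayesian logistic mixed model
`response ~ status * parentality * sex + (status + parentality | assigned baby) + (status | subject)`,
fitted with JAGS: Normal(0, 1) priors on effect coefficients and
Normal(logit(0.2), 1) on the intercept — priors centered on "no effect and
chance performance". Design factors use sum-to-zero ±1/2 coding so each
coefficient is a full logit-scale contrast and the intercept is the grand
mean; the reference's coding is unstated. The intercept prior is placed on
the logit scale (the reference says only "mean given by the chance level");
a probability-scale prior would not be conjugate with a logistic model and
logit is the natural scale. Random-effect SDs get half-Normal(0, 1) priors
and are mutually independent (no estimated correlations; with 9 assigned
babies a full covariance is weakly identified). Subject intercepts are
hierarchically centred on the population intercept — the zero-centred
parameterization leaves the split between the intercept and the
random-effect mean poorly mixed in JAGS. Default MCMC matches the
reference (2 chains × 3000 iterations, first 1000 for adaptation);
`listener_mcmc_fast()` (2 × 1100) is used for quick runs. Convergence is
summarized by the maximum between-chain R-hat of the reported rate
quantities and flagged, never silently ignored.

Posterior recognition and false-positive rates are reported on the
probability scale for the *population-median* subject and baby — the
inverse logit of the fixed-effect linear predictor with random effects at
zero, averaged over design cells. Whether such rates should instead be
marginalized over the random-effect distribution is a genuine modeling
choice; marginalization was implemented and rejected because the marginal
rates inherit the posterior of the baby-level intercept SD, which is weakly
identified with only nine assigned babies — its heavy upper tail drags
every marginal rate toward 0.5 and away from the observed response
frequencies, while the median-subject rates sit on the same scale as the
raw data. Contrasts (familiar vs unknown, sex, parentality) are medians and
95% credible intervals of differences of these rates, with a flag when the
interval excludes zero.

The machine listener mirrors the human protocol: per familiar baby, an LDA
(familiar vs rest) trained on 10 of its discomfort cries against the other
babies' discomfort cries in the 20-component MPS space, applied to the
20-cry pain test set. Class priors are set to the test prevalence (20%),
the same base rate human subjects faced; training-set proportions would
encode an arbitrary imbalance instead.

## Numerical choices and problem sizes

* FFT-based filters zero-pad to highly composite lengths; the spectrogram
  samples each frame's DTFT on the coarse frequency grid by time-domain
  folding, which is exact and avoids full-length transforms.
* PCA uses a fixed sign convention; fold-wise PCAs use the Gram-matrix
  identity; eigenvalues below 1e-8 of the leading one are dropped.
* The regularized QDA adds `0.1 × mean diagonal` of each class covariance
  to its diagonal.
* Saliency is clipped to [0, 1]; the autocorrelation lag-bias correction is
  clamped at 1.
* Ties, degenerate inputs (silence, pure tones, single-condition tables,
  too-short recordings) raise typed errors rather than propagating NaN.
* The test suite exercises the full default corpus once for the headline
  classification regimes, and uses reduced corpora (shorter sequences,
  fewer discomfort cries per baby, 2–4 s durations) for replicated
  property checks — e.g. shrinkage replicates across 20 seeds — so the
  whole suite stays within a routine CI budget. Replicate counts and sizes
  are stated in the tests themselves; enlarging them is a one-line change.

## Known limitations

* The synthesizer's cries are caricatures: no deterministic chaos,
  biphonation, inhalation sounds, or room acoustics. Passing tests show
  the *pipeline* behaves correctly on signals with known structure, not
  that any scientific claim transfers to real recordings.
* Formant estimation degrades for babies with mean fundamentals above
  roughly 430 Hz (harmonic sampling of F1 becomes too sparse); estimates
  remain internally consistent per baby, which is what identity
  classification uses.
* The listener model treats stimulus babies other than the familiar one as
  exchangeable; only the assigned baby enters the random-effect structure,
  as in the reference model formula.
* WAV I/O is deliberately minimal: 16-bit PCM mono (stereo files are read
  only to be rejected with a clear message).
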