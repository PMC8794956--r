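---
title: "Quantifying neural inertia from EEG at anesthetic steady state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neural inertia from EEG at anesthetic steady state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Neural inertia is the brain's intrinsic resistance to transitions between
the awake and anesthetized states: at the same anesthetic concentration, the
state of an individual depends on the *history* of drug exposure, not only
the current dose. `neuroinertia` quantifies this path dependence from murine
EEG recorded at a steady near-EC50 isoflurane concentration (0.6%). Two
exposure paradigms end on the same extended 0.6% step: the *induction* arm
reaches it from oxygen, the *emergence* arm from a deeper 1.2% exposure.
Brain drug levels equilibrate in under about 12 minutes, so any EEG
difference between the arms during a test span beginning 30 minutes into the
final step (minutes 30--130) must come from the initial condition — that is
neural inertia. The measurement instrument is a classifier: ensembles of
linear-discriminant (LDA) and support-vector (SVM) classifiers are trained
to label 4-s spectral windows as induction or emergence; above-chance
balanced accuracy on held-out steady-state windows is evidence of path
dependence, and a decrease of that accuracy over the test span is evidence
that inertia collapses in the limit of time.

## The stochastic state-switching model

The latent arousal state is modeled as Brownian motion of a particle in a
double-well potential

$$V(x) = \tfrac{a}{4}x^4 - \tfrac{b}{2}x^2 + c(t)\,x,
\qquad c(t) = -k\,(\mathrm{conc}(t) - \mathrm{conc}_{\mathrm{ref}}),$$

integrated by Euler--Maruyama:
$x \leftarrow x - V'(x)\,\mathrm{d}t + \sqrt{2D\,\mathrm{d}t}\,\mathcal N(0,1)$.
The negative well is the awake state, the positive well the anesthetized
state; the binary state is the sign of $x$. Relative well depths set
occupancy; the noise amplitude $D$ sets the transition frequency. At the
reference concentration (0.6%, the EC50-equivalent) the wells are symmetric,
so during the final step the only asymmetry between the arms is where the
particle starts. That memory decays at twice the Kramers escape rate

$$r = \frac{\sqrt{V''(x_{\min})\,\lvert V''(x_{\mathrm{bar}})\rvert}}{2\pi}
      e^{-\Delta V / D}, \qquad \Delta V = \frac{b^2}{4a},$$

which the package inverts (`noise_for_relaxation()`) to pick $D$ for a
requested relaxation time constant. The simulator's escape statistics are
checked against this closed form in the test suite (factor 1.5 over 200
first-passage simulations), and symmetric-well occupancy against 0.5.

### Parameter choices

The model's quantitative scales are module defaults, not literature claims:

* `a = b = 1` (barrier height 0.25), `dt = 10` ms. The stability guard
  rejects `dt` for which the drift update could overshoot; behavioral dwell
  times are minutes, far above `dt`, and the recorded path is thinned to
  0.25 s.
* `tilt_gain = 1` per percent isoflurane, with `reference_conc = 0.6`. At
  0% (oxygen) the awake well is then deep enough that anesthetized occupancy
  is negligible, and at 1.2% the reverse, so the arms enter the final step
  from opposite wells — the generated hysteresis.
* Default relaxation target 40 min; per-individual variability is a ±20%
  jitter on the relaxation time realized through $D$. (Jittering $D$ itself
  by ±20% would move the relaxation time by roughly a factor of 5 in either
  direction because the escape rate is exponential in $1/D$, which would
  destroy the cohort's timescale semantics.)

### Why the spectral drive averages several modules

A single particle with a 40-min memory necessarily dwells ~80 min per well,
so one realized recording is a handful of all-or-nothing bouts and the
realized test-period occupancy of an individual is near 0 or 1. Real
individual mice instead show graded, reliably above-chance accuracies. The
generator therefore drives the EEG spectra with the anesthetized *fraction*
of `n_modules = 48` independent particles sharing the same landscape and
initial condition (`simulate_state_mixture()`) — a cortical-ensemble reading
of the same model. Each module keeps the single-particle switching
statistics, so the memory time constant is unchanged; the aggregate tracks
the expected occupancy with $\sim 1/\sqrt{48}$ fluctuations, giving smooth
per-individual accuracy that decays over the test span. The single-particle
operations (`simulate_two_well()`, `occupancy()`, `escape_times()`) remain
available and are what the Kramers and symmetry oracles test.

## Synthetic EEG and EMG

EEG is synthesized in 4-s blocks by frequency-domain amplitude shaping
(random phases, amplitude $\propto \sqrt{P(f)}$) with 0.25-s raised-cosine
cross-fades, so bout boundaries never produce clicks and a block's Welch
spectrum matches its target. The per-state templates encode the canonical
isoflurane contrast — awake: $1/f$ background, theta peak, elevated gamma;
anesthetized: boosted slow-delta, attenuated above 30 Hz — with per-individual
log-normal band gains ($\sigma = 0.2$). The block spectrum interpolates
between the two templates linearly in dB according to the anesthetized
fraction.

Two forms of window-to-window spectral variability ride on top: a smooth
log-spectral modulation (24-term cosine series in frequency, 4.5 dB per-bin
SD) and an independent per-bin jitter (3.2 dB SD). These emulate the
within-state spectral wandering visible in real steady-state spectrograms,
and their amplitudes are the generator calibration that places the share of
feature variance captured by 50 principal components in the reported
70--78% band. The template contrast exponent (0.7) is part of the same
calibration.

EMG is baseline Gaussian noise (5 uV RMS) plus movement bursts — an
inhomogeneous Poisson process whose rate (2/min when fully awake) scales
with the awake fraction, amplitude 8x baseline, gamma-distributed durations
(mean 1.5 s). Large-amplitude artifacts (decaying exponentials, default
1500 uV peak at 0.1/min) are injected with recorded ground-truth times so
artifact-window recovery is testable.

What the generator does *not* emulate: burst suppression, more than two
latent spectral states, pharmacokinetic lag (concentration steps act
immediately, justified by the ≤12-min equilibration and the 30-min analysis
guard), line noise, electrode drift, or cross-channel phase structure.
Passing tests therefore show that the pipeline correctly recovers the
statistics this model encodes — not that real mouse EEG satisfies them.

## Preprocessing

The conditioning chain mirrors standard murine EEG practice:

* 1 kHz acquisitions are decimated to 250 Hz (8th-order zero-phase
  Butterworth anti-alias at 0.8x the new Nyquist, then subsampling).
* EEG is band-passed 1--120 Hz with a 6th-order zero-phase Butterworth,
  implemented as a cascade of the 1-Hz high-pass and the 120-Hz low-pass
  sections applied forward-backward. A single 12-pole transfer-function
  band-pass with its upper edge at 0.96 Nyquist is numerically fragile in
  polynomial form; the cascade has the same band edges and keeps the
  zero-phase contract (cross-correlation lag 0, tested).
* Channels with impedance above 30 kOhm are excluded (exactly 30 is kept);
  manual exclusion is a metadata flag. Losing M2 or V1 aborts the analysis.
* Artifact masking: the per-channel noise scale $\sigma$ is estimated from
  all samples excluding those beyond ±700 uV and those inside high-EMG
  seconds; any 4-s window containing a sample beyond $6\sigma$ or ±700 uV
  is excluded. "Period" granularity is the 4-s spectral window, because the
  mask's only consumer is window-level spectral analysis; $\sigma$ is a
  single per-recording scalar per channel. Boundary convention: values at
  exactly the threshold are kept.
* Retained channels are mean re-referenced. With only the two analysis
  channels in scope this produces an anticorrelated pair (a difference
  montage): both channels carry the same spectrum afterwards. The step is
  kept because it is part of the analyzed chain; its consequence — the two
  241-bin feature blocks become duplicates — is immaterial to the
  classifiers and is absorbed by the PCA.

## EMG tone rule

Movement epochs make the 1-s log-RMS distribution bimodal. The rule
estimates a Gaussian-kernel smoothed CDF of the *centered* log10 RMS on a
512-point grid (Silverman bandwidth) and scans upward from the main mode for
the first grid point where the CDF slope — the smoothed density — drops
below 1. Centering makes the threshold invariant to rescaling the EMG
signal (a positive gain is a shift in log space). The natural log10 spread
is deliberately *not* standardized to unit variance: the slope-below-1
criterion carries information only because the quiet-muscle mode is tight
(SD well below one log10 unit); forcing unit variance would make the peak
density ~0.4 and place the threshold at the mode. If the slope never
reaches 1 the distribution has no resolvable movement mode and an all-false
mask is returned with a warning; a constant RMS series is likewise
degenerate. EMG lead selection from multi-lead montages is out of scope —
the generator produces one EMG channel.

## Spectral features and PCA

Power is estimated per non-overlapping 4-s window with Thomson multitaper
estimation (time-bandwidth NW = 2, 3 Slepian tapers computed from the
tridiagonal eigenproblem), reported on the 241-bin 0--120 Hz grid at 0.5 Hz
spacing — the unique grid consistent with 241 independent estimates per
channel and with a Bonferroni family of 241 per-channel tests giving the
99.979% CI level ($1 - 0.05/241$). With a 4-s window the taper half-bandwidth
is 0.5 Hz, so adjacent grid estimates are approximately independent.

Features are dB differences from the mean dB spectrum over *all* windows of
the three sources (induction recording, emergence arm, induction arm of the
emergence recording), M2 then V1, concatenated to 482 dimensions; spectral
contrasts in EEG are multiplicative, so differencing is done on the log
scale. PCA keeps the first 50 components (scores for classification,
loadings sign-fixed so the largest-magnitude element is positive).

## Classifiers and statistics

Training sets draw 260 windows per class from minutes 10--30 of the relevant
0.6% steps — emergence from the emergence arm; induction split 130 + 130
between the induction recording and the induction arm of the emergence
recording, so recording-day differences cannot impersonate the
induction/emergence contrast. Ensembles of 250 classifiers differ through
independent resampling of the training pool (member $i$ uses seed
`base_seed + i`); this is the only stochastic ingredient available given a
fixed 20-min pool. LDA is classical Fisher/Gaussian discriminant analysis
with the pooled covariance shrunk toward its diagonal at an automatically
estimated (Ledoit--Wolf-style) intensity; SVMs default to a Gaussian RBF
kernel ($\gamma = 1/(50 \cdot \text{mean feature variance})$, $C = 1$), the
nonlinear counterpart, with a linear kernel by argument. The shuffled-label
null retrains on label-permuted training sets and calibrates chance.

Balanced accuracy is $\tfrac12(I_C/I_T + E_C/E_T)$, computed per classifier
per evaluation period from pooled window counts (one confusion summary per
classifier-period, not an average of sub-period accuracies, so the formula's
totals are respected). Population-level training draws 260 windows per class
from each of the other individuals (1,300 per class for a 6-mouse cohort)
in a PCA space fitted to the pooled features of the contributing
individuals; the held-out individual's features are projected with those
loadings. The paper-level statistics are: per-individual 95% percentile
bootstrap CIs of the median accuracy (10,000 resamples); Kruskal--Wallis
comparisons against the shuffled null (the inertia call = real median above
null at p < 0.05); a Friedman test of LDA vs SVM blocked by individual; and
the collapse test — per-classifier mean accuracy for minutes 30--50 vs
110--130, pooled across individuals with a two-sided Wilcoxon matched-pairs
signed-rank test, plus a two-way ANOVA (period x individual) with
Sidak-corrected per-individual contrasts. All tests are two-sided at
$\alpha = 0.05$. Fully tied rank tests (identical inputs) return p = 1 by
the documented degenerate branch.

## Problem sizes and numerical choices

The default study configuration is 6 individuals x 2 paradigms, 250 LDA
classifiers per ensemble, and synthesis restricted to the spans the analysis
consumes (training minutes 10--30 of each 0.6% step and test minutes
30--130 of the final step); trajectory simulation always covers the full
schedule so state memory is exact. This keeps a full cohort run at roughly
two minutes on one core. The test suite exercises the same code on smaller
fixtures (16-min test slices, reduced ensembles) and runs the
chance-calibration and collapse checks at the full stated conditions; the
type-I-error property for inertia calls is established at the statistics
level with 1,000 replicate null comparisons plus a full arm-exchangeable
pipeline run, rather than 100 full pipeline replicates. Half-open interval
conventions `[start, end)` are used for all time selections; exact-zero
positions in the two-well model keep the previous state; window counts are
`floor(duration / 4 s)`; trailing partial seconds of EMG are dropped.

## Known limitations

* The generator's spectra are stationary within a state up to the modeled
  modulation; real EEG has slower drifts and arousal micro-structure that
  the pipeline would see as additional variance.
* With only two EEG channels, mean re-referencing collapses the montage to
  a single effective signal; with a fuller montage the re-referenced
  channels would stay distinct.
* The multitaper parameters of the original analysis chain are not public;
  any estimator with ~0.5 Hz resolution that passes the tone/flatness tests
  would serve. Absolute power levels are therefore not comparable across
  estimators, but all downstream statistics are differences or ranks.
* Population-level training assumes the per-individual mean-centered
  feature spaces are commensurable across mice; this is a modeling choice,
  not a property the paper specifies.
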