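---
title: "Models and methods behind audscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind audscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audscreen)
```

`audscreen` implements the computational core of a web-based psychoacoustics
workflow: synthesizing the stimuli, deciding who gets screened in or out,
fitting psychometric functions to the resulting forced-choice data, comparing
remote measurements against laboratory references, and simulating observers
so that every stage can be validated end to end without human data. This
vignette explains the models, the tunable parameters, and the design choices
that were genuinely open.

## The screening problem and the two-Gaussian score model

Anonymous web participants cannot be audiometrically tested, so hearing
status is inferred from a suprathreshold word-recognition-in-babble task
(modified rhyme test, 6AFC) scored at several signal-to-noise ratios. The
calibration question is where to place per-SNR percent-correct cutoffs.

The model treats normal-hearing (NH) and hearing-loss (HL) scores as two
Gaussians: NH scores $\sim \mathcal{N}(\mu, \sigma)$ and HL scores
$\sim \mathcal{N}(\mu - g\,s_p,\; r\sigma)$, where $g$ is the standardized
mean difference on the pooled scale
$s_p = \sqrt{(\sigma^2 + r^2\sigma^2)/2}$ and $r$ is the HL/NH SD ratio.
The meta-analytically calibrated operating values are $g = 2.05$ and
$r = 3$. For a cutoff placed at the NH distribution's $q$ quantile, the
expected fraction of HL listeners excluded is

$$\Phi\!\left(\frac{\Phi^{-1}(q)\,\sigma - (\mu_{HL} - \mu)}{r\sigma}\right),$$

computed analytically by `expected_hl_exclusion()` and swept into a full
receiver operating characteristic by `theoretical_roc()`. At the deployed
operating point ($q = 0.35$) this predicts roughly 92% HL exclusion, and
stays near 90% across the 20–40% NH-exclusion range:

```{r roc}
model <- population_model(g = 2.05, sd_ratio = 3)
round(expected_hl_exclusion(model, c(0.20, 0.35, 0.40)), 3)
```

`derive_cutoffs()` reproduces the deployed calibration schedule: initial
per-SNR cutoffs at a cohort's 65th percentile, then simultaneous relaxation
in 2-percentile-point steps until the *joint* exclusion (failing any SNR
gate) first reaches the target. The published schedule is ambiguous about
whether relaxation is per-SNR or simultaneous; we chose simultaneous
relaxation with a first-crossing stopping rule because it is the only
reading under which the trace is monotone and the reported joint target is
well defined. Quantiles use linear interpolation (`type = 7`), cutoff
comparisons use `>=`, and the Gaussian model is used untruncated for the
analytic ROC while simulated scores are clipped to [0, 100] (clipping mass
is negligible at the default score scale, NH mean 85, SD 5).

The decision layer on top is deliberately plain: `classify_hearing()` passes
a participant iff every per-SNR score meets its cutoff (100 / 83 / 75
percent at 10 / 5 / 0 dB SNR by default, with the −5 dB block recorded but
never gating), at most two browser focus-loss ("blur") events occurred, and
the survey explicitly denies hearing loss, neurological disorders, and
persistent tinnitus. `score_headphone_check()` implements the 5-of-6
conjunction over the two headphone tasks (relaxed to 4-of-6 for cohorts
recruited for diagnosed hearing loss). Flow gates of the form "more than
X%" are strict inequalities; screening cutoffs are `>=` — the two boundary
semantics are documented per gate because they differ in the deployed rules.

## Stimulus synthesis

All synthesis is sample-accurate at 48 kHz (the browser-standard rate) with
levels in dB re full-scale RMS, and a nominal presentation level of −30 dB
FS so that antiphase sums and multi-band maskers can never clip. Tone levels
are exact after ramping (tones are renormalized post-taper). Key stimuli:

* **Antiphase triad** (headphone check 1): three tones, target 6 dB softer
  than two foils, one foil polarity-inverted between channels. Defaults —
  200 Hz, 1 s, 20-ms Hann tapers — follow the antecedent loudness-based
  procedure; the deployed description says only "low-frequency tones".
* **Dichotic chirp in noise** (headphone check 2, N0Sπ): a 150–400 Hz
  linear chirp, polarity-inverted between channels, in noise (100–500 Hz)
  identical in both channels. The per-channel SNR defaults to −16 dB,
  chosen so monaural detection is near chance while the binaural masking
  level difference makes the dichotic percept easy; the deployed SNR is not
  published. The flat variant sits at the geometric mean (≈245 Hz).
* **F0 discrimination**: four 200-ms harmonic complexes (F0 110 Hz,
  equal-amplitude harmonics 1–10 in sine phase — the source spectrum is
  unspecified, so the simplest standard complex is used), 20-ms tapers,
  50-ms gaps between tones. The listed F0 shift is interpreted as the total
  excursion split symmetrically (tones 1 and 3 at $110 \pm \Delta/2$, tone
  1 up); the alternative per-tone reading would only rescale the ladder by
  a factor of two.
* **Gap detection**: two 125-ms 4-kHz markers with 1-ms tapers, the gap
  replacing tone only; band noise half an octave either side of 4 kHz at
  tone level −10 dB, leading by 50 ms and (by symmetry, unstated in the
  source) trailing by 50 ms.
* **ITD / ILD pairs**: the ITD is realized as an interaural carrier phase
  $2\pi f \tau$ (exact for pure tones; a whole-waveform sample delay is
  available as an option), the ILD as a symmetric $\pm$ILD/2 split that
  preserves the mean level.
* **CMR**: 1-ERB-wide on-band noise at 4 kHz (ERB per Glasberg–Moore,
  $24.7\,(4.37 F_{kHz} + 1)$ Hz) with 10-Hz raised-sine amplitude
  modulation at 100% depth; flankers are 1-ERB bands whose near edges sit
  2 ERB away, sharing the on-band modulator (CORR) or its π-shifted inverse
  (ACORR). Band noises are synthesized in the frequency domain, so spectral
  containment is exact up to windowing.

Every task's calibration sound is a concatenation of representative task
stimuli (at least 3 s), and all task stimuli must sit within 6 dB of the
calibration RMS (`check_headroom()`). Modulator coherence between bands is
verified with `modulation_envelope()`, which projects the Hilbert envelope
onto the DC and modulation-rate components; this isolates the imposed
modulator from the carrier's intrinsic envelope fluctuations, which would
otherwise cap measurable envelope correlations well below 1 for 1-ERB-wide
carriers.

## Bayesian psychometric fitting

Forced-choice accuracy is modelled as

$$P(\text{correct} \mid x) = \gamma + (1 - \gamma - \lambda)\,
S\!\left(\log x;\, m, w\right),$$

with $S$ a logistic sigmoid on the log-stimulus axis parameterised by its
midpoint $m$ and the width $w$ between its 5% and 95% points, a fixed guess
rate $\gamma$ (1/2, 1/3, or 1/6 by design — never estimated), and a lapse
rate $\lambda$. Observations are beta-binomial: given the predicted $p$ and
an overdispersion parameter $\eta \in [0, 1)$ (intraclass correlation),
counts follow a beta-binomial with mean $p$ and shape $\nu = (1-\eta)/\eta$;
$\eta = 0$ recovers the binomial exactly. This parameterisation approximates
the referenced fitting framework's conventions rather than cloning them;
its exact sigmoid and prior hyperparameters are not public, so ours are
documented here as the package's own defaults.

The posterior over $(m, w, \lambda, \eta)$ is computed by numerical
integration on a product grid (default 40 × 40 × 20 × 10) with priors:
uniform $m$ over the data's log-level range padded by 30% per side;
log-uniform $w$ from the smallest level gap to three times the range;
Beta(1, 24) on $\lambda/\lambda_{max}$ with $\lambda_{max} = 0.1$;
Beta(1, 9) on $\eta$. Thresholds at a target proportion correct (79.4% for
3AFC, 75% for 2AFC) are obtained by inverting the sigmoid at every grid
point and propagating posterior weights into a posterior-mean estimate and
a 95% credible interval. All-correct or all-chance data return a fit with a
`boundary` flag instead of an error; for chance-level data the model
correctly concludes the threshold lies *above* the tested range (a
below-range midpoint would predict ceiling performance), so the credible
interval hugs the top of the ladder rather than spanning it.

Negative-dB SNR ladders (as in CMR) are mapped to linear amplitude ratios
with `snr_db_to_ratio()` before fitting and thresholds mapped back, keeping
the log-axis model applicable. `cmr_effect()` differences per-condition
thresholds with the release-positive convention: CMR(A−B) is B's threshold
minus A's, so a lower CORR threshold yields a positive release.

Grid resolution is a quality/cost dial, not part of the model: the test
suite uses 25 × 20 × 10 × 6 grids for its 200-replicate coverage study
(where credible intervals cover the generating threshold in ≥ 90% of runs)
and the default grid for single high-precision fits; a parameter-recovery
check at roughly 10,000 simulated trials recovers the generating threshold
within 5%.

## Effect sizes and the web-vs-lab comparison

Comparisons against published laboratory references use Hedges' bias
corrected standardized mean difference
$g = J\,(\mu_1 - \mu_2)/s_p$, $J = 1 - 3/(4\,df - 1)$, with n-weighted
pooling when group sizes are known. Several reference sources report only a
median and an SEM without usable group sizes; `stats_from_report()` converts
SEM to SD via $\sigma = SEM\sqrt{n}$ when $n$ is known and otherwise flags
the size as unknown, in which case `hedges_g()` falls back to equal-weight
pooling $s_p = \sqrt{(\sigma_1^2 + \sigma_2^2)/2}$ with $J = 1$ and records
the mode. This equal-weight fallback exactly reproduces the published F0
comparison row and bounds the others; the reference-study sizes behind the
remaining rows are not reconstructible from the printed values.
`pool_effects()` provides fixed-effect inverse-variance pooling
($w_i = 1/v_i$), the convention behind the $g = 2.05$ calibration; CIs use
the 1.96 multiplier without a small-sample t adjustment, as is standard in
meta-analysis.

## Consonant confusions

`build_confusion_matrix()` tallies presented-by-responded counts over the
16-consonant C/a/ inventory. For clustering, pairwise similarity is the
symmetrized off-diagonal confusion probability
$(p_{i \to j} + p_{j \to i})/2$ (the source does not state a
symmetrization), converted to a distance by $1 - s/\max(s)$, and fed to
agglomerative clustering with average linkage by default (complete and
single are selectable; the source does not name its linkage, and for single
linkage the topology depends only on the similarity ordering, so the
monotone distance conversion is innocuous — a caveat worth remembering for
the other linkages). The merge threshold is swept to the largest height
yielding exactly the requested number of clusters, singletons included;
counts unattainable by any threshold (ties) raise an error listing the
attainable counts.

## What the simulators emulate — and what they do not

`observer_model()` is exactly the response model the fit assumes, so
fit-then-recover round trips test the estimation machinery, not auditory
realism. `simulate_cohort_scores()` draws overall scores from the
two-Gaussian model and derives per-SNR scores through a logistic-in-SNR map
whose horizontal offset tracks the participant's latent ability (slope 2 dB,
per-SNR jitter 0.5 dB — chosen as plausible word-recognition growth rates;
the source publishes only aggregate cutoffs, not an individual SNR model).
`listening_mode()` encodes the qualitative selectivity claims as per-task
trial accuracies: stereo (0.98, 0.95), mono earphone (0.98, chance),
free-field (0.40, chance).

None of these observers process sound: CMR and BMLD magnitudes are inputs
to the simulators, not predictions, and no auditory-periphery model is
included. Passing simulation-based tests therefore demonstrates that the
pipeline's statistics are correct and internally consistent under its own
assumptions — not that real listeners behave this way, and not that
human-cohort numbers (thresholds near 0.5% F0, 6 ms gaps, 28 µs ITD,
0.8 dB ILD, or the published screening sensitivities) are reproducible
without human data. Problem sizes in the shipped tests — 10⁴-participant
cohorts for cutoff derivation, 10⁵ for the empirical-vs-analytic ROC
comparison, 10⁶ Monte-Carlo draws for the analytic ROC cross-check, 200
replicate fits for coverage — were chosen so Monte-Carlo error sits well
below each assertion's tolerance.

## Known limitations

* The beta-binomial priors and sigmoid approximate, rather than replicate,
  the referenced fitting software; threshold estimates can differ in the
  second significant figure for small datasets.
* Speech corpora are out of scope: word and consonant tasks are exercised
  at the score level, with manifest placeholders standing in for audio.
* The equal-weight pooling fallback makes cross-study effect sizes
  comparable only up to the unknown reference-group sizes.
* The WAV codec is deliberately minimal (RIFF float32/PCM16, single data
  chunk) — sufficient for the synthesis pipeline's round trips, not a
  general-purpose audio reader.
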