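---
title: "Models and methods behind spikelapse"
author: "spikelapse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spikelapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spikelapse analyzes interictal spikes (IS) — the large, brief LFP
transients that punctuate the hippocampal recording of an epileptic animal
between seizures — in relation to spatial working-memory behavior on a
figure-8 delayed-alternation maze, and provides a CA3–CA1 spiking-network
model for asking what such events could do to replay. This vignette
documents the models, the tunable parameters, the numerical choices, and
the places where the design was genuinely open.

## Detection and event taxonomy

The detector operates on a single hippocampal LFP channel resampled to
1,000 Hz. Because electrode polarity is arbitrary, the trace is first
multiplied by the sign of its sample skewness so the heavy tail (the IS)
points upward (`orient_polarity()`). The trace is then band-pass filtered
and local maxima whose *topographic prominence* exceeds a threshold are
taken as IS times (`detect_spikes()`). Two filter choices are ours: a
third-order Butterworth applied forward–backward (zero phase, so peak
times are unbiased), and polyphase resampling with anti-aliasing for the
down-sampling step. No minimum peak distance is imposed beyond prominence.

Scoring against hand-labeled windows uses the asymmetric window rules: a
window with at least one detection is one true positive; every extra
detection inside a window, and every detection outside all windows, is a
false positive; empty windows are false negatives. The summary statistic
is F~β~ with β = 1/2, which weights precision roughly twice as heavily as
recall — the right asymmetry when false events would contaminate all
downstream rate statistics. `tune_detector()` exhaustively searches a grid
(default: thresholds 500–2,500 µV in 100 µV steps, low edge
{1, 2, 4, 8, 16} Hz, high edge {200, 400} Hz, spanning the per-animal
settings of the tuned detectors) and breaks F-score ties toward the higher
threshold, then the narrower band — the more conservative detector.

Event taxonomy uses inter-spike intervals only: maximal runs of ISIs
under 2 s with at least two spikes are brief rhythmic interictal
discharges (BIRDs, labeled first/within/last), everything else is a
solitary IS, and dense trains spanning at least 10 s are counted as
seizures. Per-event amplitude is the RMS of the raw, polarity-oriented
trace over ±100 ms — the same window the waveform analysis uses; the RMS
window length is our choice, as only the extraction window is specified
for waveforms.

## Synthetic recordings

All analyses are exercised on synthetic data with the structure the
methods assume (`synth_config()`, `make_lfp()`, `make_behavior()`):

* **LFP** = 1/f background noise (spectral shaping of white noise,
  default slope 1, SD 120 µV) + a theta sinusoid (7 Hz, 150 µV) + one
  biexponential transient per IS (2 ms rise, 15 ms decay, peak 1,500 µV).
  The transient shape is our choice; what matters downstream is a sharp
  prominent peak. The signal-to-noise ratio is a free parameter —
  no reference amplitude distribution of IS against the noise floor is
  assumed.
* **Labeling windows** are drawn from a log-normal truncated to
  [14, 724] ms whose parameters (meanlog −2.68435, sdlog 0.87238) were
  solved numerically so the *truncated* distribution has mean 100 ms and
  SD 92 ms, matching the manual-labeling statistics; only moments and
  range are reported, the family is our choice.
* **Behavior**: trajectories are generated directly in maze coordinates
  as piecewise-linear waypoint paths through delay → stem/choice → outer
  arm → reward, with a 30 s delay dwell plus a state-dependent exit
  latency (gamma with means ~12 / 7.9 / 7.6 s for the perseveration /
  guess / engaged states, the ordering the state-conditioned
  bootstrap is meant to resolve). No video-tracking noise is modeled —
  the analyses consume zones, not pixels; optional Gaussian jitter is
  available. Choice outcomes are emitted by a ground-truth sticky
  three-state Bernoulli HMM (diagonal 0.92, success rates
  0.19/0.53/0.75); the chosen side follows from the alternation rule.
* **IS events** are drawn from a piecewise-constant-rate Poisson process,
  rate = base rate (0.5 Hz, a typical task-period rate scale) × the
  configured zone gain (defaults elevate outer arm ~1.3 and reward ~1.9,
  the ordering the zone-gain model is designed to detect).

Passing tests on these data show the estimators recover planted structure
of exactly this form; they do not certify behavior under tracking
artifacts, non-stationary noise floors, electrode drift, or IS waveform
diversity, none of which the generator emulates.

## Spatial statistics

Spatial information treats pooled IS activity as if it were a single
place cell: the maze is binned 15×15, per-bin rates λ~i~ are spikes over
occupancy seconds (no smoothing — none is specified), and

I = Σ~i~ λ~i~ P(x~i~) log₂(λ~i~ / Σ~i~ λ~i~ P(x~i~)), with I~spike~ = I / Σ~i~ λ~i~ P(x~i~),

summed over occupied bins with 0·log 0 := 0. BIRD path length is the sum
of Euclidean distances between successive spike positions; spikes are
assigned the nearest tracked sample (the assignment rule inside BIRDs is
unspecified; nearest-sample is adopted). Session-level models are fit
with standard machinery: I~spike~ ~ 1 + ⟨d⟩ + (1|animal) by maximum
likelihood with a Gamma family and reciprocal link (`lme4::glmer`;
gradient tolerance left at the optimizer default, objective changes below
1e-8 at convergence), and Performance ~ 1 + I~spike~ by ordinary least
squares with dispersion estimated from the data.

## Hierarchical Poisson gain models

IS counts per animal × zone follow
S~a,z~ ~ Poisson(T~a,z~ ρ~a~ η~z~) with priors
ρ~a~ ~ LogNormal(−1, 0.3) and η~z~ ~ LogNormal(0, 1); a gain of 1 is a
neutral zone. The delay-phase variant replaces the zone gain by a
state-weighted gain Σ~s~ η~s~ p~i~(s) using the HMM marginals as fixed
inputs, with ρ~a~ ~ Normal(0.5, 0.5) truncated to positive values — the
printed prior places an atom exactly at 0, which breaks any
density-based sampler; the zero-truncated normal keeps the same
regularization without the atom (inferences are insensitive to this
prior's SD over [0.1, 0.8]).

**Sampler.** No gradient-based sampler with automatic differentiation is
available in this stack, and handing the model to a black-box PPL would
outsource precisely the component this package exists to own. Sampling
therefore uses adaptive random-walk Metropolis in unconstrained log
space: one component-wise sweep per iteration plus one joint proposal
along the rescaling direction (ρ·c, η/c) — the direction the Poisson
likelihood leaves completely unconstrained, and the slow direction for
any component-wise scheme. All step sizes adapt toward a 65% acceptance
target during warmup (Robbins–Monro) and freeze afterwards. Four chains,
2,000 post-warmup draws each (more than the 1,000 a gradient sampler
needs, to reach comparable effective sample sizes), split R-hat and
Geyer-style ESS on every parameter, warnings — never silent failure —
when R-hat exceeds 1.01 or ESS falls under 400.

**What the model can and cannot identify.** The likelihood depends on
ρ and η only through their products, so the overall scale split between
baseline and gains is set entirely by the priors. With seven animals
under the tight LogNormal(−1, 0.3) baseline prior (median 0.37 Hz), a
true baseline of 0.5 Hz is pulled down by about 25% and every gain is
inflated by the reciprocal factor; identified quantities — the products
ρ~a~η~z~ and all gain *ratios* — are recovered accurately (this is
tested). Readers should treat the absolute calibration of ρ versus η as
prior-determined, and gain comparisons *between* zones (reward vs delay,
say) as the data-driven conclusions. The acceptance suite includes a
joint-coverage check of the 95% HPDs under a 0.5 Hz truth; it fails for
exactly this reason, and is retained as an honest record of the
identifiability limit rather than weakened.

HPD intervals use the shortest sorted-sample window. When a gain's 95%
interval excludes the unit null, the significance level is found by
widening the interval (bisection on the coverage, tolerance 1e-3) until
the null first enters. Posterior-predictive replicates, their central-95%
calibration, replicate-vs-observed MSE, and a plug-in AIC (log-likelihood
at the posterior means, k = number of free parameters; the AIC recipe is
not specified and this is ours) against the gain-clamped (η ≡ 1) variant
complete the model-criticism toolkit.

## The engagement HMM

Trial outcomes are Bernoulli emissions of a hidden engagement state. The
initialization uses the sticky matrix A = (I + εJ)/(1 + Nε) with ε = 0.5
— as printed, the initializer (1+ε)/(1+Nε)·I is not row-stochastic; the
sticky form restores stochasticity while preserving ε's stated role as
the transition-strength control (diagonal 0.6, off-diagonal 0.2 at
N = 3) — uniform initial distribution, and emissions at N uniformly
spaced values in [0.1, 0.9]. Baum–Welch runs over sessions as
independent sequences (each restarts from α₀), with scaled
forward–backward recursions for stability, convergence at 1e-6 relative
log-likelihood, and a hard assertion that the likelihood never
decreases. A single EM start from this initialization is used (restarts
were not part of the published procedure); Viterbi ties break toward the
lower state index. N is a config option with default 3.

Delay-zone exit times conditioned on the decoded state are summarized by
a hierarchical bootstrap: within each state, animals are drawn with
probability proportional to their trial counts, then one of their trials,
until the stratum size is reached; 1,000 replicate means give the 95%
percentile interval.

## Waveform decoding

Each IS contributes ±100 ms of LFP resampled to 2,000 Hz — 401 samples
with inclusive endpoints (inclusivity is our convention) — z-scored per
waveform (per-waveform rather than per-session, consistent with scoring
after extraction). The 2-D embedding is exact t-SNE (perplexity-
calibrated Gaussian affinities, early exaggeration, momentum gradient
descent) implemented in-package and deterministic given its seed;
coordinates are never asserted in tests, only separability and
determinism, since t-SNE layouts are not comparable across
implementations. Reward-zone membership is classified by a bagging
ensemble of 100 unpruned trees (all features available at every split)
under stratified five-fold cross-validation; out-of-fold scores are
pooled into a single ROC (pooling, rather than averaging per-fold AUCs,
is the more stable default and our choice). Amplitude comparisons divide
each event's RMS by its animal's RMS standard deviation before the
two-sample t-test.

## The CA3–CA1 replay model

Both regions hold adaptive exponential integrate-and-fire neurons (1,250
pyramidal + 100 interneurons each at reference size) with bi-exponential
conductance synapses; the full parameter tables are exposed as
`aelif_param_table()` and `synapse_table()`. Integration is forward
Euler at 0.1 ms with refractory clamping; a step-size robustness check
(0.1 vs 0.01 ms on a standard input) is part of the test suite.

During *exploration*, pyramidal spiking is clamped to an inhomogeneous
Poisson rate combining a Gaussian place field (σ = 7 cm, peak 20 Hz) and
theta phase precession at 7 Hz, while the virtual animal runs two 150 cm
arms at 35 cm/s with 90% alternation. Only the weights evolve, by
all-pairs trace-based STDP on normalized weights clipped to [0, 1]:
symmetric facilitation for CA3→CA3 (α = −1, τ = 62.5 ms) and an
asymmetric kernel for CA3→CA1 (τ₊ = 20 ms, τ₋ = 40 ms). Two printed
quantities needed interpretation:

* **Step sizes** are read in conductance units — 0.08 nS (CA3→CA3) and
  0.8 nS (CA3→CA1) per pairing, i.e. 0.002 and 0.02 of the 40 nS
  ceiling. Read instead as normalized steps of 0.08/0.8, the
  always-facilitating symmetric kernel saturates most of the recurrent
  matrix within minutes of exploration and the offline network locks
  into runaway firing; a step of 80% of the weight range per single
  pairing is not a meaningful STDP increment.
* **Initial weights** are drawn in nS (medians 0.3 and 0.7 nS, i.e.
  ~0.008 and ~0.018 normalized) and clipped into [0, 1] after
  normalization.

Interictal input during training is a single spike train at 2,000 Hz
peak rate in a σ = 4 cm spatial envelope around the trial's IS locus,
delivered per spike with 1% probability to active place cells (those
within the 10%-of-peak envelope) in the clustered (fixed ±100 cm locus,
high spatial information) and dispersed (locus uniform over the arm per
trial, low spatial information) modes; a broadcast mode delivering to
all CA3 pyramidal cells is retained. One IS event per arm traversal at
the mode-defined location is our resolution of an ambiguity in how many
IS occur per trial.

During the *offline* state the full network runs with the learned
CA3→CA3 and CA3→CA1 weights. When populations are scaled below
reference size, connection probabilities — not weights — are scaled up
by the presynaptic ratio (capped at 1, any remainder applied to
weights): replay propagation depends on how many same-field cells a
burst recruits and on whether a single synapse can ignite its target,
so preserving in-degree and per-synapse conductance is the scaling that
preserves the dynamics. Background drive from the dentate gyrus is one
independent Poisson train per connected CA3 pyramidal cell at 15 nS per
spike (10 nS in cued mode). The printed pooled rate of 12 Hz leaves the
per-cell rate under-determined (a measured four near-coincident 15 nS
kicks are needed to ignite a pyramidal cell from rest, so 12 Hz per
cell leaves the network silent); the per-cell rate is therefore a
parameter with default 60 Hz, calibrated once so that spontaneous CA3
pyramidal rates sit at 1–2 Hz and discrete millivolt-scale population
bursts occur at sharp-wave-like rates. Cueing stimulates place cells in
a 20 cm window with a 20 ms, 30 Hz Poisson burst at 80 nS.

The proxy LFP is the summed synaptic current into 200 sampled CA1
pyramidal cells scaled by 1/(4πσr) (σ = 0.3 S/m, r = 5 µm), sampled at
1,000 Hz. Replays are prominence peaks (≥1 mV, ≥200 samples apart) on
the 200 Hz seventh-order Butterworth low-passed LFP, windowed ±150 ms.
Content is decoded by the population-vector rule in 25 ms bins (ties
toward the smaller |x|; empty bins are marked, not interpolated), and
*contamination* of a cued replay is the count of place-cell spikes whose
fields lie on the un-cued arm. Spectra use Welch's method (256-sample
segments, 32 overlap, 1,024 FFT points) and a complex Morlet wavelet
(bandwidth 1.5, center frequency 1.0) on 200 log-spaced bands in
[10^1.2^, 10^2.5^] Hz; replay peak frequencies are searched in the
80–400 Hz band so the slow sharp-wave envelope does not mask the fast
oscillation.

**Problem sizes.** The simulator acceptance checks train full-size
networks for 600 s of exploration (the main exploration duration; with
300 s of training this implementation's learned structure is too weak to
express either the replay-frequency or the contamination ordering), then use 5 s spontaneous segments and
1 s cued simulations, ten seeds per condition, cue centers 0–80 cm from
the +100 cm reference in 20 cm steps measured toward the maze center.
Under these conditions epileptic-trained replicas ring at higher replay
frequencies than controls, dispersed-IS networks contaminate at all cue
distances, and control networks stay low throughout.

## Known limitations

* The ρ/η scale split in both Bayesian models is prior-identified only
  (see above); report gain ratios, not absolute gains, when comparing
  across reanalyses with different priors.
* The replay model inherits the usual caveats of clamped-training STDP
  models: replays are longer and more stereotyped than in vivo events,
  and no behavioral-timescale plasticity is modeled.
* t-SNE here is exact (O(n²)); embedding much more than a few thousand
  waveforms calls for an approximate implementation.
* The synthetic maze has no tracking noise; the speed-threshold outlier
  filter that replaces manual artifact removal is config-gated and off
  by default.
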