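---
title: "Inferring latent behavioural states from pre-stimulus facial features"
author: "facestates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring latent behavioural states from pre-stimulus facial features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facestates)
```

## The model

Animals performing the same task drift through internal states —
engagement, disengagement, habit — that are not directly observable but
leave traces in spontaneous behaviour. This package models the
trial-by-trial relationship between pre-stimulus facial features and
reaction time (RT) as a Markov-switching linear regression (MSLR): a
discrete latent state $z_t \in \{1,\dots,S\}$ evolves as a first-order
Markov chain,

$$P(z_{t+1} = j \mid z_t = i) = \pi_{ij},$$

and, given the state, the RT is a linear function of the $M$-dimensional
facial-feature vector $x_t$ plus Gaussian noise:

$$y_t \mid z_t, x_t \sim \mathcal{N}(W_{z_t} x_t + b_{z_t},\ \Sigma_{z_t}).$$

Each state is a distinct *rule* linking face to behaviour: its weight
vector $W_s$ says which facial features speed or slow the upcoming
reaction while the animal is in that state. The emission here is the
scalar RT, so $\Sigma_s$ degenerates to a variance; the code keeps the
per-state variance vector and the contracts would extend to vector
emissions.

### Priors on the transition matrix

Transition rows carry a sticky Dirichlet prior: concentration $\alpha$
on every entry and an extra $\beta$ on the diagonal. $\alpha$ controls
row sparseness; $\beta$ biases self-transitions, encoding the
observation that behavioural states persist over many trials. Both are
pseudo-counts in $[0, 100]$ in the search interface. The M-step uses the
MAP form: row $i$ of the updated matrix is proportional to the expected
transition counts plus $(\alpha - 1)$ everywhere and $(\beta - 1)$ on
the diagonal, clipped at zero before normalisation. With
$\alpha = \beta = 1$ this reduces to expected-count normalisation.

### Fitting

`fit_em()` runs expectation-maximisation: the E-step is scaled
forward-backward smoothing (compiled code; exact marginal likelihood),
the M-step solves a responsibility-weighted least-squares problem per
state and applies the MAP transition update. Following standard
practice for switching models, each of the 10 restarts draws weights
and biases from a standard normal, initialises the emission variance at
1 (the scalar analogue of an identity covariance) and the transitions
at the sticky-prior mean, runs 50 iterations, and the restart with the
highest final marginal log-likelihood wins.

Two numerical points deserve note:

* **Monotonicity.** MAP-EM monotonically increases the *penalised*
  objective (log-likelihood plus the transition log-prior), not
  necessarily the raw likelihood. `fit_em()` returns both traces;
  under the flat prior they coincide and the raw trace is monotone.
* **Variance floor and dead states.** Emission variances are floored at
  `1e-6` so a state cannot collapse onto a single trial, and a state
  whose total responsibility falls below `1e-8` is re-seeded from a
  fresh normal draw rather than deleted, preserving $S$.

### Sessions

Training sessions are concatenated with 50 zero-valued padding trials
between them (predictors and emissions 0, flagged), which forces the
state probabilities to reset across session boundaries while keeping a
single chain. The alternative — dropping the padding and re-initialising
the chain to the uniform distribution at each session start — is
available via `session_reset = "reset"`; the suite checks both give the
same posteriors on real trials to within a small tolerance. Padding
trials are excluded from every downstream statistic.

### Prediction

`mslr_predict()` computes the smoothed posterior over states given all
data of a segment (including its emissions) and predicts
$\hat y_t = \sum_s p(z_t = s \mid \text{data}) (W_s x_t + b_s)$. Each
trial is assigned to its most probable state for the discrete analyses.
Because inference conditions on the emissions, chance levels must come
from a surrogate rather than from intuition (below).

## Reaction times from trajectories

RT is defined as the onset of the first substantial lateral deviation
of the virtual-movement trajectory; forward movement is ignored. The
detector slides paired windows over the lateral track (sizes 100, 150,
200, 250 ms; stride one sample): a line fitted to the first window is
extrapolated onto the second and scored with $R^2$ there. A deviation
from straight movement makes the extrapolation fail, so candidate turn
points are prominence-filtered local maxima of $-R^2$, and candidates
from all window sizes are fused by summing Gaussian bumps
($\sigma = n_w/4$ samples, truncated at $3\sigma$) and taking the
argmax of the fused weight divided by the 1-based sample index — a time
decay that prefers the earliest well-supported deviation.

Three hardening choices matter in practice, all exposed in
`detector_config()`:

* **Regularised $R^2$** (`regularize`, default 0.02). The textbook
  ratio is scale-free in the window-local noise: on any noise-only
  segment it produces dips as deep as a genuine turn, at *any* noise
  amplitude. The denominator is therefore padded with
  $0.02\, n_w \widehat{\mathrm{Var}}$ of the globally detrended track,
  so a dip registers only when the deviation is substantial at the
  scale of the trajectory's overall movement — which is what a directed
  reaction is. Detrending keeps the series exactly invariant under
  affine shifts of the track.
* **Relative prominence** (`rel_prominence`, default 0.5). Candidates
  must reach half the prominence of their window's strongest deviation;
  incidental slope changes are minor next to the actual turn. The
  absolute threshold $\lambda_0 = 0.05$ is interpreted as a fraction of
  the $-R^2$ dynamic range — the only scale on which its exact value is
  uncritical.
* **Displacement gate** (`min_displacement`, default 0.5 lateral
  units). Stimuli sit at a fixed lateral offset in the task geometry; a
  genuine approach displaces the track by a substantial fraction of
  that offset, postural drift does not. Trajectories failing the gate
  return an undefined RT (`NA`, never a sentinel), read downstream as
  "no directed reaction".

On noiseless fixtures the detector localises kinks within one largest
window; across 200 fixtures with smooth drift noise graded up to 10% of
the post-turn displacement it stays above 95% detection inside the same
tolerance, with no false alarms on turn-free tracks (these are suite
properties).

## Facial features

`build_trial_features()` summarises the 250 ms window before each
stimulus onset: per landmark the median x and y position and the total
velocity (mean per-frame Euclidean displacement), plus the median pupil
size. The window precedes the stimulus so expressions reflect
internally generated processing. Frames with landmark confidence below
0.6 are dropped from that landmark's medians; features left undefined
are imputed with session medians so the MSLR's fixed-$M$ contract
holds. Window sizes of 200–500 ms give tables of identical shape. The
pupil is z-scored with training-set statistics
(`zscore_pupil()`); `zscore_features()` applies the same treatment to
every feature so regression weights are comparable across features —
the package default in the pipeline, flagged as configurable because
non-pupil features could also be left on their native scales.
Synchronisation with the recording uses infra-red flash timestamps
(`detect_sync_flashes()`): a burst of five flashes within a second
marks the session start, isolated flashes mark trials.

## Model selection

The chronologically last 20% of each session is held out
(`split_train_test()`). Hyperparameters are tuned on the training set
with 5-fold time-blocked cross-validation: folds are contiguous blocks,
so temporal dependence is respected; repetitions differ in restart
seeds. Held-out performance is $R^2$ on the fold's trials.

The number of states is chosen from the CV curve by the largest finite
difference $R^2(S) - R^2(S-1)$ — the point of greatest marginal gain
before the curve saturates — with ties toward fewer states
(`select_n_states()`). An alternative reading (largest absolute second
difference) is a one-liner on the returned curve; the first-difference
rule is the default. $\alpha$ and $\beta$ are searched over $[0,100]^2$
with a pluggable backend (`hyperparam_search()`); the default spends
70% of the budget on seeded uniform exploration and the rest on
Gaussian refinement around the incumbent. An evolutionary-strategy
backend can be plugged in through the same signature.

### Chance floors

Because state inference conditions on the emissions, a "shuffled"
control that re-runs inference on shuffled emissions is *not* at
chance — it stays positively correlated with its own target. The
surrogate therefore fixes the model's predictions (computed from the
real data) and scores them against shuffled emissions
(`surrogate_performance()`, 500 shuffles): the resulting $R^2$
distribution is centred below zero, and its 99th percentile is the
floor real performance must clear.

## The recovery experiment

`recover_states_experiment()` is the pipeline's end-to-end validation
with known ground truth:

1. simulate ~4000 trials from a seeded 5-state MSLR (AR(1) features,
   $M = 10$);
2. deliberately overfit with $S = 10$;
3. merge redundant states: per state, the histogram of its predicted
   emissions over all trials (Freedman–Diaconis bins on shared edges),
   pairwise Jensen–Shannon distances, average-linkage hierarchical
   clustering cut at a shuffle-surrogate threshold;
4. refit at the selected state count;
5. score recovery as the optimally matched correlation between one-hot
   encodings of the true and inferred state sequences, masking entries
   below the 99th percentile of a shuffle surrogate of that
   correlation.

Two details are easy to get wrong:

* **The Jensen–Shannon surrogate.** Histograms are invariant to
  permuting a series, so "shuffle and re-histogram" would produce a
  degenerate null. The null here shuffles one state's
  predicted-emission series, splits it in half, and measures the JS
  distance between the two half-histograms — the sampling noise of the
  JS distance between histograms drawn from one and the same
  distribution. States closer than the 95th percentile of this null
  (the middle of the 90–99 band; the result is insensitive across the
  band) are indistinguishable and merge.
* **Unused states.** Maximum-likelihood EM with twice the necessary
  states reliably spends surplus capacity memorising a handful of
  trials each ($M = 10$ regressors interpolate up to 11 points
  exactly, and the variance collapses to the floor). A state that is
  the most probable on fewer than 1% of trials represents no
  behaviour; such states are excluded from the clustering
  (`min_occupancy`). Genuine states occupy around 800 trials each
  under the near-uniform stationary distribution of the sticky chain,
  two orders of magnitude above the cutoff.

With the default conditions the experiment selects exactly 5 states and
the matched diagonal correlations exceed 0.95 (the masked threshold is
about 0.04), across seeds.

## What the generator emulates — and what it does not

`make_ground_truth_params()` + `generate_facial_inputs()` +
`sample_mslr_dataset()` define the study conditions:

* predictors are stationary AR(1) series (lag-1 coefficient 0.3) with
  unit marginal variance, emulating slow trial-to-trial facial drift,
  standardised before emission sampling as the real features are;
* per-state weights are $\mathcal{N}(0, 1)$ per feature
  (`weight_scale = 1`), biases $\mathcal{N}(0, 2^2)$ with a minimum
  pairwise gap of 1.5 enforced by rejection, alongside a minimum
  distance between full $(W_s, b_s)$ vectors. The bias gap is what
  makes states *identifiable from their emission distributions alone*:
  behavioural states differ foremost in their characteristic RT level
  (fast engaged responses versus slow disengaged ones), with facial
  features modulating RT within a state. Without distinct levels, no
  emission-histogram clustering could separate duplicated from distinct
  states — marginal emission distributions only expose the bias and
  the weight norm;
* transitions come from the sticky prior with $\alpha = 1$,
  $\beta = 20$ (mean self-transition $\approx 0.84$, dwell times of a
  few to tens of trials); emission noise SD is 0.3, roughly a third of
  the within-state feature-driven spread;
* trajectories are piecewise linear with smooth Gaussian drift noise
  (correlation time 1 s): virtual positions are integrated trackball or
  treadmill movements, band-limited by the physics of moving — not
  frame-wise jitter.

The generator does not emulate: landmark-tracking noise or dropped
frames (features arrive clean), skewed RT distributions (emissions are
conditionally Gaussian, as the model assumes), input-driven transitions,
session-to-session parameter drift, or class imbalance in outcomes.
Passing tests therefore show that the machinery recovers what the model
can represent under realistic sizes and noise — not that real faces obey
a switching linear model.

## Problem sizes and runtime choices

The suite runs its recovery checks at 3000–4000 trials with 3–5 states
and 3–10 features, CV checks at 300–1200 trials, and the trajectory
properties over 200 fixtures — sizes at which every statistical margin
in the assertions is comfortable while the whole suite stays fast. The
recovery experiment itself (two EM fits at 10 restarts x 50 iterations,
plus 1000 surrogate shuffles) takes well under a minute.

## Known limitations

* The one-dimensional emission keeps $\Sigma_s$ scalar; vector
  emissions would need a covariance update in the M-step.
* The MAP transition update with $\alpha, \beta < 1$ relies on clipping
  at zero; the penalised-objective monotonicity guarantee holds for
  $\alpha, \beta \ge 1$.
* State matching uses exhaustive assignment up to $S = 8$ and a greedy
  fallback beyond; for the experiment's $S = 5$ the exact optimum is
  always found.
* The hyperparameter search backend is a seeded random+refine scheme;
  it reproduces histories bit-for-bit under a fixed seed but makes no
  claim of sample-efficiency against dedicated optimisers.
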