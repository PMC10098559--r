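---
title: "Wrapper-based metaheuristic feature selection for fNIRS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper-based metaheuristic feature selection for fNIRS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

An fNIRS brain–computer interface records slow oxyhemoglobin (ΔHbO)
fluctuations on tens of channels while a participant performs cued tasks
(motor imagery, mental arithmetic, rest). Decoding reduces each 10-s task
window to a handful of temporal statistics per channel; with 36 channels and
5 statistics that is a 180-dimensional feature vector per trial, of which
only the features on task-responsive channels carry information. With 20
trials per session the classifier is starved: distances in the full feature
space are dominated by noise dimensions. Wrapper feature selection treats the
classifier itself as the evaluation function and searches the space of
feature subsets for the one that classifies best with the fewest features.
`nirselect` implements that search with seven continuous population
metaheuristics and all the machinery needed to test them.

# Pipeline and conventions

## Synthetic sessions

`generate_session()` emulates a standard block paradigm: 60 s pre-rest, then
for each trial a 2-s cue, a 10-s task phase, and a rest drawn uniformly from
15–17 s (seeded per trial), then 60 s post-rest; 10 trials per class in
shuffled order; 36 channels sampled at 12.5 Hz. Triggers mark task onsets.

The signal model is

* **activation** — a boxcar over the task phase convolved with a gamma-shaped
  hemodynamic response function (shape 6, peak at 6 s, 20-s support, unit
  peak), added on each class's *informative channels* and scaled by
  `amplitude`;
* **noise**, on every channel — linear drift (0.01 units/min), Mayer waves
  (0.1 Hz, amplitude 0.2), respiration (0.25 Hz, 0.1), cardiac pulsation
  (1 Hz, 0.1) with per-channel random phases, and white noise (sd 0.2).

Units are arbitrary concentration units; only ratios matter. The default
amplitude of 0.5 places the response at the scale of the physiological noise:
with these defaults a full-feature k-NN scores roughly 75–85% on a default
session, the regime reported for real single-session recordings, rather than
saturating at 100%. This was fixed once, before the acceptance suite was
frozen, and is the key knob a user should revisit for harder or easier worlds.

What the generator does **not** emulate: optode geometry and scalp coupling,
motion artifacts, ΔHbR, trial-to-trial amplitude variability, and spatially
correlated noise. A green test on synthetic data therefore establishes that
the pipeline recovers planted structure under a plausible noise model — not
that any particular accuracy will be achieved on real recordings.

The oscillation frequencies were chosen so that the band-pass below visibly
suppresses the cardiac and respiratory components while Mayer waves, at the
low-pass corner, are only partially attenuated — the realistic nuisance.

## Preprocessing

Conditioning follows the standard recipe: down-sample 12.5 Hz → 10 Hz, then a
3rd-order Butterworth low-pass at 0.1 Hz and a 3rd-order Butterworth
high-pass at 0.01 Hz, then epoch `[0, 10)` s from each trigger.

Numerical choices:

* No DSP package ships with this R stack, so the Butterworth design is done
  from first principles (analog prototype poles, frequency pre-warp, bilinear
  transform); the coefficients match `scipy.signal.butter` to printed
  precision.
* Each filter is applied **zero-phase** (forward–backward with odd-reflection
  padding sized to ~18 time constants of the high-pass corner). Phase
  distortion would shift statistics within the 10-s window; the price is a
  doubled effective order, i.e. the realized magnitude response is the square
  of the single-pass response. A causal single-pass mode is available
  (`filter_spec(zero_phase = FALSE)`).
* Filtering is applied to the continuous recording *before* epoching, so edge
  transients fall into the rest periods.
* Resampling is polyphase windowed-sinc (10 half-lobes, Hamming window), with
  each polyphase branch normalized to unit DC gain so constant signals are
  preserved to machine precision. Trigger onsets are rescaled and rounded
  half-up.
* Sample indices are 1-based (the R convention); epoch windows are half-open
  `[start, end)` seconds relative to the trigger.

## Features

Five statistics per (trial, channel) window: mean, peak (maximum), slope of a
least-squares line with time in **seconds**, skewness, and kurtosis. Skewness
and kurtosis are population-moment ratios (divide by N, σ in the
denominator); kurtosis is the raw fourth standardized moment, so a Gaussian
signal has kurtosis 3. A constant window makes them undefined and raises an
error naming the (trial, channel). Columns are channel-major (five statistics
of channel 1, then channel 2, ...), recorded in the table header so masks are
portable.

## The wrapper cost

A continuous position in [0, 1]^D is thresholded at 0.5 (strict `>`) into a
mask. Non-empty masks are scored as

$$J = \alpha\,(1 - \text{Accuracy}) + \beta\,\frac{n_{selected}}{D},
\qquad \alpha = 0.99,\ \beta = 0.01,$$

where Accuracy is the k-NN (k = 5, Euclidean) accuracy on one stratified 0.2
holdout split. Empty masks score the worst cost 1.0 rather than being
repaired, which leaves the search space untouched and strongly repels the
degenerate solution. The split is drawn once per optimizer run (seeded from
the run seed via a counter-based derivation) and reused for every evaluation,
so the cost landscape is static and convergence curves are meaningful.
Features are fed raw by default, matching common wrapper-toolbox behavior; a
z-score-on-training-statistics option exists (`cost_spec(standardize=)`).

k-NN tie rules are pinned for bit-exact reproducibility: neighbors are
ordered by distance with ties broken by training-trial index, and vote ties
go to the alphabetically smallest class label. The accuracy used during the
search is the holdout-test accuracy itself (one split; no separate validation
share).

`exhaustive_oracle()` enumerates all 2^D − 1 masks (refusing D > 12), with
ties broken by fewer features and then the lexicographically smaller bit
vector. It is the ground truth against which every optimizer is tested.

# The seven optimizers

All algorithms share the run contract of `run_optimizer()`: N positions
initialized uniformly in the box, T iteration steps, positions clamped (not
reflected) into [0, 1] after every move, every evaluated mask recorded, and
the best mask ever evaluated returned (elitism), so the best-cost curve is
non-increasing by construction. Cost evaluations are cached per mask — the
cost is a pure function of the mask given the fixed split. Defaults T = 100,
N = 10; each algorithm's tunables (`default_params()`) follow the published
configuration for this wrapper framework unless noted.

* **PSO** — velocity update
  `v ← w·v + c1·b1·(pbest − x) + c2·b2·(gbest − x)` with per-dimension
  uniform draws b1, b2. The published parameter set for this framework
  (inertia 2, c1 = 1, c2 = 2) makes the velocity recursion divergent —
  |v| grows geometrically and particles pin to box corners; in our oracle
  benchmark it finds the known optimum in only 7/20 runs. The default is
  therefore the conventional convergent preset (inertia decaying 0.9 → 0.4,
  c1 = c2 = 2, velocity clamped to ±0.5 box widths, asynchronous global-best
  update); the literal values remain available via
  `params = list(preset = "literal")`.
* **CSO** — each cuckoo proposes `x + α·Levy(λ)` (Mantegna scheme, λ = 1.5),
  which replaces a randomly chosen nest if strictly fitter; then the worst
  ⌊Pa·N⌋ nests (Pa = 0.25) are abandoned and re-seeded by Lévy steps from
  surviving nests.
* **FA** — every firefly moves toward each brighter one by
  `β0·exp(−γ r²)·(xj − xi)` plus a random term `α·ε`, ε ~ U(−0.5, 0.5) per
  dimension (the conventional choice; the source leaves ε unspecified); the
  brightest firefly performs only the random walk.
* **BA** — frequency `f = fmin + (fmax − fmin)·β` with β ~ U(0, 1),
  velocity `v ← v + (x − x*)·f`, candidate `x + v`; with probability r_i the
  candidate is instead a local walk `x* + ε·mean(A)`, ε ~ U(−1, 1). The
  candidate is accepted when `rand < A_i` **and** it strictly improves the
  bat's own fitness (the wrapper-toolbox convention; gating on the global
  best instead freezes the population — 3/20 vs 20/20 oracle hits); on
  acceptance loudness decays (A ← 0.9A) and the pulse rate is set to
  `0.5·(1 − exp(−0.9 t))`. Initial loudness 2, initial pulse rate 0.5.
* **FPO** — with probability p_switch = 0.8, global pollination
  `x ← x + α·L(λ)∘(g* − x)` with a per-dimension Lévy step; otherwise local
  pollination `x ← x + ε·(xj − xk)` with distinct random flowers j, k and
  scalar ε ~ U(0, 1); greedy per-flower acceptance (strict improvement).
  The pseudocode's switch inequality is read in the conventional direction
  (global pollination is the frequent branch).
* **WOA** — control `a = 2(1 − t/T)`; coefficient vectors `A = 2a·r − a`,
  `C = 2r` drawn **per dimension** (as in the algorithm's reference code;
  scalar coefficients markedly weaken the search), with the shrinking
  encirclement branch decided on mean |A|: encircle the best, move relative
  to a random whale, or spiral `|x* − x|·e^{bl}·cos(2πl) + x*` with b = 1,
  l ~ U(−1, 1).
* **GWO** — control `a = 2 − 2t/T`; per wolf and dimension,
  `A = 2a·r1 − a`, `C = 2·r2`, distances `D_L = |C∘x_L − x|` to the three
  best-ever solutions (alpha, beta, delta), candidates `x_L − A∘D_L`,
  averaged. The absolute-value bars in the published leader-candidate
  equations are read as applying to the distance terms only — the standard
  grey-wolf update; reading them as absolute values of the candidates has no
  precedent and would confine wolves to the positive orthant.

Per-dimension versus scalar random draws follow each algorithm's reference
formulation and are noted above where they differ from the published symbol
list. Iteration accounting: one initial evaluation sweep plus T step sweeps;
CSO and BA evaluate extra candidates (abandonment, local walks), and the
`evaluations` field of a `run_result` records the exact count.

# Evaluation machinery

`repeat_runs()` launches n_runs = 10 runs with seeds base+1 … base+n, and
summarizes holdout accuracy (%) and selected-feature count as mean and
sample (n−1) sd; all per-run results are retained so every printed mean ± sd
is exactly recomputable. `full_feature_baseline()` scores the all-ones mask
with the identical split machinery. Significance uses the Welch
(unequal-variance) two-sample t-test — the safer default given unequal run
variances; a pooled-variance option exists. Zero-variance edge cases are
handled by convention (equal means → p = 1). `compare_algorithms()` assembles
the per-algorithm table plus pairwise tests; reports serialize to JSON with
per-run masks and curves intact. Wall-clock times are recorded as
information only — they are hardware-dependent and never part of any check.

# Testing strategy and limitations

The oracle for optimizer correctness is exhaustive enumeration on a D = 8
table with one perfectly separating feature and seven noise features. The
fixture uses 25 trials per class: with only 10 trials per class a 4-trial
holdout can be separated by a noise feature by chance, making the "oracle
optimum = the separating feature" semantics fail. Each algorithm must reach
the oracle minimum in at least 16 of 20 seeded runs and may never report a
cost below it.

Known limitations: the k-NN is the only wrapped classifier (no SVM/LDA);
no cross-validation variants; no binary/discrete metaheuristic variants; the
CSO/FPO Lévy exponent is fixed per run; and the synthetic generator's HRF is
a stand-in — none of the reference datasets' response shapes were fitted.
Reproducing any published accuracy table for real 29-subject recordings is
out of scope: it would require the external dataset and unrecorded RNG state.
What the package's checks do establish is the direction of the headline
effect on synthetic ground truth — selected subsets match or beat the
full-feature baseline at a fraction of the feature count, and the selected
features concentrate on the truly informative channels (grey-wolf runs
exceed the informative-channel base rate more than three-fold).
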