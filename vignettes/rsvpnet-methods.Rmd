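---
title: "Models and methods in rsvpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rsvpnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsvpnet)
```

## The modelling problem

Human observers detect cued target categories in rapid serial visual
presentation (RSVP) streams down to very short image durations. `rsvpnet`
provides the pieces needed to ask whether a recurrent rate network that
processes such a stream *sequentially* — one model step at a time, with
state carried across image boundaries — can account for that behaviour:
how its task sensitivity grows with presentation duration, and how well its
trial-level evidence predicts which particular trials humans find easy or
hard.

A presentation duration is emulated by repeating an image for `n`
consecutive model steps, so a stream of `m` images spans `m × n` steps. The
contrast between *sequential* processing and *single-image* processing
(state reset before every image) is a first-class design axis: the same
network can be run both ways (`run_sequential()`, `run_single_image()`).

## Intrinsic suppression

Adaptation is modelled as activation-based intrinsic suppression on every
rectified unit. A state `s` integrates the unit's own recent activation and
is subtracted, scaled by a gain `β`, from the incoming drive before the
ReLU:

$$a_t = \sigma(b + W x_t - \beta s_t), \qquad
  s_t = \alpha s_{t-1} + (1 - \alpha)\, a_{t-1}.$$

* **Exponential preset**: one decay factor, `α = 0.96`, `β = 0.7`
  (dimensionless; `α` per model step).
* **Power-law preset**: suppression as a *sum of exponentials* with
  `α = (0.96, 0.75)` and a much lower gain `β = 0.15`, compensating for the
  larger summed state. Each channel integrates the same activation with its
  own `(1 − α_k)` input weight — the reading of the sum formula we adopt,
  since the per-channel form is what a sum of independent exponentials
  means; a shared input weight would just rescale `β`.

Two ordering decisions matter numerically and are fixed throughout:

1. **Within a step**, activation is computed from the *current* state, then
   the state is updated from that activation — suppression at `t` reflects
   activity strictly before `t`. The first step of any run is therefore a
   pure feedforward pass.
2. **The stored state is pre-`β`** (raw channel sums); the gain is applied
   at subtraction time, so `β` can be swept without re-simulating.

Consequences used as test anchors: from zero state, non-negative
activations keep every channel non-negative; `β = 0` is bitwise identical
to no adaptation; for constant drive `x` the exponential unit converges to
`a* = s* = x/(1+β)`; the open-loop state admits the closed form
`s_T = (1-\alpha)\sum_{k<T}\alpha^{T-1-k}a_k`; and over long constant
drives the power-law preset loses strictly less activation than the
exponential preset.

## Network architecture

The simulator is a configurable toy: dense rectified layers over the
flattened image (pixels in `[0, 1]`), optional lateral recurrent weights
per layer entering the pre-activation additively
(`drive = b + W_ff x_t + W_lat h_{t-1}`), adaptation on every rectified
layer, and a **linear readout** with no saturating transform and no
adaptation. Two properties motivate the linear readout: it keeps
representational traces smooth across steps, and it makes the readout
exactly homogeneous (doubling the last hidden state doubles the output),
which the tests assert. Normalization statistics are **frozen**:
`freeze_normalization()` standardizes each layer's drive by per-unit mean
and standard deviation computed once from a calibration batch
(feedforward, no recurrence) and never updated, which keeps activity
bounded over long sequences. Weights are seeded Gaussian
(`sd = 1/sqrt(fan_in)`; lateral weights at half that scale so recurrence
perturbs rather than dominates). Convolutional weight sharing is not
implemented: every contract exercised here — recurrence, adaptation,
frozen normalization, linear readout, sequential vs reset processing — is
architecture-agnostic, and dense layers keep the base-R implementation
small and auditable.

## Prototype readout

A trial's cue category is represented in the network's output space by a
prototype `φ`: the arithmetic mean (geometric centre) of the readout states
of the `k` most relevant exemplars of that category, each processed in
isolation (final model step of a 4-step presentation by default; the
exemplar step count is a documented argument). Relevance is the Pearson
correlation between an exemplar's readout and the mean readout of the
trial's target and foil image — whatever target and foil share approximates
the intended category. The metric is a design choice (the similarity used
everywhere else in the package); Euclidean distance is available behind a
flag. `k = 10` is the default, with 50 and 100 as conventional
alternatives.

Representational strength is `p_t = r(φ, y_t)` per step; targets may also
be one-hot vectors or single-image reference states. A zero-variance
readout row yields an `NA` sentinel ("no evidence") rather than an error,
because all-zero rectified outputs do occur in small toy nets; peaks ignore
`NA`s, and sensitivity analyses drop sentinel trials with a logged count.

## Sensitivity and the model–human comparison

Trial evidence is the **peak prototype correlation** `PPC = max(p)` (over
steps in sequential mode, over images in single-image mode). Model
sensitivity converts the separation of PPC distributions into
`d′ = √2 · z(AUC)`. The AUC uses the midrank Mann–Whitney estimator —
exactly the criterion-sweep integral with ties counted half, but `O(n log
n)` and deterministic; the equivalence is asserted against a
threshold-sweep oracle in the tests. Because `z` diverges at 0 and 1, the
AUC is clipped to `[1/(2n+2), 1 − 1/(2n+2)]` before the probit (the clamp
is configurable). Human sensitivity uses the log-linear correction: 0.5
added to every cell, which keeps `d′` finite at perfect and null
performance.

Trial-by-trial predictivity is the Spearman correlation (midranks, no
continuity correction — the natural choice when one margin is a binary
report and the other a continuous PPC) between PPC and the group-average
report rate, computed per (steps-per-image × duration) cell. Uncertainty
comes from bootstrapping **subjects** (a trial bootstrap sits behind a
flag, off by default, since the trial set is fixed in the reference
design), 95%
percentile intervals, with the drawn subject indices stored for exact
reproducibility. Noise ceilings are Spearman-based: upper = mean
correlation of each subject with the `N`-subject average, lower = the same
against the `(N−1)`-subject average; both are computed **per duration**,
matching the per-panel ceilings the analyses display. Temporal
correspondence takes the argmax of ρ over steps per duration, ties resolved
to the *fewest* steps (parsimony and reproducibility); explanatory power is
the mean over durations of best-ρ divided by the lower ceiling, legal above
1, with non-positive ceilings excluded with a warning.

## What the synthetic generator emulates — and what it does not

`synth_config()` defaults encode the reference task structure: streams of 6
images, exactly 25% target-absent trials (stratified as `round(n·p)`, not
sampled — stable fixtures beat binomial jitter), targets uniform over
interior positions 2–5, unique cue categories while the bank permits, four
duration labels (13/40/80/160 ms) cycled over 176 trials, and a panel of 36
observers. Images are category templates (uniform pixel bands around
mid-grey, width `category_signal`) plus Gaussian pixel noise, clipped to
`[0, 1]` — linearly separable by construction at zero noise. Observers
respond "present" with probability
`logistic(gain · (evidence − center) + bias_s)`, with per-subject biases
`N(0, subject_noise_sd)`; a deterministic threshold mode makes zero-noise
panels exactly identical (ceilings of 1). The default latent evidence is
the model's *own* PPC, at the steps condition matched to the trial's
duration rank — which builds a known temporal correspondence into the
panel and enables self-consistency tests in which the generating model
should approach the lower noise ceiling.

What passing tests on these data do **not** show: anything about natural
image statistics, trained representations, or the absolute sensitivity
values real networks reach — toy banks are linearly separable and the toy
network is untrained, so absolute accuracies and d′ values are
deliberately uninterpretable. The synthetic results validate the
*machinery* (dynamics, estimators, pipeline plumbing), not the
neuroscience.

## Numerical choices and problem sizes

* Pure recursions are checked at relative tolerance `1e-10`; quantities
  downstream of rectification chains at `1e-6`; rank statistics against
  independent oracles at `1e-12`–`1e-14` (two algebraically identical
  formulas differ only in summation order).
* The exponential fixed point is approached with contraction factor
  `α − (1−α)β ≈ 0.93` per step; 400 steps give six decimals of headroom.
* Top-k ties break toward the smallest category index; per-image accuracy
  is the within-window mean of per-step correctness, with final-step
  scoring available as a flag (the reference protocol does not pin the
  aggregation down, so both are exposed and neither is asserted as
  canonical).
* Carry-over of a previous image is quantified as the *mean* of its
  representational-strength trace during the next image's window: random
  lateral weights produce oscillatory traces, so onset-to-offset
  differences confound oscillation phase with decay, while the lingering
  mean isolates how much of the old representation survives. With
  adaptation the lingering strength should be lower (faster decay); the
  tests assert the direction by majority vote over 12 seeded networks.
* Test and demonstration sizes are chosen for tight feedback loops: toy
  networks of 2 dense layers (16–32 units), 8×8 images, studies of 16–64
  trials with 8–20 subjects and 15–200 bootstraps, and 10,000 samples per
  class for Gaussian d′ recovery. The reference design (176 trials, 36
  subjects, 1000 bootstraps) remains the generator default.

## Known limitations

* No training: weights are random, so task accuracies are near chance and
  only contrasts (sequential vs reset, adaptation kinds) are meaningful.
* Dense layers only; no convolutional weight sharing, no top-down
  recurrence, no spiking dynamics, and subtractive (not divisive)
  adaptation only.
* Criterion placement (bias) is out of scope: the package estimates
  sensitivity, not `c` or likelihood-ratio `β`.
* Noise ceilings assume exchangeable subjects; panels with structured
  subgroups would need a stratified bootstrap the package does not provide.
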