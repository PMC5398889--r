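---
title: "Reward-modulated Hebbian learning in chaotic rate networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-modulated Hebbian learning in chaotic rate networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
network model, the plasticity rule and the reasoning behind every numerical
choice that the primary sources of the method leave open. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The network model

The canonical network is a fully connected continuous-time rate network of
$N = 200$ neurons,

$$\tau \frac{dx_i}{dt} = -x_i + \sum_{j=1}^{N} J_{ij}\, r_j
  + \sum_{k=1}^{M} B_{ik}\, u_k, \qquad r_i = \tanh(x_i),$$

integrated by explicit Euler steps of $dt = 1$ ms with $\tau = 30$ ms.
$J$ is initialized i.i.d. $\mathcal{N}(0, g^2/N)$ with $g = 1.5$, which
places the autonomous network in the early chaotic regime: activity is
self-sustained and irregular, which is the raw material the learning rule
shapes. $B$ is i.i.d. uniform on $[-1, 1]$ and never learned. Four
arbitrarily chosen neurons (indices 2–5) are clamped to $x = 1$ at every step
and act as bias inputs; one arbitrarily chosen neuron (index 1) is the
output, and its response over the trial's final response window is the
network's answer. Activations are reset to uniform $[-0.1, 0.1]$ noise at
every trial start.

A second, more biologically constrained variant obeys Dale's law: 100
excitatory and 100 inhibitory neurons, a semi-sparse initial connectivity
(each neuron receives 50 excitatory connections of weight 1 and 50 inhibitory
connections of weight $-1.2$), and the nonnegative piecewise-linear response
$r = \min(\max(x + m, 0), M_{sat})$ with $m = 2$, $M_{sat} = 20$. Weight
updates clamp excitatory columns at 0 from below and inhibitory columns at 0
from above, so the sign structure holds at all times.

## The plasticity rule

Exploration comes from random perturbations: each non-bias neuron receives,
at a mean rate of 3 Hz, an additive kick to $x$ drawn uniformly from
$[-0.5, 0.5]$. Perturbations are on in every simulation, during learning and
during testing/decoding alike.

Each synapse accumulates a potential weight change over the trial,

$$e_{ij}(t) = e_{ij}(t-1) + S\!\left(r_j(t-1)\,\big(x_i(t) - \bar{x}_i(t)\big)\right),$$

where $\bar{x}$ is a fast exponential running average of the activation and
$S(v) = v^3$ amplifies large co-fluctuations (the perturbations) over small
ones (the relaxation of $\bar{x}$ back to the signal, whose contributions
would otherwise cancel the perturbation terms — the package's gradient
laboratory quantifies this). At the end of the trial the reward
$R = -\text{error}$ is compared with a per-trial-type expectation
$\bar{R}$, and

$$\Delta J_{ij} = \eta\, e_{ij} (R - \bar{R}),$$

clipped elementwise at $10^{-4}$, is applied. $\bar{R}$ is itself a running
average, $\bar{R} \leftarrow \alpha_{trace} \bar{R} + (1-\alpha_{trace}) R$
with $\alpha_{trace} = 0.33$, kept separately for every trial type
(combination of inputs), which is what removes the reward-independent
Hebbian component in expectation.

### Parameters, defaults, and why

| parameter | default | role |
|---|---|---|
| $\tau$ | 30 ms | neural relaxation time constant |
| $g$ | 1.5 | recurrent gain; early chaotic regime |
| $dt$ | 1 ms | Euler step; trials are specified in whole ms |
| perturbation rate | 3 Hz/neuron | exploration rate |
| perturbation amplitude | uniform $[-0.5, 0.5]$ | exploration scale |
| $\eta$ | 0.5 (0.03 long delay; 0.003 variable delay) | learning rate |
| clip | $10^{-4}$ | per-trial cap on each $|\Delta J_{ij}|$ |
| $\alpha_{trace}$ | 0.33 | reward-baseline smoothing |
| $\alpha_{avg}$ | 0.33 | $\bar{x}$ smoothing per step |

Two of these require justification beyond their face value.

**The learning rate.** The sources of the method state a single learning
rate for all simulations in one place and, elsewhere, describe reducing the
long-delay task's rate "from 0.1 to 0.03" — an unresolvable internal
inconsistency. The package exposes $\eta$ per task and defaults to 0.5 for
the standard, Dale and selective-integration tasks, 0.03 for the long-delay
variant and 0.003 for the variable-delay variant.

**The $\bar{x}$ smoothing constant.** The time constant of the activation
running average is nowhere stated. It is, however, strongly constrained by a
stated quantity: roughly 10% of per-trial weight modifications are expected
to exceed the $10^{-4}$ cap. The clipped fraction is a direct observable of
the eligibility scale, and calibrating $\alpha_{avg}$ against it (with
$\eta$ fixed at its stated value) gives $\alpha_{avg} \approx 0.33$ — the
same value as the reward-trace constant, which is also the most natural
reading of a single smoothing constant serving both traces. With
$\alpha_{avg} = 0.33$ the measured clipped fraction on standard training
runs is 6–15%; with, say, $\alpha_{avg} = 0.8$ it is 60–75% and learning
slows visibly. The default is therefore 0.33, and it was fixed from this
clipping calibration alone.

**A non-choice: the indexing of $\bar{x}$ in the increment.** Whether the
step-$t$ increment uses the running average before or after it absorbs
$x(t)$ turns out to be irrelevant: $x - \bar{x}_{post} =
\alpha\,(x - \bar{x}_{pre})$ exactly, so the two conventions rescale every
increment by a constant that $\eta$ absorbs. The package pairs $x(t)$ with
the post-update average and documents the equivalence here so nobody burns a
day on it again.

Other conventions: $\bar{x}$ starts each trial at the initial state (first
increments are then zero); $\bar{R}$ for a type's first trial is initialized
at the observed reward, so the first trial of each type causes no update
(avoiding one large arbitrary step); clipping is elementwise, not a norm
clip; weights never change inside a trial; bias neurons are
perturbation-exempt (their clamp would erase the kick anyway), their rows
receive no updates because their fluctuation is identically zero, and their
columns stay plastic, acting as learned bias weights.

## Tasks

* **Delayed nonmatch-to-sample (DNMS).** Two stimuli from $\{A, B\}$ (one-hot
  on two channels) for 200 ms each, separated by a 200 ms delay, in a
  1000 ms trial; target $-1$ if they match, $+1$ otherwise; the error is the
  mean $|$output $-$ target$|$ over the last 200 ms, a trial is "correct"
  when the error is below 1, and the learning criterion is 95 correct of the
  last 100 trials. Variants: 400/1000 ms (long delay, 2000 ms trials),
  300 ms stimuli with delay uniform on 300–800 ms (variable delay, 1600 ms
  trials), and the Dale network with targets 0/5 and correctness threshold
  2.5. Trial types (AA, AB, BA, BB) are sampled uniformly during training.
* **Selective integration.** Two noisy sensory channels (per-step Gaussian,
  SD 1, mean = the per-trial bias, $\pm 0.5$ during training) for 500 ms,
  two constant context channels cueing the relevant modality, 200 ms
  response period; target is the sign of the cued modality's bias. The
  baseline trial type is the triple (context, sign of bias 1, sign of
  bias 2) — 8 types. Psychometric testing sweeps biases over the 11-point
  grid $-0.5, -0.4, \ldots, 0.5$ with frozen weights; a relevant bias of
  exactly 0 has no defined target and is permitted only in this non-strict
  mode.
* **Sign discrimination (gradient laboratory).** Ten constant inputs, i.i.d.
  uniform $[-1,1]$, shown for 100 ms; after a 100 ms delay the output neuron
  must report the sign of their mean over the last 100 ms of the 300 ms
  episode. Each episode contains exactly one scheduled perturbation of
  magnitude 0.5 and random sign at 250 ms — the midpoint of the response
  window — and fresh random weights; no learning is applied.

## The gradient laboratory

`run_gradient_experiment()` compares, per episode, the weight updates
proposed by rule variants against node perturbation as ground truth.
Node perturbation credits $e_{ij} = \sum_t \xi_i(t)\, r_j(t-1)$ and
multiplies by $\eta (R - R_0)$; the package computes the baseline $R_0$
exactly, by replaying the identical episode (same weights, same initial
state, same inputs) without the perturbation. The Hebbian variants replace
$\xi$ with the running-average fluctuation $x - \bar{x}$ under different
amplifications (cubic, signed square, signed square root, identity) and
windows (full episode, or the 10 ms after the perturbation), and the full
Exploratory-Hebbian rule modulates each step by a real-time reward
fluctuation $R(t) - \bar{R}(t)$ with $R(t) = -|$output$(t) -$ target$|$
inside the response window. That real-time trace exists only where a reward
signal exists; its running average is initialized at the first in-window
sample (the same first-observation convention used everywhere else), which
avoids manufacturing a spurious reward jump at the window's onset.

One quantitative caveat that the package measures rather than hides: pooled
over all matrix entries, the unamplified variants can only align so far with
node perturbation, because node perturbation is exactly zero in every row
whose neuron was not perturbed while unamplified Hebbian accumulation
collects relaxation drift there. Supralinear amplification crushes that
drift (cubing a value a tenth the size costs it a factor of a thousand),
which is precisely the rule's point; the 10-ms-window ablation, having no
amplification, shows positive but diluted pooled correlation at $N = 200$.
The qualitative ordering — cubic $\gg$ windowed $\gg$ identity $\approx$
sqrt $\approx$ 0 — is the reproducible signature.

## Population analyses

**Cross-temporal decoding.** Responses are sampled every 10 ms (100
timepoints for a 1000 ms trial) from 80 frozen-weight trials (20 per
condition, perturbations on). For each of 100 random stratified half/half
splits, class prototypes are pointwise means over training trials, and every
test-trial row is assigned the class whose prototype row correlates best
(Pearson, across neurons), for every (training time, testing time) pair. Tie
handling is deterministic (lowest class index); a zero-variance row has no
defined correlation and scores as incorrect, a conservative convention that
perturbation noise makes essentially unreachable. High diagonal but
near-chance off-diagonal blocks indicate a dynamic code: the information is
present throughout but its population pattern keeps changing.

**Orthogonal decoding.** For each timepoint, each neuron's response across
trials is regressed on the task features; collecting the per-feature
coefficients across neurons gives a population vector per feature and
timepoint, the vector with maximal norm over time is kept per feature, and
the set is QR-orthogonalized. QR output depends on column order, which is
therefore explicit (`order` argument; the first feature's axis is preserved
up to normalization). Projecting condition-averaged activity of correct
trials onto these axes yields per-feature trajectories; groups that are
impossible among correct trials (e.g. a positive relevant bias with a
negative choice) are simply absent, which halves the trajectory count when
grouping by the relevant modality.

Both analyses are validated against planted-code fixtures
(`planted_code_fixture()`): tensors built as value × direction × timecourse
plus Gaussian noise, for which ground truth is known exactly. These fixtures
emulate the dimensionality and code structure of network activity but not
its temporal autocorrelation, nonstationarity or perturbation spikes — so
passing decoder tests certifies the analysis code, not the biology.

## Problem sizes and reproducibility

All randomness flows through R's global RNG; a fit is bitwise reproducible
from `(task, config, seed)`, and the test suite asserts this. The reference
study conditions used by the package's own acceptance checks are: 5 seeded
standard-DNMS runs (cap 2600 trials) for the trials-to-criterion statistics;
3 long-delay runs (cap 2000); one network trained to criterion plus 500 stabilization trials, 80 trials and
100 split iterations for the decoding matrix; 500 episodes at $N = 200$ for the
gradient comparison; a 1500-trial Dale run for the constraint checks; and a full 20000-trial
selective-integration run for the psychometric checks, since suppression of
the uncued modality continues to sharpen well past criterion. These
sizes are the package's chosen desk-scale study conditions; the original
experiments used 20 runs of 10000–20000 trials.

## Known limitations

* Trials-to-criterion is a high-variance statistic under this rule: across
  seeds we observe runs from a few hundred trials to several thousand, a
  wider spread than the published inter-quartile range, and small-sample
  medians inherit that volatility. The package reports what its frozen
  configuration produces.
* At $g = 1.5$ with the constant bias drive, nearby trajectories of the
  autonomous network separate but need not show fast exponential divergence
  for every weight draw; the "chaos" smoke test asserts separation and
  sustained irregular activity, not a Lyapunov spectrum.
* The arm-reaching task of the original study requires a musculoskeletal
  simulator and is out of scope, as are MDS/PCA visualizations.
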