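---
title: "Neuro-fuzzy classification of neurodegenerative gait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuro-fuzzy classification of neurodegenerative gait: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitanfis)
```

## The problem

Neurodegenerative diseases — amyotrophic lateral sclerosis (ALS),
Parkinson's disease (PD) and Huntington's disease (HD) — disturb the
neural control of locomotion, and the disturbance is visible in the
timing of the gait cycle: stride intervals lengthen (markedly so in ALS),
stride-to-stride variability grows, and the proportions of the cycle
spent in stance and double support shift. `gaitanfis` classifies a
subject as patient or healthy control (CO) from five gait-cadence time
series measured by in-shoe footswitches during a hallway walk:

left and right **stride interval** (one full gait cycle per foot), left
and right **stance interval** (foot on the ground) and the **double
support interval** (both feet on the ground), all in seconds, one sample
per stride.

Every stride in the retained portion of a record is treated as an
independent 5-dimensional observation. The classifier is trained as a
regressor of a group target (0 for controls, 4 for patients) and a test
subject is labeled by whichever target the *average* model output over
that subject's strides is closer to.

## The model

The classifier is a first-order Sugeno fuzzy system realized as a
five-layer adaptive network. With inputs $x_1,\dots,x_n$ ($n = 5$ here),
each input carries $m$ fuzzy sets with generalized bell membership
functions

$$\mu(x) = \frac{1}{1 + \left|\frac{x - c}{a}\right|^{2b}},$$

parameterized by width $a > 0$, shape $b > 0$ and center $c$ (the
*premise parameters*). $\mu(c) = 1$ and $\mu(c \pm a) = 1/2$ for any
$b$. The rule base is the full grid partition: one rule per cell of the
$m^n$ Cartesian product of fuzzy sets — with $n = 5$ and $m = 2$, 32
rules. Rule $i$ computes:

- **Layer 1** — membership values $\mu_{ij}(x_j)$;
- **Layer 2** — firing strength $\omega_i = \prod_j \mu_{ij}(x_j)$;
- **Layer 3** — normalized strength
  $\bar\omega_i = \omega_i / \sum_k \omega_k$;
- **Layer 4** — weighted first-order consequent
  $\bar\omega_i f_i$, with $f_i = \sum_j p_{ij} x_j + r_i$
  (the *consequent parameters*);
- **Layer 5** — network output $f_{\text{out}} = \sum_i \bar\omega_i f_i$.

The free parameters number $3mn$ premise plus $m^n(n+1)$ consequent
values — 222 for the 5-input, 2-MF configuration. Rules are enumerated
in odometer order over membership indices with the last input varying
fastest; that fixed order defines the flat parameter vector used by the
optimizer and the serialization format.

## Training

All parameters (premise and consequent jointly) are fitted by particle
swarm optimization. Particle velocities and positions follow

$$v \leftarrow w\,v + c_1 r_1 (P_{\text{best}} - x)
              + c_2 r_2 (G_{\text{best}} - x), \qquad
  x \leftarrow x + v,$$

with per-dimension uniform random factors $r_1, r_2$, attraction
constants $c_1 = c_2 = 2.0$, and an inertia weight decaying linearly
from $w_{\max} = 0.9$ to $w_{\min} = 0.4$ over the fixed iteration
budget (the inertia weight approach). The fitness minimized is the RMSE
between network outputs and the 0/4 targets over all training
observations. Design choices where conventions vary:

- the global best is updated *asynchronously* — as soon as any particle
  improves on it within a sweep — which converges faster than the
  synchronous variant and is equally standard; determinism under a seed
  is preserved because particles are processed in fixed order;
- velocities are capped at 0.2 of each dimension's bound width;
  positions are clamped to their bounds and the offending velocity
  component zeroed;
- particle 1 is seeded at the grid-partition heuristic (equally spaced
  centers over each feature's training range,
  $a = \text{range}/(2(m-1))$, $b = 2$, zero consequents); the remaining
  particles start uniformly inside the bounds, velocities at zero;
- premise bounds keep the membership functions non-degenerate
  ($a \in [0.1a_0, 10a_0]$, $b \in [0.5, 5]$, $c$ within a window 1.5
  times the feature range); consequents are unbounded, with a $[-5, 5]$
  initialization window that also scales their velocity cap;
- the run always uses its full iteration budget — the inertia schedule
  is defined relative to it — with no early stopping.

Default budgets are 30 particles and 200 iterations
(`pso_config()`); the cross-validation experiments in this package's
validation suite use 15 particles and 50 iterations, which is already
ample for well-separated synthetic cohorts and keeps a 64-fold run in
minutes on one core.

## Preprocessing

Raw records pass through three stages, in this order:

1. **Start-up removal** — strides before 20 s of elapsed walking are
   discarded (gait initiation is not steady-state walking); the boundary
   is closed at 20 s (a stride at exactly 20 s survives).
2. **Walking-turn segmentation** — subjects walk a hallway back and
   forth, so each turn appears as a large stride-time spike. A stride is
   flagged as a turn when its left or right stride interval exceeds the
   column median plus 3 column SDs (an absolute threshold, e.g. 2 s, is
   available as an alternative rule). Only the longest contiguous run
   between flagged strides is kept; ties go to the earliest run.
3. **Median-referenced outlier rejection** — within the retained
   segment, a stride is dropped if any feature deviates from its column
   median by more than 3 column SDs. A zero-SD column keeps exactly the
   values equal to its median.

Segmentation runs *before* outlier rejection, deliberately: the turn
spikes are themselves far beyond the 3-SD limit, so a filter-first order
would delete the markers that separate hallway traversals and splice
unrelated segments together. Filtering afterwards still removes
measurement artifacts inside the chosen segment. The chain never edits
values — it only deletes rows — and it is idempotent on its own output
for well-behaved records (a second pass can in principle remove more
points, since the SD shrinks, but does not on data without borderline
outliers).

## Classification protocol

Experiments oppose a positive group set (one disease, or all three
combined) to the healthy controls. Evaluation is leave-one-subject-out
cross-validation: for each fold, a fresh model is trained on the pooled
observations of all remaining subjects and the held-out subject is
labeled by the minimum-distance rule on its mean output. Salient
choices:

- membership-function ranges are computed from each fold's *training*
  data only, so nothing about the held-out subject reaches training;
- a mean output exactly at the midpoint (2.0) classifies as positive —
  deterministic and clinically conservative;
- each fold's PSO seed derives from the experiment seed and the held-out
  subject's id (a string hash), and folds are processed in sorted
  subject-id order, so results are invariant to the order in which the
  cohort is supplied (a fold-index seed would not be);
- severity stratification splits patients into severe (PD with
  Hoehn–Yahr ≥ 3, HD with total functional capacity ≤ 5, ALS with mean
  stride time > 1.2 s) and mild for the strata-vs-control and
  mild-vs-severe experiments, which reuse the same machinery with
  targets 0 (mild) and 4 (severe).

Performance is reported as sensitivity $S_n = TP/(TP+FN)$, specificity
$S_p = TN/(TN+FP)$ and accuracy $C_a = (TP+TN)/\text{total}$, as
percentages rounded half-up to two decimals; a statistic with a zero
denominator is reported as undefined, never as zero.

## The synthetic cohort generator

Because the underlying clinical recordings cannot ship with the package,
`generate_cohort()` simulates gaitndd-style records with the statistical
structure the method relies on. Per group, stride-to-stride fluctuations
follow a stationary lag-1 autoregressive process (default
$\varphi = 0.3$) with truncated-Gaussian marginals; the five features
share a cross-correlation (default $\rho = 0.5$ — a placeholder, as the
true cross-correlations of the real data are not published). Group
means, SDs and cohort sizes (13 ALS / 15 PD / 20 HD / 16 CO) match the
reported per-group summary statistics of the five features; walking
speed per group places a turn spike each time a 77 m hallway is
traversed. A fraction (default 0.4) of each feature's SD is attributed
to stable between-subject differences, with the within-subject SD shrunk
so the pooled SD stays calibrated — without this, all subjects of a
group would share one mean, which is unrealistically easy for
subject-level classification. Severity covariates are sampled so 9 PD
and 9 HD patients fall in the severe stratum.

What the generator does **not** emulate: long-range (fractal)
correlations of real stride series beyond lag-1 structure, drift or
fatigue effects, footswitch waveform artifacts, and realistic
between-subject heterogeneity of ALS stride means — with the calibrated
ALS group mean of 1.52 s essentially every synthetic ALS subject
exceeds the 1.2 s severity threshold, so the stride-based severity rule
cannot reproduce a 9/13 severe split on synthetic data. Passing
synthetic-recovery tests therefore demonstrates that the pipeline's
machinery is correct, not that real-data accuracies are reproducible;
applying the package to the real PhysioNet recordings is a supported
workflow via `read_cohort()` but requires a download.

For end-to-end validation the package uses `separated_group_specs(k)`:
the default calibration with each disease-group feature mean pushed to
at least $k$ pooled SDs from the control mean (default $k = 3$; means
already farther, like the ALS stride interval, are untouched). Under
this construction a correct pipeline must classify nearly perfectly, so
the validation suite requires LOOCV accuracy of at least 95% on the
64-subject cohort; the acceptance script recomputes these figures from
scratch at 15 particles × 50 iterations.

## Numerical choices and degenerate inputs

- The bell membership uses $|\cdot|^{2b}$, keeping it defined for
  non-integer $b$.
- An input so far outside every membership support that all firing
  strengths underflow to zero yields a diagnosable error (scalar path)
  or an `NA` that training penalizes with infinite fitness (batch
  path); the premise bounds make this unreachable in practice.
- Non-finite fitness values are penalized with $+\infty$, never crash
  the swarm.
- Model files store doubles as `%.17g` strings inside JSON:
  human-readable and bit-exact on round trip, which raw JSON number
  formatting does not guarantee.
- Record files print values at 6 decimal places; the derived percentage
  columns are computed from the rounded values so a write/read/write
  cycle is byte-identical.
- Sub-seeds derived from subject ids stay below $2^{31}$.

## Known limitations

- PSO-only training fits the 222-parameter model far less precisely
  than hybrid least-squares/gradient schemes would; on hard regression
  surfaces the swarm's terminal RMSE plateaus near 0.1 on a 0–4 target
  scale at conventional budgets. For the subject-level distance rule
  this is immaterial — means need only fall on the correct side of
  2.0 — but per-observation outputs should not be over-interpreted.
- The full grid partition scales as $m^n$; the implementation is
  intended for the five-feature, two-MF configuration and small
  variants, not for high-dimensional feature sets.
- With the default calibration (disease and control distributions a
  fraction of an SD apart on most features), synthetic cohorts are far
  harder than the separated construction; classification accuracy on
  them reflects the calibration overlap, not a defect of the method.
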