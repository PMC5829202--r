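---
title: "Quantifying collective behaviour and group-level repeatability in fish shoals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective behaviour and group-level repeatability in fish shoals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Shoals of small fish differ from one another in how fast they swim, how
tightly they school, how strongly they align, and how clearly the same
individuals keep leading from the front. `shoalr` asks whether such
differences are *consistent* properties of the group — a "group
personality" — rather than noise: do the same groups remain fast, cohesive,
aligned or leader-structured when tested repeatedly, and across different
ecological settings (an open arena, an arena with food patches, an arena
with food and a plant refuge)?

The package provides the full chain needed to answer that question from
trajectory data:

1. **Trajectories** — reading, gap filling and Savitzky–Golay smoothing of
   per-frame 2-D positions of tagged individuals.
2. **Group metrics** — per-frame centroid, individual speed, distance to
   centroid (cohesion), polarization, and a front-of-centroid leadership
   indicator; per-trial summaries used as model responses.
3. **Density maps** — relative neighbour position in body lengths, and the
   joint distribution of group speed and polarization.
4. **Variance partitioning** — a Gibbs-sampled Gaussian linear mixed model
   with group and individual random intercepts, from which *consistency
   repeatability* is derived.
5. **An agent-based shoal simulator** that generates the whole experiment
   with known ground truth, so every inference stage can be validated
   without empirical data.

## Metric definitions and conventions

Positions are in mm, the arena centre is the origin, frames are 0-based
and windows half-open `[start, end)`. The frame rate defaults to 24 Hz.

* **Centroid** `c(t)`: arithmetic mean member position. Residual member
  displacements about it sum to zero by construction.
* **Speed**: one-frame displacement times the frame rate, reported in
  cm/s. The last frame repeats the previous value so series lengths match
  the trajectory.
* **Heading** `u_i(t)`: direction of the one-frame displacement when the
  step is at least `min_step` (0.2 mm by default); below that, tracking
  jitter dominates and the previous heading is carried forward. Headings
  are taken from displacement, not body axis, because point tracking has
  no orientation information.
* **Polarization** `P(t) = ||Σ u_i(t)|| / n`: the standard order
  parameter, 1 for perfect alignment, 0 for cancelling headings;
  undefined with fewer than two defined headings.
* **Leadership** (`in_front`): member i is in front at frame t when
  `(p_i − c) · v_c > 0`, with `v_c` the centroid velocity. The inequality
  is strict (a fish exactly at the centroid is not leading), and the
  indicator is undefined for every member when the centroid moves slower
  than `min_centroid_speed` (0.5 cm/s): a stationary group has no front.
* **Leadership structure**: the *population* variance (divisor n) across
  members of their front proportions — the five members are the whole
  group, not a sample from one.
* Per-trial summaries use the **median** for speed and polarization
  (robust to burst-and-glide and to brief tracking glitches) and the
  **mean** for centre distance and front proportion.

All metrics are invariant under translation and rotation of the
coordinate frame, and polarization under relabelling of individuals;
these are enforced by property tests at 1e-9 tolerance.

### Smoothing

Coordinates are smoothed with a Savitzky–Golay filter, window 15 frames.
The polynomial order is not dictated by the filter choice; the package
defaults to order 3, the standard choice for kinematics since it
preserves velocity and acceleration structure, and both window and order
are arguments. At the series ends the window shrinks to the available
frames (a plain least-squares polynomial on what is observed) rather than
padding: padding would fabricate positions outside the observation
interval. Gap filling is linear interpolation bounded at `max_gap` = 15
frames (one smoothing window); longer occlusions raise an error rather
than inventing data.

### Density maps

The neighbour map accumulates, over every frame with a defined focal
heading and every ordered (focal, neighbour) pair, the neighbour position
in the focal fish's frame (origin at the focal fish, heading up),
expressed in body lengths (40.6 mm default). Bins are 0.25 BL wide over
±5 BL — wide enough to contain the within-two-BL side-by-side,
within-four-BL front-back structure typical of schooling — and values are
normalized as percent of the densest bin. Samples outside the extent are
dropped, not clamped, and tallied. The speed–polarization map bins frames
at 0.25 cm/s × 0.05. Plain histograms are used deliberately; no kernel
smoothing.

## The variance-partitioning model

Each per-trial response `y` (e.g. a fish's median speed in a trial) is
modelled as

$$y = X\beta + Z_g a + Z_i b + e, \qquad
  a \sim N(0, V_{group}), \; b \sim N(0, V_{id}), \; e \sim N(0, V_{res})$$

with context (or trial number) as the fixed factor, a random intercept per
group, and — for individually measured responses — a random intercept per
individual nested within its group. Group-level responses (polarization,
leadership structure) omit the individual term. Consistency repeatability
is the intraclass correlation

$$R_{group} = \frac{V_{group}}{V_{group} + V_{id} + V_{res}}, \qquad
  R_{id} = \frac{V_{id}}{V_{group} + V_{id} + V_{res}}.$$

`rc_lmm()` estimates the model by Gibbs sampling; every full conditional
is conjugate (normal for `β` and the random-effect blocks, inverse-gamma
for the variances). Priors are non-informative but proper: N(0, 1e8) on
fixed effects and inverse-gamma(0.001, 0.001) on each variance, all
configurable. Prior insensitivity is not assumed — the calibration tests
fit data with known truth and check coverage.

`repeatability()` computes the ratio *per posterior draw* and summarizes
with the posterior mean and equal-tailed 95% CI, propagating the
uncertainty; the ratio of posterior-mean components is also reported as
`point` for comparison with published point estimates (the two differ
slightly because the ratio is nonlinear).

Decisions worth calling out:

* **"CI does not reach zero."** Inverse-gamma draws are strictly
  positive, so a variance CI never literally contains 0. The package's
  operational rule: a component is significantly repeatable when the
  lower 2.5% posterior quantile of its variance exceeds 1% of the
  posterior-mean total variance. On null data (true `V_group` = 0) this
  flags at most ~10% of replicates; with genuine heterogeneity the lower
  bound sits far above the threshold.
* **Chain settings.** The default is 5 chains × 20,000 iterations
  (burn-in 2,000, thinning 10); published MCMCglmm analyses of this
  design used 500,000 iterations, which the defaults scale down because
  the conjugate sampler mixes quickly here (across-chain potential scale
  reduction factors are reported with every fit and sit below 1.1 in the
  test suite). Full-size settings are one argument away.
* **Oracle.** `moment_estimator()` solves the balanced nested ANOVA
  expected mean squares (via `stats::aov`, fixed effects regressed out
  first, negative solutions truncated at 0). It is exact for balanced
  designs and is the independent reference the sampler is tested
  against; `lme4::lmer` serves as a second, external cross-check in the
  tests. Removing fixed effects by OLS before the ANOVA ignores a few
  degrees of freedom, which is immaterial at the tolerances used.
* **Inference across contexts** follows CI overlap: two level means are
  called different when their 95% CIs are disjoint. No multiplicity
  correction is applied, deliberately, to match the CI-overlap
  convention; `compare_levels()` just reports the two intervals and the
  verdict.

## The synthetic experiment

Two generators stand in for unreleased empirical data.

`generate_lmm_data()` is the exact generative mirror of the mixed model
and is used to test the inference machinery: balanced draws of
`n_groups × n_per_group × n_obs` with known `V_group, V_id, V_res`.

`simulate_trial()` / `simulate_experiment()` implement a zonal schooling
model: each agent is repelled from neighbours within 30 mm; otherwise it
aligns with headings of neighbours within 120 mm and is attracted to
neighbours beyond that out to 400 mm (concentric shells, the classic
formulation — blending attraction with alignment at all ranges produces
milling, not schooling). Headings turn towards the desired direction at
most 0.3 rad per frame (instant reorientation is both unphysical and
numerically unstable under repulsion) with von Mises noise of SD 0.3 rad
per frame, which yields open-arena polarization around 0.95. Agents move
at their preferred speed (population mean 3.25 cm/s) inside an 80 cm
circular arena with soft wall avoidance from 80% of the radius and a hard
projection at the wall; trials start from a 10 cm central release
cylinder, mirroring the assay protocol.

Heterogeneity enters through preferred speed only: a group-level offset
(SD 0.5 cm/s) plus an individual-level offset (SD 0.05 cm/s). The
near-zero individual SD encodes strong within-group speed conformity —
groups differ, members of a group do not — which is the regime the
repeatability analysis is designed to detect (high group, null
individual repeatability for speed). Hooks exist for heterogeneity in
other parameters but are off by default.

Contexts:

* **Foraging** adds three 5-item food patches in a triangle at 2/3 the
  arena radius. Agents notice a patch within 175 mm and steer to it,
  consume one item on contact, and pause 2 s to handle it; while any food
  remains the group travels at 75% speed, and after the last item it
  speeds up by a factor 1.3. The logged `depletion_frame` (when the 15th
  item is eaten) is the ground truth used to split trials into pre- and
  post-depletion windows. The detection radius was set so that all items
  are reliably consumed within the 300 s protocol trial; the slowdown and
  speed-up reproduce the qualitative ordering slow-while-foraging,
  fastest-after-depletion.
* **Cover** adds a 15 cm central plant circle; an agent inside it starts
  hiding with probability 0.4 per second and resumes with probability
  0.15 per second, so only a subset of the group is typically out of
  cover at any time.

The simulator makes no claim of behavioural realism beyond these
qualitative patterns: there is no hydrodynamics, vision cone, body shape,
or individually varying interaction rule. Consequently, passing tests
demonstrate that the *pipeline* recovers what the generator put in — they
do not validate the zonal model against real fish.

## Problem sizes and run times

The package's own test and pipeline defaults use shortened trials
(60–300 s rather than the 5–30 min protocol) and scaled-down chains;
these sizes are stated here as the package's choices for routine runs.
The calibration study fits 100 replicates at the study design size (25
groups × 5 individuals × 4 contexts) with true `R_group` = 0.5 and 100
with true `V_group` = 0, checking ≥90% CI coverage and ≤10% false
positives. The end-to-end check simulates the full 25-group design
(open 60 s, foraging 300 s, cover 60 s), and verifies: pre-depletion
median speed below post-depletion in ≥90% of groups; a positive
speed–polarization rank correlation; significant group-level speed
repeatability with individual-level speed repeatability near zero.

## Degenerate inputs and numerical notes

* Trajectories must be gap-free before smoothing and metrics; gaps are
  either interpolated (bounded) or an error.
* A stationary group yields no leadership frames; summarizing such a
  trial is an error rather than a silent zero.
* An empty pre-depletion window (depletion at frame 0) is flagged; the
  pipeline drops empty windows.
* A context level with no data is dropped from the fixed factor rather
  than estimated from the prior.
* `rc_lmm` refuses non-nested individual ids and groups with fewer than
  two observations; `moment_estimator` warns on unbalanced designs and
  flags the confounded one-observation-per-individual case.
* With one individual per heading frame polarization is undefined (`NA`),
  never 1.

## Known limitations

* Headings come from displacement, so slow near-stationary fish carry
  stale headings into the polarization and neighbour maps.
* The leadership definition needs a moving centroid; cover trials with
  long collective pauses contribute fewer leadership frames.
* The moment estimator assumes (near-)balance; strongly unbalanced
  designs should rely on the sampler.
* Repeatability ratios are reported unconditionally on convergence;
  inspect the reported PSRF (and trace plots via `plot()`) for any fit
  used in earnest.
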