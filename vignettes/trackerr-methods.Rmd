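---
title: "Methods: quantifying GPS measurement error in fine-scale trajectories"
author: "trackerr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying GPS measurement error in fine-scale trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ground-dwelling insects such as large *Carabus* beetles move a few meters
between relocations taken every few hours. Two field methods compete for
recording such fine-scale trajectories:

* **Distance-bearing (DB)**: each movement step is recorded as a
  tape-measured distance plus a magnetic-compass azimuth from the previous
  fix; coordinates are reconstructed by dead reckoning from a known start
  point. Instrument error is on the order of centimeters and one degree.
* **GPS**: each fix is a hand-held receiver reading, with positional error
  on the order of 3 m — the same order as the movement steps themselves.

`trackerr` quantifies what that positional error does to derived movement
parameters (step lengths, bearings, total path length) and to the biological
signal extracted downstream by a two-state hidden Markov movement model. The
package treats DB-measured trajectories as the error-free reference and
simulated GPS recordings as the biased measurement, so every reported "error"
is GPS relative to DB.

## Angle conventions

Trajectory software reports step directions as *absolute angles*: radians,
counterclockwise, from the x (east/longitude) axis. Field compasses report
*azimuths*: degrees, clockwise, from north. The two are linked by

$$\mathrm{az} = (90^\circ - \theta \cdot 180/\pi) \bmod 360,$$

so 0 rad is east (90°), $+\pi/2$ rad is north (0°), $-\pi/2$ rad is south
(180°) and $\pi$ rad is west (270°). Turning angles are wrapped differences
of successive absolute angles in $(-\pi, \pi]$, with ties at $\pm\pi$
resolved to $+\pi$. Magnetic declination is east-positive and is *added* to a
magnetic azimuth to obtain the true azimuth (e.g. +5.133° at a Budapest
grassland site in spring 2020). A zero-length (passive) step has *missing*
azimuth, never 0°: coding it as 0 would fabricate northward bearings for
stationary animals.

## Earth model

All noise injection and distance computation happens on a local azimuthal
equirectangular tangent plane at the track origin, with
$x = \Delta\lambda \cdot R\pi/180 \cdot \cos\varphi_0$ east and
$y = \Delta\varphi \cdot R\pi/180$ north, $R = 6{,}371{,}000$ m. A
great-circle spherical mode with the same radius is available; at the
package's design scale (steps of 0.5–20 m, tracks within ~1 km) the two agree
to a few millimeters, which a unit test asserts, and both agree with an
independent ellipsoidal geodesic to ~1 mm per 10 m step. Using one shared
radius for both modes keeps them mutually consistent; ellipsoidal (Karney)
geodesics and UTM handling are deliberately out of scope at this extent.

## The synthetic-data generator

The generator is a first-class module: it defines the study conditions under
which everything else is tested.

**Artificial trajectory designs.** Step lengths are drawn by a four-stage
funnel per step: 100 uniform values on [0.5, 20.0] m rounded to one decimal,
a without-replacement subsample of 50, then of 5, then a single pick.
Azimuths run the same funnel on 100 uniform integers 1–12, mapped to 30°
units (12 → 0°/north). The funnel preserves marginal uniformity (a
Monte-Carlo test checks each 30° class at 1/12 ± 0.01) while emulating the
field selection protocol, in which the final pick is made by a human to
avoid machine-randomization artifacts. A human pick is irreproducible, so
the package replaces it with a seeded uniform choice among the five
candidates — the one deliberate deviation in this module. The default
experiment generates three 10-step and three 20-step designs; with one DB
build and three GPS repeats each, this yields 24 trajectories and 384 fixes
including start points.

**GPS error.** No mechanism for the receiver's error is published, so the
model is per-fix isotropic bivariate Gaussian noise in the local plane with
per-axis SD `sigma * canopy_factor * rain_factor`. This single assumption
reproduces both qualitative findings at once, with no separate tuning:

* $E\,\lVert d + \varepsilon \rVert > d$ for zero-mean isotropic
  $\varepsilon$, so GPS-measured distances are biased upward;
* the angular error of $d + \varepsilon$ shrinks as $d$ grows, so bearing
  error concentrates at short steps.

Defaults: `sigma = 3` m (the nominal accuracy of the hand-held receiver
class used in such studies); `canopy_factor = rain_factor = 1` on open
grassland and 1.5 each in the forest scenario. The 1.5 factors are free
parameters — the field data needed to calibrate them are not bundled — and
are documented as uncalibrated. The start fix is noised like any other fix (a
GPS reading is a measurement wherever it falls), and noise is independent
across fixes; real hand-held receivers show temporally autocorrelated error,
which nothing here calibrates, so independence is stated rather than argued.

**Beetle-like tracks.** True paths are simulated from the movement HMM below
with zero inflation 0.5, a latent heading that persists through passive
steps, and a 0.5 m passive threshold applied to the true step length. The
default scale — 6 animals × 27 fixes per method — mirrors a 4-hourly,
five-day field schedule; because real schedules lose and add fixes
irregularly, the generator is parameterized rather than pinned to one total.

## Error metrics and mixed models

Per active step, the signed distance error is GPS − DB (positive = GPS
larger) and the bearing error is the absolute circular difference
$\min(|a-b|, 360-|a-b|) \in [0, 180]$. Passive steps are excluded — their
movement parameters are undefined — and bearing records are additionally
dropped when either method's step is zero-length.

Single-argument error regressions are Gaussian random-intercept models,
`error ~ predictor + (1 | track)`, fitted with lme4: REML for the reported
variance components, ML refits for the likelihood-ratio test against the
intercept-only model, $p$ from the $\chi^2$ reference distribution with df
equal to the number of fixed-effect parameters tested. When the predictor is
the DB-measured bearing it enters as a 12-level categorical factor (the 30°
design units), giving an 11-df test; distance and fix order enter as
continuous. $R^2$ follows the Nakagawa–Schielzeth decomposition, computed
directly from the fit:
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_\alpha + \sigma^2_\epsilon)$ and
$R^2_c = (\sigma^2_f + \sigma^2_\alpha) / (\cdot)$. The state-proportion
comparison uses a binomial GLMM with logit link on the per-track
`[random walk, directed]` count matrix, method as fixed effect, design as
random intercept, Laplace approximation, with the theoretical logit
distribution variance $\pi^2/3$ in the $R^2$ denominator; the raw DB−GPS
difference in pooled random-walk proportion is reported in percentage points
alongside the coefficient. A dedicated test calibrates both stages' type-I
error at $\alpha = 0.05$ over 500 null simulations.

## The movement HMM

Two states with the standard carabid interpretation: state 1, *random walk*
(short steps, dispersed turning angles — foraging); state 2, *directed
movement* (long steps, turning angles concentrated at 0 — transit). Emissions,
conditionally independent given the state:

* step length: zero-inflated gamma, parameterized by mean $m$ and SD $s$
  (shape $m^2/s^2$, rate $m/s^2$) with point mass $z$ at exactly 0;
* turning angle: von Mises$(\mu, \kappa)$, uniform at $\kappa = 0$.

Starting values follow the conventional fine-scale parameterization: means
1 m and 10 m, SD equal to the mean (the simplest reading of "SD of the same
order as the mean"; configurable), $\mu = \pi$ and $0$ rad, $\kappa = 0.5$
and $2.5$, $z = 0$ for designs without passive steps and $0.5$ for
field-style data. No published initial transition matrix exists; the default
$[[0.8, 0.2], [0.3, 0.7]]$ is moderately persistent, and only the fit — not
the start — is reported.

**Numerics.** The likelihood is the scaled forward recursion (implemented in
C++; no underflow up to at least $10^5$ steps), with each track restarting
the chain at the stationary distribution of the transition matrix and missing
turning angles contributing step density only. Fitting maximizes the joint
likelihood over all tracks by BFGS on a working scale: log for means and SDs,
logit for zero masses and the off-diagonal transition probabilities, and an
unconstrained Cartesian pair $(\kappa\cos\mu, \kappa\sin\mu)$ per state for
the angle parameters, recovered by `atan2`. Convergence tolerance is a
relative $10^{-8}$ on the objective; a seeded jittered multi-start (default
5 starts, SD 0.25 on the working scale) guards against local optima. Zero
masses are estimated only when the data contain exact zeros — otherwise the
logit coordinate would drift unbounded along a flat likelihood. After
fitting, states are relabeled so state 1 has the smaller step mean; Viterbi
decoding runs in log space with ties broken toward state 1. Both the forward
value and the Viterbi path are verified against exhaustive $2^n$-path
enumeration on random instances.

## Pipeline and provenance

`run_experiment1()` chains designs → dead reckoning → GPS repeats → error
records and correlations → mixed models → per-method HMM fits and decoding →
state-proportion comparison; `run_experiment2()` does the same from simulated
beetle tracks with passive fixes excluded. Everything derives from one master
seed, and identical configurations are byte-identical in their outputs; the
written artifacts are plain CSVs plus a JSON manifest with md5 hashes. An
off-by-default `emulate_min_dist` flag floors derived step lengths at 1.6 m,
reproducing a preset minimum-distance behavior of legacy trajectory software;
it is an emulation of a third-party artifact, not part of the method. The R
functions themselves are the interface: runs live in scripts or sessions, and
every stage consumes and emits the documented CSV dialects so stages can be
rerun independently.

## Problem sizes used in the tests

The test suite pins its own scales: oracle comparisons use $n \le 10$ steps
(exhaustive enumeration), parameter recovery uses one 5,000-step series plus
50 replicates of 2,000 steps (bias within 3 Monte-Carlo SE), geometry round
trips use 1,000 random designs, the error-model checks use a few thousand
simulated repeats per distance bin, and the calibration tests use 500 null
simulations per stage. These sizes make the stochastic assertions stable
under any seed while keeping a full run in the minutes range.

## What passing tests do and do not show

The generator reproduces the *structure* of the two field experiments it
emulates (design counts, fix semantics, thresholds, parameter scales) and
the *direction* of the known error effects (upward-biased GPS distances;
bearing error concentrated at short steps; forest inflation; fewer decoded
random-walk steps under GPS). It does not reproduce any particular field
campaign's numeric estimates — grassland errors of roughly 2 m and 30°, or
bearing errors above 70° under canopy, are typical magnitudes for this
receiver class — because those depend on raw field fixes; with `sigma = 3` m
the simulator lands in the same range, but agreement in value is incidental,
not asserted. Real GPS error is neither perfectly isotropic
nor temporally independent, and real beetle movement is not exactly
gamma/von Mises; conclusions transfer to the extent those idealizations are
harmless at this spatial scale.

## Known limitations

* Two states only; no covariates on transition probabilities, no standard
  errors on HMM parameters (point estimation and decoding only).
* The planar geometry is trustworthy to ~10 km extent; beyond that it warns.
* Bearing errors are compared as absolute circular differences; no circular
  regression is attempted.
* The binomial GLMM treats GPS repeats of one design as separate tracks
  sharing a design-level random intercept; pooling repeats instead is
  possible by aggregating counts before the call.
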