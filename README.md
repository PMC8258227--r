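# trackerr

Measurement error in fine-scale animal trajectories: distance-bearing
versus GPS recording.

## The problem

Walking insects such as large carabid beetles cover 0.5–20 m between
relocations taken every few hours — the same order as the ~3 m positional
error of a hand-held GPS receiver. At that scale, GPS error does not average
out: it inflates measured step lengths (for zero-mean isotropic error
ε, E‖d + ε‖ > d), scrambles bearings at short steps, and can shift the
apparent balance between the two movement modes that matter biologically,
*random walk* (short steps, dispersed turning angles; foraging) and
*directed movement* (long steps, concentrated angles; transit). The
alternative distance-bearing (DB) method — a tape-measured distance plus a
magnetic-compass azimuth per step, reconstructed by dead reckoning — has
instrument error orders of magnitude smaller.

`trackerr` is for movement ecologists who want to quantify, on their own
designs, how much GPS positional error distorts derived movement parameters
and downstream state segmentation relative to a DB reference. It provides:

* **geometry** — conversions between absolute angles (radians ccw from
  east) and compass azimuths (`az = (90° − θ·180/π) mod 360`), declination
  handling, dead reckoning `db_to_coords()`, its inverse
  `coords_to_steps()` (step lengths, azimuths, turning angles in (−π, π]),
  and circular bearing error `min(|a−b|, 360−|a−b|)`;
* **synthetic data** — seeded artificial trajectory designs (steps uniform
  on [0.5, 20.0] m in 0.1 m units, azimuths in 30° units, selected through a
  four-stage randomization funnel), per-fix isotropic Gaussian GPS noise
  with canopy/rain inflation, and HMM-driven beetle-like tracks with
  passive (< 0.5 m) fixes;
* **error metrics** — per-fix signed distance error (GPS − DB) and absolute
  circular bearing error, Pearson coordinate correlations, and lme4
  random-intercept models with likelihood-ratio tests and
  Nakagawa–Schielzeth marginal/conditional R²;
* **a two-state movement HMM** — zero-inflated gamma step lengths
  (shape m²/s², rate m/s²), von Mises turning angles, scaled forward
  likelihood (C++ core), maximum-likelihood fitting on a working scale with
  jittered multi-starts, and Viterbi decoding;
* **a pipeline** — `run_experiment1()` (artificial designs: 6 trajectories,
  3 GPS repeats each → 24 trajectories, 384 fixes) and `run_experiment2()`
  (simulated beetle radio-tracking in forest), each fully determined by one
  seed.

## Worked example

```r
library(trackerr)
rep1 <- run_experiment1(run_config(seed = 1))
print(rep1)
```

```
Run report (artificial experiment, seed 1)
  24 trajectories, 384 fixes
  distance error: 1.354 m (SEM 0.223), bearing error: 34.749 deg (SEM 2.366)
  model table:
                      model chi_sq df        p marginal_R2 conditional_R2
 distance_error_vs_distance  10.08  1 1.50e-03     0.03637         0.0638
   bearing_error_vs_bearing  21.81 11 2.59e-02     0.07467         0.0747
  bearing_error_vs_distance 101.19  1 8.34e-24     0.31203         0.3204
    distance_error_vs_order   1.07  1 3.01e-01     0.00403         0.0260
     bearing_error_vs_order   6.49  1 1.09e-02     0.02366         0.0237
     total_length_vs_method   6.42  1 1.13e-02     0.01858         0.9413
 prop_random_walk_vs_method  23.08  1 1.56e-06     0.14343         0.1434
Proportion of random walk ~ recording method (binomial GLMM)
  chi^2 = 23.075, df = 1, p = 1.558e-06 | R2m = 0.143, R2c = 0.143
  random walk: DB 92.2%, GPS 68.9% (DB - GPS = 23.33 pp) [singular fit]
```

Reading this: with 3 m isotropic GPS noise, GPS-measured steps are on
average 1.35 m longer than the DB-measured truth; the mean absolute bearing
error is ~35°; bearing error falls steeply with DB-measured distance (the
dominant effect, marginal R² = 0.31); GPS-measured trajectories are
significantly longer in total; and Viterbi decoding under the fitted
two-state HMM labels fewer steps as random walk on the GPS side — noise
masquerades as directed movement. Exact numbers vary with the seed; the
directions are stable.

Lower-level entry points do one thing each, e.g.

```r
absangle_to_azimuth(pi / 2)        # 0  (north)
apply_declination(30, 5.133)       # 35.133 (true azimuth)
d  <- generate_design(10, seed = 1)
xy <- db_to_coords(c(19.0609, 47.4724), d$steps, declination = 5.133)
coords_to_steps(xy$lon, xy$lat)
```

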