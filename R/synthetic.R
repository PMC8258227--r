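# Generators standing in for the field devices: artificial trajectory
# designs, simulated GPS fixes, and HMM-driven beetle-like tracks.

#' GPS positional-error model
#'
#' Per-fix isotropic bivariate Gaussian positional noise in the local plane,
#' with per-axis SD `sigma * canopy_factor * rain_factor`. The base sigma
#' defaults to 3 m, the nominal accuracy scale of consumer hand-held
#' receivers; the multiplicative factors (default 1) inflate the error under
#' dense forest canopy and rainy weather. A "forest" scenario conventionally
#' sets both factors to 1.5 (uncalibrated free parameters).
#'
#' @param sigma Per-axis SD in meters (> 0).
#' @param canopy_factor,rain_factor Multipliers >= 1.
#' @param seed Optional integer; when set, [simulate_gps()] seeds its RNG.
#' @return Object of class `gps_error_model`.
#' @export
gps_error_model <- function(sigma = 3, canopy_factor = 1, rain_factor = 1,
                            seed = NULL) {
  stopifnot(sigma > 0, canopy_factor >= 1, rain_factor >= 1)
  structure(list(sigma = sigma, canopy_factor = canopy_factor,
                 rain_factor = rain_factor, seed = seed),
            class = "gps_error_model")
}

#' Generate one artificial trajectory design
#'
#' Reproduces the four-step randomization funnel used to build artificial
#' fine-scale trajectories. Per step, the distance is drawn by: 100 uniform
#' values on `[0.5, 20.0]` m rounded to one decimal, subsample 50 without
#' replacement, subsample 5, then select 1. Azimuths use the same funnel on
#' 100 uniform integers in `1..12`, mapped to 30-degree units (12 -> 0 deg,
#' i.e. north). The final single pick — made by a human in the original field
#' protocol to avoid machine-randomization artifacts — is replaced here by a
#' seeded uniform choice among the 5 candidates.
#'
#' @param n_steps Number of steps (>= 1); 10 or 20 in the default experiment.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param design_id Identifier stored with the design.
#' @return Object of class `trajectory_design`: a list with `design_id`,
#'   `n_steps` and `steps` (data.frame `track_id, order, distance_m,
#'   azimuth_deg, frame` with `frame = "magnetic"`).
#' @export
generate_design <- function(n_steps, seed = NULL, design_id = "D1") {
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  funnel <- function(pool100) {
    s50 <- sample(pool100, 50, replace = FALSE)
    s5 <- sample(s50, 5, replace = FALSE)
    sample(s5, 1)
  }
  dist <- vapply(seq_len(n_steps), function(i)
    funnel(round(runif(100, 0.5, 20.0), 1)), numeric(1))
  azu <- vapply(seq_len(n_steps), function(i)
    funnel(sample.int(12, 100, replace = TRUE)), numeric(1))
  az <- (azu * 30) %% 360  # 12 (=360) stored as 0
  structure(list(design_id = design_id, n_steps = n_steps,
                 steps = data.frame(track_id = design_id,
                                    order = seq_len(n_steps),
                                    distance_m = dist, azimuth_deg = az,
                                    frame = "magnetic",
                                    stringsAsFactors = FALSE)),
            class = "trajectory_design")
}

#' @export
print.trajectory_design <- function(x, ...) {
  cat(sprintf("trajectory_design '%s': %d steps, total %.1f m\n",
              x$design_id, x$n_steps, sum(x$steps$distance_m)))
  invisible(x)
}

#' Default artificial-trajectory experiment designs
#'
#' Six designs: three with 10 steps and three with 20 steps, generated
#' sequentially from one seed. With one DB build plus three GPS repeats per
#' design this yields 24 trajectories and 384 fixes including start points.
#'
#' @param seed Integer seed.
#' @return List of 6 `trajectory_design` objects named `D1..D6`.
#' @export
default_experiment1_designs <- function(seed) {
  set.seed(seed)
  n <- c(10, 10, 10, 20, 20, 20)
  out <- lapply(seq_along(n), function(i)
    generate_design(n[i], seed = NULL, design_id = paste0("D", i)))
  names(out) <- vapply(out, `[[`, "", "design_id")
  out
}

#' Simulate GPS measurements of a true trajectory
#'
#' Every fix of every repeat — including the start fix, which is a GPS
#' reading like any other — is displaced independently by bivariate normal
#' noise `N(0, (sigma * canopy * rain)^2 I)` in the local plane. Noise is
#' independent across fixes and repeats (no temporal autocorrelation).
#'
#' @param true_fixes Fix data.frame for one track (>= 2 fixes, method `DB`).
#' @param model A [gps_error_model()].
#' @param n_repeats Number of GPS re-recordings of the track (>= 1).
#' @return Object of class `sim_track`: list with `true_fixes` and
#'   `gps_repeats` (list of fix data.frames, method `GPS`, track ids suffixed
#'   `_r1`, `_r2`, ...).
#' @export
simulate_gps <- function(true_fixes, model = gps_error_model(),
                         n_repeats = 1) {
  if (nrow(true_fixes) < 2) stop("need at least 2 fixes")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (!is.null(model$seed)) set.seed(model$seed)
  s <- model$sigma * model$canopy_factor * model$rain_factor
  origin <- c(true_fixes$lon[1], true_fixes$lat[1])
  xy <- local_project(true_fixes$lon, true_fixes$lat, origin)
  reps <- lapply(seq_len(n_repeats), function(r) {
    n <- nrow(true_fixes)
    p <- local_unproject(xy$x + rnorm(n, 0, s), xy$y + rnorm(n, 0, s), origin)
    gf <- true_fixes
    gf$lon <- p$lon; gf$lat <- p$lat
    gf$method <- "GPS"
    gf$track_id <- paste0(true_fixes$track_id, "_r", r)
    gf
  })
  structure(list(true_fixes = true_fixes, gps_repeats = reps,
                 true_states = NULL),
            class = "sim_track")
}

#' Simulate a step series from the movement HMM
#'
#' States follow the Markov chain started from its stationary law; step
#' lengths are zero-inflated gamma and turning angles von Mises, per state.
#' The series also carries latent absolute azimuths: the initial heading is
#' uniform on the circle and each turning angle rotates it, with the heading
#' persisting through zero-length (passive) steps.
#'
#' @param params An [hmm_params()] object.
#' @param n_steps Number of steps (>= 2).
#' @param seed Optional integer seed.
#' @return List with `series` (a `step_series`), `states` (integer vector of
#'   true states, one per step) and `headings` (latent absolute angles in
#'   radians, one per step, defined even for zero-length steps).
#' @export
simulate_hmm_track <- function(params, n_steps, seed = NULL) {
  if (!inherits(params, "hmm_params")) stop("params must be hmm_params")
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  states <- integer(n_steps)
  states[1] <- sample(1:2, 1, prob = params$delta)
  for (t in 2:n_steps)
    states[t] <- sample(1:2, 1, prob = params$Gamma[states[t - 1], ])
  zero <- rbinom(n_steps, 1, params$zero_mass[states]) == 1
  shape <- params$step_mean^2 / params$step_sd^2
  rate <- params$step_mean / params$step_sd^2
  steps <- ifelse(zero, 0,
                  rgamma(n_steps, shape = shape[states], rate = rate[states]))
  turns <- vapply(2:n_steps, function(t)
    rvonmises(1, params$angle_mean[states[t]], params$angle_conc[states[t]]),
    numeric(1))
  heading <- numeric(n_steps)  # absolute angle, radians
  heading[1] <- runif(1, -pi, pi)
  for (t in 2:n_steps) heading[t] <- wrap_pi(heading[t - 1] + turns[t - 1])
  az <- absangle_to_azimuth(heading)
  az[steps == 0] <- NA_real_
  list(series = step_series(steps, az, turns), states = states,
       headings = heading)
}

#' Simulate paired DB and GPS recordings of beetle-like tracks
#'
#' HMM-driven true paths with passive (sub-threshold) fixes, recorded both as
#' error-free distance-bearing fixes and as GPS fixes with positional noise.
#' A fix is flagged passive when the true distance covered since the previous
#' fix is below `passive_threshold`; the release fix (order 0) is active by
#' convention. Starts are spaced on a coarse grid so tracks do not share an
#' origin.
#'
#' @param n_tracks Number of animals (default 6).
#' @param n_fixes Fixes per track including the release point (default 27,
#'   matching the scale of a 4-hourly, multi-day field schedule).
#' @param params HMM parameters; default [default_hmm_init()] with
#'   zero inflation 0.5 in both states.
#' @param error_model A [gps_error_model()]; the field default inflates the
#'   base 3 m sigma by canopy and rain factors of 1.5.
#' @param passive_threshold Passive cutoff in meters (default 0.5).
#' @param start `c(lon, lat)` of the first release point.
#' @param n_repeats GPS repeats per track (default 1, as in the field).
#' @param seed Optional integer seed.
#' @return List with `db` (fix data.frame over all tracks), `gps` (ditto),
#'   and `states` (list of true state vectors per track).
#' @export
simulate_beetle_tracks <- function(n_tracks = 6, n_fixes = 27,
                                   params = default_hmm_init(zero_mass = c(0.5, 0.5)),
                                   error_model = gps_error_model(
                                     sigma = 3, canopy_factor = 1.5,
                                     rain_factor = 1.5),
                                   passive_threshold = 0.5,
                                   start = c(18.9105, 47.6741),
                                   n_repeats = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  db_all <- list(); gps_all <- list(); states <- list()
  for (k in seq_len(n_tracks)) {
    id <- paste0("B", k)
    sim <- simulate_hmm_track(params, n_fixes - 1, seed = NULL)
    # release points 50 m apart on an east-west line
    origin <- local_unproject(50 * (k - 1), 0, start)
    # headings are absolute angles (ccw from east): x east = d cos(theta),
    # y north = d sin(theta)
    x <- c(0, cumsum(sim$series$step_lengths * cos(sim$headings)))
    y <- c(0, cumsum(sim$series$step_lengths * sin(sim$headings)))
    p <- local_unproject(x, y, c(origin$lon, origin$lat))
    active <- c(TRUE, sim$series$step_lengths >= passive_threshold)
    db <- data.frame(track_id = id, order = 0:(n_fixes - 1), method = "DB",
                     lon = p$lon, lat = p$lat, active = active,
                     stringsAsFactors = FALSE)
    st <- simulate_gps(db, error_model, n_repeats = n_repeats)
    db_all[[k]] <- db
    gps_all[[k]] <- do.call(rbind, st$gps_repeats)
    states[[id]] <- sim$states
  }
  list(db = do.call(rbind, db_all), gps = do.call(rbind, gps_all),
       states = states)
}
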