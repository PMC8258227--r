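# Shared fixtures and independent oracles for the HMM and geometry tests.

# Emission matrix built directly from the exported densities (the recursion
# under test never sees this code path).
oracle_emissions <- function(series, params) {
  x <- series$step_lengths
  ang <- c(NA_real_, series$turning_angles)
  E <- matrix(NA_real_, length(x), 2)
  for (s in 1:2) {
    E[, s] <- step_density(x, params, s)
    ok <- !is.na(ang)
    E[ok, s] <- E[ok, s] * angle_density(ang[ok], params, s)
  }
  E
}

# Exhaustive-path likelihood: sum over all 2^n state sequences.
brute_loglik <- function(series, params) {
  E <- oracle_emissions(series, params)
  n <- nrow(E)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  lik <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    w <- params$delta[s[1]] * E[1, s[1]]
    if (n > 1) for (t in 2:n)
      w <- w * params$Gamma[s[t - 1], s[t]] * E[t, s[t]]
    lik <- lik + w
  }
  log(lik)
}

# Exhaustive-path Viterbi: the jointly most probable sequence. Paths are
# enumerated with state 1 varying last so ties resolve toward state 1.
brute_viterbi <- function(series, params) {
  E <- oracle_emissions(series, params)
  n <- nrow(E)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  paths <- paths[order(apply(paths, 1, paste, collapse = "")), , drop = FALSE]
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    w <- log(params$delta[s[1]]) + log(E[1, s[1]])
    if (n > 1) for (t in 2:n)
      w <- w + log(params$Gamma[s[t - 1], s[t]]) + log(E[t, s[t]])
    if (w > best) { best <- w; best_path <- s }
  }
  list(path = unname(best_path), logprob = best)
}

# Random valid two-state parameter sets for property tests.
random_hmm_params <- function(zero_mass = c(0, 0)) {
  m <- sort(c(runif(1, 0.5, 2), runif(1, 5, 15)))
  hmm_params(step_mean = m, step_sd = m * runif(2, 0.5, 1.5),
             angle_mean = runif(2, -pi, pi), angle_conc = runif(2, 0, 3),
             Gamma = {
               g12 <- runif(1, 0.05, 0.95); g21 <- runif(1, 0.05, 0.95)
               matrix(c(1 - g12, g12, g21, 1 - g21), 2, 2, byrow = TRUE)
             },
             zero_mass = zero_mass)
}

# Random short step series, optionally with zero-length (passive) steps whose
# azimuths and adjacent turning angles are undefined.
random_series <- function(n, with_zeros = FALSE) {
  d <- runif(n, 0.2, 15)
  if (with_zeros && n > 2) d[sample(n, max(1, n %/% 4))] <- 0
  az <- ifelse(d > 0, runif(n, 0, 360), NA_real_)
  theta <- suppressWarnings(azimuth_to_absangle(ifelse(is.na(az), 0, az)))
  theta[is.na(az)] <- NA_real_
  turn <- if (n > 1) wrap_pi(diff(theta)) else numeric(0)
  step_series(d, az, turn)
}

# A straight toy track: n fixes due north, step_m apart, as a fix data.frame.
toy_track <- function(track_id = "T1", n = 5, step_m = 10, method = "DB",
                      start = c(19.06, 47.47)) {
  steps <- data.frame(track_id = track_id, order = seq_len(n - 1),
                      distance_m = step_m, azimuth_deg = 0,
                      frame = "magnetic", stringsAsFactors = FALSE)
  p <- db_to_coords(start, steps)
  data.frame(track_id = track_id, order = 0:(n - 1), method = method,
             lon = p$lon, lat = p$lat, active = TRUE,
             stringsAsFactors = FALSE)
}

# Build a fix data.frame directly from local planar offsets (m east/north).
track_from_xy <- function(x, y, track_id = "T1", method = "DB",
                          start = c(19.06, 47.47), active = NULL) {
  p <- local_unproject(x, y, start)
  data.frame(track_id = track_id, order = seq_along(x) - 1, method = method,
             lon = p$lon, lat = p$lat,
             active = if (is.null(active)) TRUE else active,
             stringsAsFactors = FALSE)
}
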