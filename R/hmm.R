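# Two-state hidden Markov movement model: zero-inflated gamma step lengths,
# von Mises turning angles, states "random walk" (1) and "directed" (2).

#' Construct a two-state movement-HMM parameter set
#'
#' State 1 is the random walk (short steps, dispersed turning angles), state 2
#' the directed movement (long steps, concentrated angles near 0 rad). Step
#' lengths follow a zero-inflated gamma distribution parameterized by mean and
#' SD (shape = mean^2/sd^2, rate = mean/sd^2) with a point mass `zero_mass` on
#' exact-zero (passive) steps; turning angles follow a von Mises distribution.
#'
#' @param step_mean,step_sd Length-2 positive numerics (m), per state.
#' @param angle_mean Length-2, radians in `(-pi, pi]`.
#' @param angle_conc Length-2 von Mises concentrations, >= 0 (0 = uniform).
#' @param Gamma 2x2 transition probability matrix (rows sum to 1).
#' @param zero_mass Length-2 probabilities of an exact-zero step (default 0).
#' @param delta Initial state distribution; `NULL` (default) uses the
#'   stationary distribution of `Gamma`.
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(step_mean, step_sd, angle_mean, angle_conc, Gamma,
                       zero_mass = c(0, 0), delta = NULL) {
  stopifnot(length(step_mean) == 2, length(step_sd) == 2,
            length(angle_mean) == 2, length(angle_conc) == 2,
            length(zero_mass) == 2, all(dim(Gamma) == c(2, 2)))
  if (any(!is.finite(c(step_mean, step_sd, angle_mean, angle_conc, Gamma))))
    stop("non-finite parameter")
  if (any(step_mean <= 0) || any(step_sd <= 0))
    stop("step_mean and step_sd must be positive")
  if (any(angle_conc < 0)) stop("angle_conc must be >= 0")
  if (any(zero_mass < 0 | zero_mass > 1)) stop("zero_mass must be in [0, 1]")
  if (any(Gamma < 0) || any(abs(rowSums(Gamma) - 1) > 1e-8))
    stop("Gamma rows must be nonnegative and sum to 1")
  if (is.null(delta)) delta <- stationary_distribution(Gamma)
  if (abs(sum(delta) - 1) > 1e-8 || any(delta < 0))
    stop("delta must be a probability vector")
  structure(list(step_mean = as.numeric(step_mean),
                 step_sd = as.numeric(step_sd),
                 zero_mass = as.numeric(zero_mass),
                 angle_mean = wrap_pi(as.numeric(angle_mean)),
                 angle_conc = as.numeric(angle_conc),
                 Gamma = unname(Gamma), delta = as.numeric(delta)),
            class = "hmm_params")
}

#' Default movement-HMM starting values
#'
#' The conventional fine-scale carabid parameterization: mean step length 1 m
#' (random walk) and 10 m (directed), SD equal to the mean, angle means pi and
#' 0 rad with concentrations 0.5 and 2.5, and a moderately persistent
#' transition matrix `[[0.8, 0.2], [0.3, 0.7]]`.
#'
#' @param zero_mass Length-2 zero-inflation probabilities; 0 for designs with
#'   no passive steps, 0.5 for field-style tracking data.
#' @return An `hmm_params` object.
#' @export
default_hmm_init <- function(zero_mass = c(0, 0)) {
  hmm_params(step_mean = c(1, 10), step_sd = c(1, 10),
             angle_mean = c(pi, 0), angle_conc = c(0.5, 2.5),
             Gamma = matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE),
             zero_mass = zero_mass)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Two-state movement HMM parameters\n")
  tab <- data.frame(state = c("random walk", "directed"),
                    step_mean = x$step_mean, step_sd = x$step_sd,
                    zero_mass = x$zero_mass,
                    angle_mean = x$angle_mean, angle_conc = x$angle_conc)
  print(tab, row.names = FALSE, digits = 4)
  cat("Gamma:\n"); print(round(x$Gamma, 4))
  cat("delta:", round(x$delta, 4), "\n")
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `delta %*% Gamma = delta`, `sum(delta) = 1` by the standard linear
#' system; errors on reducible chains (singular system).
#'
#' @param Gamma Square transition probability matrix.
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(Gamma) {
  m <- nrow(Gamma)
  A <- t(diag(m) - Gamma + 1)
  delta <- tryCatch(solve(A, rep(1, m)),
                    error = function(e) stop("chain is reducible: ", conditionMessage(e)))
  if (any(delta < -1e-12)) stop("chain is reducible (negative stationary mass)")
  pmax(delta, 0) / sum(pmax(delta, 0))
}

#' Zero-inflated gamma step-length density
#'
#' @param x Step length(s), m, >= 0.
#' @param params An `hmm_params` object.
#' @param state State index (1 or 2).
#' @return Density values; at `x = 0` the zero-inflation point mass.
#' @export
step_density <- function(x, params, state) {
  if (any(x < 0)) stop("step lengths must be >= 0")
  m <- params$step_mean[state]; s <- params$step_sd[state]
  z <- params$zero_mass[state]
  shape <- m^2 / s^2; rate <- m / s^2
  out <- (1 - z) * dgamma(x, shape = shape, rate = rate)
  out[x == 0] <- z
  out
}

#' von Mises turning-angle density
#'
#' `exp(kappa * cos(phi - mu)) / (2 * pi * I0(kappa))`, computed with the
#' exponentially scaled Bessel function for stability at large concentration.
#' At concentration 0 this is the circular uniform density `1/(2*pi)`.
#'
#' @param phi Angle(s), radians in `(-pi, pi]`.
#' @param params An `hmm_params` object.
#' @param state State index (1 or 2).
#' @return Density values.
#' @export
angle_density <- function(phi, params, state) {
  dvonmises(phi, params$angle_mean[state], params$angle_conc[state])
}

dvonmises <- function(phi, mu, kappa) {
  if (kappa == 0) return(rep(1 / (2 * pi), length(phi)))
  exp(kappa * (cos(phi - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm).
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_pi(sign(u[3] - 0.5) * acos(f) + mu)
      i <- i + 1
    }
  }
  out
}

# n x 2 matrix of joint emission probabilities for a step_series.
# Turning angles are aligned so observation t pairs step t with the turning
# angle between steps t-1 and t; the first angle is missing by construction.
# Missing angles contribute step density only (factor 1).
emission_probs <- function(series, params) {
  x <- series$step_lengths
  ang <- c(NA_real_, series$turning_angles)
  n <- length(x)
  P <- matrix(1, n, 2)
  ok <- !is.na(ang)
  for (s in 1:2) {
    P[, s] <- step_density(x, params, s)
    P[ok, s] <- P[ok, s] * angle_density(ang[ok], params, s)
  }
  P
}

#' Forward log-likelihood of a step series under a movement HMM
#'
#' Scaled forward recursion over joint step-length/turning-angle emissions.
#' Each track restarts the chain at the initial distribution `delta`; a list
#' of series gives the sum of per-track log-likelihoods. Missing turning
#' angles (the first step of a track, and steps adjacent to zero-length steps)
#' contribute their step density only.
#'
#' @param series A `step_series` or a list of them.
#' @param params An `hmm_params` object.
#' @return Log-likelihood (scalar).
#' @export
forward_loglik <- function(series, params) {
  if (!inherits(params, "hmm_params")) stop("params must be hmm_params")
  if (inherits(series, "step_series")) series <- list(series)
  sum(vapply(series, function(s) {
    if (length(s$step_lengths) == 0) return(0)
    hmm_forward_cpp(emission_probs(s, params), params$Gamma, params$delta)
  }, numeric(1)))
}

#' Viterbi decoding of movement states
#'
#' Recovers the jointly most probable hidden-state path by log-space dynamic
#' programming. Ties are broken toward state 1 (random walk).
#'
#' @param series A `step_series`.
#' @param params An `hmm_params` object.
#' @return Integer vector of decoded states (1 = random walk, 2 = directed),
#'   one per step.
#' @export
viterbi <- function(series, params) {
  P <- emission_probs(series, params)
  n <- nrow(P)
  if (n == 0) return(integer(0))
  lP <- log(P); lG <- log(params$Gamma)
  v <- log(params$delta) + lP[1, ]
  back <- matrix(1L, n, 2)
  if (n > 1) for (t in 2:n) {
    for (j in 1:2) {
      cand <- v + lG[, j]
      back[t, j] <- which.max(cand)  # first max -> state 1 on ties
      lPtj <- lP[t, j]
      if (j == 1) v1 <- cand[back[t, 1]] + lPtj else v2 <- cand[back[t, 2]] + lPtj
    }
    v <- c(v1, v2)
  }
  states <- integer(n)
  states[n] <- which.max(v)
  if (n > 1) for (t in n:2) states[t - 1] <- back[t, states[t]]
  states
}

# ---- working-scale transforms for fitting -----------------------------------

# Working vector layout: log step means (2), log step sds (2),
# angle coords x1,y1,x2,y2 (mu = atan2(y, x), kappa = sqrt(x^2 + y^2)),
# qlogis off-diagonals of Gamma (g12, g21), then optionally qlogis zero_mass (2).
pack_params <- function(p, est_zero) {
  w <- c(log(p$step_mean), log(p$step_sd),
         p$angle_conc[1] * c(cos(p$angle_mean[1]), sin(p$angle_mean[1])),
         p$angle_conc[2] * c(cos(p$angle_mean[2]), sin(p$angle_mean[2])),
         qlogis(pmin(pmax(c(p$Gamma[1, 2], p$Gamma[2, 1]), 1e-6), 1 - 1e-6)))
  if (est_zero)
    w <- c(w, qlogis(pmin(pmax(p$zero_mass, 1e-6), 1 - 1e-6)))
  w
}

unpack_params <- function(w, est_zero, zero_fixed) {
  kappa1 <- sqrt(w[5]^2 + w[6]^2); kappa2 <- sqrt(w[7]^2 + w[8]^2)
  mu1 <- atan2(w[6], w[5]); mu2 <- atan2(w[8], w[7])
  g12 <- plogis(w[9]); g21 <- plogis(w[10])
  zm <- if (est_zero) plogis(w[11:12]) else zero_fixed
  hmm_params(step_mean = exp(w[1:2]), step_sd = exp(w[3:4]),
             angle_mean = c(mu1, mu2), angle_conc = c(kappa1, kappa2),
             Gamma = matrix(c(1 - g12, g12, g21, 1 - g21), 2, 2, byrow = TRUE),
             zero_mass = zm)
}

# Relabel so state 1 has the smaller step mean.
sort_states <- function(p) {
  if (p$step_mean[1] <= p$step_mean[2]) return(p)
  hmm_params(step_mean = rev(p$step_mean), step_sd = rev(p$step_sd),
             angle_mean = rev(p$angle_mean), angle_conc = rev(p$angle_conc),
             Gamma = p$Gamma[2:1, 2:1], zero_mass = rev(p$zero_mass),
             delta = rev(p$delta))
}

#' Fit the two-state movement HMM by maximum likelihood
#'
#' Direct numerical maximization of the forward log-likelihood on a working
#' scale (log for positive parameters, logit for probabilities, per-state
#' unconstrained Cartesian pair for the von Mises mean/concentration). The
#' initial state distribution is fixed to the stationary distribution of the
#' transition matrix. Zero-inflation masses are estimated only when the data
#' contain exact-zero steps, and held at their initial values otherwise.
#' Seeded, jittered multi-starts guard against local optima. After
#' convergence, states are relabeled so state 1 has the smaller step mean.
#'
#' @param series A `step_series` or list of them (each track restarts the
#'   chain at the stationary distribution).
#' @param init An `hmm_params` starting point; see [default_hmm_init()].
#' @param n_starts Number of optimizer starts (first from `init`, the rest
#'   jittered on the working scale). Default 5.
#' @param jitter_sd SD of working-scale jitter for extra starts.
#' @param seed Optional integer seed for the jitter draws.
#' @param maxit,reltol Passed to [stats::optim()] (BFGS).
#' @param decode If `TRUE` (default), Viterbi-decode every track under the
#'   fitted parameters.
#' @return Object of class `fitted_hmm`: `params`, `log_likelihood`, `n_obs`,
#'   `npar`, `aic`, `converged`, and `decoded_states` (list per track).
#' @export
fit_hmm <- function(series, init = default_hmm_init(), n_starts = 5,
                    jitter_sd = 0.25, seed = NULL, maxit = 500,
                    reltol = 1e-8, decode = TRUE) {
  if (inherits(series, "step_series")) series <- list(series)
  n_obs <- sum(vapply(series, function(s) length(s$step_lengths), numeric(1)))
  if (n_obs < 20) stop("need at least 20 steps in total to fit the HMM")
  has_zeros <- any(vapply(series, function(s) any(s$step_lengths == 0),
                          logical(1)))
  est_zero <- has_zeros
  zero_fixed <- init$zero_mass
  Plist <- NULL  # emissions rebuilt each eval; series captured in closure

  negll <- function(w) {
    p <- tryCatch(unpack_params(w, est_zero, zero_fixed),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- tryCatch(suppressWarnings(forward_loglik(series, p)),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  w0 <- pack_params(init, est_zero)
  if (!is.null(seed)) set.seed(seed)
  starts <- list(w0)
  if (n_starts > 1)
    for (k in 2:n_starts)
      starts[[k]] <- w0 + rnorm(length(w0), 0, jitter_sd)

  best <- NULL
  for (w in starts) {
    fit <- tryCatch(
      optim(w, negll, method = "BFGS",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")

  params <- sort_states(unpack_params(best$par, est_zero, zero_fixed))
  ll <- -best$value
  npar <- length(best$par)
  occ <- table(factor(unlist(lapply(series, viterbi, params = params)),
                      levels = 1:2))
  if (any(occ == 0))
    warning("degenerate state: one state has no decoded occupancy")
  out <- structure(list(params = params, log_likelihood = ll, n_obs = n_obs,
                        npar = npar, aic = 2 * npar - 2 * ll,
                        converged = best$convergence == 0,
                        decoded_states = NULL),
                   class = "fitted_hmm")
  if (decode) {
    out$decoded_states <- lapply(series, viterbi, params = params)
    names(out$decoded_states) <- names(series)
  }
  out
}

#' @export
print.fitted_hmm <- function(x, ...) {
  cat(sprintf("Fitted two-state movement HMM: logLik = %.3f, AIC = %.3f, n = %d steps%s\n",
              x$log_likelihood, x$aic, x$n_obs,
              if (x$converged) "" else " (NOT converged)"))
  print(x$params)
  invisible(x)
}

#' Tabular report of a fitted HMM
#'
#' @param fit A `fitted_hmm`.
#' @return A data.frame with one row per state and columns for every emission
#'   parameter, plus attributes `Gamma`, `delta`, `logLik`, `AIC`.
#' @export
hmm_report <- function(fit) {
  p <- fit$params
  tab <- data.frame(state = c("random_walk", "directed"),
                    step_mean = p$step_mean, step_sd = p$step_sd,
                    zero_mass = p$zero_mass, angle_mean = p$angle_mean,
                    angle_conc = p$angle_conc)
  attr(tab, "Gamma") <- p$Gamma
  attr(tab, "delta") <- p$delta
  attr(tab, "logLik") <- fit$log_likelihood
  attr(tab, "AIC") <- fit$aic
  tab
}
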