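test_that("step density carries the zero-inflation point mass", {
  p <- default_hmm_init(zero_mass = c(0.5, 0.5))
  expect_equal(step_density(0, p, 1), 0.5)
  expect_equal(step_density(0, p, 2), 0.5)
  p0 <- default_hmm_init()
  x <- c(0.3, 1, 4)
  expect_equal(step_density(x, p0, 2),
               dgamma(x, shape = 100 / 100, rate = 10 / 100))
  # continuous part integrates to 1 - zero_mass
  for (s in 1:2) {
    q <- integrate(function(x) step_density(x, p, s), 0, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(q, 0.5, tolerance = 1e-6)
  }
  expect_error(step_density(-1, p, 1), ">= 0")
})

test_that("turning-angle density is von Mises with a uniform limit", {
  p <- hmm_params(step_mean = c(1, 10), step_sd = c(1, 10),
                  angle_mean = c(pi, 0.7), angle_conc = c(0, 2.5),
                  Gamma = matrix(c(.8, .2, .3, .7), 2, 2, byrow = TRUE))
  phi <- seq(-pi + 0.01, pi, length.out = 101)
  expect_equal(angle_density(phi, p, 1), rep(1 / (2 * pi), 101))
  d2 <- angle_density(phi, p, 2)
  expect_equal(phi[which.max(d2)], 0.7, tolerance = 0.05)  # mode at the mean
  for (s in 1:2) {
    q <- integrate(function(x) angle_density(x, p, s), -pi, pi,
                   rel.tol = 1e-12)$value
    expect_equal(q, 1, tolerance = 1e-8)
  }
})

test_that("stationary distribution solves delta Gamma = delta", {
  expect_equal(stationary_distribution(matrix(0.5, 2, 2)), c(0.5, 0.5))
  G <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  d <- stationary_distribution(G)
  expect_equal(d, c(0.75, 0.25))                       # 0.1 d1 = 0.3 d2
  expect_lt(max(abs(d %*% G - d)), 1e-12)
  expect_error(stationary_distribution(diag(2)), "reducible")
})

test_that("forward likelihood degenerates to iid emissions for a frozen chain", {
  set.seed(51)
  p <- random_hmm_params()
  # nearly-frozen chain in state 1 with all start mass there
  G <- matrix(c(1 - 1e-12, 1e-12, 1e-12, 1 - 1e-12), 2, 2, byrow = TRUE)
  p1 <- hmm_params(p$step_mean, p$step_sd, p$angle_mean, p$angle_conc,
                   Gamma = G, delta = c(1, 0))
  s <- random_series(8)
  iid <- sum(log(step_density(s$step_lengths, p1, 1))) +
    sum(log(angle_density(s$turning_angles, p1, 1)))
  expect_equal(forward_loglik(s, p1), iid, tolerance = 1e-6)
})

test_that("forward likelihood matches the exhaustive-path oracle", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    with_zeros <- i %% 3 == 0
    p <- random_hmm_params(zero_mass = if (with_zeros) runif(2, 0.2, 0.6)
                           else c(0, 0))
    s <- random_series(n, with_zeros = with_zeros)
    expect_equal(forward_loglik(s, p), brute_loglik(s, p),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under a joint state relabeling", {
  set.seed(53)
  p <- random_hmm_params()
  swapped <- hmm_params(step_mean = rev(p$step_mean), step_sd = rev(p$step_sd),
                        angle_mean = rev(p$angle_mean),
                        angle_conc = rev(p$angle_conc),
                        Gamma = p$Gamma[2:1, 2:1], delta = rev(p$delta))
  s <- random_series(25)
  expect_equal(forward_loglik(s, p), forward_loglik(s, swapped),
               tolerance = 1e-10)
})

test_that("a list of tracks sums per-track likelihoods with chain restarts", {
  set.seed(54)
  p <- random_hmm_params()
  s1 <- random_series(12); s2 <- random_series(9)
  expect_equal(forward_loglik(list(s1, s2), p),
               forward_loglik(s1, p) + forward_loglik(s2, p))
})

test_that("Viterbi matches the exhaustive argmax and stays below total likelihood", {
  set.seed(55)
  for (i in 1:15) {
    n <- sample(3:9, 1)
    p <- random_hmm_params()
    s <- random_series(n)
    oracle <- brute_viterbi(s, p)
    expect_equal(viterbi(s, p), oracle$path)
    expect_lte(oracle$logprob, forward_loglik(s, p) + 1e-10)
  }
})

test_that("a frozen chain decodes constantly in the dominant state", {
  p <- hmm_params(step_mean = c(1, 10), step_sd = c(1, 10),
                  angle_mean = c(pi, 0), angle_conc = c(0.5, 2.5),
                  Gamma = matrix(c(1 - 1e-9, 1e-9, 1e-9, 1 - 1e-9), 2, 2,
                                 byrow = TRUE))
  set.seed(56)
  sim <- simulate_hmm_track(default_hmm_init(), 30)
  path <- viterbi(sim$series, p)
  expect_length(unique(path), 1)
})

test_that("fitting recovers parameters and respects the label convention", {
  truth <- default_hmm_init()
  set.seed(61)
  sim <- simulate_hmm_track(truth, 2000)
  fit <- fit_hmm(sim$series, init = truth, n_starts = 1)
  expect_true(fit$converged)
  expect_lte(fit$params$step_mean[1], fit$params$step_mean[2])
  expect_lt(max(abs(fit$params$step_mean - truth$step_mean) /
                  truth$step_mean), 0.1)
  # decoding accuracy against the true states
  expect_gte(mean(unlist(fit$decoded_states) == sim$states), 0.9)
  # refitting from the optimum cannot decrease the log-likelihood
  refit <- fit_hmm(sim$series, init = fit$params, n_starts = 1)
  expect_gte(refit$log_likelihood, fit$log_likelihood - 1e-6)
})

test_that("jittered multi-starts land on the same optimum", {
  truth <- default_hmm_init()
  set.seed(62)
  sim <- simulate_hmm_track(truth, 600)
  fit1 <- fit_hmm(sim$series, init = truth, n_starts = 3, seed = 99)
  fit2 <- fit_hmm(sim$series, init = truth, n_starts = 3, seed = 100)
  expect_lt(abs(fit1$log_likelihood - fit2$log_likelihood), 1e-3)
  expect_gte(fit1$log_likelihood,
             fit_hmm(sim$series, init = truth, n_starts = 1)$log_likelihood - 1e-6)
})

test_that("zero-inflated series are fitted with an estimated zero mass", {
  truth <- default_hmm_init(zero_mass = c(0.5, 0.5))
  set.seed(63)
  sim <- simulate_hmm_track(truth, 1500)
  fit <- fit_hmm(sim$series, init = truth, n_starts = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$zero_mass - 0.5)), 0.1)
})

test_that("fit refuses undersized data and reports state occupancy issues", {
  set.seed(64)
  sim <- simulate_hmm_track(default_hmm_init(), 10)
  expect_error(fit_hmm(sim$series), "at least 20")
})
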