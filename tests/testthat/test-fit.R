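test_that("working-scale transforms round-trip a model", {
  m <- random_model(3, seed = 30, covariates = "temperature_c")
  v <- herdhmm:::pack_params(m)
  m2 <- herdhmm:::unpack_params(v, 3, "temperature_c", "truncnorm")
  expect_equal(m2$emissions, m$emissions, tolerance = 1e-9)
  expect_equal(m2$beta, m$beta, tolerance = 1e-12)
  expect_equal(m2$pi0, m$pi0, tolerance = 1e-12)
  expect_equal(herdhmm:::n_free_params(3, 0), 23L)
  expect_equal(length(v), herdhmm:::n_free_params(3, 1))
})

test_that("optimisation never degrades the starting likelihood", {
  m <- reference_model()
  st <- simulate_states(m, 2000, seed = 31)
  d <- sim_series_for_states(m, st, seed = 32)
  f <- fit_hmm(d, 3, init = m, max_iter = 200)
  expect_gte(f$loglik, log_likelihood(m, d) - 1e-6)
  expect_true(f$converged)
})

test_that("one-state fit recovers the zero-excluded sample moments", {
  m1 <- hmm_model(emission_params(150, 80, 0.05, 0, 0.8),
                  gamma = matrix(1), pi0 = 1)
  d <- sim_series_for_states(m1, rep(1L, 8000), seed = 33)
  f <- fit_hmm(d, 1, init = hmm_model(
    emission_params(100, 100, 0.01, 0.1, 1), gamma = matrix(1), pi0 = 1))
  pos <- d$step_m[d$step_m > 0]
  # the truncated-normal MLE of (mu, sigma) is not the sample moments, but
  # at mu/sigma ~ 2 truncation is mild; compare against the fitted law's
  # own implied moments instead of the raw parameters
  em <- f$model$emissions
  a <- -em$mu / em$sigma
  lambda <- dnorm(a) / (1 - pnorm(a))
  implied_mean <- em$mu + em$sigma * lambda
  implied_var <- em$sigma^2 * (1 + a * lambda - lambda^2)
  expect_equal(implied_mean, mean(pos), tolerance = 0.01)
  expect_equal(sqrt(implied_var), sd(pos), tolerance = 0.01)
  expect_equal(em$zeta, mean(d$step_m == 0), tolerance = 0.01)
})

test_that("a fit from near truth recovers well-separated parameters", {
  m <- reference_model()
  st <- simulate_states(m, 8000, seed = 34)
  d <- sim_series_for_states(m, st, seed = 35)
  init <- hmm_model(
    emission_params(c(20, 150, 600), c(20, 120, 500), c(1e-3, 1e-5, 1e-5),
                    c(-3, 0.1, 0), c(0.5, 0.5, 1.5)),
    gamma = matrix(c(0.8, 0.1, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1, 0.8), 3),
    pi0 = rep(1/3, 3))
  f <- fit_hmm(d, 3, init = init)
  expect_lt(max(abs(f$model$emissions$mu / m$emissions$mu - 1)), 0.05)
  G <- transition_matrix(f$model)
  expect_lt(max(abs(G - synthetic_reference_gamma())), 0.05)
})

test_that("multistart is deterministic and reports consensus", {
  m <- reference_model()
  st <- simulate_states(m, 3000, seed = 36)
  d <- sim_series_for_states(m, st, seed = 37)
  f1 <- multistart_fit(d, 3, n_restarts = 4, seed = 99, max_iter = 300)
  f2 <- multistart_fit(d, 3, n_restarts = 4, seed = 99, max_iter = 300)
  expect_identical(f1$model$emissions, f2$model$emissions)
  expect_identical(f1$restarts$loglik, f2$restarts$loglik)
  expect_true(f1$consensus >= 0 && f1$consensus <= 1)
  expect_equal(nrow(f1$restarts), 4)
})

test_that("degenerate sampling limits pin the starting point", {
  m <- reference_model()
  st <- simulate_states(m, 500, seed = 38)
  d <- sim_series_for_states(m, st, seed = 39)
  em <- m$emissions
  pin <- list(mu = cbind(em$mu, em$mu), sigma = cbind(em$sigma, em$sigma),
              mu_angle = cbind(em$mu_angle, em$mu_angle),
              kappa = cbind(em$kappa, em$kappa),
              zeta = cbind(em$zeta, em$zeta))
  f <- multistart_fit(d, 3, bounds = pin, n_restarts = 2, seed = 40,
                      max_iter = 150)
  # both restarts start identically, so they end identically
  expect_equal(f$restarts$loglik[1], f$restarts$loglik[2],
               tolerance = 1e-8)
  expect_error(multistart_fit(d, 3,
                              bounds = modifyList(pin, list(
                                mu = cbind(em$mu, em$mu - 1))),
                              n_restarts = 1, seed = 1),
               "well-ordered")
})
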