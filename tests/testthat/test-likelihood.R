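test_that("forward log-likelihood equals the exhaustive-path sum", {
  m <- random_model(3, seed = 1)
  st <- simulate_states(m, 4, seed = 2)
  d <- sim_series_for_states(m, st, seed = 3)
  expect_equal(log_likelihood(m, d), brute_loglik(m, d),
               tolerance = 1e-10)
  # with a temperature covariate on the transitions
  mc <- random_model(3, seed = 4, covariates = "temperature_c")
  dc <- sim_series_for_states(mc, st, seed = 5,
                              covariates = data.frame(
                                temperature_c = c(25, 30, 38, 44)))
  expect_equal(log_likelihood(mc, dc), brute_loglik(mc, dc),
               tolerance = 1e-10)
})

test_that("one-state likelihood is the plain sum of emission log densities", {
  m1 <- hmm_model(emission_params(100, 60, 0.02, 0.5, 1.2),
                  gamma = matrix(1), pi0 = 1)
  st <- rep(1L, 50)
  d <- sim_series_for_states(m1, st, seed = 6)
  expect_equal(log_likelihood(m1, d), sum(emission_matrix_R(m1, d)),
               tolerance = 1e-10)
  expect_true(all(viterbi(m1, d) == 1L))
})

test_that("likelihood is invariant under simultaneous state permutation", {
  m <- random_model(3, seed = 7)
  st <- simulate_states(m, 60, seed = 8)
  d <- sim_series_for_states(m, st, seed = 9)
  base <- log_likelihood(m, d)
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(3, 2, 1)))
    expect_equal(log_likelihood(herdhmm:::permute_states(m, perm), d),
                 base, tolerance = 1e-10)
})

test_that("segments are independent: likelihood adds over segments", {
  m <- random_model(2, seed = 10)
  st <- simulate_states(m, 40, seed = 11)
  d <- sim_series_for_states(m, st, seed = 12)
  d2 <- d
  d2$segment_id <- rep(c("a", "b"), each = 20)
  d2$angle_rad[21] <- NA # new segment loses its first angle
  da <- as_two <- d2[1:20, ]; db <- d2[21:40, ]
  expect_equal(log_likelihood(m, d2),
               log_likelihood(m, herdhmm:::as_step_series(da)) +
                 log_likelihood(m, herdhmm:::as_step_series(db)),
               tolerance = 1e-10)
})

test_that("viterbi equals the brute-force argmax and breaks ties low", {
  m <- random_model(3, seed = 13)
  st <- simulate_states(m, 5, seed = 14)
  d <- sim_series_for_states(m, st, seed = 15)
  expect_identical(viterbi(m, d), brute_viterbi(m, d))
  # exact tie: identical states, uniform transitions -> all paths tie,
  # decoder must return all-ones
  em <- emission_params(c(50, 50), c(20, 20), c(0, 0), c(0, 0), c(1, 1))
  mt <- hmm_model(em, gamma = matrix(0.5, 2, 2), pi0 = c(0.5, 0.5))
  dt <- sim_series_for_states(mt, rep(1L, 6), seed = 16)
  expect_true(all(viterbi(mt, dt) == 1L))
})

test_that("forward and viterbi match brute force across a seeded sweep", {
  # moderate sweep here; the full 200-instance sweep runs in the
  # acceptance suite
  count <- 0
  for (seed in 1:40) {
    set.seed(seed + 1000)
    N <- sample(1:3, 1)
    T <- sample(2:8, 1)
    m <- random_model(N, seed = seed)
    st <- simulate_states(m, T, seed = seed + 1)
    d <- sim_series_for_states(m, st, seed = seed + 2)
    expect_equal(log_likelihood(m, d), brute_loglik(m, d),
                 tolerance = 1e-10)
    expect_identical(viterbi(m, d), brute_viterbi(m, d))
    count <- count + 1
  }
  expect_equal(count, 40)
})

test_that("invalid inputs raise errors rather than returning NaN", {
  m <- random_model(2, seed = 17)
  expect_error(log_likelihood(m, step_series(character(0), numeric(0))),
               "at least one")
  d <- sim_series_for_states(m, rep(1L, 10), seed = 18)
  expect_error(step_series(rep("a", 3), c(1, -2, 3)), "non-negative")
  mc <- random_model(2, seed = 19, covariates = "temperature_c")
  expect_error(log_likelihood(mc, d), "covariate")
})
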