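test_that("state simulation follows the chain's stationary behaviour", {
  em3 <- emission_params(c(10, 100, 500), c(5, 50, 200), rep(0, 3),
                         rep(0, 3), c(0.3, 0.2, 2))
  # absorbing chain: (numerically) identity transitions, start at state 2
  G_abs <- matrix(1e-4, 3, 3); diag(G_abs) <- 1 - 2e-4
  m_abs <- hmm_model(em3, gamma = G_abs, pi0 = c(0, 1, 0))
  m_abs$beta[] <- -30 # push off-diagonals to exp(-30): exactly absorbing
  expect_true(all(simulate_states(m_abs, 100, seed = 1) == 2L))
  # doubly stochastic uniform chain: frequencies 1/3 each
  m_unif <- hmm_model(em3, gamma = matrix(1 / 3, 3, 3), pi0 = rep(1 / 3, 3))
  st <- simulate_states(m_unif, 30000, seed = 2)
  expect_equal(tabulate(st, 3) / 30000, rep(1 / 3, 3), tolerance = 0.01)
  # 2-state chain [[0.9,0.1],[0.5,0.5]]: stationary pi = (5/6, 1/6)
  em2 <- emission_params(c(10, 100), c(5, 50), c(0, 0), c(0, 0), c(1, 1))
  m2 <- hmm_model(em2, gamma = matrix(c(0.9, 0.1, 0.5, 0.5), 2,
                                      byrow = TRUE), pi0 = c(0.5, 0.5))
  st2 <- simulate_states(m2, 50000, seed = 3)
  expect_equal(mean(st2 == 1), 5 / 6, tolerance = 0.01)
})

test_that("ergodic chains converge to the analytic stationary law", {
  for (seed in c(7, 8, 9)) {
    m <- random_model(3, seed = seed)
    G <- transition_matrix(m)
    # stationary distribution: left eigenvector of G for eigenvalue 1
    ev <- eigen(t(G))
    pi_st <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
    pi_st <- pi_st / sum(pi_st)
    n <- 30000
    st <- simulate_states(m, n, seed = seed + 100)
    freq <- tabulate(st, 3) / n
    expect_lt(max(abs(freq - pi_st)), 3 / sqrt(n) * 3)
  }
})

test_that("degenerate straight-line state yields collinear equal steps", {
  em <- emission_params(100, 1e-6, 0, wrap_angle(pi * 2), 1e7)
  # mu_angle 0 via wrap, kappa huge, sigma tiny -> straight line
  m <- hmm_model(em, gamma = matrix(1), pi0 = 1)
  tr <- simulate_track(m, rep(1L, 10), start = c(-16.5, 14.5), seed = 4)
  xy <- local_xy(tr, c(-16.5, 14.5))
  d <- diff(xy)
  steps <- sqrt(rowSums(d^2))
  expect_equal(steps, rep(100, 10), tolerance = 1e-3)
  headings <- atan2(d[, 2], d[, 1])
  expect_lt(max(abs(diff(headings))), 1e-3)
})

test_that("resting-state simulated steps match the published mean", {
  m <- reference_model()
  set.seed(5)
  x <- rstep(10000, m$emissions$mu[1], m$emissions$sigma[1],
             m$emissions$zeta[1])
  pos <- x[x > 0]
  # truncated-normal mean implied by (mu, sigma) = (13.53, 11.99)
  a <- -m$emissions$mu[1] / m$emissions$sigma[1]
  lam <- dnorm(a) / (1 - pnorm(a))
  expected <- m$emissions$mu[1] + m$emissions$sigma[1] * lam
  se <- sd(pos) / sqrt(length(pos))
  expect_lt(abs(mean(pos) - expected), 2 * se + 1e-9)
  # and the published 13.53 m is within a whisker of that implied mean
  expect_equal(expected, 13.53, tolerance = 0.25)
})

test_that("a reversal state walks back and forth, not away", {
  em <- emission_params(100, 1, 0, wrap_angle(pi), 50)
  m <- hmm_model(em, gamma = matrix(1), pi0 = 1)
  tr <- simulate_track(m, rep(1L, 500), start = c(-16.5, 14.5), seed = 6)
  xy <- local_xy(tr, c(-16.5, 14.5))
  net <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  total <- sum(sqrt(rowSums(diff(xy)^2)))
  expect_lt(net / total, 0.05)
})

test_that("gps noise is exact at sd 0 and Rayleigh-scaled otherwise", {
  pos <- data.frame(lon = rep(-16.5, 1000), lat = rep(14.5, 1000))
  expect_identical(add_gps_noise(pos, 0), pos)
  sd_m <- 5
  noisy <- add_gps_noise(pos, sd_m, seed = 7)
  series <- compute_steps(cbind(noisy, segment_id = "s"),
                          distance_mode = "planar")
  # mean distance between two independent 2-D gaussians = sd * sqrt(pi)
  expect_equal(mean(series$step_m), sd_m * sqrt(pi), tolerance = 0.05)
  # turning angles of a jittered stationary point concentrate at +-pi
  ang <- series$angle_rad[!is.na(series$angle_rad)]
  expect_lt(herdhmm:::angle_dist(herdhmm:::circular_mean(ang), pi), 0.2)
  expect_gt(herdhmm:::circular_resultant(ang), 0.1)
})

test_that("the 95% radial error quantile calibration holds", {
  sd_m <- gps_noise_sd_for_quantile(10, 0.95)
  set.seed(8)
  r <- sqrt(rnorm(40000, 0, sd_m)^2 + rnorm(40000, 0, sd_m)^2)
  expect_equal(unname(quantile(r, 0.95)), 10, tolerance = 0.1)
})
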