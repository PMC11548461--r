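# Shared fixtures: observation-series simulator driven by a model's own
# emission laws, and exhaustive-path oracles for the forward likelihood and
# Viterbi decoding (enumeration over all state paths; tractable for the
# tiny instances used in tests).

# simulate a step/angle series for a given latent state sequence
sim_series_for_states <- function(model, states, seed = 1,
                                  covariates = NULL) {
  simulate_series(model, states, seed = seed, covariates = covariates)
}

# per-observation transition matrices (t = 2..T uses the covariate row t)
gamma_list <- function(model, data) {
  T <- nrow(data)
  if (!length(model$covariates)) {
    G <- transition_matrix(model)
    return(rep(list(G), T))
  }
  zmat <- as.matrix(data[model$covariates])
  lapply(seq_len(T), function(t) transition_matrix(model, zmat[t, ]))
}

# per-observation log emission matrix computed in R (independent of the
# C++ path): step density x angle density
emission_matrix_R <- function(model, data) {
  em <- model$emissions
  sapply(seq_len(model$n_states), function(i) {
    l <- step_log_density(data$step_m, em$mu[i], em$sigma[i], em$zeta[i],
                          family = model$step_family)
    ok <- !is.na(data$angle_rad)
    l[ok] <- l[ok] + angle_log_density(data$angle_rad[ok], em$mu_angle[i],
                                       em$kappa[i])
    l
  })
}

# log probability of every latent path (rows of the returned matrix of
# paths align with the vector of log probabilities)
brute_path_logprobs <- function(model, data) {
  lb <- emission_matrix_R(model, data)
  T <- nrow(data)
  N <- model$n_states
  Gs <- gamma_list(model, data)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T)))
  lp <- apply(paths, 1, function(s) {
    l <- log(model$pi0[s[1]]) + lb[1, s[1]]
    if (T > 1) for (t in 2:T)
      l <- l + log(Gs[[t]][s[t - 1], s[t]]) + lb[t, s[t]]
    l
  })
  list(paths = paths, lp = lp)
}

# brute-force log-likelihood: sum over all n_states^T latent paths
brute_loglik <- function(model, data) {
  lp <- brute_path_logprobs(model, data)$lp
  mx <- max(lp)
  mx + log(sum(exp(lp - mx)))
}

# brute-force Viterbi: argmax path, ties toward the lexicographically
# smallest path (expand.grid varies the first index fastest, so the first
# maximal row has the lowest early state indices)
brute_viterbi <- function(model, data) {
  b <- brute_path_logprobs(model, data)
  unname(b$paths[which.max(b$lp), ])
}

# a random valid model for property sweeps
random_model <- function(n_states, seed, covariates = character(0)) {
  set.seed(seed)
  em <- emission_params(
    mu = sort(exp(runif(n_states, log(10), log(800)))),
    sigma = exp(runif(n_states, log(8), log(400))),
    zeta = runif(n_states, 0, 0.05),
    mu_angle = wrap_angle(runif(n_states, -pi, pi)),
    kappa = runif(n_states, 0, 3))
  G <- matrix(runif(n_states^2, 0.05, 1), n_states)
  G <- G / rowSums(G)
  p <- runif(n_states, 0.1, 1)
  beta <- beta_from_gamma(G)
  if (length(covariates)) {
    beta <- rbind(beta, matrix(runif(length(covariates) * ncol(beta),
                                     -0.2, 0.2),
                               nrow = length(covariates)))
  }
  hmm_model(em, beta = beta, pi0 = p / sum(p), covariates = covariates)
}

# small survey used by several test files (cached per session)
small_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_survey(sim_config(
        n_herds = 2, herd_types = c("resident", "transhumant"),
        n_days = 30, seed = 42))
    cache
  }
})
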