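# State-sequence and track simulation from a behaviour model.

#' Simulate a latent state sequence
#'
#' First state drawn from `pi0`; each subsequent state from the row of the
#' transition matrix of the previous state, evaluated at that step's
#' covariate values when the model declares covariates.
#'
#' @param model an `hmm_model`.
#' @param n_steps sequence length (>= 1).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param covariates optional data.frame (n_steps rows) with the model's
#'   covariate columns.
#' @return integer vector of states (1-based), length `n_steps`.
#' @export
simulate_states <- function(model, n_steps, seed = NULL, covariates = NULL) {
  stopifnot(n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- model$n_states
  p <- length(model$covariates)
  if (p > 0) {
    if (is.null(covariates)) stop("model declares covariates; supply them")
    zmat <- as.matrix(as.data.frame(covariates)[model$covariates])
    stopifnot(nrow(zmat) == n_steps)
  }
  states <- integer(n_steps)
  states[1] <- sample.int(n, 1, prob = model$pi0)
  const_gamma <- p == 0
  if (const_gamma) {
    G <- transition_matrix(model)
    check_stochastic(G)
    # inverse-CDF draw per step keeps one runif per transition
    cum <- t(apply(G, 1, cumsum))
    u <- runif(n_steps)
    for (t in seq_len(n_steps)[-1])
      states[t] <- findInterval(u[t], cum[states[t - 1], ],
                                left.open = TRUE) + 1L
  } else {
    u <- runif(n_steps)
    for (t in seq_len(n_steps)[-1]) {
      G <- transition_matrix(model, zmat[t, ])
      states[t] <- findInterval(u[t], cumsum(G[states[t - 1], ]),
                                left.open = TRUE) + 1L
    }
  }
  states
}

check_stochastic <- function(G) {
  if (any(G < 0) || any(abs(rowSums(G) - 1) > 1e-8))
    stop("transition matrix rows must be probability vectors")
  invisible(TRUE)
}

#' Simulate a GPS track from a state sequence
#'
#' For each step, a length is drawn from the state's zero-inflated step law
#' and a turning angle from its von Mises law; the heading accumulates the
#' turning angles from an initial heading uniform on the circle. Positions
#' are advanced on a local planar frame centred on `start` and re-expressed
#' in WGS84 longitude/latitude.
#'
#' @param model an `hmm_model`.
#' @param states integer state sequence (from [simulate_states()]).
#' @param start numeric `c(lon, lat)` of the first fix.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param init_heading optional initial heading (rad, math convention);
#'   default drawn uniformly.
#' @return data.frame with columns lon, lat (`length(states) + 1` fixes).
#' @export
simulate_track <- function(model, states, start, seed = NULL,
                           init_heading = NULL) {
  if (any(states < 1 | states > model$n_states))
    stop("states invalid for model")
  if (!is.null(seed)) set.seed(seed)
  n <- length(states)
  em <- model$emissions
  fam <- model$step_family
  heading <- init_heading %||% runif(1, -pi, pi)
  xy <- matrix(0, n + 1, 2)
  for (t in seq_len(n)) {
    s <- states[t]
    len <- rstep(1, em$mu[s], em$sigma[s], em$zeta[s], family = fam)
    if (len > 0) {
      turn <- rvonmises(1, em$mu_angle[s], em$kappa[s])
      heading <- wrap_angle(heading + turn)
    }
    xy[t + 1, ] <- xy[t, ] + len * c(cos(heading), sin(heading))
  }
  as.data.frame(local_lonlat(xy, start))
}

#' Simulate an observation series directly from the emission laws
#'
#' Draws one step length and one turning angle per state of `states` from
#' that state's zero-inflated step and von Mises angle laws — the
#' emission-level counterpart of [simulate_track()], used when exact
#' state/observation alignment matters (parameter-recovery studies). The
#' first angle and angles adjacent to zero steps are missing, as in series
#' derived from fixes.
#'
#' @param model an `hmm_model`.
#' @param states integer state sequence.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param covariates optional data.frame of per-step covariates carried
#'   into the series.
#' @return a [step_series()].
#' @export
simulate_series <- function(model, states, seed = NULL, covariates = NULL) {
  if (any(states < 1 | states > model$n_states))
    stop("states invalid for model")
  if (!is.null(seed)) set.seed(seed)
  em <- model$emissions
  n <- length(states)
  step <- numeric(n)
  ang <- numeric(n)
  for (s in sort(unique(states))) {
    ix <- states == s
    step[ix] <- rstep(sum(ix), em$mu[s], em$sigma[s], em$zeta[s],
                      family = model$step_family)
    ang[ix] <- rvonmises(sum(ix), em$mu_angle[s], em$kappa[s])
  }
  ang[step == 0 | c(TRUE, step[-n] == 0)] <- NA
  ang[1] <- NA
  step_series(rep("sim1", n), step, ang, covariates)
}

#' Add isotropic GPS noise to a position sequence
#'
#' Independent Gaussian jitter of scale `sd` per axis, applied in a local
#' planar frame. The radial 95% quantile of the resulting error is
#' `sd * sqrt(-2 log 0.05)` (about 2.45 sd); [gps_noise_sd_for_quantile()]
#' inverts this.
#'
#' @param positions data.frame/matrix with columns lon, lat.
#' @param sd per-axis noise scale, metres (>= 0).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return data.frame lon, lat of the same size.
#' @export
add_gps_noise <- function(positions, sd, seed = NULL) {
  if (sd < 0) stop("sd must be non-negative")
  positions <- as.data.frame(positions)
  if (sd == 0) return(positions)
  if (!is.null(seed)) set.seed(seed)
  centre <- c(mean(positions$lon), mean(positions$lat))
  xy <- local_xy(positions[, c("lon", "lat")], centre)
  n <- nrow(xy)
  xy <- xy + cbind(rnorm(n, 0, sd), rnorm(n, 0, sd))
  out <- as.data.frame(local_lonlat(xy, centre))
  rownames(out) <- rownames(positions)
  out
}

#' Per-axis noise scale matching a radial accuracy quantile
#'
#' Collar data sheets state accuracy as "q of fixes within r metres"; for
#' isotropic Gaussian noise the radial error is Rayleigh, so the per-axis
#' scale is `r / sqrt(-2 log(1 - q))`.
#'
#' @param radius_m accuracy radius in metres.
#' @param q quantile (default 0.95).
#' @return per-axis standard deviation in metres.
#' @export
gps_noise_sd_for_quantile <- function(radius_m = 10, q = 0.95) {
  radius_m / sqrt(-2 * log(1 - q))
}
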