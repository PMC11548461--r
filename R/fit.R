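# Maximum-likelihood fitting: working-scale parameter transforms, a single
# quasi-Newton (nlm) fit, and the multistart wrapper with uniform sampling
# of starting points within per-parameter limits.

# ---- working-scale transforms -------------------------------------------
# mu, sigma, kappa on the log scale; zeta on the logit scale; the angle
# mean unconstrained and wrapped via atan2(sin, cos) (wrap-safe near +-pi);
# beta unconstrained; pi0 as multinomial logits against state 1.

pack_params <- function(model) {
  em <- model$emissions
  c(log(em$mu), log(em$sigma), qlogis(pmin(pmax(em$zeta, 1e-300), 1 - 1e-12)),
    em$mu_angle, log(pmax(em$kappa, 1e-10)),
    as.numeric(model$beta),
    log(model$pi0[-1] / model$pi0[1]))
}

unpack_params <- function(vec, n_states, covariates, step_family) {
  n <- n_states
  p <- length(covariates)
  i <- 0
  take <- function(k) {
    if (k == 0) return(numeric(0))
    out <- vec[(i + 1):(i + k)]; i <<- i + k; out
  }
  mu <- pmax(exp(take(n)), 1e-8); sigma <- pmax(exp(take(n)), 1e-8)
  zeta <- plogis(take(n))
  w <- take(n); mu_angle <- wrap_angle(atan2(sin(w), cos(w)))
  kappa <- pmin(exp(take(n)), 1e8)
  beta <- matrix(take((1 + p) * n * (n - 1)), nrow = 1 + p)
  lp <- c(0, take(n - 1)); pi0 <- exp(lp - max(lp)); pi0 <- pi0 / sum(pi0)
  hmm_model(emission_params(mu, sigma, zeta, mu_angle, kappa),
            beta = beta, pi0 = pi0, covariates = covariates,
            step_family = step_family)
}

n_free_params <- function(n_states, n_covariates = 0) {
  5L * n_states + (1L + n_covariates) * n_states * (n_states - 1L) +
    (n_states - 1L)
}

# negative log-likelihood on the working scale
make_nll <- function(data, n_states, covariates, step_family) {
  m <- series_matrices(data, covariates)
  fam <- if (step_family == "gamma") 2L else 1L
  p <- length(covariates)
  n <- n_states
  function(vec) {
    i <- 0
    take <- function(k) {
      if (k == 0) return(numeric(0))
      out <- vec[(i + 1):(i + k)]; i <<- i + k; out
    }
    mu <- exp(take(n)); sigma <- exp(take(n)); zeta <- plogis(take(n))
    w <- take(n); mu_angle <- atan2(sin(w), cos(w))
    kappa <- exp(take(n))
    beta <- matrix(take((1 + p) * n * (n - 1)), nrow = 1 + p)
    lp <- c(0, take(n - 1)); pi0 <- exp(lp - max(lp)); pi0 <- pi0 / sum(pi0)
    # guard against non-finite excursions and the degenerate likelihood
    # spike of a vanishing step SD (0.1 m is far below GPS noise)
    if (any(!is.finite(c(mu, sigma, kappa))) ||
        any(sigma < 0.1) || any(mu < 0.1) || any(kappa > 1e4))
      return(1e15)
    v <- .cpp_forward_nll(m$step, m$angle, m$seg, m$covar, mu, sigma, zeta,
                          mu_angle, kappa, beta, pi0, fam)
    if (!is.finite(v)) 1e15 else v
  }
}

#' Fit an N-state behaviour model by nonlinear likelihood minimisation
#'
#' Quasi-Newton minimisation (`nlm`) of the negative log-likelihood over
#' unconstrained working parameters, starting from `init`. The achieved
#' log-likelihood is never below that of the starting model (up to
#' optimiser tolerance); non-convergence within `max_iter` returns the best
#' point reached with `converged = FALSE`.
#'
#' @param data a `step_series`.
#' @param n_states number of behaviour states.
#' @param init an `hmm_model` with `n_states` states used as the starting
#'   point (its covariate declaration and step family are adopted).
#' @param max_iter iteration cap for the minimiser.
#' @param gradtol gradient tolerance passed to `nlm`.
#' @return object of class `hmm_fit`: list with `model` (canonicalized),
#'   `loglik`, `n_iter`, `converged`, `restart_id`.
#' @export
fit_hmm <- function(data, n_states = init$n_states, init,
                    max_iter = 1000, gradtol = 1e-6) {
  if (init$n_states != n_states) stop("init must have n_states states")
  nll <- make_nll(data, n_states, init$covariates, init$step_family)
  start <- pack_params(init)
  res <- suppressWarnings(
    nlm(nll, start, iterlim = max_iter, gradtol = gradtol,
        check.analyticals = FALSE))
  model <- unpack_params(res$estimate, n_states, init$covariates,
                         init$step_family)
  structure(list(model = canonicalize(model), loglik = -res$minimum,
                 n_iter = res$iterations,
                 converged = res$code %in% c(1L, 2L, 3L),
                 restart_id = NA_integer_),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("HMM fit: lnL = %.2f, %d iterations, converged = %s\n",
              x$loglik, x$n_iter, x$converged))
  print(x$model)
  invisible(x)
}

#' Default sampling limits for starting points
#'
#' Per-parameter uniform limits used to draw multistart initial values. For
#' three states the limits are those used for the field model (step means
#' 5-100 / 50-250 / 100-1000 m, and so on); zero-inflation starting values
#' are pinned at the observed zero-step fraction for the lowest state and
#' its hundredth elsewhere. For other state counts, geometric bands spread
#' over the same overall range.
#'
#' @param n_states number of states.
#' @param p0 observed fraction of exactly-zero steps (scalar).
#' @return list of `n_states x 2` matrices: `mu`, `sigma`, `zeta`,
#'   `mu_angle`, `kappa` (columns lower, upper; lower = upper pins the
#'   start). Limits constrain initialisation only, never the optimiser.
#' @export
default_bounds <- function(n_states, p0 = P0_REFERENCE) {
  two <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  if (n_states == 3) {
    return(list(
      mu = two(5, 100, 50, 250, 100, 1000),
      sigma = two(5, 100, 50, 500, 100, 1000),
      mu_angle = two(-3, 3, -3, 3, -0.5, 0.5),
      kappa = two(0.1, 1, 1.5, 5, 1, 15),
      zeta = two(p0, p0, p0 / 100, p0 / 100, p0 / 100, p0 / 100)))
  }
  br <- exp(seq(log(5), log(1000), length.out = n_states + 1))
  mu <- cbind(br[-(n_states + 1)], br[-1])
  list(mu = mu, sigma = mu,
       mu_angle = matrix(rep(c(-3, 3), n_states), ncol = 2, byrow = TRUE),
       kappa = cbind(rep(0.1, n_states),
                     c(rep(5, n_states - 1), 15)),
       zeta = cbind(c(p0, rep(p0 / 100, n_states - 1)),
                    c(p0, rep(p0 / 100, n_states - 1))))
}

sample_init <- function(n_states, bounds, covariates, step_family,
                        diag_weight = 0.8) {
  draw <- function(b) runif(n_states, b[, 1], b[, 2])
  em <- emission_params(draw(bounds$mu), draw(bounds$sigma),
                        draw(bounds$zeta),
                        wrap_angle(draw(bounds$mu_angle)),
                        draw(bounds$kappa))
  off <- (1 - diag_weight) / (n_states - 1)
  gamma <- matrix(off, n_states, n_states)
  diag(gamma) <- diag_weight
  beta <- beta_from_gamma(gamma)
  if (length(covariates))
    beta <- rbind(beta, matrix(0, length(covariates), ncol(beta)))
  hmm_model(em, beta = beta, pi0 = rep(1 / n_states, n_states),
            covariates = covariates, step_family = step_family)
}

#' Multistart maximum-likelihood fit
#'
#' Draws `n_restarts` starting parameter sets uniformly within `bounds`,
#' fits each by [fit_hmm()], canonicalizes the results, and returns the
#' best-likelihood fit together with a consensus summary: the fraction of
#' converged restarts whose log-likelihood lies within `delta` log-units of
#' the best (the practical criterion for "the same optimum").
#'
#' @inheritParams fit_hmm
#' @param bounds sampling limits as from [default_bounds()].
#' @param n_restarts number of starting points.
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param covariates character vector of transition covariate names.
#' @param step_family step law family.
#' @param delta consensus window in log-likelihood units.
#' @param max_iter,gradtol passed to [fit_hmm()].
#' @return an `hmm_fit` (the best restart) with extra fields `consensus`,
#'   `n_restarts`, `restarts` (per-restart lnL/convergence table).
#' @export
multistart_fit <- function(data, n_states, bounds = NULL, n_restarts = 10,
                           seed = 1, covariates = character(0),
                           step_family = c("truncnorm", "gamma"),
                           delta = 0.5, max_iter = 1000, gradtol = 1e-6) {
  step_family <- match.arg(step_family)
  p0 <- attr(data, "p0") %||% mean(data$step_m < 1e-6)
  if (!is.finite(p0) || p0 <= 0) p0 <- P0_REFERENCE
  if (is.null(bounds)) bounds <- default_bounds(n_states, p0)
  if (any(bounds$mu[, 1] > bounds$mu[, 2]))
    stop("bounds must be well-ordered (lower <= upper)")
  set.seed(seed)
  inits <- lapply(seq_len(n_restarts), function(r)
    sample_init(n_states, bounds, covariates, step_family))
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    fits[[r]] <- tryCatch(
      fit_hmm(data, n_states, inits[[r]], max_iter = max_iter,
              gradtol = gradtol),
      error = function(e) e)
    if (inherits(fits[[r]], "hmm_fit")) fits[[r]]$restart_id <- r
  }
  ok <- vapply(fits, inherits, logical(1), "hmm_fit")
  if (!any(ok))
    stop("all ", n_restarts, " restarts failed; first error: ",
         conditionMessage(fits[[1]]))
  lls <- vapply(fits[ok], `[[`, numeric(1), "loglik")
  conv <- vapply(fits[ok], `[[`, logical(1), "converged")
  best <- fits[ok][[which.max(lls)]]
  consensus <- mean(conv & (max(lls) - lls <= delta))
  best$consensus <- consensus
  best$n_restarts <- n_restarts
  best$restarts <- data.frame(restart = which(ok), loglik = lls,
                              converged = conv)
  best
}
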