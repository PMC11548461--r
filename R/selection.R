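# State-count selection by BIC and subset refits.

#' Bayesian information criterion
#'
#' `k * ln(n) - 2 * loglik`. Two k conventions circulate for this model
#' family: the standard free-parameter count (default elsewhere in the
#' package) and the number of states; [select_n_states()] reports both.
#'
#' @param loglik log-likelihood.
#' @param k parameter count entering the penalty.
#' @param n number of observations (>= 1).
#' @export
bic <- function(loglik, k, n) {
  stopifnot(n >= 1)
  k * log(n) - 2 * loglik
}

#' Free-parameter count of a covariate-free N-state model
#'
#' 5 emission parameters per state, N(N-1) transition intercepts and N-1
#' free initial probabilities (each extra transition covariate adds another
#' N(N-1) slopes).
#'
#' @param n_states number of states.
#' @param n_covariates number of transition covariates.
#' @export
k_free <- function(n_states, n_covariates = 0) {
  n_free_params(n_states, n_covariates)
}

# crude behavioural reading of a canonical emission table
interpret_states <- function(em) {
  n <- nrow(em)
  lab <- character(n)
  near_pi <- angle_dist(em$mu_angle, pi) < 1
  lab[1] <- if (near_pi[1]) "resting" else "slow"
  if (n == 1) return("single state")
  for (i in 2:n) {
    lab[i] <- if (near_pi[i] && em$mu[i] < 100) "active resting"
    else if (em$kappa[i] >= 1) "travelling"
    else "foraging"
  }
  if (n == 2 && lab[2] != "travelling") lab[2] <- "moving"
  if (sum(lab == "travelling") > 1)
    lab[lab == "travelling"] <-
      paste(c("short", "long")[seq_len(sum(lab == "travelling"))], "travel")
  lab
}

#' Fit models over a range of state counts and compare by BIC
#'
#' One multistart fit per state count; each row reports the log-likelihood,
#' both BIC conventions (`bic_free` with k = free parameters, `bic_states`
#' with k = number of states), the restart consensus and a heuristic
#' behavioural interpretation. A state count whose every restart fails is
#' flagged (`failed = TRUE`) rather than aborting the table.
#'
#' @param data a `step_series`.
#' @param state_range integer vector of state counts within 1..6.
#' @param n_restarts restarts per state count.
#' @param seed integer seed (one deterministic child seed per state count).
#' @param bounds_per_k optional list (indexed by state count as character)
#'   of sampling limits; defaults per [default_bounds()].
#' @param ... passed to [multistart_fit()].
#' @return data.frame of class `selection_table` with one row per state
#'   count; fitted models in attribute `fits`.
#' @export
select_n_states <- function(data, state_range = 2:4, n_restarts = 10,
                            seed = 1, bounds_per_k = NULL, ...) {
  if (any(state_range < 1 | state_range > 6))
    stop("state_range must lie within 1..6")
  n_obs <- nrow(data)
  rows <- list()
  fits <- list()
  for (k in state_range) {
    b <- bounds_per_k[[as.character(k)]]
    fit <- tryCatch(
      multistart_fit(data, k, bounds = b, n_restarts = n_restarts,
                     seed = child_seed(seed, k), ...),
      error = function(e) e)
    failed <- !inherits(fit, "hmm_fit")
    rows[[as.character(k)]] <- data.frame(
      n_states = k,
      loglik = if (failed) NA_real_ else fit$loglik,
      n_obs = n_obs,
      k_free = k_free(k),
      bic_free = if (failed) NA_real_ else bic(fit$loglik, k_free(k), n_obs),
      bic_states = if (failed) NA_real_ else bic(fit$loglik, k, n_obs),
      consensus = if (failed) NA_real_ else fit$consensus,
      interpretation = if (failed) NA_character_ else
        paste(interpret_states(fit$model$emissions), collapse = " / "),
      failed = failed)
    fits[[as.character(k)]] <- if (failed) NULL else fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("selection_table", "data.frame")
  out
}

#' Refit the model independently on data subsets
#'
#' Multistart fits per group (e.g. transhumant vs resident herds) plus the
#' pooled fit, with canonical emission parameters tabulated side by side.
#' Groups with fewer than `min_obs` observations are skipped with a
#' warning.
#'
#' @param data a `step_series`.
#' @param groups group label per observation row (e.g. herd type).
#' @param n_states states per fit.
#' @param n_restarts restarts per fit.
#' @param seed integer seed.
#' @param min_obs minimum observations per subset.
#' @param ... passed to [multistart_fit()].
#' @return list with `fits` (named: `pooled` + one per group) and `table`
#'   (long data.frame: group, state, mu, sigma, mu_angle, kappa, zeta).
#' @export
compare_subsets <- function(data, groups, n_states = 3, n_restarts = 10,
                            seed = 1, min_obs = 50, ...) {
  stopifnot(length(groups) == nrow(data))
  fits <- list()
  fits$pooled <- multistart_fit(data, n_states, n_restarts = n_restarts,
                                seed = seed, ...)
  for (g in unique(as.character(groups))) {
    sub <- data[groups == g, , drop = FALSE]
    sub <- as_step_series(sub)
    if (nrow(sub) < min_obs) {
      warning("subset '", g, "' has fewer than ", min_obs,
              " observations; skipped")
      next
    }
    fits[[g]] <- multistart_fit(sub, n_states, n_restarts = n_restarts,
                                seed = seed, ...)
  }
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    em <- fits[[nm]]$model$emissions
    cbind(group = nm, state = seq_len(nrow(em)), as.data.frame(em))
  }))
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}
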