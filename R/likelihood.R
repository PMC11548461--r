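# Likelihood evaluation and state decoding.

validate_model_data <- function(model, data) {
  if (!inherits(model, "hmm_model")) stop("model must be an hmm_model")
  if (!nrow(data)) stop("data must contain at least one observation")
  invisible(TRUE)
}

#' Forward-algorithm log-likelihood
#'
#' Sum over independent segments of the scaled forward recursion; stable at
#' 1e5+ observations. The per-observation emission density is the product
#' of the step density and, where defined, the angle density; missing
#' angles contribute a factor of one. Each segment restarts from `pi0`.
#'
#' @param model an `hmm_model`.
#' @param data a `step_series` (or data.frame with its columns).
#' @return the log-likelihood (scalar).
#' @export
log_likelihood <- function(model, data) {
  validate_model_data(model, data)
  m <- series_matrices(data, model$covariates)
  em <- model$emissions
  nll <- .cpp_forward_nll(m$step, m$angle, m$seg, m$covar,
                          em$mu, em$sigma, em$zeta, em$mu_angle, em$kappa,
                          model$beta, model$pi0, state_family_code(model))
  -nll
}

#' Most probable state sequence (Viterbi decoding)
#'
#' Dynamic-programming argmax over latent state paths, per segment, in log
#' space; ties are broken toward the lower state index.
#'
#' @inheritParams log_likelihood
#' @return integer vector of decoded states (1-based), one per observation.
#' @export
viterbi <- function(model, data) {
  validate_model_data(model, data)
  m <- series_matrices(data, model$covariates)
  em <- model$emissions
  .cpp_viterbi(m$step, m$angle, m$seg, m$covar,
               em$mu, em$sigma, em$zeta, em$mu_angle, em$kappa,
               model$beta, model$pi0, state_family_code(model))
}
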