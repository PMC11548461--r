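# Emission densities and random-variate generators for the step and
# turning-angle laws.

#' Log density/mass of the zero-inflated step law
#'
#' A mixed law: point mass `zeta` at step length exactly zero (computed
#' distance below 1e-6 m) and, with probability `1 - zeta`, a positive
#' continuous law. The default family is the normal truncated to (0, Inf)
#' and renormalised, parameterised by the *untruncated* mean and SD so the
#' printed state parameters keep their usual reading; a gamma law with the
#' same mean and SD is the alternative.
#'
#' @param x step lengths (m, >= 0).
#' @param mu,sigma,zeta state parameters (see [emission_params()]).
#' @param family `"truncnorm"` or `"gamma"`.
#' @return log density (log mass at zero).
#' @export
step_log_density <- function(x, mu, sigma, zeta,
                             family = c("truncnorm", "gamma")) {
  family <- match.arg(family)
  if (any(x < 0)) stop("step lengths must be non-negative")
  out <- numeric(length(x))
  zero <- x < 1e-6
  out[zero] <- if (zeta > 0) log(zeta) else -Inf
  if (any(!zero)) {
    xp <- x[!zero]
    lp <- if (family == "truncnorm") {
      dnorm(xp, mu, sigma, log = TRUE) -
        pnorm(0, mu, sigma, lower.tail = FALSE, log.p = TRUE)
    } else {
      dgamma(xp, shape = (mu / sigma)^2, scale = sigma^2 / mu, log = TRUE)
    }
    out[!zero] <- log1p(-zeta) + lp
  }
  out
}

#' Von Mises log density
#'
#' Circular analogue of the normal law; `kappa = 0` degenerates to the
#' uniform density 1/(2 pi). The Bessel-I0 normaliser is evaluated on the
#' exponential scale for stability at large `kappa`.
#'
#' @param theta angles, rad in (-pi, pi].
#' @param mu_angle mean direction, rad.
#' @param kappa concentration (>= 0).
#' @export
angle_log_density <- function(theta, mu_angle, kappa) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (any(theta <= -pi | theta > pi, na.rm = TRUE))
    stop("angles must lie in (-pi, pi]")
  kappa * cos(theta - mu_angle) - log(2 * pi) -
    (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

#' Draw turning angles from a von Mises law
#'
#' Best-Fisher rejection sampler; uses the session RNG stream.
#'
#' @param n sample size.
#' @param mu_angle mean direction.
#' @param kappa concentration; 0 gives circular uniform draws.
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu_angle, kappa) {
  if (kappa < 1e-10) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu_angle
      i <- i + 1L
    }
  }
  wrap_angle(out)
}

#' Draw step lengths from the zero-inflated step law
#'
#' Zeros with probability `zeta`; positive part by inverse-CDF sampling for
#' the truncated normal (exact, no rejection) or `rgamma` for the gamma
#' family.
#'
#' @inheritParams step_log_density
#' @param n sample size.
#' @export
rstep <- function(n, mu, sigma, zeta = 0,
                  family = c("truncnorm", "gamma")) {
  family <- match.arg(family)
  zero <- runif(n) < zeta
  x <- numeric(n)
  np <- sum(!zero)
  if (np) {
    x[!zero] <- if (family == "truncnorm") {
      p0 <- pnorm(0, mu, sigma)
      qnorm(p0 + runif(np) * (1 - p0), mu, sigma)
    } else {
      rgamma(np, shape = (mu / sigma)^2, scale = sigma^2 / mu)
    }
  }
  x
}
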