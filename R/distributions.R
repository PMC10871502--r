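#' Moment-matched beta parameters
#'
#' Solves the method-of-moments equations for a beta distribution so that the
#' returned `Beta(shape1, shape2)` has exactly the requested mean and standard
#' deviation. Used to turn published (value, SD) pairs for probabilities and
#' utilities into sampling-ready distributions.
#'
#' @param mean Target mean, strictly inside (0, 1).
#' @param sd Target standard deviation, positive. Must satisfy
#'   `sd^2 < mean * (1 - mean)` for the moment equations to be feasible.
#' @param name Parameter name used in error messages.
#' @return A list with `shape1` and `shape2` (both positive).
#' @examples
#' beta_from_moments(0.95, 0.005)
#' @export
beta_from_moments <- function(mean, sd, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop(sprintf("beta moment matching for '%s': mean must lie in (0, 1), got %s",
                 name, format(mean)), call. = FALSE)
  }
  if (!is.finite(sd) || sd <= 0) {
    stop(sprintf("beta moment matching for '%s': sd must be positive", name),
         call. = FALSE)
  }
  if (sd^2 >= mean * (1 - mean)) {
    stop(sprintf(
      "beta moment matching for '%s': infeasible pair (mean = %s, sd = %s); need sd^2 < mean*(1-mean)",
      name, format(mean), format(sd)), call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Moment-matched gamma parameters
#'
#' @param mean Target mean, positive.
#' @param sd Target standard deviation, positive.
#' @param name Parameter name used in error messages.
#' @return A list with `shape` and `scale`; `shape * scale = mean` and
#'   `shape * scale^2 = sd^2` exactly.
#' @examples
#' gamma_from_moments(18180, 2272)
#' @export
gamma_from_moments <- function(mean, sd, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || !is.finite(sd) || sd <= 0) {
    stop(sprintf("gamma moment matching for '%s': mean and sd must be positive", name),
         call. = FALSE)
  }
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Moment-matched lognormal parameters
#'
#' Matches the natural-scale mean and SD (not the log-scale ones): the returned
#' `Lognormal(meanlog, sdlog)` has expectation `mean` and standard deviation
#' `sd`. Published hazard-ratio SDs are read on the hazard-ratio scale.
#'
#' @param mean Target natural-scale mean, positive.
#' @param sd Target natural-scale standard deviation, positive.
#' @param name Parameter name used in error messages.
#' @return A list with `meanlog` and `sdlog`.
#' @examples
#' lognormal_from_moments(2.37, 0.235)
#' @export
lognormal_from_moments <- function(mean, sd, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || !is.finite(sd) || sd <= 0) {
    stop(sprintf("lognormal moment matching for '%s': mean and sd must be positive", name),
         call. = FALSE)
  }
  s2 <- log(1 + sd^2 / mean^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Dirichlet concentration parameters from a category distribution
#'
#' Scales a probability vector by an effective sample size: `alpha_i = ess *
#' p_i`. A zero probability yields a zero concentration, which the sampler
#' treats as a structural zero (the category is never drawn).
#'
#' @param probs Nonnegative probability vector summing to 1 (e.g. a month-3
#'   mRS distribution).
#' @param ess Effective sample size, positive.
#' @return Vector of concentrations, same length and names as `probs`.
#' @export
dirichlet_alphas <- function(probs, ess) {
  if (!is.numeric(probs) || any(!is.finite(probs)) || any(probs < 0)) {
    stop("dirichlet_alphas: probs must be finite and nonnegative", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("dirichlet_alphas: probs must sum to 1", call. = FALSE)
  }
  if (!is.finite(ess) || ess <= 0) stop("dirichlet_alphas: ess must be positive", call. = FALSE)
  ess * probs
}

# Dirichlet sampler via independent gammas; alpha = 0 gives a structural zero.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(0, nrow = n, ncol = k)
  pos <- which(alpha > 0)
  for (j in pos) g[, j] <- stats::rgamma(n, shape = alpha[j], rate = 1)
  g / rowSums(g)
}

#' Draw samples from a parameter specification
#'
#' Dispatches on the `family` of a [dist_spec()]: beta and gamma are
#' moment-matched from (base, sd); lognormal is moment-matched on the natural
#' scale and optionally truncated below (hazard ratios are clamped at 1);
#' `fixed` repeats the base value. A beta spec with `scale_low`/`scale_high`
#' (e.g. patient weight) is sampled on the rescaled unit interval and mapped
#' back to its physical range.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_spec <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  x <- switch(spec$family,
    fixed = rep.int(spec$base, n),
    beta = {
      if (!is.null(spec$scale_low)) {
        lo <- spec$scale_low; hi <- spec$scale_high
        mm <- beta_from_moments((spec$base - lo) / (hi - lo), spec$sd / (hi - lo), spec$name)
        lo + (hi - lo) * stats::rbeta(n, mm$shape1, mm$shape2)
      } else {
        mm <- beta_from_moments(spec$base, spec$sd, spec$name)
        stats::rbeta(n, mm$shape1, mm$shape2)
      }
    },
    gamma = {
      mm <- gamma_from_moments(spec$base, spec$sd, spec$name)
      stats::rgamma(n, shape = mm$shape, scale = mm$scale)
    },
    lognormal = {
      mm <- lognormal_from_moments(spec$base, spec$sd, spec$name)
      stats::rlnorm(n, mm$meanlog, mm$sdlog)
    },
    stop(sprintf("unknown family '%s' for parameter '%s'", spec$family, spec$name),
         call. = FALSE)
  )
  if (!is.null(spec$truncate_low)) x <- pmax(x, spec$truncate_low)
  x
}
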