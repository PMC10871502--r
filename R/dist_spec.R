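#' Parameter specification
#'
#' One published model input: its point estimate, the distribution family used
#' in probabilistic sensitivity analysis, the dispersion, and the range used in
#' one-way sensitivity analysis.
#'
#' @param name Identifier for the parameter.
#' @param base Point estimate used in the base case.
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#'   `fixed` parameters are never sampled; they may still carry a one-way range
#'   (the discount rate does).
#' @param sd Standard deviation on the natural scale; `NA` for fixed.
#' @param low,high One-way sensitivity bounds; `NA` when the parameter has no
#'   published range.
#' @param scale_low,scale_high Physical support for beta-sampled quantities
#'   that do not live on `[0, 1]` (patient weight in kg): sampling happens on
#'   the rescaled unit interval.
#' @param truncate_low Lower clamp applied after sampling (hazard ratios are
#'   clamped at 1).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(name, base, family = c("beta", "gamma", "lognormal", "fixed"),
                      sd = NA_real_, low = NA_real_, high = NA_real_,
                      scale_low = NULL, scale_high = NULL, truncate_low = NULL) {
  family <- match.arg(family)
  spec <- structure(
    list(name = as.character(name), base = as.numeric(base), family = family,
         sd = as.numeric(sd), low = as.numeric(low), high = as.numeric(high),
         scale_low = scale_low, scale_high = scale_high, truncate_low = truncate_low),
    class = "dist_spec")
  validate_dist_spec(spec)
  spec
}

#' Validate a parameter specification
#'
#' Checks family-specific support (beta in `[0,1]` unless rescaled, gamma
#' nonnegative), that the base value lies inside any declared range, that
#' sampled families carry a positive SD, and that beta moment matching is
#' feasible. Errors name the offending parameter.
#'
#' @param spec A [dist_spec()].
#' @return `spec`, invisibly.
#' @export
validate_dist_spec <- function(spec) {
  nm <- spec$name
  if (!is.finite(spec$base)) stop(sprintf("'%s': base value must be finite", nm), call. = FALSE)
  if (spec$family != "fixed") {
    if (!is.finite(spec$sd) || spec$sd <= 0) {
      stop(sprintf("'%s': sampled family '%s' requires a positive sd", nm, spec$family),
           call. = FALSE)
    }
  }
  if (spec$family == "beta") {
    if (is.null(spec$scale_low)) {
      if (spec$base < 0 || spec$base > 1) {
        stop(sprintf("'%s': beta base value must lie in [0, 1]", nm), call. = FALSE)
      }
      # feasibility surfaces at validation time, not mid-PSA
      beta_from_moments(spec$base, spec$sd, nm)
    } else {
      if (spec$base < spec$scale_low || spec$base > spec$scale_high) {
        stop(sprintf("'%s': base value outside physical support [%s, %s]",
                     nm, spec$scale_low, spec$scale_high), call. = FALSE)
      }
      w <- spec$scale_high - spec$scale_low
      beta_from_moments((spec$base - spec$scale_low) / w, spec$sd / w, nm)
    }
  }
  if (spec$family == "gamma" && spec$base < 0) {
    stop(sprintf("'%s': gamma base value must be nonnegative", nm), call. = FALSE)
  }
  if (is.finite(spec$low) && is.finite(spec$high)) {
    if (spec$low > spec$high) stop(sprintf("'%s': range_low > range_high", nm), call. = FALSE)
    if (spec$base < spec$low - 1e-12 || spec$base > spec$high + 1e-12) {
      stop(sprintf("'%s': base value %s outside range [%s, %s]",
                   nm, spec$base, spec$low, spec$high), call. = FALSE)
    }
  }
  invisible(spec)
}

#' @export
format.dist_spec <- function(x, ...) {
  rng <- if (is.finite(x$low)) sprintf(" range [%g, %g]", x$low, x$high) else ""
  sd <- if (is.finite(x$sd)) sprintf(" sd %g", x$sd) else ""
  sprintf("<dist_spec %s: %g (%s%s)%s>", x$name, x$base, x$family, sd, rng)
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Month-3 disability distribution
#'
#' Probability vector over the seven modified Rankin Scale states (mRS 0-6,
#' with 6 = death); must be nonnegative and sum to 1 within 1e-9.
#'
#' @param probs Numeric vector of length 7.
#' @return Named numeric vector of class `mrs_distribution`.
#' @export
mrs_distribution <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) != 7) stop("mrs_distribution: need 7 probabilities (mRS 0-6)", call. = FALSE)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("mrs_distribution: entries must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop(sprintf("mrs_distribution: probabilities sum to %.12f, not 1", sum(probs)),
         call. = FALSE)
  }
  structure(stats::setNames(probs, paste0("mrs", 0:6)), class = "mrs_distribution")
}
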