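# Prior distributions.
#
# Linear-model coefficients get diffuse normal(0, sd = 100) priors;
# detection probabilities get uniform(0, 1); the egg-hatch and pupation
# probabilities get informative beta priors, standing in for lab-rearing
# data on transitions that the field survey almost never observes.

#' Specify prior distributions
#'
#' @param hatch,pupation length-2 numeric `c(alpha, beta)` shape parameters
#'   of the informative beta priors on the per-3-day-step egg-hatch and
#'   pupation probabilities.  These must be supplied: the package has no
#'   defensible default for transitions it cannot observe (see
#'   [matched_priors()] for building them from known truth in simulation
#'   studies).
#' @param coef_sd standard deviation of the mean-zero normal prior on all
#'   logit/multinomial-logit coefficients (default 100, effectively
#'   uninformative).
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec(hatch = c(6, 4), pupation = c(3.5, 6.5))
#' @export
prior_spec <- function(hatch, pupation, coef_sd = 100) {
  chk <- function(x, what) {
    if (length(x) != 2 || any(!is.finite(x)) || any(x <= 0))
      stop(what, " prior must be c(alpha, beta) with alpha, beta > 0")
  }
  chk(hatch, "hatch"); chk(pupation, "pupation")
  if (!is.finite(coef_sd) || coef_sd <= 0) stop("coef_sd must be positive")
  out <- list(coef_sd = coef_sd,
              hatch = as.numeric(hatch), pupation = as.numeric(pupation))
  class(out) <- "prior_spec"
  out
}

#' Matched informative priors for simulation studies
#'
#' Beta priors for the egg-hatch and pupation probabilities centered on the
#' generating truth with a chosen effective sample size ("strength", a
#' pseudo-count scale): `Beta(p * strength, (1 - p) * strength)`.  The
#' prior mean equals the truth for any strength, and the prior concentrates
#' on it as strength grows.
#'
#' @param truth an [hmm_parameters()] object, or a list with elements
#'   `hatch` and `pupation` in (0, 1).
#' @param strength effective prior sample size (> 0); default 20.
#' @param coef_sd passed to [prior_spec()].
#' @return A [prior_spec()] object.
#' @examples
#' matched_priors(list(hatch = 0.5, pupation = 0.5), strength = 10)
#' @export
matched_priors <- function(truth, strength = 20, coef_sd = 100) {
  if (!is.finite(strength) || strength <= 0)
    stop("strength must be a positive pseudo-count")
  for (p in c(truth$hatch, truth$pupation))
    if (!is.finite(p) || p <= 0 || p >= 1)
      stop("matched priors need true probabilities strictly inside (0, 1)")
  prior_spec(hatch = c(truth$hatch, 1 - truth$hatch) * strength,
             pupation = c(truth$pupation, 1 - truth$pupation) * strength,
             coef_sd = coef_sd)
}

#' Log prior density of a parameter vector
#'
#' Sum of independent prior log-densities on the natural scale:
#' normal(0, `coef_sd`) for every coefficient, uniform(0, 1) for every
#' estimated detection probability, and the informative beta densities for
#' hatch and pupation.  Returns `-Inf` outside the support.
#'
#' @param params an [hmm_parameters()] object (or a bare list with the same
#'   elements).
#' @param priors a [prior_spec()].
#' @param structure a [model_structure()]; defaults to the one in `params`.
#' @return log prior density (scalar).
#' @export
log_prior <- function(params, priors, structure = params$structure) {
  coefs <- c(params$b0, params$b1, params$a0, params$a1)
  probs <- c(params$p_live[ESTIMATED_P_LIVE], params$p_dead[ESTIMATED_P_DEAD])
  if (any(!is.finite(coefs))) return(-Inf)
  if (any(probs < 0 | probs > 1)) return(-Inf)
  if (params$hatch < 0 || params$hatch > 1 ||
      params$pupation < 0 || params$pupation > 1) return(-Inf)
  sum(dnorm(coefs, 0, priors$coef_sd, log = TRUE)) +
    dbeta(params$hatch, priors$hatch[1], priors$hatch[2], log = TRUE) +
    dbeta(params$pupation, priors$pupation[1], priors$pupation[2], log = TRUE)
}

# log prior on the sampler's unconstrained scale, including the
# logit-transform Jacobians for every probability parameter
log_prior_theta <- function(theta, structure, priors) {
  is_prob <- param_is_prob(structure)
  nm <- param_names(structure)
  lp <- sum(dnorm(theta[!is_prob], 0, priors$coef_sd, log = TRUE))
  tp <- theta[is_prob]
  p <- plogis(tp)
  # Jacobian of p = logistic(t): log p + log(1 - p)
  lp <- lp + sum(plogis(tp, log.p = TRUE) + plogis(-tp, log.p = TRUE))
  lp + dbeta(p[match("hatch", nm[is_prob])],
             priors$hatch[1], priors$hatch[2], log = TRUE) +
    dbeta(p[match("pupation", nm[is_prob])],
          priors$pupation[1], priors$pupation[2], log = TRUE)
}
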