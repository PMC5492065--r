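# Bayesian fitting by blocked adaptive random-walk Metropolis.
#
# The sampler works on an unconstrained scale (identity for coefficients,
# logit for probabilities, with Jacobian terms in the prior) and updates
# four blocks per iteration: survival coefficients, growth coefficients,
# detection probabilities, and the informative-prior parameters.  Proposal
# scale and covariance adapt with a diminishing schedule during burn-in and
# are frozen afterwards, so the retained chain is a valid Markov chain
# targeting the posterior.

#' MCMC settings
#'
#' Defaults mirror the study-scale fit (120,000 burn-in iterations, 10,000
#' retained draws without thinning, 3 chains); simulation tests use scaled-
#' down settings.
#'
#' @param chains number of independent chains.
#' @param burn_in adaptation/burn-in iterations discarded per chain.
#' @param samples retained iterations per chain (no thinning).
#' @param seed integer seed; every chain derives its stream from it, so a
#'   fit is bit-reproducible.
#' @param target_accept per-block acceptance rate targeted by the
#'   adaptation (0.3).
#' @param sweeps Metropolis sweeps over all blocks per recorded iteration
#'   (default 2; more sweeps cost proportionally more likelihood
#'   evaluations but lower the autocorrelation of the recorded chain).
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3, burn_in = 120000, samples = 10000,
                          seed = 1, target_accept = 0.3, sweeps = 2) {
  stopifnot(chains >= 1, burn_in >= 0, samples >= 1,
            target_accept > 0, target_accept < 1, sweeps >= 1)
  out <- list(chains = as.integer(chains), burn_in = as.integer(burn_in),
              samples = as.integer(samples), seed = as.integer(seed),
              target_accept = target_accept, sweeps = as.integer(sweeps))
  class(out) <- "mcmc_settings"
  out
}

#' Blocked adaptive random-walk Metropolis sampler
#'
#' Generic sampler core: multivariate-normal random-walk proposals per
#' block, with Robbins-Monro adaptation of the per-block log step size
#' toward a target acceptance rate and running adaptation of the proposal
#' covariance, both frozen when burn-in ends.  Exposed so the same
#' machinery can be tested on analytically known posteriors.
#'
#' @param log_post function of the full parameter vector returning either a
#'   scalar log posterior or a length-2 vector `c(log_posterior,
#'   auxiliary)`; the auxiliary value (e.g. a log-likelihood) is recorded
#'   per retained draw.
#' @param init numeric initial parameter vector (finite log posterior
#'   required).
#' @param blocks list of integer index vectors partitioning the parameters.
#' @param n_burn,n_keep burn-in and retained iteration counts.
#' @param target_accept adaptation target.
#' @param sweeps Metropolis sweeps over the blocks per recorded iteration.
#' @return List with `draws` (`n_keep` x d matrix), `lp`, `aux`,
#'   `acceptance` (per-block rates measured after adaptation), and
#'   `scales`.
#' @export
adaptive_metropolis <- function(log_post, init,
                                blocks = list(seq_along(init)),
                                n_burn = 1000, n_keep = 1000,
                                target_accept = 0.3, sweeps = 1) {
  d <- length(init)
  theta <- as.numeric(init)
  cur <- log_post(theta)
  if (!is.finite(cur[1]))
    stop("log posterior is not finite at the initial values; re-initialize")
  nb <- length(blocks)
  log_scale <- vapply(blocks, function(b) log(0.5 / sqrt(length(b))),
                      numeric(1))
  mean_b <- lapply(blocks, function(b) theta[b])
  cov_b <- lapply(blocks, function(b) diag(length(b)))
  chol_b <- lapply(cov_b, chol)
  acc <- att <- numeric(nb)
  draws <- matrix(NA_real_, n_keep, d)
  lp_keep <- aux_keep <- numeric(n_keep)
  total <- n_burn + n_keep
  for (i in seq_len(total)) {
    adapting <- i <= n_burn
    gam <- 1 / (20 + i)^0.6
    for (sw in seq_len(sweeps)) for (j in seq_len(nb)) {
      b <- blocks[[j]]
      z <- rnorm(length(b))
      # symmetric mixture proposal: an occasional 3x step traverses heavy
      # logit-scale tails that the adapted step size undersamples
      mult <- if (runif(1) < 0.1) 3 else 1
      prop <- theta
      prop[b] <- theta[b] + mult * exp(log_scale[j]) * drop(z %*% chol_b[[j]])
      cand <- log_post(prop)
      lr <- cand[1] - cur[1]
      if (is.finite(lr) && log(runif(1)) < lr) {
        theta <- prop
        cur <- cand
        accepted <- 1
      } else accepted <- 0
      if (adapting) {
        a_prob <- if (is.finite(lr)) min(1, exp(lr)) else 0
        log_scale[j] <- log_scale[j] + gam * (a_prob - target_accept)
        delta <- theta[b] - mean_b[[j]]
        mean_b[[j]] <- mean_b[[j]] + gam * delta
        cov_b[[j]] <- cov_b[[j]] + gam * (tcrossprod(delta) - cov_b[[j]])
        if (i %% 25 == 0)
          chol_b[[j]] <- chol(cov_b[[j]] + 1e-8 * diag(length(b)))
      } else {
        att[j] <- att[j] + 1
        acc[j] <- acc[j] + accepted
      }
    }
    if (i > n_burn) {
      k <- i - n_burn
      draws[k, ] <- theta
      lp_keep[k] <- cur[1]
      aux_keep[k] <- if (length(cur) > 1) cur[2] else NA_real_
    }
  }
  list(draws = draws, lp = lp_keep, aux = aux_keep,
       acceptance = acc / pmax(att, 1), scales = exp(log_scale))
}

# Overdispersed starting values on the unconstrained scale, centered on
# field-plausible values (3-day survival and detection of marked
# caterpillars are high in this kind of study) rather than drawn from the
# sd-100 coefficient priors, which would start chains at degenerate
# probabilities; informative-prior parameters start from draws of their
# own priors.
draw_inits <- function(structure, priors) {
  nm <- param_names(structure)
  th <- rnorm(length(nm), 0, 0.8)
  th[grepl("^b0", nm)] <- th[grepl("^b0", nm)] + qlogis(0.85)
  th[grepl("^a0", nm)] <- th[grepl("^a0", nm)] - 0.5
  th[grepl("^p_live", nm)] <- th[grepl("^p_live", nm)] + qlogis(0.7)
  th[match("hatch", nm)] <- qlogis(rbeta(1, priors$hatch[1], priors$hatch[2]))
  th[match("pupation", nm)] <-
    qlogis(rbeta(1, priors$pupation[1], priors$pupation[2]))
  th
}

#' Fit the cohort hidden Markov model by MCMC
#'
#' Fits one candidate model structure to encounter histories: the exact
#' forward-algorithm marginal likelihood is combined with the priors and
#' sampled by [adaptive_metropolis()] in four parameter blocks (survival,
#' growth, detection, informative).  Chains are initialized from
#' overdispersed starting points and are reproducible given
#' `settings$seed`.
#'
#' @param data encounter-history data frame (see [as_encounter_data()]) or
#'   a prepared `hmm_data` object from [prepare_data()].
#' @param structure the candidate [model_structure()] to fit.
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()] object.
#' @param temperature plot-by-occasion temperature table, required when the
#'   growth form is `"temperature"`.
#' @param density_metric,death_partition passed to [prepare_data()].
#' @return An object of class `instar_hmm` with components `draws`
#'   (samples x parameter x chain array on the sampling scale), `deviance`
#'   (samples x chain), `mean_deviance`, `acceptance` (block x chain),
#'   `structure`, `priors`, `settings`, `K` (number of sampled parameters),
#'   `n` (number of encounter histories), and `scaling` (covariate
#'   standardization constants).  Methods: `print`, `summary`, `coef`,
#'   `confint`, `plot`, `simulate`.
#' @seealso [select_models()] to fit and rank a whole candidate grid.
#' @export
fit_hmm <- function(data, structure = model_structure(), priors,
                    settings = mcmc_settings(), temperature = NULL,
                    density_metric = c("size", "count"),
                    death_partition = c("growth", "stay")) {
  if (!inherits(priors, "prior_spec"))
    stop("priors must be a prior_spec(); informative hatch/pupation priors ",
         "are required")
  enc <- if (inherits(data, "hmm_data")) data else
    prepare_data(data, structure,
                 temperature = temperature,
                 density_metric = match.arg(density_metric),
                 death_partition = match.arg(death_partition))
  if (!identical(unclass(enc$structure), unclass(structure)))
    enc <- prepare_data_restructure(enc, structure)
  nm <- param_names(structure)
  lay <- param_layout(structure)
  blocks <- list()
  pos <- 0L
  for (bn in names(lay)) {
    blocks[[bn]] <- pos + seq_along(lay[[bn]])
    pos <- pos + length(lay[[bn]])
  }
  # live and dead detection probabilities mix better as separate blocks
  det <- blocks$detection
  blocks$detection <- NULL
  blocks$p_live <- det[seq_along(ESTIMATED_P_LIVE)]
  blocks$p_dead <- det[length(ESTIMATED_P_LIVE) + seq_along(ESTIMATED_P_DEAD)]
  blocks <- blocks[c("survival", "growth", "p_live", "p_dead",
                     "informative")]
  loglik_fn <- make_loglik_fn(enc)
  is_prob <- param_is_prob(structure)
  i_coef <- which(!is_prob)
  i_prob <- which(is_prob)
  i_hatch <- match("hatch", nm)
  i_pup <- match("pupation", nm)
  coef_sd <- priors$coef_sd
  pr_h <- priors$hatch; pr_p <- priors$pupation
  log_post <- function(theta) {
    # prior on the unconstrained scale, logit Jacobians included
    tp <- theta[i_prob]
    lp0 <- sum(dnorm(theta[i_coef], 0, coef_sd, log = TRUE)) +
      sum(plogis(tp, log.p = TRUE) + plogis(-tp, log.p = TRUE)) +
      dbeta(plogis(theta[i_hatch]), pr_h[1], pr_h[2], log = TRUE) +
      dbeta(plogis(theta[i_pup]), pr_p[1], pr_p[2], log = TRUE)
    if (!is.finite(lp0)) return(c(-Inf, -Inf))
    ll <- loglik_fn(theta)
    c(lp0 + ll, ll)
  }
  t0 <- proc.time()[["elapsed"]]
  n_chain <- settings$chains
  draws <- array(NA_real_, c(settings$samples, length(nm), n_chain),
                 dimnames = list(NULL, nm, NULL))
  devi <- matrix(NA_real_, settings$samples, n_chain)
  accm <- matrix(NA_real_, length(blocks), n_chain,
                 dimnames = list(names(blocks), NULL))
  for (ch in seq_len(n_chain)) {
    set.seed(settings$seed + 7919L * ch)
    init <- NULL
    for (try in 1:50) {
      cand <- draw_inits(structure, priors)
      if (is.finite(log_post(cand)[1])) { init <- cand; break }
    }
    if (is.null(init))
      stop("could not find a finite-posterior starting point in 50 draws; ",
           "re-initialize (check the data/structure combination)")
    res <- adaptive_metropolis(log_post, init, blocks,
                               n_burn = settings$burn_in,
                               n_keep = settings$samples,
                               target_accept = settings$target_accept,
                               sweeps = settings$sweeps)
    draws[, , ch] <- res$draws
    devi[, ch] <- -2 * res$aux
    accm[, ch] <- res$acceptance
  }
  out <- list(
    draws = draws, deviance = devi, mean_deviance = mean(devi),
    acceptance = rowMeans(accm), acceptance_by_chain = accm,
    structure = structure, priors = priors, settings = settings,
    K = length(nm), n = enc$n, n_occasions = enc$n_occasions,
    scaling = enc$scaling, density_metric = enc$density_metric,
    death_partition = enc$death_partition,
    elapsed = proc.time()[["elapsed"]] - t0
  )
  class(out) <- "instar_hmm"
  out
}

# re-derive covariates when a prepared dataset was built for a different
# structure (used by select_models, which prepares per structure anyway)
prepare_data_restructure <- function(enc, structure) {
  stop("prepared data was built for a different model structure; ",
       "call prepare_data() with the structure being fitted")
}

#' @rdname fit_hmm
#' @export
run_mcmc <- fit_hmm

# fast, validation-free counterpart of unflatten_parameters for the sampler
unflatten_fast <- function(theta, structure) {
  nm <- param_names(structure)
  names(theta) <- nm
  groups <- survival_group_levels(structure$survival_grouping)
  get <- function(pat, lab) setNames(theta[paste0(pat, "[", lab, "]")], lab)
  p_live <- setNames(numeric(N_STAGES), STAGES)
  p_live[ESTIMATED_P_LIVE] <- plogis(get("p_live", ESTIMATED_P_LIVE))
  p_dead <- setNames(numeric(N_STAGES), STAGES)
  p_dead[ESTIMATED_P_DEAD] <- plogis(get("p_dead", ESTIMATED_P_DEAD))
  out <- list(
    structure = structure,
    b0 = get("b0", groups),
    b1 = if (structure$survival_form != "constant") get("b1", groups),
    a0 = get("a0", growth_intercept_labels()),
    a1 = if (structure$growth_form != "constant") get("a1", GROWTH_STAGES),
    p_live = p_live, p_dead = p_dead,
    hatch = plogis(theta[["hatch"]]), pupation = plogis(theta[["pupation"]])
  )
  class(out) <- "hmm_parameters"
  out
}
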