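# Shared fixtures: random-but-valid parameter draws and tiny cohorts.

# a random valid parameter vector for a structure (seeded by the caller)
random_parameters <- function(structure = model_structure()) {
  groups <- instarhmm:::survival_group_levels(structure$survival_grouping)
  lab <- instarhmm:::growth_intercept_labels()
  b0 <- setNames(rnorm(length(groups), 1, 1.5), groups)
  b1 <- if (structure$survival_form == "constant") NULL else
    setNames(rnorm(length(groups), 0, 0.5), groups)
  a0 <- setNames(rnorm(length(lab), -0.5, 1), lab)
  a1 <- if (structure$growth_form == "constant") NULL else
    setNames(rnorm(4, 0, 0.5), c("I1", "I2", "I3", "I4"))
  hmm_parameters(structure, b0 = b0, b1 = b1, a0 = a0, a1 = a1,
                 p_live = c(runif(6), 0),
                 p_dead = c(0, runif(5), 0),
                 hatch = runif(1, 0.05, 0.95),
                 pupation = runif(1, 0.05, 0.95))
}

# random vital rates: valid phi and a psi respecting the transition mask
random_vital_rates <- function() {
  mask <- instarhmm:::growth_mask()
  psi <- matrix(0, 7, 7, dimnames = dimnames(mask))
  for (i in 1:7) {
    sup <- which(mask[, i])
    w <- rexp(length(sup))
    psi[sup, i] <- w / sum(w)
  }
  vital_rates(phi = runif(7), psi = psi)
}

# perfect-information transition/observation pair (certain survival,
# stasis, certain detection of live instars)
deterministic_kernels <- function() {
  vr <- vital_rates(rep(1, 7), stasis_psi())
  px <- build_transition_matrix(vr)
  po <- build_observation_matrix(
    detection_params(p_live = c(0, rep(1, 5), 0), p_dead = rep(0, 7)))
  list(px = px, po = po)
}

# small cohort shared by io/summary tests
small_cohort <- function(seed = 42, n = 60, ...) {
  simulate_cohort(cohort_config(n_individuals = n, seed = seed, ...))
}
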