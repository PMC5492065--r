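# State space, transition matrix PX, and observation matrix PO for the
# juvenile cohort hidden Markov model.
#
# States are ordered: 7 live stages (egg, I1..I5, pupa), the same 7 stages
# newly dead, then one absorbing "dead" state, 15 in all.  The process runs
# in 3-day steps; PX is column stochastic so PX %*% x propagates a column
# state distribution forward one step.

#' Stage and state space of the juvenile cohort model
#'
#' Returns the fixed stage/state layout used throughout the package: seven
#' live stages (egg, five instars, pupa), the same seven stages as transient
#' "newly dead" states in which a corpse can still be found, and a single
#' absorbing dead state, for 15 states in total.  Observation categories
#' mirror the states with a leading "not seen" category.
#'
#' @return A list with components `live_stages`, `newly_dead_stages`,
#'   `absorbing`, `states` (all 15 state labels in order), `categories`
#'   (the 15 observation category labels), `n_states`, and
#'   `growth_destinations` (allowed non-stasis growth moves per stage).
#' @examples
#' stage_space()$states
#' @export
stage_space <- function() {
  list(
    live_stages = STAGES,
    newly_dead_stages = paste0("nd_", STAGES),
    absorbing = "dead",
    states = STATE_NAMES,
    categories = CATEGORIES,
    n_states = N_STATES,
    growth_destinations = GROWTH_DESTS
  )
}

stage_index <- function(stage) {
  i <- match(stage, STAGES)
  if (anyNA(i)) stop("unknown stage: ", paste(stage[is.na(i)], collapse = ", "))
  i
}

# logical 7x7 mask, [j, i] TRUE if stage i may occupy stage j next step
growth_mask <- function() {
  m <- matrix(FALSE, N_STAGES, N_STAGES, dimnames = list(STAGES, STAGES))
  for (i in seq_along(STAGES)) {
    m[i, i] <- TRUE # stasis always allowed
    m[GROWTH_DESTS[[STAGES[i]]], i] <- TRUE
  }
  m
}

#' Construct and validate a set of vital rates
#'
#' Bundles stage-specific 3-day survival probabilities `phi` and the growth
#' kernel `psi` (conditional on survival) into a validated `vital_rates`
#' object.  `psi[j, i]` is the probability that a survivor of stage `i`
#' occupies stage `j` after one step; each column must be a simplex whose
#' support respects the allowed-transition mask: eggs may only hatch to I1,
#' I1-I3 may advance one or two instars, I4 advances to I5, I5 pupates, and
#' the pupa is terminal.
#'
#' @param phi numeric vector of length 7 (or named by stage) of survival
#'   probabilities in `[0, 1]`.  The pupa entry is conventionally 1: pupa
#'   survival is not estimated and the pupa is an absorbing live stage here.
#' @param psi 7x7 numeric matrix of growth probabilities, columns indexed by
#'   source stage and rows by destination stage; columns must sum to 1.
#' @return An object of class `vital_rates`: a list with elements `phi`
#'   (named length-7 vector) and `psi` (7x7 named matrix).
#' @examples
#' vr <- vital_rates(phi = c(.9, .92, .92, .92, .92, .92, 1),
#'                   psi = stasis_psi())
#' vr$phi
#' @export
vital_rates <- function(phi, psi) {
  phi <- as.numeric(phi)
  if (length(phi) != N_STAGES)
    stop("phi must have length ", N_STAGES)
  names(phi) <- STAGES
  bad <- which(!is.finite(phi) | phi < 0 | phi > 1)
  if (length(bad))
    stop("survival probability out of [0,1] for stage ",
         paste(STAGES[bad], collapse = ", "))
  psi <- as.matrix(psi)
  if (!all(dim(psi) == c(N_STAGES, N_STAGES)))
    stop("psi must be a ", N_STAGES, "x", N_STAGES, " matrix")
  dimnames(psi) <- list(STAGES, STAGES)
  if (any(!is.finite(psi)) || any(psi < 0) || any(psi > 1))
    stop("psi entries must lie in [0,1]")
  csum <- colSums(psi)
  bad <- which(abs(csum - 1) > 1e-12)
  if (length(bad))
    stop("growth simplex does not sum to 1 for stage ",
         paste(STAGES[bad], collapse = ", "))
  mask <- growth_mask()
  off <- which(psi > 0 & !mask, arr.ind = TRUE)
  if (nrow(off))
    stop("disallowed growth transition ", STAGES[off[1, 2]], " -> ",
         STAGES[off[1, 1]])
  structure(list(phi = phi, psi = psi), class = "vital_rates")
}

#' Pure-stasis growth kernel
#'
#' Identity growth kernel (every survivor stays in its stage); convenient as
#' a starting point for building `psi` matrices in examples and tests.
#'
#' @return 7x7 identity matrix with stage dimnames.
#' @export
stasis_psi <- function() {
  m <- diag(1, N_STAGES, N_STAGES)
  dimnames(m) <- list(STAGES, STAGES)
  m
}

#' Build the column-stochastic transition matrix PX
#'
#' Assembles the 15x15 one-step transition kernel from vital rates.  The
#' matrix is a block matrix: the live-to-live block `J` has entries
#' `phi_i * psi[j, i]` (survive, then grow); the live-to-newly-dead block
#' `M` partitions the dying mass `1 - phi_i`; dead-to-live transitions are
#' impossible (`Z = 0`); and every newly-dead state moves to the absorbing
#' dead state with probability one (`U`).  Columns sum to one, so all
#' possible fates are accounted for.
#'
#' @param vital a [vital_rates()] object.
#' @param death_partition how the dying mass `1 - phi_i` is spread over the
#'   newly-dead stage classes.  `"growth"` (default) partitions it by the
#'   same growth kernel `psi` — individuals that die during a failed molt
#'   are recorded as deaths in the new stage.  `"stay"` leaves all dying
#'   mass in the current stage's newly-dead class.
#' @return An object of class `transition_matrix`: the 15x15 matrix with a
#'   `death_partition` attribute.
#' @examples
#' vr <- vital_rates(phi = rep(1, 7), psi = stasis_psi())
#' px <- build_transition_matrix(vr)
#' colSums(px)  # all one
#' @export
build_transition_matrix <- function(vital,
                                    death_partition = c("growth", "stay")) {
  if (!inherits(vital, "vital_rates"))
    vital <- vital_rates(vital$phi, vital$psi)
  death_partition <- match.arg(death_partition)
  phi <- vital$phi
  psi <- vital$psi
  px <- matrix(0, N_STATES, N_STATES,
               dimnames = list(STATE_NAMES, STATE_NAMES))
  live <- 1:7
  nd <- 8:14
  # J: survive and grow
  px[live, live] <- psi * rep(phi, each = N_STAGES)
  # M: die, partitioned over newly-dead classes
  if (death_partition == "growth") {
    px[nd, live] <- psi * rep(1 - phi, each = N_STAGES)
  } else {
    px[cbind(nd, live)] <- 1 - phi
  }
  # U: newly dead -> absorbing dead with certainty; dead stays dead
  px[15, nd] <- 1
  px[15, 15] <- 1
  structure(px, class = c("transition_matrix", "matrix"),
            death_partition = death_partition)
}

#' Construct and validate detection parameters
#'
#' Stage-specific detection probabilities for live individuals and for fresh
#' corpses.  Corpses of eggs and pupae are never recovered in the field, so
#' their dead-detection probabilities are fixed at zero.
#'
#' @param p_live numeric length-7 vector of live detection probabilities
#'   (egg, I1..I5, pupa).
#' @param p_dead numeric length-7 vector of newly-dead detection
#'   probabilities; entries for egg and pupa must be 0.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(p_live, p_dead) {
  p_live <- as.numeric(p_live); p_dead <- as.numeric(p_dead)
  if (length(p_live) != N_STAGES || length(p_dead) != N_STAGES)
    stop("p_live and p_dead must have length ", N_STAGES)
  names(p_live) <- names(p_dead) <- STAGES
  chk <- function(p, what) {
    bad <- which(!is.finite(p) | p < 0 | p > 1)
    if (length(bad))
      stop(what, " out of [0,1] for stage ", paste(STAGES[bad], collapse = ", "))
  }
  chk(p_live, "p_live"); chk(p_dead, "p_dead")
  if (p_dead[["egg"]] != 0 || p_dead[["pupa"]] != 0)
    stop("p_dead must be 0 for egg and pupa (their corpses are unobservable)")
  structure(list(p_live = p_live, p_dead = p_dead), class = "detection_params")
}

#' Build the observation matrix PO
#'
#' The 15x15 observation kernel: columns are true states, rows are
#' observation categories ("not seen", seen alive per stage, corpse per
#' stage).  A live stage `i` is seen in its own category with probability
#' `p_live[i]` and missed with the complement; likewise for newly-dead
#' states and `p_dead`.  There is no misclassification mass, and the
#' absorbing dead state is never observed.
#'
#' @param det a [detection_params()] object.
#' @return An object of class `observation_matrix` (15x15, columns sum to 1).
#' @examples
#' det <- detection_params(p_live = c(0, rep(.9, 5), 0),
#'                         p_dead = c(0, rep(.5, 5), 0))
#' po <- build_observation_matrix(det)
#' colSums(po)
#' @export
build_observation_matrix <- function(det) {
  if (!inherits(det, "detection_params"))
    det <- detection_params(det$p_live, det$p_dead)
  p <- c(det$p_live, det$p_dead, 0) # detection per state; absorbing unseen
  po <- matrix(0, N_CATEGORIES, N_STATES,
               dimnames = list(CATEGORIES, STATE_NAMES))
  po[1, ] <- 1 - p
  po[cbind(1 + 1:14, 1:14)] <- p[1:14]
  structure(po, class = c("observation_matrix", "matrix"))
}

#' Propagate a state distribution one step
#'
#' Multiplies a probability distribution over the 15 states by the
#' transition kernel: the state at time t given time t-1 is categorical with
#' probabilities `PX %*% x`.
#'
#' @param px a 15x15 column-stochastic transition matrix.
#' @param x probability vector of length 15.
#' @return The propagated probability vector (sums to 1).
#' @export
evolve_state <- function(px, x) {
  x <- as.numeric(x)
  if (length(x) != N_STATES)
    stop("state distribution must have length ", N_STATES)
  if (!all(dim(px) == c(N_STATES, N_STATES)))
    stop("transition matrix must be ", N_STATES, "x", N_STATES)
  if (abs(sum(x) - 1) > 1e-9)
    stop("x is not a probability distribution (sum = ", format(sum(x)), ")")
  drop(px %*% x)
}
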