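# Candidate model structures, their parameter vectors, and the link
# functions that map linear predictors to vital rates.
#
# Survival uses a logit link; growth uses a multinomial logit with stasis as
# the reference category.  Egg hatching and pupation are not multinomial-
# logit parameters: they are probabilities with informative beta priors,
# because those transitions are essentially unobserved in the field.

SURVIVAL_FORMS <- c("constant", "date", "density")
GROUPINGS <- c("full_stage", "early_grouped")
GROWTH_FORMS <- c("constant", "date", "temperature")

# stages whose growth kernel is multinomial-logit (egg and I5 use the
# informative-prior hatch/pupation probabilities instead)
GROWTH_STAGES <- c("I1", "I2", "I3", "I4")

#' Specify a candidate model structure
#'
#' A model structure names the covariate form for survival and growth and
#' the survival stage grouping.  Survival may be constant or a linear
#' (logit-scale) function of survey date or conspecific density; growth may
#' be constant or a linear (multinomial-logit-scale) function of date or
#' 3-day mean temperature.  `early_grouped` pools first to fourth instars
#' into one survival class, distinct from fifth instars (the egg keeps its
#' own class in both groupings).
#'
#' @param survival_form one of `"constant"`, `"date"`, `"density"`.
#' @param survival_grouping one of `"full_stage"`, `"early_grouped"`.
#' @param growth_form one of `"constant"`, `"date"`, `"temperature"`.
#' @return An object of class `model_structure`.
#' @examples
#' model_structure("constant", "early_grouped", "constant")
#' @export
model_structure <- function(survival_form = "constant",
                            survival_grouping = "full_stage",
                            growth_form = "constant") {
  survival_form <- match.arg(survival_form, SURVIVAL_FORMS)
  survival_grouping <- match.arg(survival_grouping, GROUPINGS)
  growth_form <- match.arg(growth_form, GROWTH_FORMS)
  structure(list(survival_form = survival_form,
                 survival_grouping = survival_grouping,
                 growth_form = growth_form),
            class = "model_structure")
}

#' @export
print.model_structure <- function(x, ...) {
  cat("model structure: survival ~ ", x$survival_form, " (",
      x$survival_grouping, "), growth ~ ", x$growth_form, "\n", sep = "")
  invisible(x)
}

#' @export
format.model_structure <- function(x, ...) {
  paste0("phi(", x$survival_form, ",", x$survival_grouping, ")",
         ".psi(", x$growth_form, ")")
}

#' Enumerate the candidate model grid
#'
#' Full Cartesian product of the supplied options, in deterministic order:
#' survival form varies slowest, then grouping, then growth form.  The
#' default options give the 18-model candidate set used for model
#' selection.
#'
#' @param survival_forms,groupings,growth_forms character vectors of allowed
#'   values for each structure field.
#' @return A list of [model_structure()] objects.
#' @examples
#' length(model_grid())  # 18
#' @export
model_grid <- function(survival_forms = SURVIVAL_FORMS,
                       groupings = GROUPINGS,
                       growth_forms = GROWTH_FORMS) {
  if (!length(survival_forms) || !length(groupings) || !length(growth_forms))
    stop("each option list must be non-empty")
  out <- list()
  for (s in survival_forms)
    for (g in groupings)
      for (w in growth_forms)
        out[[length(out) + 1L]] <- model_structure(s, g, w)
  out
}

# stage -> survival group label, for the 6 stages with estimated survival
survival_groups <- function(grouping) {
  stages <- c("egg", "I1", "I2", "I3", "I4", "I5")
  if (grouping == "full_stage") {
    setNames(stages, stages)
  } else {
    setNames(c("egg", "early", "early", "early", "early", "I5"), stages)
  }
}

survival_group_levels <- function(grouping) {
  unique(unname(survival_groups(grouping)))
}

# a0 parameter labels in canonical order, "stage.dest"
growth_intercept_labels <- function() {
  unlist(lapply(GROWTH_STAGES, function(s)
    paste0(s, ".", GROWTH_DESTS[[s]])), use.names = FALSE)
}

#' Construct a full parameter vector for a model structure
#'
#' Bundles every sampled quantity of a candidate model: survival intercepts
#' `b0` (one per survival group) and slopes `b1` (present only when the
#' survival form has a covariate), growth multinomial-logit intercepts `a0`
#' (one per stage-destination pair for I1-I4) and per-stage shared slopes
#' `a1`, stage-specific detection probabilities, and the informative-prior
#' egg-hatch and pupation probabilities.
#'
#' @param structure a [model_structure()].
#' @param b0 named numeric, survival intercepts by group
#'   (see `survival_grouping`); logit scale.
#' @param b1 named numeric of slopes by group; required iff `survival_form`
#'   is not `"constant"`.
#' @param a0 named numeric of growth intercepts, names `"I1.I2"`, `"I1.I3"`,
#'   ..., `"I4.I5"` (7 in all); multinomial-logit scale against stasis.
#' @param a1 named numeric of growth slopes, one per stage I1-I4, shared
#'   across that stage's destinations; required iff `growth_form` is not
#'   `"constant"`.
#' @param p_live length-7 live detection probabilities (egg..pupa);
#'   the pupa entry must be 0 (pupae are unobservable).
#' @param p_dead length-7 corpse detection probabilities; egg and pupa 0.
#' @param hatch probability an egg hatches within one 3-day step.
#' @param pupation probability a surviving fifth instar pupates within one
#'   step.
#' @return An object of class `hmm_parameters`.
#' @export
hmm_parameters <- function(structure,
                           b0, b1 = NULL, a0, a1 = NULL,
                           p_live, p_dead, hatch, pupation) {
  stopifnot(inherits(structure, "model_structure"))
  groups <- survival_group_levels(structure$survival_grouping)
  b0 <- b0[groups]
  if (anyNA(b0) || !all(is.finite(b0)))
    stop("b0 must supply a finite intercept for each survival group: ",
         paste(groups, collapse = ", "))
  if (structure$survival_form == "constant") {
    b1 <- NULL
  } else {
    b1 <- b1[groups]
    if (anyNA(b1) || !all(is.finite(b1)))
      stop("b1 must supply a finite slope for each survival group")
  }
  lab <- growth_intercept_labels()
  a0 <- a0[lab]
  if (anyNA(a0) || !all(is.finite(a0)))
    stop("a0 must supply finite intercepts named ",
         paste(lab, collapse = ", "))
  if (structure$growth_form == "constant") {
    a1 <- NULL
  } else {
    a1 <- a1[GROWTH_STAGES]
    if (anyNA(a1) || !all(is.finite(a1)))
      stop("a1 must supply a finite slope for each of ",
           paste(GROWTH_STAGES, collapse = ", "))
  }
  det <- detection_params(p_live, p_dead)
  if (det$p_live[["pupa"]] != 0)
    stop("p_live for pupa is fixed at 0 in this model")
  for (p in c(hatch, pupation))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("hatch and pupation must be probabilities in [0,1]")
  out <- list(structure = structure, b0 = b0, b1 = b1, a0 = a0, a1 = a1,
              p_live = det$p_live, p_dead = det$p_dead,
              hatch = hatch, pupation = pupation)
  class(out) <- "hmm_parameters"
  out
}

#' Stage-specific survival probability from the logit link
#'
#' `logistic(b0_g + b1_g * x)` where `g` is the stage's survival group and
#' `x` the (standardized) covariate selected by the structure's survival
#' form; `x` is ignored (taken as 0) under the constant form.
#'
#' @param stage a live stage among egg, I1..I5 (pupa survival is not
#'   estimated).
#' @param x covariate value; must be finite when the form has a covariate.
#' @param params an [hmm_parameters()] object.
#' @param structure a [model_structure()]; defaults to the one stored in
#'   `params`.
#' @return survival probability in `(0, 1)`.
#' @examples
#' st <- model_structure()
#' pars <- example_parameters(st)
#' survival_probability("I1", 0, pars)
#' @export
survival_probability <- function(stage, x = 0, params,
                                 structure = params$structure) {
  if (stage == "pupa")
    stop("pupa survival is not estimated in this model")
  g <- survival_groups(structure$survival_grouping)[[stage]]
  eta <- params$b0[[g]]
  if (structure$survival_form != "constant") {
    if (length(x) != 1 || !is.finite(x))
      stop("missing covariate value for survival form '",
           structure$survival_form, "'")
    eta <- eta + params$b1[[g]] * x
  }
  plogis(eta)
}

#' Growth probabilities from the multinomial-logit link
#'
#' For instars I1-I4 the destination probabilities are
#' `psi_j = exp(a0_j + a1 * x) / (1 + sum_j exp(a0_j + a1 * x))` with stasis
#' as the reference category receiving the remainder; the slope `a1` is
#' shared across a stage's destinations.  The egg returns
#' `(1 - hatch, hatch)` and the fifth instar `(1 - pupation, pupation)`,
#' taken from the informative-prior parameters.  Computed with
#' max-subtraction so extreme logits cannot overflow.
#'
#' @inheritParams survival_probability
#' @return Named probability vector over (stasis, destinations); sums to 1.
#' @examples
#' pars <- example_parameters()
#' growth_probabilities("I1", 0, pars)
#' @export
growth_probabilities <- function(stage, x = 0, params,
                                 structure = params$structure) {
  dests <- GROWTH_DESTS[[stage]]
  if (!length(dests))
    stop("stage ", stage, " has no growth destinations")
  if (stage == "egg")
    return(setNames(c(1 - params$hatch, params$hatch), c("egg", "I1")))
  if (stage == "I5")
    return(setNames(c(1 - params$pupation, params$pupation), c("I5", "pupa")))
  lw <- params$a0[paste0(stage, ".", dests)]
  if (structure$growth_form != "constant") {
    if (length(x) != 1 || !is.finite(x))
      stop("missing covariate value for growth form '",
           structure$growth_form, "'")
    lw <- lw + params$a1[[stage]] * x
  }
  lw <- c(0, unname(lw)) # stasis reference
  lw <- lw - max(lw)
  p <- exp(lw) / sum(exp(lw))
  setNames(p, c(stage, dests))
}

#' Assemble vital rates for one covariate context
#'
#' Composes the survival and growth links into a complete [vital_rates()]
#' object for given covariate values, ready for
#' [build_transition_matrix()].  The pupa row is terminal (`phi = 1`,
#' stasis), and the egg-hatch and pupation entries come from the
#' informative-prior parameters.
#'
#' @param params an [hmm_parameters()] object.
#' @param structure a [model_structure()]; defaults to the one in `params`.
#' @param x_survival,x_growth standardized covariate values entering the
#'   survival and growth linear predictors (ignored under constant forms).
#' @return A [vital_rates()] object.
#' @export
assemble_vital_rates <- function(params, structure = params$structure,
                                 x_survival = 0, x_growth = 0) {
  phi <- setNames(rep(1, N_STAGES), STAGES)
  for (s in c("egg", "I1", "I2", "I3", "I4", "I5"))
    phi[[s]] <- survival_probability(s, x_survival, params, structure)
  psi <- matrix(0, N_STAGES, N_STAGES, dimnames = list(STAGES, STAGES))
  for (s in STAGES[-N_STAGES]) {
    pr <- growth_probabilities(s, x_growth, params, structure)
    psi[names(pr), s] <- pr
  }
  psi["pupa", "pupa"] <- 1
  vital_rates(phi, psi)
}

#' Example parameter vector
#'
#' A complete, field-plausible parameter vector for a given structure;
#' used in examples and as a starting point for simulations.  All slopes
#' default to zero.
#'
#' @param structure a [model_structure()].
#' @return An [hmm_parameters()] object.
#' @export
example_parameters <- function(structure = model_structure()) {
  groups <- survival_group_levels(structure$survival_grouping)
  b0 <- setNames(rep(qlogis(0.9), length(groups)), groups)
  b1 <- if (structure$survival_form == "constant") NULL else
    setNames(rep(0, length(groups)), groups)
  lab <- growth_intercept_labels()
  a0 <- setNames(rep(-0.5, length(lab)), lab)
  a1 <- if (structure$growth_form == "constant") NULL else
    setNames(rep(0, length(GROWTH_STAGES)), GROWTH_STAGES)
  hmm_parameters(structure, b0 = b0, b1 = b1, a0 = a0, a1 = a1,
                 p_live = c(0.2, 0.9, 0.9, 0.8, 0.8, 0.9, 0),
                 p_dead = c(0, 0.5, 0.5, 0.5, 0.5, 0.5, 0),
                 hatch = 0.6, pupation = 0.35)
}

# ---- internal flat parameterization for the sampler ----------------------
#
# The sampler works on an unconstrained vector: coefficients as-is,
# probabilities on the logit scale.  Layout (and block membership) is fully
# determined by the structure.

ESTIMATED_P_LIVE <- c("egg", "I1", "I2", "I3", "I4", "I5")
ESTIMATED_P_DEAD <- c("I1", "I2", "I3", "I4", "I5")

param_layout <- function(structure) {
  groups <- survival_group_levels(structure$survival_grouping)
  nm <- list(survival = paste0("b0[", groups, "]"),
             growth = paste0("a0[", growth_intercept_labels(), "]"),
             detection = c(paste0("p_live[", ESTIMATED_P_LIVE, "]"),
                           paste0("p_dead[", ESTIMATED_P_DEAD, "]")),
             informative = c("hatch", "pupation"))
  if (structure$survival_form != "constant")
    nm$survival <- c(nm$survival, paste0("b1[", groups, "]"))
  if (structure$growth_form != "constant")
    nm$growth <- c(nm$growth, paste0("a1[", GROWTH_STAGES, "]"))
  nm
}

param_names <- function(structure) unlist(param_layout(structure),
                                          use.names = FALSE)

# which flat entries are probabilities (logit-transformed)?
param_is_prob <- function(structure) {
  nm <- param_names(structure)
  grepl("^p_live|^p_dead|^hatch$|^pupation$", nm)
}

flatten_parameters <- function(params, structure = params$structure) {
  th <- c(params$b0,
          if (!is.null(params$b1)) params$b1,
          params$a0,
          if (!is.null(params$a1)) params$a1,
          qlogis(pmin(pmax(params$p_live[ESTIMATED_P_LIVE], 1e-12), 1 - 1e-12)),
          qlogis(pmin(pmax(params$p_dead[ESTIMATED_P_DEAD], 1e-12), 1 - 1e-12)),
          qlogis(pmin(pmax(c(params$hatch, params$pupation), 1e-12), 1 - 1e-12)))
  groups <- survival_group_levels(structure$survival_grouping)
  names(th) <- c(paste0("b0[", groups, "]"),
                 if (!is.null(params$b1)) paste0("b1[", groups, "]"),
                 paste0("a0[", growth_intercept_labels(), "]"),
                 if (!is.null(params$a1)) paste0("a1[", GROWTH_STAGES, "]"),
                 paste0("p_live[", ESTIMATED_P_LIVE, "]"),
                 paste0("p_dead[", ESTIMATED_P_DEAD, "]"),
                 "hatch", "pupation")
  th[param_names(structure)]
}

unflatten_parameters <- function(theta, structure) {
  nm <- param_names(structure)
  stopifnot(length(theta) == length(nm))
  names(theta) <- nm
  groups <- survival_group_levels(structure$survival_grouping)
  get <- function(pat, lab) setNames(theta[paste0(pat, "[", lab, "]")], lab)
  b0 <- get("b0", groups)
  b1 <- if (structure$survival_form != "constant") get("b1", groups) else NULL
  a0 <- get("a0", growth_intercept_labels())
  a1 <- if (structure$growth_form != "constant") get("a1", GROWTH_STAGES)
        else NULL
  p_live <- setNames(rep(0, N_STAGES), STAGES)
  p_live[ESTIMATED_P_LIVE] <- plogis(get("p_live", ESTIMATED_P_LIVE))
  p_dead <- setNames(rep(0, N_STAGES), STAGES)
  p_dead[ESTIMATED_P_DEAD] <- plogis(get("p_dead", ESTIMATED_P_DEAD))
  hmm_parameters(structure, b0 = b0, b1 = b1, a0 = a0, a1 = a1,
                 p_live = p_live, p_dead = p_dead,
                 hatch = plogis(theta[["hatch"]]),
                 pupation = plogis(theta[["pupation"]]))
}
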