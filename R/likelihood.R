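# Marginal likelihood of encounter histories.
#
# The latent state path is never sampled: the forward algorithm sums the
# joint state/observation probability over all hidden paths exactly.  The
# recursion is conditioned on the state at first detection (individuals
# enter the study when first seen alive), and the forward vector is
# rescaled at every step so 9-occasion histories with tiny probabilities
# stay finite.  A brute-force path-enumeration oracle is provided for
# testing on short histories.

# file-format observation categories -> internal category index (1..15);
# corpses of eggs (9) and pupae (15) are internal-only and never occur in
# data files
# accept internal labels, file labels, or 1..15 integers
category_index <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x) | x < 1L | x > N_CATEGORIES))
      stop("category index out of 1..", N_CATEGORIES)
    return(x)
  }
  i <- match(x, CATEGORIES)
  j <- FILE_CATEGORY_INDEX[match(x, names(FILE_CATEGORY_INDEX))]
  i[is.na(i)] <- j[is.na(i)]
  if (anyNA(i))
    stop("unknown observation category: ",
         paste(unique(x[is.na(i)]), collapse = ", "))
  as.integer(i)
}

# parse a single history: category indices, first-detection occasion and
# the conditioned-on live state
parse_history <- function(categories) {
  y <- category_index(categories)
  det <- which(y != 1L)
  if (!length(det)) stop("history contains no detection")
  f <- det[1]
  if (y[f] < 2L || y[f] > 8L)
    stop("first detection must be a live stage, got category ",
         CATEGORIES[y[f]])
  list(y = y, first = f, first_state = y[f] - 1L)
}

# normalize the PX argument: one matrix or list of per-transition matrices
as_px_list <- function(px, n_trans) {
  if (is.list(px)) {
    if (length(px) != n_trans)
      stop("need one transition matrix per interval (", n_trans, ")")
    px
  } else {
    rep(list(px), n_trans)
  }
}

#' Log-likelihood of one encounter history
#'
#' Exact marginal log-likelihood of an individual's observation sequence
#' under the hidden Markov model, by the forward algorithm.  The recursion
#' starts at the first detection with all probability on the observed live
#' state; each later occasion multiplies by the transition kernel and by
#' the observation probabilities of the recorded category (including "not
#' seen", which carries information).  `-Inf` is returned for histories the
#' model gives probability zero.
#'
#' @param categories vector of observed categories, one per occasion, as
#'   internal labels (`"NS"`, `"seen_I1"`, `"dead_I3"`, ...), file labels
#'   (`"NS"`, `"L1"`, `"D3"`, ...), or integer indices 1..15.  Entries
#'   before the first detection are ignored.
#' @param px a 15x15 transition matrix, or a list of `length(categories)-1`
#'   matrices when the kernel varies between occasions (transition `t ->
#'   t+1` is element `t`).
#' @param po a 15x15 observation matrix.
#' @return log-likelihood (scalar; possibly `-Inf`).
#' @examples
#' vr <- vital_rates(rep(1, 7), stasis_psi())
#' px <- build_transition_matrix(vr)
#' po <- build_observation_matrix(
#'   detection_params(c(0, rep(1, 5), 0), rep(0, 7)))
#' loglik_history(c("L1", "L1", "L1"), px, po)  # 0: certain outcome
#' @export
loglik_history <- function(categories, px, po) {
  info <- parse_history(categories)
  T_occ <- length(info$y)
  if (info$first == T_occ) return(0)
  pxl <- as_px_list(px, T_occ - 1L)
  alpha <- numeric(N_STATES)
  alpha[info$first_state] <- 1
  ll <- 0
  for (t in seq(info$first + 1L, T_occ)) {
    alpha <- drop(pxl[[t - 1L]] %*% alpha) * po[info$y[t], ]
    tot <- sum(alpha)
    if (!(tot > 0) || !is.finite(tot)) return(-Inf)
    alpha <- alpha / tot
    ll <- ll + log(tot)
  }
  ll
}

#' Brute-force log-likelihood by path enumeration
#'
#' Independent oracle for [loglik_history()]: sums the product of
#' transition and observation probabilities explicitly over every possible
#' hidden-state path.  Cost grows as `15^m` in the number of post-detection
#' occasions `m`, so histories are limited to 6 occasions.
#'
#' @inheritParams loglik_history
#' @return log-likelihood (scalar; possibly `-Inf`).
#' @export
brute_force_loglik <- function(categories, px, po) {
  info <- parse_history(categories)
  T_occ <- length(info$y)
  m <- T_occ - info$first
  if (m > 5L)
    stop("path enumeration is limited to histories of at most 6 occasions")
  if (m == 0L) return(0)
  pxl <- as_px_list(px, T_occ - 1L)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N_STATES)), m),
                                 KEEP.OUT.ATTRS = FALSE))
  prev <- rep(info$first_state, nrow(paths))
  pr <- rep(1, nrow(paths))
  for (t in seq_len(m)) {
    cur <- paths[, t]
    step <- info$first + t
    pr <- pr * pxl[[step - 1L]][cbind(cur, prev)] * po[info$y[step], cur]
    prev <- cur
  }
  s <- sum(pr)
  if (s > 0) log(s) else -Inf
}

# ---- vectorized transition-array construction ----------------------------
#
# The sampler evaluates the likelihood thousands of times; PX is built for
# all G distinct covariate contexts at once from the link functions.

build_px_array <- function(params, structure = params$structure,
                           x_survival = 0, x_growth = 0,
                           death_partition = "growth") {
  G <- max(length(x_survival), length(x_growth))
  xs <- rep_len(x_survival, G)
  xg <- rep_len(x_growth, G)
  groups <- survival_groups(structure$survival_grouping)
  phi <- matrix(1, N_STAGES, G, dimnames = list(STAGES, NULL))
  for (s in names(groups)) {
    g <- groups[[s]]
    eta <- params$b0[[g]]
    if (structure$survival_form != "constant")
      eta <- eta + params$b1[[g]] * xs
    phi[s, ] <- plogis(eta)
  }
  psi <- array(0, c(N_STAGES, N_STAGES, G),
               dimnames = list(STAGES, STAGES, NULL))
  psi["egg", "egg", ] <- 1 - params$hatch
  psi["I1", "egg", ] <- params$hatch
  for (s in GROWTH_STAGES) {
    dests <- GROWTH_DESTS[[s]]
    lw <- matrix(params$a0[paste0(s, ".", dests)], length(dests), G)
    if (structure$growth_form != "constant")
      lw <- lw + rep(params$a1[[s]] * xg, each = length(dests))
    mx <- pmax(0, apply(lw, 2, max)) # guard against overflow
    e <- exp(sweep(lw, 2, mx))
    denom <- exp(-mx) + colSums(e)
    psi[s, s, ] <- exp(-mx) / denom
    psi[dests, s, ] <- sweep(e, 2, denom, "/")
  }
  psi["I5", "I5", ] <- 1 - params$pupation
  psi["pupa", "I5", ] <- params$pupation
  psi["pupa", "pupa", ] <- 1
  px <- array(0, c(N_STATES, N_STATES, G))
  px[1:7, 1:7, ] <- psi * rep(phi, each = N_STAGES)
  if (death_partition == "growth") {
    px[8:14, 1:7, ] <- psi * rep(1 - phi, each = N_STAGES)
  } else {
    for (i in 1:7) px[7 + i, i, ] <- 1 - phi[i, ]
  }
  px[15, 8:14, ] <- 1
  px[15, 15, ] <- 1
  px
}

# Sampler hot path: a closure evaluating the dataset log-likelihood
# directly from the flat unconstrained parameter vector, with all name
# lookups resolved to integer indices up front.
make_loglik_fn <- function(enc) {
  st <- enc$structure
  nm <- param_names(st)
  groups <- survival_group_levels(st$survival_grouping)
  gmap <- match(survival_groups(st$survival_grouping), groups) # 6 stages
  i_b0 <- match(paste0("b0[", groups, "]"), nm)
  has_b1 <- st$survival_form != "constant"
  i_b1 <- if (has_b1) match(paste0("b1[", groups, "]"), nm)
  lab <- growth_intercept_labels()
  i_a0 <- match(paste0("a0[", lab, "]"), nm)
  has_a1 <- st$growth_form != "constant"
  i_a1 <- if (has_a1) match(paste0("a1[", GROWTH_STAGES, "]"), nm)
  i_pl <- match(paste0("p_live[", ESTIMATED_P_LIVE, "]"), nm)
  i_pd <- match(paste0("p_dead[", ESTIMATED_P_DEAD, "]"), nm)
  i_h <- match("hatch", nm)
  i_pp <- match("pupation", nm)
  xs <- enc$x_survival_g
  xg <- enc$x_growth_g
  G <- length(xs)
  grow_death <- enc$death_partition == "growth"
  obs <- enc$obs; first_occ <- enc$first_occ
  first_state <- enc$first_state; grp <- enc$grp

  none <- numeric(0)
  function(theta) {
    hmm_loglik_cpp(
      theta[i_b0][gmap],
      if (has_b1) theta[i_b1][gmap] else none,
      theta[i_a0],
      if (has_a1) theta[i_a1] else none,
      theta[i_h], theta[i_pp],
      theta[i_pl], theta[i_pd],
      xs, xg, grow_death,
      obs, first_occ, first_state, grp)
  }
}

# observation matrix without validation overhead (sampler hot path)
build_po <- function(p_live, p_dead) {
  p <- c(p_live, p_dead, 0)
  po <- matrix(0, N_CATEGORIES, N_STATES)
  po[1, ] <- 1 - p
  po[cbind(1 + 1:14, 1:14)] <- p[1:14]
  po
}

# fast dataset log-likelihood on an encoded dataset
loglik_encoded <- function(params, enc) {
  px <- build_px_array(params, enc$structure, enc$x_survival_g, enc$x_growth_g,
                       death_partition = enc$death_partition)
  po <- build_po(params$p_live, params$p_dead)
  forward_loglik_cpp(enc$obs, enc$first_occ, enc$first_state, enc$grp,
                     px, po)
}

#' Deviance of a dataset under given parameters
#'
#' `-2` times the summed forward-algorithm log-likelihood over all
#' individuals.  Any individual history with zero probability makes the
#' deviance `+Inf`.
#'
#' @param params an [hmm_parameters()] object.
#' @param data an encounter-history data frame (see
#'   [read_encounter_file()] for the column layout) or a prepared dataset
#'   from [prepare_data()].
#' @param structure model structure; defaults to the one in `params`.
#' @param ... passed to [prepare_data()] when `data` is a data frame
#'   (`temperature`, `density_metric`, ...).
#' @return The deviance (scalar).
#' @export
dataset_deviance <- function(params, data, structure = params$structure, ...) {
  enc <- if (inherits(data, "hmm_data")) data
         else prepare_data(data, structure, ...)
  -2 * sum(loglik_encoded(params, enc))
}

#' Prepare encounter data for likelihood evaluation
#'
#' Validates an encounter-history table, builds the standardized covariates
#' the model structure requires (survey date, size-scaled density from
#' observed plant co-occupants, 3-day mean temperature), and packs
#' everything into the indexed form the forward algorithm consumes.
#' Transition covariates are measured at the source occasion: the kernel
#' for `[t, t+1)` uses covariate values at occasion `t`.
#'
#' @param enc encounter-history data frame with columns `individual_id`,
#'   `plot_id`, `plant_id`, `occasion`, `day`, `category`, `length_mm`.
#' @param structure a [model_structure()]; decides which covariates enter.
#' @param temperature data frame `plot_id`, `occasion`, `mean_temp`;
#'   required when the growth form is `"temperature"`.
#' @param density_metric `"size"` (summed lengths) or `"count"`.
#' @param death_partition passed through to the transition-matrix builder.
#' @return An object of class `hmm_data` (opaque list; used by
#'   [dataset_deviance()] and [fit_hmm()]).
#' @export
prepare_data <- function(enc, structure = model_structure(),
                         temperature = NULL,
                         density_metric = c("size", "count"),
                         death_partition = c("growth", "stay")) {
  density_metric <- match.arg(density_metric)
  death_partition <- match.arg(death_partition)
  enc <- as_encounter_data(enc)
  T_occ <- max(enc$occasion)
  cat_idx <- category_index(enc$category)

  detected <- tapply(cat_idx != 1L, enc$individual_id, any)
  ids <- names(detected)[detected]
  if (!length(ids)) stop("no individual in the dataset was ever detected")
  if (any(!detected))
    message(sum(!detected), " individual(s) never detected were dropped")
  keep <- enc$individual_id %in% ids
  enc_k <- enc[keep, ]
  row <- match(enc_k$individual_id, ids)
  n <- length(ids)

  obs <- matrix(1L, n, T_occ)
  obs[cbind(row, enc_k$occasion)] <- cat_idx[keep]
  first_occ <- apply(obs, 1, function(r) which(r != 1L)[1])
  first_cat <- obs[cbind(seq_len(n), first_occ)]
  first_state <- first_cat - 1L # seen-live category c corresponds to state c-1

  # per-individual plot and plant (fixed; taken at first detection)
  fd <- enc_k[order(row, enc_k$occasion), ]
  fd_first <- fd[!duplicated(fd$individual_id), ]
  plot_id <- fd_first$plot_id[match(ids, fd_first$individual_id)]
  plant_id <- fd_first$plant_id[match(ids, fd_first$individual_id)]

  # plot schedule: day of each plot x occasion.  Rows only cover occasions
  # with individuals present, so missing entries are completed on each
  # plot's arithmetic lattice day = offset + (occasion - 1) * step.
  sched <- unique(enc[, c("plot_id", "occasion", "day")])
  if (anyDuplicated(sched[, c("plot_id", "occasion")]))
    stop("inconsistent day index within a plot x occasion")
  steps <- unlist(lapply(split(sched, sched$plot_id), function(g) {
    g <- g[order(g$occasion), ]
    if (nrow(g) < 2) return(NULL)
    diff(g$day) / diff(g$occasion)
  }))
  step <- unique(steps)
  if (length(step) > 1)
    stop("survey days are not on a regular per-plot schedule")
  plots <- sort(unique(sched$plot_id))
  offset <- vapply(plots, function(p) {
    g <- sched[sched$plot_id == p, ]
    off <- unique(g$day - (g$occasion - 1L) * if (length(step)) step else 0)
    if (length(off) > 1)
      stop("day indices of plot ", p, " violate its survey schedule")
    off
  }, numeric(1))
  names(offset) <- plots
  if (!length(step)) step <- 0 # single-occasion data: no transitions anyway

  src <- seq_len(T_occ - 1L) # source occasions for transitions
  cell_plot <- rep(plot_id, times = length(src))
  cell_occ <- rep(src, each = n)
  cell_day <- offset[as.character(cell_plot)] + (cell_occ - 1L) * step
  if (anyNA(cell_day))
    stop("plot schedule is missing some (plot, occasion) days")

  scaling <- list()
  x_surv <- x_grow <- rep(0, n * length(src))
  need_date <- structure$survival_form == "date" ||
    structure$growth_form == "date"
  if (need_date) {
    zd <- standardize(cell_day)
    scaling$date <- c(center = zd$center, scale = zd$scale)
  }
  if (structure$survival_form == "date") x_surv <- zd$z
  if (structure$growth_form == "date") x_grow <- zd$z
  if (structure$survival_form == "density") {
    live <- cat_idx[keep] >= 3L & cat_idx[keep] <= 7L # detected instars
    dk <- enc_k[live, ]
    dkey <- paste(dk$plot_id, dk$plant_id, dk$occasion)
    dens <- if (density_metric == "size")
      tapply(ifelse(is.na(dk$length_mm), 0, dk$length_mm), dkey, sum)
    else tapply(dkey, dkey, length)
    cell_key <- paste(cell_plot, rep(plant_id, times = length(src)), cell_occ)
    dv <- unname(dens[cell_key])
    dv[is.na(dv)] <- 0
    zv <- standardize(dv)
    scaling$density <- c(center = zv$center, scale = zv$scale)
    x_surv <- zv$z
  }
  if (structure$growth_form == "temperature") {
    if (is.null(temperature))
      stop("growth form 'temperature' requires a temperature covariate ",
           "table (plot_id, occasion, mean_temp)")
    tkey <- paste(temperature$plot_id, temperature$occasion)
    tv <- temperature$mean_temp[match(paste(cell_plot, cell_occ), tkey)]
    if (anyNA(tv))
      stop("temperature table is missing some (plot, occasion) values")
    zt <- standardize(tv)
    scaling$temperature <- c(center = zt$center, scale = zt$scale)
    x_grow <- zt$z
  }

  key <- paste(signif(x_surv, 12), signif(x_grow, 12))
  ukey <- unique(key)
  gidx <- match(key, ukey)
  grp <- matrix(gidx, n, length(src))
  first_idx <- match(ukey, key)

  out <- list(
    obs = obs, first_occ = as.integer(first_occ),
    first_state = as.integer(first_state), grp = grp,
    x_survival_g = x_surv[first_idx], x_growth_g = x_grow[first_idx],
    n = n, n_occasions = T_occ, ids = ids,
    plot_id = plot_id, plant_id = plant_id,
    structure = structure, scaling = scaling,
    density_metric = density_metric, death_partition = death_partition
  )
  class(out) <- "hmm_data"
  out
}
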