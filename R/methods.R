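# S3 methods for fitted models.

#' @export
print.instar_hmm <- function(x, ...) {
  cat("Juvenile cohort hidden Markov model (Bayesian fit)\n")
  print(x$structure)
  cat(sprintf("  %d encounter histories, %d occasions; K = %d parameters\n",
              x$n, x$n_occasions, x$K))
  cat(sprintf("  %d chains x %d retained draws (burn-in %d)\n",
              x$settings$chains, x$settings$samples, x$settings$burn_in))
  cat(sprintf("  mean posterior deviance: %.2f\n", x$mean_deviance))
  cat("  block acceptance rates:",
      paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.instar_hmm <- function(object, level = 0.95, diagnostics = TRUE,
                               ...) {
  s <- posterior_summary(object, level = level)
  if (diagnostics && object$settings$chains >= 2) {
    gr <- gelman_rubin(object)
    s$psrf <- unname(gr$psrf[s$parameter])
    attr(s, "mpsrf") <- gr$mpsrf
  }
  attr(s, "mean_deviance") <- object$mean_deviance
  attr(s, "structure") <- format(object$structure)
  class(s) <- c("summary.instar_hmm", "data.frame")
  s
}

#' @export
print.summary.instar_hmm <- function(x, ...) {
  cat("Posterior summary —", attr(x, "structure"), "\n")
  cat(sprintf("mean posterior deviance %.2f", attr(x, "mean_deviance")))
  if (!is.null(attr(x, "mpsrf")))
    cat(sprintf(", multivariate psrf %.3f", attr(x, "mpsrf")))
  cat("\n\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Posterior-mean parameters of a fitted model
#'
#' @param object a fitted `instar_hmm`.
#' @param scale `"natural"` (probabilities back-transformed; default) or
#'   `"sampling"` (the unconstrained scale the chains run on).
#' @param ... unused.
#' @return Named numeric vector of posterior means.
#' @export
coef.instar_hmm <- function(object, scale = c("natural", "sampling"), ...) {
  scale <- match.arg(scale)
  flat <- apply(object$draws, 2, as.vector)
  if (scale == "natural") {
    is_prob <- param_is_prob(object$structure)
    flat[, is_prob] <- plogis(flat[, is_prob])
  }
  colMeans(flat)
}

#' @export
confint.instar_hmm <- function(object, parm, level = 0.95, ...) {
  s <- posterior_summary(object, level = level)
  ci <- as.matrix(s[, c("lower", "upper")])
  rownames(ci) <- s$parameter
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2,
                                       1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Trace plots of posterior draws
#'
#' @param x a fitted `instar_hmm`.
#' @param pars parameter names to plot (default: the first 6).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.instar_hmm <- function(x, pars = NULL, ...) {
  nm <- dimnames(x$draws)[[2]]
  if (is.null(pars)) pars <- nm[seq_len(min(6, length(nm)))]
  old <- par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(old))
  for (p in pars) {
    matplot(x$draws[, p, ], type = "l", lty = 1,
            col = gray(seq(0.1, 0.6, length.out = dim(x$draws)[3])),
            ylab = p, xlab = "", main = "", ...)
  }
  invisible(x)
}

#' Simulate cohorts from a fitted model
#'
#' Posterior-predictive style simulation: for each replicate a posterior
#' draw is selected at random, converted to a parameter vector, and a
#' cohort generated under the fitted structure with [simulate_cohort()].
#'
#' @param object a fitted `instar_hmm`.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param config a [cohort_config()] supplying the survey design; its
#'   `structure`/`params` fields are overridden by the fit.
#' @param ... unused.
#' @return A list of `cohort` objects (length `nsim`).
#' @export
simulate.instar_hmm <- function(object, nsim = 1, seed = 1,
                                config = cohort_config(), ...) {
  set.seed(seed)
  n_iter <- dim(object$draws)[1]
  n_chain <- dim(object$draws)[3]
  picks <- cbind(sample.int(n_iter, nsim, replace = TRUE),
                 sample.int(n_chain, nsim, replace = TRUE))
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    theta <- object$draws[picks[i, 1], , picks[i, 2]]
    pars <- unflatten_parameters(theta, object$structure)
    cfg <- config
    cfg$structure <- object$structure
    cfg$params <- pars
    cfg$death_partition <- object$death_partition
    cfg$predation_slope <- 0 # the fitted model carries no external trend
    cfg$seed <- as.integer(seed + i)
    out[[i]] <- simulate_cohort(cfg)
  }
  out
}
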