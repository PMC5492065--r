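# AICc model selection over the candidate grid, with the mean posterior
# deviance standing in for the maximized-likelihood deviance (DIC is
# deliberately not offered: its effective-parameter estimate can go
# negative for models like these).

#' AICc from a mean posterior deviance
#'
#' `AICc = D + 2K + 2K(K+1)/(n - K - 1)` where `D` is the mean posterior
#' deviance, `K` the number of sampled parameters, and `n` the
#' small-sample size (here: the number of encounter histories).
#'
#' @param mean_dev mean posterior deviance.
#' @param K number of free (sampled) parameters.
#' @param n effective sample size for the correction; must exceed `K + 1`.
#' @return The AICc value.
#' @examples
#' aicc_from_deviance(100, 5, 50)  # 111.3636...
#' @export
aicc_from_deviance <- function(mean_dev, K, n) {
  if (K < 0) stop("K must be nonnegative")
  if (n <= K + 1)
    stop("AICc correction undefined: n (", n, ") must exceed K + 1 (",
         K + 1, ")")
  mean_dev + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Number of sampled parameters of a model structure
#'
#' Deterministic count implied by the structure: survival intercepts (one
#' per survival group) and, under a covariate form, one slope per group;
#' growth multinomial-logit intercepts (7: two destinations each for
#' I1-I3, one for I4) and, under a covariate form, one shared slope per
#' stage I1-I4; stage-specific detection probabilities (6 live + 5 dead);
#' and, unless excluded, the 2 informative-prior parameters (hatch,
#' pupation).
#'
#' @param structure a [model_structure()].
#' @param include_informative count the informative-prior parameters
#'   (default TRUE).
#' @return Integer parameter count.
#' @examples
#' count_parameters(model_structure("constant", "full_stage", "constant"))
#' @export
count_parameters <- function(structure, include_informative = TRUE) {
  k <- length(param_names(structure))
  if (!include_informative) k <- k - 2L
  as.integer(k)
}

#' Rank candidate models by AICc
#'
#' Orders model scores by ascending AICc and attaches `delta_aicc`
#' relative to the best model.  Ties are broken by smaller `K`, then by the
#' lexicographic order of the structure label, so the ranking does not
#' depend on input order.
#'
#' @param scores a data frame with columns `structure` (label), `K`, `n`,
#'   `mean_deviance`, `aicc` — as produced by [select_models()] — or a list
#'   of such rows.
#' @return The ranked data frame with a `delta_aicc` column.
#' @export
rank_models <- function(scores) {
  scores <- as.data.frame(scores)
  if (!nrow(scores)) stop("no model scores to rank")
  ord <- order(scores$aicc, scores$K, scores$structure)
  scores <- scores[ord, , drop = FALSE]
  scores$delta_aicc <- scores$aicc - scores$aicc[1]
  rownames(scores) <- NULL
  scores
}

#' Fit and rank a grid of candidate models
#'
#' Fits every structure in the grid with [fit_hmm()] (same data, priors,
#' and settings throughout) and ranks them by AICc computed from each
#' fit's mean posterior deviance.  The small-sample `n` is the number of
#' encounter histories.
#'
#' @param data encounter-history data frame.
#' @param grid list of [model_structure()] objects (default: the full
#'   18-model grid; density models use the size-scaled metric).
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param temperature plot-by-occasion temperature table (needed when any
#'   candidate uses temperature-dependent growth).
#' @param include_informative count informative-prior parameters in `K`.
#' @param ... passed to [fit_hmm()].
#' @return An object of class `instar_hmm_selection`: list with `ranking`
#'   (data frame) and `fits` (named list of `instar_hmm` objects).
#' @export
select_models <- function(data, grid = model_grid(), priors,
                          settings = mcmc_settings(),
                          temperature = NULL, include_informative = TRUE,
                          ...) {
  stopifnot(length(grid) >= 1)
  fits <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    st <- grid[[i]]
    fit <- fit_hmm(data, st, priors, settings, temperature = temperature,
                   ...)
    K <- count_parameters(st, include_informative)
    lab <- format(st)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      structure = lab,
      survival_form = st$survival_form,
      survival_grouping = st$survival_grouping,
      growth_form = st$growth_form,
      K = K, n = fit$n,
      mean_deviance = fit$mean_deviance,
      aicc = aicc_from_deviance(fit$mean_deviance, K, fit$n)
    )
  }
  names(fits) <- vapply(grid, format, character(1))
  ranking <- rank_models(do.call(rbind, rows))
  out <- list(ranking = ranking, fits = fits)
  class(out) <- "instar_hmm_selection"
  out
}

#' @export
print.instar_hmm_selection <- function(x, ...) {
  cat("AICc ranking of", nrow(x$ranking), "candidate models",
      "(mean posterior deviance):\n")
  print(x$ranking[, c("structure", "K", "n", "mean_deviance", "aicc",
                      "delta_aicc")],
        digits = 5)
  invisible(x)
}
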