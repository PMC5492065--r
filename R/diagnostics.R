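# Convergence diagnostics: Gelman-Rubin potential scale reduction factors
# and the multivariate effective sample size from batch means.

# accept a fit, an iter x par x chain array, or a list of iter x par
# matrices
chains_array <- function(x) {
  if (inherits(x, "instar_hmm")) return(x$draws)
  if (is.list(x)) {
    mats <- lapply(x, as.matrix)
    dims <- vapply(mats, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all chains must have the same dimensions")
    arr <- array(unlist(mats), c(dims[1, 1], dims[2, 1], length(mats)),
                 dimnames = list(NULL, colnames(mats[[1]]), NULL))
    return(arr)
  }
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.matrix(x)) return(array(x, c(dim(x), 1),
                                 dimnames = list(NULL, colnames(x), NULL)))
  stop("cannot interpret input as MCMC chains")
}

#' Gelman-Rubin convergence diagnostics
#'
#' Per-parameter potential scale reduction factor
#' `psrf = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of the chain means (times
#' `n`), plus the Brooks-Gelman multivariate psrf computed from the largest
#' eigenvalue of `W^-1 B / n`.  Values near 1 indicate the chains agree;
#' parameters with zero within-chain variance are flagged and reported as
#' `NA`.
#'
#' @param x a fitted `instar_hmm`, an iterations x parameters x chains
#'   array, or a list of equally sized chain matrices.  At least 2 chains
#'   of length >= 10 are required.
#' @return List with `psrf` (named vector), `mpsrf` (scalar), and
#'   `flagged` (names of parameters with undefined psrf).
#' @export
gelman_rubin <- function(x) {
  arr <- chains_array(x)
  n <- dim(arr)[1]; p <- dim(arr)[2]; m <- dim(arr)[3]
  if (m < 2) stop("gelman_rubin needs at least 2 chains")
  if (n < 10) stop("chains are too short (need >= 10 iterations)")
  nm <- dimnames(arr)[[2]]
  if (is.null(nm)) nm <- paste0("par", seq_len(p))
  mu <- apply(arr, c(2, 3), mean) # p x m chain means
  psrf <- numeric(p)
  flagged <- character(0)
  W_diag <- numeric(p)
  for (j in seq_len(p)) {
    s2 <- apply(arr[, j, , drop = FALSE], 3, var)
    W <- mean(s2)
    W_diag[j] <- W
    B <- n * var(mu[j, ])
    if (W <= 0) {
      psrf[j] <- NA_real_
      flagged <- c(flagged, nm[j])
    } else {
      psrf[j] <- sqrt(((n - 1) / n * W + B / n) / W)
    }
  }
  names(psrf) <- nm
  # multivariate psrf (Brooks & Gelman): largest eigenvalue of W^-1 B / n
  mpsrf <- NA_real_
  ok <- W_diag > 0
  if (sum(ok) >= 1) {
    Wm <- matrix(0, sum(ok), sum(ok))
    for (ch in seq_len(m))
      Wm <- Wm + cov(matrix(arr[, ok, ch], n, sum(ok)))
    Wm <- Wm / m
    Bn <- cov(t(mu[ok, , drop = FALSE])) # B / n
    ev <- tryCatch(
      eigen(solve(Wm, Bn), only.values = TRUE)$values,
      error = function(e) NA
    )
    lam <- suppressWarnings(max(Re(ev)))
    if (is.finite(lam))
      mpsrf <- sqrt((n - 1) / n + (m + 1) / m * lam)
  }
  list(psrf = psrf, mpsrf = mpsrf, flagged = flagged)
}

#' Multivariate effective sample size
#'
#' `mESS = n * (det(Lambda) / det(Sigma))^(1/p)` where `Lambda` is the
#' sample covariance of the draws and `Sigma` a batch-means estimate of the
#' long-run (Monte Carlo) covariance, with batch size `floor(sqrt(n))`.
#' For multiple chains the per-chain estimates are summed.
#'
#' @param x chains as in [gelman_rubin()]; a single matrix is one chain.
#' @param batch_size batch length for the batch-means estimator; default
#'   `floor(sqrt(n))`.
#' @return Effective sample size (scalar).
#' @export
multivariate_ess <- function(x, batch_size = NULL) {
  arr <- chains_array(x)
  n <- dim(arr)[1]; p <- dim(arr)[2]; m <- dim(arr)[3]
  if (n <= p^2)
    stop("chain length (", n, ") must exceed the squared dimension (",
         p^2, "); select a parameter subset")
  one_chain <- function(ch) {
    b <- if (is.null(batch_size)) floor(sqrt(n)) else as.integer(batch_size)
    a <- floor(n / b)
    lam <- cov(ch)
    ldl <- determinant(lam, logarithm = TRUE)
    if (ldl$sign <= 0 || !is.finite(ldl$modulus) ||
        rcond(lam) < .Machine$double.eps * 100)
      stop("singular sample covariance (duplicated or constant ",
           "parameters?); select a parameter subset")
    idx <- seq_len(a * b)
    bm <- rowsum(ch[idx, , drop = FALSE],
                 rep(seq_len(a), each = b)) / b
    sig <- b * cov(bm)
    lds <- determinant(sig, logarithm = TRUE)
    if (lds$sign <= 0 || !is.finite(lds$modulus))
      stop("singular batch-means covariance; use longer chains")
    n * exp((as.numeric(ldl$modulus) - as.numeric(lds$modulus)) / p)
  }
  sum(vapply(seq_len(m),
             function(ch) one_chain(matrix(arr[, , ch], n, p)),
             numeric(1)))
}

#' Posterior summaries
#'
#' Per-parameter posterior mean, standard deviation, and central credible
#' interval from quantiles.  For a fitted model, probability-type
#' parameters (detection, hatch, pupation) are back-transformed to the
#' probability scale draw by draw before summarizing, and coefficients are
#' reported on the link scale; the stored covariate standardization is
#' attached so slopes can be mapped back to natural units
#' (`slope / scale`).
#'
#' @param x a fitted `instar_hmm`, an array, a list of chain matrices, or a
#'   single matrix of draws.
#' @param level credible level (default 0.95).
#' @return Data frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper` (and attribute `scaling` for fits).
#' @export
posterior_summary <- function(x, level = 0.95) {
  arr <- chains_array(x)
  is_fit <- inherits(x, "instar_hmm")
  nm <- dimnames(arr)[[2]]
  if (is.null(nm)) nm <- paste0("par", seq_len(dim(arr)[2]))
  flat <- apply(arr, 2, as.vector)
  if (is.null(dim(flat))) flat <- matrix(flat, nrow = 1)
  if (is_fit) {
    is_prob <- param_is_prob(x$structure)
    flat[, is_prob] <- plogis(flat[, is_prob])
  }
  alpha <- (1 - level) / 2
  qs <- apply(flat, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  out <- data.frame(
    parameter = nm,
    mean = colMeans(flat),
    sd = apply(flat, 2, sd),
    lower = qs[1, ],
    upper = qs[2, ],
    row.names = NULL
  )
  if (is_fit) attr(out, "scaling") <- x$scaling
  out
}
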