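# Priors, the adaptive Metropolis core on analytically known posteriors,
# and convergence diagnostics.

test_that("log prior matches closed-form contributions", {
  st <- model_structure()
  pars <- example_parameters(st)
  pri <- prior_spec(hatch = c(2, 2), pupation = c(2, 2))
  # a single coefficient at 0 contributes -log(100) - log(2*pi)/2
  pars0 <- pars
  pars0$b0[] <- 0; pars0$a0[] <- 0
  base <- log_prior(pars0, pri)
  pars1 <- pars0
  pars1$b0[1] <- 1
  expect_equal(log_prior(pars1, pri) - base,
               dnorm(1, 0, 100, TRUE) - dnorm(0, 0, 100, TRUE))
  expect_equal(dnorm(0, 0, 100, TRUE), -log(100) - 0.5 * log(2 * pi))
  # uniform detection contributes zero inside the support
  pars2 <- pars0
  pars2$p_live[3] <- 0.23
  expect_equal(log_prior(pars2, pri), base)
  # outside-support probabilities are impossible
  pars3 <- pars0
  pars3$p_dead[3] <- 1.2
  expect_identical(log_prior(pars3, pri), -Inf)
  # informative beta priors enter through hatch/pupation
  pars4 <- pars0
  pars4$hatch <- 0.3
  expect_equal(log_prior(pars4, pri) - base,
               dbeta(0.3, 2, 2, log = TRUE) -
                 dbeta(pars0$hatch, 2, 2, log = TRUE))
})

test_that("unconstrained-scale prior equals natural-scale prior + Jacobian", {
  set.seed(41)
  st <- model_structure("date", "early_grouped", "temperature")
  pri <- prior_spec(hatch = c(6, 4), pupation = c(3.5, 6.5), coef_sd = 10)
  for (i in 1:5) {
    theta <- rnorm(length(instarhmm:::param_names(st)), 0, 1)
    pars <- instarhmm:::unflatten_parameters(theta, st)
    ip <- instarhmm:::param_is_prob(st)
    jac <- sum(log(plogis(theta[ip])) + log(1 - plogis(theta[ip])))
    expect_equal(instarhmm:::log_prior_theta(theta, st, pri),
                 log_prior(pars, pri) + jac, tolerance = 1e-10)
  }
})

test_that("matched priors are centered on the truth at any strength", {
  tr <- list(hatch = 0.5, pupation = 0.35)
  pri <- matched_priors(tr, strength = 10)
  expect_equal(pri$hatch, c(5, 5))
  expect_equal(pri$pupation[1] / sum(pri$pupation), 0.35)
  # variance shrinks as strength grows
  v <- function(ab) prod(ab) / (sum(ab)^2 * (sum(ab) + 1))
  expect_lt(v(matched_priors(tr, 1000)$hatch), v(pri$hatch))
  expect_error(matched_priors(list(hatch = 0, pupation = 0.5), 10),
               "inside")
  expect_error(prior_spec(hatch = c(-1, 2), pupation = c(1, 1)), "alpha")
})

test_that("sampler is deterministic given the seed", {
  cohort <- small_cohort(seed = 1, n = 40, predation_slope = 0)
  enc <- prepare_data(cohort$encounters, cohort$config$structure,
                      death_partition = "stay")
  pri <- matched_priors(cohort$config$params, 20)
  st <- mcmc_settings(chains = 2, burn_in = 50, samples = 50, seed = 99)
  f1 <- fit_hmm(enc, cohort$config$structure, pri, st)
  f2 <- fit_hmm(enc, cohort$config$structure, pri, st)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("conjugate check: binomial detection with uniform prior", {
  # y successes in n trials, uniform(0,1) prior on p: posterior is
  # Beta(y + 1, n - y + 1); the sampler works on the logit scale with a
  # Jacobian, exactly as in the full model
  set.seed(12)
  n <- 60; y <- 42
  log_post <- function(theta) {
    p <- plogis(theta)
    y * log(p) + (n - y) * log(1 - p) +
      plogis(theta, log.p = TRUE) + plogis(-theta, log.p = TRUE)
  }
  res <- adaptive_metropolis(log_post, init = 0, n_burn = 1500,
                             n_keep = 8000)
  p_draws <- plogis(res$draws[, 1])
  exact_mean <- (y + 1) / (n + 2)
  exact_sd <- sqrt((y + 1) * (n - y + 1) / ((n + 2)^2 * (n + 3)))
  expect_equal(mean(p_draws), exact_mean, tolerance = 0.02)
  expect_equal(sd(p_draws), exact_sd, tolerance = 0.15)
})

test_that("detailed-balance smoke test on a bivariate normal posterior", {
  set.seed(31)
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  Sinv <- solve(S)
  log_post <- function(th) -0.5 * drop(th %*% Sinv %*% th)
  res <- adaptive_metropolis(log_post, init = c(3, -3),
                             blocks = list(1:2),
                             n_burn = 2000, n_keep = 5000)
  direct <- matrix(rnorm(5000 * 2), ncol = 2) %*% chol(S)
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(res$draws[, j], direct[, j]))
    expect_gt(ks$p.value, 0.01)
  }
  expect_true(all(res$acceptance >= 0.1 & res$acceptance <= 0.6))
})

test_that("non-finite posterior at initialization is refused", {
  expect_error(adaptive_metropolis(function(th) -Inf, init = 0),
               "re-initialize")
})

test_that("gelman_rubin matches its defining formula and flags degeneracy", {
  set.seed(8)
  n <- 200
  z <- rnorm(n)
  # two identical chains: B = 0, psrf = sqrt((n-1)/n)
  gr <- gelman_rubin(list(matrix(z), matrix(z)))
  expect_equal(unname(gr$psrf), sqrt((n - 1) / n), tolerance = 1e-12)
  # independent standard-normal chains: psrf near 1
  ch <- lapply(1:3, function(i) matrix(rnorm(1000)))
  gr2 <- gelman_rubin(ch)
  expect_gt(gr2$psrf, 0.99)
  expect_lt(gr2$psrf, 1.05)
  # disjoint chains: psrf blows up
  gr3 <- gelman_rubin(list(matrix(rnorm(100, 0, 0.01)),
                           matrix(rnorm(100, 10, 0.01))))
  expect_gt(gr3$psrf, 5)
  # constant parameter is flagged, not fabricated
  gr4 <- gelman_rubin(list(cbind(a = rep(1, 50), b = rnorm(50)),
                           cbind(a = rep(1, 50), b = rnorm(50))))
  expect_true(is.na(gr4$psrf[["a"]]))
  expect_identical(gr4$flagged, "a")
  expect_error(gelman_rubin(list(matrix(rnorm(100)))), "2 chains")
})

test_that("gelman_rubin agrees with coda on well-behaved chains", {
  skip_if_not_installed("coda")
  set.seed(14)
  ch <- lapply(1:3, function(i) {
    x <- matrix(rnorm(2000), ncol = 2)
    x[, 2] <- x[, 1] * 0.5 + x[, 2]
    colnames(x) <- c("a", "b")
    x
  })
  gr <- gelman_rubin(ch)
  cd <- coda::gelman.diag(coda::mcmc.list(lapply(ch, coda::mcmc)),
                          autoburnin = FALSE, transform = FALSE)
  # coda's point estimate includes a variability correction absent from
  # the plain psrf; both must be very near 1 here and within 2%
  expect_equal(unname(gr$psrf), unname(cd$psrf[, 1]), tolerance = 0.02)
  expect_equal(gr$mpsrf, cd$mpsrf, tolerance = 0.02)
})

test_that("multivariate ESS behaves at the iid and AR(1) limits", {
  set.seed(21)
  x <- matrix(rnorm(4000))
  ess_iid <- multivariate_ess(x)
  expect_gt(ess_iid / 4000, 0.8)
  expect_lt(ess_iid / 4000, 1.2)
  # AR(1) with coefficient 0.9: strong autocorrelation shrinks the ESS
  ar <- as.matrix(as.numeric(arima.sim(list(ar = 0.9), 4000)))
  ess_ar <- multivariate_ess(ar)
  expect_lt(ess_ar / 4000, 0.2)
  # duplicated coordinate: singular covariance is an error
  expect_error(multivariate_ess(cbind(x, x)), "singular|exceed")
  expect_error(multivariate_ess(matrix(rnorm(8), ncol = 2)), "exceed")
})

test_that("posterior_summary matches degenerate and analytic cases", {
  const <- matrix(5, 100, 1, dimnames = list(NULL, "c"))
  s <- posterior_summary(const)
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$lower, 5)
  expect_equal(s$upper, 5)
  two <- matrix(rep(c(-1, 1), 50), ncol = 1)
  expect_equal(posterior_summary(two)$mean, 0)
  set.seed(2)
  z <- matrix(rnorm(40000), ncol = 1)
  sz <- posterior_summary(z)
  expect_equal(sz$lower, -1.96, tolerance = 0.04)
  expect_equal(sz$upper, 1.96, tolerance = 0.04)
})
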