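# Link functions, covariates, and the candidate model grid.

test_that("survival logit link matches closed forms", {
  st <- model_structure("constant", "full_stage", "constant")
  pars <- example_parameters(st)
  pars$b0[] <- 0
  expect_equal(survival_probability("I2", 0, pars), 0.5)
  pars$b0[] <- log(9)
  expect_equal(survival_probability("I2", 0, pars), 0.9)
  std <- model_structure("date", "full_stage", "constant")
  p2 <- example_parameters(std)
  p2$b0[] <- 0; p2$b1[] <- log(9)
  expect_equal(survival_probability("I4", 1, p2), 0.9)
  expect_error(survival_probability("pupa", 0, pars), "pupa")
  expect_error(survival_probability("I1", NA, p2), "covariate")
})

test_that("survival grouping pools early instars", {
  st <- model_structure("constant", "early_grouped", "constant")
  pars <- example_parameters(st)
  pars$b0[] <- c(0, 1, 2)[seq_along(pars$b0)]
  phis <- vapply(c("I1", "I2", "I3", "I4"), survival_probability,
                 numeric(1), x = 0, params = pars)
  expect_true(all(phis == phis[1]))
  expect_false(survival_probability("I5", 0, pars) == phis[1])
  expect_false(survival_probability("egg", 0, pars) == phis[1])
})

test_that("multinomial-logit growth matches closed forms", {
  st <- model_structure()
  pars <- example_parameters(st)
  pars$a0[] <- 0
  expect_equal(unname(growth_probabilities("I1", 0, pars)), rep(1 / 3, 3))
  expect_equal(unname(growth_probabilities("I4", 0, pars)), c(0.5, 0.5))
  pars$a0["I4.I5"] <- log(3)
  expect_equal(unname(growth_probabilities("I4", 0, pars)), c(0.25, 0.75))
  # egg and I5 simplices come from the informative-prior parameters
  expect_equal(unname(growth_probabilities("egg", 0, pars)), c(0.4, 0.6))
  expect_equal(unname(growth_probabilities("I5", 0, pars)), c(0.65, 0.35))
  expect_error(growth_probabilities("pupa", 0, pars), "destinations")
})

test_that("growth simplex sums to one for 1000 random draws per stage", {
  set.seed(7)
  st <- model_structure("constant", "full_stage", "date")
  for (i in 1:250) {
    pars <- random_parameters(st)
    x <- rnorm(1, 0, 2)
    for (s in c("I1", "I2", "I3", "I4")) {
      pr <- growth_probabilities(s, x, pars)
      expect_lt(abs(sum(pr) - 1), 1e-12)
      expect_true(all(pr >= 0))
    }
  }
  # extreme logits do not overflow
  pars$a0[] <- 800
  pr <- growth_probabilities("I1", 0, pars)
  expect_lt(abs(sum(pr) - 1), 1e-12)
})

test_that("zero slopes reproduce the constant model exactly", {
  set.seed(11)
  st_const <- model_structure("constant", "full_stage", "constant")
  pars_c <- random_parameters(st_const)
  st_cov <- model_structure("date", "full_stage", "temperature")
  pars_x <- hmm_parameters(
    st_cov,
    b0 = pars_c$b0, b1 = setNames(rep(0, 6), names(pars_c$b0)),
    a0 = pars_c$a0, a1 = setNames(rep(0, 4), c("I1", "I2", "I3", "I4")),
    p_live = pars_c$p_live, p_dead = pars_c$p_dead,
    hatch = pars_c$hatch, pupation = pars_c$pupation)
  for (x in c(-2, 0, 3.5)) {
    vr_c <- assemble_vital_rates(pars_c, st_const)
    vr_x <- assemble_vital_rates(pars_x, st_cov, x_survival = x,
                                 x_growth = x)
    expect_identical(vr_c$phi, vr_x$phi)
    expect_identical(vr_c$psi, vr_x$psi)
  }
  # nonzero slope moves survival in the direction of its sign
  pars_x$b1[] <- 0.8
  lo <- survival_probability("I1", -1, pars_x)
  hi <- survival_probability("I1", 1, pars_x)
  expect_gt(hi, lo)
})

test_that("assembled vital rates are valid and time-invariant when constant", {
  set.seed(3)
  pars <- random_parameters(model_structure())
  vr1 <- assemble_vital_rates(pars, x_survival = 0, x_growth = 0)
  vr2 <- assemble_vital_rates(pars, x_survival = 5, x_growth = -5)
  expect_identical(vr1, vr2) # constant form ignores covariates
  expect_s3_class(vr1, "vital_rates")
  expect_equal(unname(vr1$psi["I1", "egg"]), pars$hatch)
  expect_equal(unname(vr1$psi["pupa", "I5"]), pars$pupation)
  expect_equal(unname(vr1$phi[["pupa"]]), 1)
})

test_that("size-scaled density sums lengths and counts count", {
  # stage mean lengths as inputs: one first instar plus one fifth instar
  expect_equal(size_scaled_density(c(4.1, 19.9)), 24.0)
  expect_equal(size_scaled_density(numeric(0)), 0)
  expect_equal(size_scaled_density(c(3, 12, 8), metric = "count"), 3)
  expect_error(size_scaled_density(c(4, -1)), "nonnegative")
  # permutation invariance
  set.seed(9)
  lens <- runif(6, 2, 20)
  expect_equal(size_scaled_density(lens), size_scaled_density(rev(lens)))
  expect_equal(size_scaled_density(lens, "count"),
               size_scaled_density(sample(lens), "count"))
})

test_that("interval mean temperature averages hours and enforces the gap rule", {
  h <- data.frame(hour = 0:71, temp = 70)
  expect_equal(interval_mean_temperature(h, 0, 3), 70)
  ramp <- data.frame(hour = 0:71, temp = seq(60, 80, length.out = 72))
  expect_equal(interval_mean_temperature(ramp, 0, 3), 70)
  gappy <- h[-(1:15), ] # ~21% of hours missing
  expect_error(interval_mean_temperature(gappy, 0, 3), "missing")
  ok <- h[-(1:7), ] # <10% missing: mean over available hours
  expect_equal(interval_mean_temperature(ok, 0, 3), 70)
})

test_that("the default model grid has 18 structures in deterministic order", {
  grid <- model_grid()
  expect_length(grid, 18)
  labs <- vapply(grid, format, character(1))
  expect_false(anyDuplicated(labs) > 0)
  # survival form varies slowest, growth form fastest
  expect_equal(grid[[1]]$survival_form, "constant")
  expect_equal(grid[[1]]$growth_form, "constant")
  expect_equal(grid[[2]]$growth_form, "date")
  expect_equal(grid[[7]]$survival_form, "date")
  expect_length(model_grid("constant", "full_stage", "constant"), 1)
  expect_length(model_grid(c("constant", "date"),
                           c("full_stage", "early_grouped"),
                           c("constant", "date")), 8)
  expect_error(model_grid(character(0)), "non-empty")
})
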