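# Forward-algorithm likelihood vs exhaustive path enumeration, and the
# dataset deviance.

test_that("deterministic kernels give certain histories probability one", {
  kern <- deterministic_kernels()
  expect_equal(loglik_history(c("L1", "L1", "L1"), kern$px, kern$po), 0)
  expect_equal(brute_force_loglik(c("L1", "L1", "L1"), kern$px, kern$po), 0)
  # a missed detection is impossible when detection is certain
  expect_identical(loglik_history(c("L1", "NS"), kern$px, kern$po), -Inf)
  expect_identical(brute_force_loglik(c("L1", "NS"), kern$px, kern$po),
                   -Inf)
  # single detection: conditioning leaves an empty product
  expect_equal(loglik_history("L3", kern$px, kern$po), 0)
  expect_equal(brute_force_loglik("L3", kern$px, kern$po), 0)
})

test_that("history validation rejects detection-free or corpse-first input", {
  kern <- deterministic_kernels()
  expect_error(loglik_history(c("NS", "NS"), kern$px, kern$po),
               "no detection")
  expect_error(loglik_history(c("NS", "D2"), kern$px, kern$po), "live")
  expect_error(loglik_history(c("L1", "L6"), kern$px, kern$po), "unknown")
  expect_error(brute_force_loglik(rep("L1", 8), kern$px, kern$po),
               "at most 6")
})

test_that("forward equals brute force within 1e-12 over random draws", {
  set.seed(404)
  worst <- 0
  for (i in 1:100) {
    pars <- random_parameters()
    vr <- assemble_vital_rates(pars)
    px <- build_transition_matrix(vr,
                                  if (i %% 2) "growth" else "stay")
    po <- build_observation_matrix(
      detection_params(pars$p_live, pars$p_dead))
    len <- sample(2:5, 1)
    h <- c(sample(c("E", paste0("L", 1:5)), 1),
           sample(CATS <- c("NS", "E", paste0("L", 1:5), "P",
                            paste0("D", 1:5)), len - 1, replace = TRUE))
    f <- loglik_history(h, px, po)
    b <- brute_force_loglik(h, px, po)
    if (is.finite(f) || is.finite(b)) {
      expect_equal(is.finite(f), is.finite(b))
      if (is.finite(f)) worst <- max(worst, abs(f - b))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("forward handles per-occasion kernels and matches enumeration", {
  set.seed(77)
  po <- build_observation_matrix(
    detection_params(c(runif(6), 0), c(0, runif(5), 0)))
  pxl <- lapply(1:4, function(i)
    build_transition_matrix(random_vital_rates()))
  h <- c("L1", "NS", "L2", "NS", "D4")
  f <- loglik_history(h, pxl, po)
  b <- brute_force_loglik(h, pxl, po)
  expect_equal(f, b, tolerance = 1e-13)
})

test_that("summing over all categories at one occasion marginalizes it out", {
  set.seed(55)
  pars <- random_parameters()
  px <- build_transition_matrix(assemble_vital_rates(pars))
  po <- build_observation_matrix(
    detection_params(pars$p_live, pars$p_dead))
  h <- c("L2", "NS", "L3", "NS")
  # replace the final occasion by each category and sum the likelihoods
  all_cats <- stage_space()$categories
  tot <- sum(vapply(all_cats, function(cat) {
    h2 <- c(h[1:3], cat)
    exp(loglik_history(h2, px, po))
  }, numeric(1)))
  expect_equal(log(tot), loglik_history(h[1:3], px, po),
               tolerance = 1e-12)
})

test_that("log-domain scaling survives 9-occasion near-impossible histories", {
  pars <- example_parameters()
  pars$p_live[2] <- 1e-40 # each I1 detection has probability 1e-40
  pars$b0[] <- 40         # survival certain to double precision
  pars$a0[] <- -40        # stasis certain to double precision
  px <- build_transition_matrix(assemble_vital_rates(pars))
  po <- build_observation_matrix(detection_params(pars$p_live, pars$p_dead))
  h <- rep("L1", 9) # eight more detections at 1e-40 each: p = 1e-320
  ll <- loglik_history(h, px, po)
  expect_true(is.finite(ll))
  expect_equal(ll, 8 * log(1e-40), tolerance = 1e-9)
  # the C++ path agrees
  enc <- data.frame(individual_id = "a", plot_id = 1, plant_id = 1,
                    occasion = 1:9, day = seq(0, 24, by = 3),
                    category = "L1", length_mm = NA)
  dev <- dataset_deviance(pars, enc)
  expect_equal(dev, -2 * ll, tolerance = 1e-9)
})

test_that("dataset deviance is additive and minimal near the truth", {
  cohort <- small_cohort(seed = 5, n = 80, predation_slope = 0)
  cfg <- cohort$config
  enc <- prepare_data(cohort$encounters, cfg$structure,
                      death_partition = "stay")
  dev <- dataset_deviance(cfg$params, enc)
  expect_gt(dev, 0)
  # two identical individuals: deviance doubles
  one <- cohort$encounters[cohort$encounters$individual_id ==
                             cohort$encounters$individual_id[1], ]
  two <- one
  two$individual_id <- "copy"
  d1 <- dataset_deviance(cfg$params,
                         prepare_data(one, cfg$structure,
                                      death_partition = "stay"))
  d2 <- dataset_deviance(cfg$params,
                         prepare_data(rbind(one, two), cfg$structure,
                                      death_partition = "stay"))
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
  # certain-outcome dataset has deviance zero
  kernhist <- data.frame(individual_id = "a", plot_id = 1, plant_id = 1,
                         occasion = 1:3, day = c(0, 3, 6),
                         category = c("L1", "L1", "L1"), length_mm = NA)
  p_sure <- example_parameters()
  p_sure$b0[] <- 40; p_sure$a0[] <- -40
  p_sure$p_live <- c(0, 1, 1, 1, 1, 1, 0)
  p_sure$hatch <- 1e-9; p_sure$pupation <- 1e-9
  expect_equal(dataset_deviance(p_sure, kernhist), 0, tolerance = 1e-6)
})

test_that("deviance at the truth beats strongly perturbed parameters", {
  # Monte Carlo likelihood-dominance: in most replicates the generating
  # parameters fit better than a far-off alternative
  set.seed(606)
  wins <- 0
  n_rep <- 30
  for (r in 1:n_rep) {
    cohort <- simulate_cohort(
      cohort_config(n_individuals = 50, predation_slope = 0,
                    seed = 9000 + r))
    enc <- prepare_data(cohort$encounters, cohort$config$structure,
                        death_partition = "stay")
    truth <- cohort$config$params
    off <- truth
    off$b0[] <- truth$b0 - 2.5
    off$p_live[2:6] <- pmax(0.05, truth$p_live[2:6] - 0.55)
    wins <- wins + (dataset_deviance(truth, enc) <=
                      dataset_deviance(off, enc))
  }
  expect_gte(wins / n_rep, 0.95)
})
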