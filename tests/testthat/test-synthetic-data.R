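# The cohort generator: survey design, latent dynamics, observation
# process, and retained truth.

test_that("deterministic config yields full detection in the arrival stage", {
  st <- model_structure("constant", "early_grouped", "constant")
  pars <- default_true_parameters(st)
  pars$b0[] <- 40                     # certain survival
  pars$a0[] <- -40                    # certain stasis
  pars$hatch <- 1e-12; pars$pupation <- 1e-12
  pars$p_live <- c(1, 1, 1, 1, 1, 1, 0)
  pars$p_dead <- rep(0, 7)
  co <- simulate_cohort(cohort_config(n_individuals = 40, structure = st,
                                      params = pars, predation_slope = 0,
                                      seed = 2))
  enc <- co$encounters
  # every individual is seen as an egg at every surveyed occasion
  expect_true(all(enc$category == "E"))
  first <- tapply(enc$occasion, enc$individual_id, min)
  truth_first <- co$truth$first_occ
  names(truth_first) <- sprintf("ind%04d", seq_along(truth_first))
  surveyed <- !is.na(truth_first)
  expect_equal(sort(names(first)), sort(names(truth_first[surveyed])))
})

test_that("zero detection yields an empty encounter table with a warning", {
  st <- model_structure("constant", "early_grouped", "constant")
  pars <- default_true_parameters(st)
  pars$p_live <- rep(0, 7)
  pars$p_dead <- rep(0, 7)
  expect_warning(
    co <- simulate_cohort(cohort_config(n_individuals = 30, structure = st,
                                        params = pars, seed = 3)),
    "detected alive"
  )
  expect_equal(nrow(co$encounters), 0)
})

test_that("seeded generation is reproducible and respects the design", {
  cfg <- cohort_config(n_individuals = 80, seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$encounters, c2$encounters)
  expect_identical(c1$truth$states, c2$truth$states)
  # survey design: 14 plots x 9 occasions on a 3-day rotation with
  # staggered 0/1/2-day offsets
  sch <- c1$schedule
  expect_equal(nrow(sch), 14 * 9)
  expect_true(all(tapply(sch$day, sch$plot_id, function(d) all(diff(d) == 3))))
  expect_setequal(unique(sch$day %% 3), 0:2)
  # encounter days match the plot schedule
  key <- paste(sch$plot_id, sch$occasion)
  expect_equal(c1$encounters$day,
               sch$day[match(paste(c1$encounters$plot_id,
                                   c1$encounters$occasion), key)])
})

test_that("latent paths obey the transition mask and absorb at death", {
  co <- simulate_cohort(cohort_config(n_individuals = 300, seed = 19))
  st <- co$truth$states
  mask <- instarhmm:::growth_mask()
  for (k in seq_len(nrow(st))) {
    path <- st[k, st[k, ] > 0]
    if (length(path) < 2) next
    for (t in seq_len(length(path) - 1)) {
      a <- path[t]; b <- path[t + 1]
      if (a <= 7) {
        # live: next is live or newly dead, within the growth mask
        stage_a <- a
        stage_b <- if (b <= 7) b else b - 7
        expect_true(b <= 14)
        expect_true(mask[stage_b, stage_a] ||
                      (b > 7 && stage_b == stage_a))
      } else if (a <= 14) {
        expect_equal(b, 15) # newly dead -> absorbing in one step
      } else {
        expect_equal(b, 15) # absorbing stays absorbing
      }
    }
  }
})

test_that("realized transition frequencies match phi x psi products", {
  # large cohort with certain detection: empirical one-step frequencies
  # from live instars match the generating kernel within Monte Carlo error
  st <- model_structure("constant", "early_grouped", "constant")
  pars <- default_true_parameters(st)
  pars$p_live <- c(1, 1, 1, 1, 1, 1, 0)
  pars$p_dead <- c(0, 1, 1, 1, 1, 1, 0)
  cfg <- cohort_config(n_individuals = 5000, structure = st, params = pars,
                       predation_slope = 0, death_partition = "stay",
                       seed = 8)
  co <- simulate_cohort(cfg)
  states <- co$truth$states
  px <- build_transition_matrix(
    assemble_vital_rates(pars, st), "stay")
  from <- as.vector(states[, -ncol(states)])
  to <- as.vector(states[, -1])
  ok <- from > 0 & to > 0
  from <- from[ok]; to <- to[ok]
  for (s in 2:6) { # instars I1..I5
    n_s <- sum(from == s)
    if (n_s < 200) next
    emp <- tabulate(to[from == s], 15) / n_s
    the <- px[, s]
    tol <- 3 * sqrt(pmax(the * (1 - the), 1e-6) / n_s)
    expect_true(all(abs(emp - the) < pmax(tol, 0.02)))
  }
})

test_that("the realized abundance curve is a pulse (rises then falls)", {
  co <- simulate_cohort(cohort_config(seed = 29))
  ab <- abundance_series(co$encounters)
  peak <- which.max(ab$live)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(ab))
  expect_gt(max(ab$live), 2 * ab$live[1])
  expect_gt(max(ab$live), 2 * ab$live[nrow(ab)])
  # dead-category detections exist but are a small minority
  frac_dead <- sum(ab$corpses) / sum(ab$live)
  expect_gt(frac_dead, 0)
  expect_lt(frac_dead, 0.2)
})

test_that("temperature series has the configured trend and periodicity", {
  cfg <- cohort_config(temp_noise_sd = 0, temp_rise = 20,
                       temp_season_days = 30, seed = 1)
  h <- generate_temperature_series(cfg)
  expect_equal(nrow(h), 30 * 24)
  # zero noise, zero trend: all 3-day means equal
  cfg0 <- cohort_config(temp_noise_sd = 0, temp_rise = 0, seed = 1)
  h0 <- generate_temperature_series(cfg0)
  m0 <- vapply(seq(0, 27, by = 3), function(d)
    interval_mean_temperature(h0, d, d + 3), numeric(1))
  expect_lt(max(m0) - min(m0), 1e-9)
  # 20-unit rise over 30 days: last minus first 3-day mean is 20 * 27/30
  m <- vapply(c(0, 27), function(d)
    interval_mean_temperature(h, d, d + 3), numeric(1))
  expect_equal(m[2] - m[1], 20 * 27 / 30, tolerance = 1e-9)
  # seeded reproducibility with noise
  cfgn <- cohort_config(seed = 4)
  expect_identical(generate_temperature_series(cfgn),
                   generate_temperature_series(cfgn))
})

test_that("plot-occasion temperature covariates align with the schedule", {
  cfg <- cohort_config(temp_noise_sd = 0, seed = 1)
  co <- simulate_cohort(cfg)
  tt <- co$temperature
  expect_equal(nrow(tt), 14 * 9)
  # recompute one cell independently
  sch <- co$schedule
  d <- sch$day[sch$plot_id == 5 & sch$occasion == 4]
  expect_equal(tt$mean_temp[tt$plot_id == 5 & tt$occasion == 4],
               interval_mean_temperature(co$hourly_temperature, d, d + 3))
})
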