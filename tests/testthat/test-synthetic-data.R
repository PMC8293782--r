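test_that("identical config and seed give bit-identical simulations", {
  cfg <- trial_sim_config(trial_duration = 6300, seed = 7)
  s1 <- simulate_trial_trace(cfg)
  s2 <- simulate_trial_trace(cfg)
  expect_identical(s1, s2)

  co1 <- simulate_cohort(cohort_sim_config(seed = 7))
  co2 <- simulate_cohort(cohort_sim_config(seed = 7))
  expect_identical(co1, co2)

  # different seed, different data
  s3 <- simulate_trial_trace(trial_sim_config(trial_duration = 6300, seed = 8))
  expect_false(identical(s1$trace$o2_mg_per_l, s3$trace$o2_mg_per_l))
})

test_that("seed is mandatory and config invariants are enforced", {
  expect_error(trial_sim_config(), "seed")
  expect_error(cohort_sim_config(), "seed")
  expect_error(trial_sim_config(fish_mass = 3000, chamber_volume = 2, seed = 1),
               "effective volume")
  expect_error(trial_sim_config(activity_multiplier = 0.5, seed = 1))
  expect_error(trial_sim_config(trial_duration = 1000, seed = 1), "5 loops")
})

test_that("noise-free trace yields the configured mass-specific MO2 in every loop", {
  cfg <- clean_trial_cfg(true_smr = 100, fish_mass = 100, chamber_volume = 2)
  sim <- simulate_trial_trace(cfg)
  fits <- fit_phase_slopes(sim$trace)
  m <- compute_mo2(fits, 2, 100)
  expect_equal(m$mo2_raw / 0.1, rep(100, nrow(m)), tolerance = 1e-12)
  expect_equal(fits$r_squared, rep(1, nrow(fits)))
  # truth record agrees
  expect_equal(sim$truth$mo2_true, rep(100, nrow(sim$truth)))
})

test_that("without bouts and drift the SMR statistic equals the all-loop mean", {
  cfg <- clean_trial_cfg(background_mo2_start = 0.2, seed = 3)
  sim <- simulate_trial_trace(cfg)
  fits <- fit_phase_slopes(sim$trace)
  m <- compute_mo2(fits, cfg$chamber_volume, cfg$fish_mass)
  bg <- fit_background_model(data.frame(chamber_id = "C1",
                                        time_s = c(0, 90000),
                                        mo2_raw = 0.2, r_squared = 1))
  m <- apply_background_correction(m, bg, cfg$fish_mass)
  res <- compute_smr(m)
  expect_equal(res$smr, mean(m$mo2_mass_specific), tolerance = 1e-9)
})

test_that("activity bouts hit the expected fraction of loops", {
  cfg <- trial_sim_config(seed = 1) # defaults: full-length trial
  sim <- simulate_trial_trace(cfg)
  # direct counting from the returned bout schedule must match the truth flags
  lp <- cfg$loop
  L <- loop_length(lp)
  n_loops <- nrow(sim$truth)
  overlap <- vapply(seq_len(n_loops), function(i) {
    ts <- seq((i - 1) * L + lp$flush_s + lp$wait_s, i * L - 1)
    hit <- FALSE
    for (k in seq_len(nrow(sim$bouts))) {
      hit <- hit || any(ts >= sim$bouts[k, "start"] & ts < sim$bouts[k, "end"])
    }
    hit
  }, logical(1))
  expect_identical(overlap, sim$truth$bout_fraction > 0)
  # Poisson-process expectation: a loop's measure window (length m) is
  # missed only if no bout starts within (start - d, end)
  p_hit <- 1 - exp(-cfg$activity_bout_rate *
                     (cfg$bout_duration_s + lp$measure_s) / 3600)
  obs <- mean(overlap)
  tol <- 4 * sqrt(p_hit * (1 - p_hit) / n_loops)
  expect_lt(abs(obs - p_hit), tol)
})

test_that("background segments reflect only chamber respiration", {
  # zero background: flat trace (no noise)
  cfg0 <- clean_trial_cfg()
  bg0 <- simulate_background_trace(cfg0, "pre")
  expect_equal(var(bg0$trace$o2_mg_per_l), 0, tolerance = 1e-20)

  # 0.5 mg O2/hr in 2 L: measured slope -0.25 mg/L/hr
  cfg <- clean_trial_cfg(background_mo2_start = 0.5, chamber_volume = 2,
                         fish_mass = 100)
  # fish volume must not enter background conversion (blank chamber)
  bg <- simulate_background_trace(cfg, "pre")
  f <- fit_phase_slopes(bg$trace, loop_spec(measure_s = 900))
  expect_equal(f$slope, rep(-0.25, nrow(f)), tolerance = 1e-9)
  m <- compute_mo2(f, 2, fish_mass = 0)
  expect_equal(m$mo2_raw, rep(0.5, nrow(m)), tolerance = 1e-9)

  # drifting background: the post-trial fit exceeds the pre-trial fit
  cfgd <- clean_trial_cfg(background_mo2_start = 0.2,
                          background_mo2_slope = 0.05, trial_duration = 71000)
  pre <- fit_phase_slopes(simulate_background_trace(cfgd, "pre")$trace,
                          loop_spec(measure_s = 900))
  post <- fit_phase_slopes(simulate_background_trace(cfgd, "post")$trace,
                           loop_spec(measure_s = 900))
  expect_gt(mean(-post$slope), mean(-pre$slope))
})

test_that("noiseless cohort recovers the configured TDF models exactly", {
  cfg <- cohort_sim_config(
    smr_allometry = list(intercept = 125.8, exponent = -0.179,
                         pelagic_offset = 10, residual_sd = 8),
    muscle_d13c_tdf_model = list(intercept = 6.2, slope = -0.035, residual_sd = 0),
    muscle_d15n_tdf_model = list(intercept = -1.6, slope = 0.043, residual_sd = 0),
    isotope_measurement_sd = c(d13c = 0, d15n = 0),
    muscle_cn_sd = 0, liver_cn_sd = 0,
    seed = 11)
  co <- simulate_cohort(cfg)
  muscle <- co$tissue[co$tissue$tissue == "muscle", ]
  tdf <- muscle$d13c - co$diet$mean_d13c
  fit <- fit_regression(tdf, co$truth$true_smr)
  expect_equal(fit$slope, -0.035, tolerance = 1e-10)
  expect_equal(fit$intercept, 6.2, tolerance = 1e-8)
  tdf_n <- muscle$d15n - co$diet$mean_d15n
  fit_n <- fit_regression(tdf_n, co$truth$true_smr)
  expect_equal(fit_n$slope, 0.043, tolerance = 1e-10)
})

test_that("liver TDF is independent of SMR by construction", {
  groups <- default_cohort_groups()
  groups$n <- rep(60L, 5)
  co <- simulate_cohort(cohort_sim_config(groups = groups, seed = 5))
  liver <- co$truth$liver_d13c_tdf
  fit <- fit_regression(liver, co$truth$true_smr)
  expect_lt(abs(fit$slope), 3 * fit$se_slope)
})

test_that("simulated group SMR means track the configured allometric means", {
  groups <- default_cohort_groups()
  groups$n <- rep(60L, 5)
  cfg <- cohort_sim_config(groups = groups, seed = 2)
  co <- simulate_cohort(cfg)
  se <- cfg$smr_allometry$residual_sd / sqrt(60)
  # 3 SE: five group means are checked simultaneously
  for (g in groups$group) {
    obs <- mean(co$truth$true_smr[co$truth$group == g])
    expect_lt(abs(obs - co$group_smr_mean[[g]]), 3 * se)
  }
})

test_that("lipid distortion only depletes 13C in liver", {
  for (seed in 1:5) {
    co <- simulate_cohort(cohort_sim_config(
      seed = seed, isotope_measurement_sd = c(d13c = 0, d15n = 0)))
    liver <- co$tissue[co$tissue$tissue == "liver", ]
    expect_true(all(liver$d13c <= co$truth$liver_d13c_lipid_free + 1e-12))
  }
})
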