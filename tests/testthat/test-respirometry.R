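test_that("loop segmentation finds every complete measurement phase", {
  cfg <- trial_sim_config(seed = 1) # 71000 s, 420 s loops
  sim <- simulate_trial_trace(cfg)
  meas <- segment_loops(sim$trace)
  expect_equal(length(unique(meas$loop_index)), 169) # floor(71000 / 420)
  expect_equal(unique(table(meas$loop_index)), 210) # one sample per second

  # trace shorter than one loop: empty result with a warning
  short <- sim$trace[sim$trace$time_s < 150, ]
  expect_warning(out <- segment_loops(short), "no measurement")
  expect_equal(nrow(out), 0)
})

test_that("schedule inference reproduces the labeled segmentation", {
  cfg <- trial_sim_config(trial_duration = 6300, seed = 4)
  sim <- simulate_trial_trace(cfg)
  labeled <- segment_loops(sim$trace)
  unlabeled <- sim$trace[, c("time_s", "o2_mg_per_l")]
  inferred <- segment_loops(unlabeled, cfg$loop)
  expect_equal(inferred$time_s, labeled$time_s)
  expect_equal(inferred$loop_index, labeled$loop_index)

  # irregular unlabeled sampling defeats inference
  irregular <- unlabeled[sort(sample(nrow(unlabeled), 500)), ]
  expect_error(segment_loops(irregular, cfg$loop), "irregular")
})

test_that("phase slope fitting matches a normal-equations oracle", {
  # exact line: o2 = 9.0 - 0.5 mg/L/hr
  t <- 0:209
  seg <- data.frame(time_s = t, o2_mg_per_l = 9.0 - (0.5 / 3600) * t)
  f <- fit_phase_slope(seg)
  expect_equal(f$slope, -0.5, tolerance = 1e-9)
  expect_equal(f$r_squared, 1)

  # constant O2 is a degenerate fit by definition: slope 0, R^2 0
  f0 <- fit_phase_slope(data.frame(time_s = t, o2_mg_per_l = rep(9, 210)))
  expect_equal(f0$slope, 0)
  expect_equal(f0$r_squared, 0)

  # noisy points against the independent OLS oracle
  set.seed(42)
  tt <- seq(0, 245, by = 5)[1:50]
  y <- 8.7 - 1.2e-4 * tt + rnorm(50, 0, 0.01)
  f2 <- fit_phase_slope(data.frame(time_s = tt, o2_mg_per_l = y))
  oracle <- ols_oracle(tt / 3600, y)
  expect_equal(f2$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(f2$r_squared, oracle$r_squared, tolerance = 1e-10)

  expect_error(fit_phase_slope(seg[1:2, ]), "3 points")
})

test_that("MO2 conversion uses the effective (chamber minus fish) volume", {
  f <- data.frame(slope = -1.0, mid_time_s = 100, r_squared = 1, n_points = 10)
  expect_equal(compute_mo2(f, 2.0, 100)$mo2_raw, 1.9)
  f$slope <- 0
  expect_equal(compute_mo2(f, 2.0, 100)$mo2_raw, 0)
  f$slope <- -0.25
  expect_equal(compute_mo2(f, 2.0, 0)$mo2_raw, 0.5) # blank chamber
  f$chamber_id <- "C9"
  expect_error(compute_mo2(f, 0.1, 200), "C9")
})

test_that("background model pools chambers, filters on R^2, and interpolates", {
  # constant background
  bf <- data.frame(chamber_id = "C1", time_s = c(0, 3600, 86400),
                   mo2_raw = 0.5, r_squared = 1)
  m <- fit_background_model(bf)
  expect_equal(m$C1$intercept, 0.5, tolerance = 1e-12)
  expect_equal(m$C1$slope, 0, tolerance = 1e-12)

  # two points define the line: value at 12 h is the midpoint
  bf2 <- data.frame(chamber_id = "C1", time_s = c(0, 24 * 3600),
                    mo2_raw = c(0.2, 0.8), r_squared = 1)
  m2 <- fit_background_model(bf2)
  expect_equal(predict_background(m2, "C1", 12 * 3600), 0.5, tolerance = 1e-12)
  expect_error(predict_background(m2, "C2", 0), "C2")

  # the R^2 > 0.1 inclusion rule is strict, per chamber
  bf3 <- data.frame(chamber_id = "C1", time_s = c(0, 3600, 7200, 10800),
                    mo2_raw = c(0.2, 9.9, 0.3, 0.4),
                    r_squared = c(0.9, 0.05, 0.9, 0.1))
  m3 <- fit_background_model(bf3, r2_min = 0.1)
  expect_equal(m3$C1$n_used, 2) # the 0.05 and the boundary 0.1 fit drop out
  expect_equal(m3$C1$n_excluded, 2)

  # single survivor falls back to its mean; none -> zero with warning
  bf4 <- data.frame(chamber_id = "C1", time_s = c(0, 3600),
                    mo2_raw = c(0.7, 5), r_squared = c(0.8, 0.01))
  expect_equal(fit_background_model(bf4)$C1$intercept, 0.7)
  bf5 <- data.frame(chamber_id = "C1", time_s = 0, mo2_raw = 5, r_squared = 0.01)
  expect_warning(m5 <- fit_background_model(bf5), "zero background")
  expect_equal(m5$C1$intercept, 0)
})

test_that("background drift is recovered within 2 SE from simulated blanks", {
  cfg <- trial_sim_config(background_mo2_start = 0.3,
                          background_mo2_slope = 0.02,
                          chamber_volume = 1.0, seed = 9)
  fits <- list()
  for (i in 1:10) {
    c_i <- cfg
    c_i$trial_start_s <- (i - 1) * 90000
    c_i$seed <- i
    class(c_i) <- class(cfg)
    for (when in c("pre", "post")) {
      f <- fit_phase_slopes(simulate_background_trace(c_i, when)$trace,
                            loop_spec(measure_s = 900))
      f$chamber_id <- "C1"
      fits[[length(fits) + 1]] <- compute_mo2(f, 1.0, 0)
    }
  }
  bf <- do.call(rbind, fits)
  m <- fit_background_model(bf[, c("chamber_id", "time_s", "mo2_raw", "r_squared")])
  oracle <- ols_oracle(bf$time_s / 3600, bf$mo2_raw)
  expect_equal(m$C1$slope, oracle$slope, tolerance = 1e-9)
  expect_lt(abs(m$C1$slope - 0.02), 2 * oracle$se_slope + 1e-9)
})

test_that("background correction is exact in expectation and flags negatives", {
  # zero background model: corrected == raw
  zero <- fit_background_model(data.frame(chamber_id = "C1",
                                          time_s = c(0, 3600),
                                          mo2_raw = 0, r_squared = 1))
  meas <- data.frame(chamber_id = "C1", time_s = 500, loop_index = 1,
                     mo2_raw = 1.9, r_squared = 1)
  out <- apply_background_correction(meas, zero, 100)
  expect_equal(out$mo2_corrected, 1.9)

  # raw 1.9, background 0.4, 100 g fish -> 15 mg/kg/hr
  m04 <- fit_background_model(data.frame(chamber_id = "C1",
                                         time_s = c(0, 3600),
                                         mo2_raw = 0.4, r_squared = 1))
  out2 <- apply_background_correction(meas, m04, 100)
  expect_equal(out2$mo2_mass_specific, 15)
  expect_true(out2$retained)

  # over-correction is excluded, not clamped
  meas$mo2_raw <- 0.3
  out3 <- apply_background_correction(meas, m04, 100)
  expect_false(out3$retained)
  expect_equal(out3$reason, "nonpositive_after_correction")

  # simulated drifting trial: corrected loop MO2 tracks the truth below the
  # per-loop noise floor
  cfg <- trial_sim_config(background_mo2_start = 0.3,
                          background_mo2_slope = 0.02,
                          activity_bout_rate = 0, seed = 13)
  sim <- simulate_trial_trace(cfg)
  fits <- fit_phase_slopes(sim$trace)
  mm <- compute_mo2(fits, cfg$chamber_volume, cfg$fish_mass)
  bgf <- do.call(rbind, lapply(c("pre", "post"), function(w) {
    f <- fit_phase_slopes(simulate_background_trace(cfg, w)$trace,
                          loop_spec(measure_s = 900))
    compute_mo2(f, cfg$chamber_volume, 0)
  }))
  bgf$chamber_id <- "C1"
  bg <- fit_background_model(bgf[, c("chamber_id", "time_s", "mo2_raw", "r_squared")])
  mm$chamber_id <- "C1"
  mm <- apply_background_correction(mm, bg, cfg$fish_mass)
  mae <- mean(abs(mm$mo2_mass_specific - sim$truth$mo2_true))
  # per-loop slope-error SD from the sensor noise, propagated to mg/kg/hr
  t <- seq(0, cfg$loop$measure_s - 1)
  se_slope_hr <- cfg$sensor_noise_sd / sqrt(sum((t - mean(t))^2)) * 3600
  noise_floor <- se_slope_hr * (cfg$chamber_volume - cfg$fish_mass / 1000) /
    (cfg$fish_mass / 1000)
  expect_lt(mae, noise_floor)
})

test_that("SMR is the mean of the lowest decile with the floor-plus-min rule", {
  res <- compute_smr(measures_fixture(1:20))
  expect_equal(res$smr, 1.5) # k = 2
  expect_equal(res$n_lowest_used, 2)

  res5 <- compute_smr(measures_fixture(c(5, 3, 9, 4, 7)))
  expect_equal(res5$smr, 3) # k = max(1, floor(0.5)) = 1 -> min
  expect_lte(res5$smr, mean(c(5, 3, 9, 4, 7)))

  set.seed(99)
  vals <- rlnorm(500, 3, 0.4)
  res500 <- compute_smr(measures_fixture(vals))
  expect_identical(res500$smr, smr_oracle(vals, 0.10))
})

test_that("SMR filtering rules behave monotonically", {
  set.seed(7)
  vals <- runif(20, 50, 150) # n fixed at 20 -> k = 2 before and after adding
  base <- compute_smr(measures_fixture(vals))
  kth <- sort(vals)[base$n_lowest_used]
  # adding a value above the k-th smallest (n 20 -> 21 keeps k = 2)
  up <- compute_smr(measures_fixture(c(vals, kth + 10)))
  expect_identical(up$smr, base$smr)
  # adding a value below the minimum never increases SMR
  dn <- compute_smr(measures_fixture(c(vals, min(vals) - 5)))
  expect_lte(dn$smr, base$smr)

  # raising the R^2 threshold never increases the number retained
  r2 <- seq(0.90, 1.0, length.out = 20)
  m <- measures_fixture(vals, r_squared = r2)
  n_ret <- vapply(c(0.90, 0.95, 0.99),
                  function(th) compute_smr(m, r2_threshold = th)$n_retained, 0)
  expect_true(all(diff(n_ret) <= 0))

  # nothing retained is an error that reports the exclusion tally
  expect_error(compute_smr(measures_fixture(vals, r_squared = 0.5)),
               "low_r_squared = 20")
})

test_that("noise-free trials with background drift recover true SMR exactly", {
  cfg <- clean_trial_cfg(background_mo2_start = 0.3,
                         background_mo2_slope = 0.02,
                         trial_duration = 71000, true_smr = 85,
                         fish_mass = 120, chamber_volume = 2)
  sim <- simulate_trial_trace(cfg)
  fish <- data.frame(fish_id = "F1", trial_id = cfg$trial_id,
                     chamber_id = cfg$chamber_id, final_mass_g = cfg$fish_mass)
  chambers <- data.frame(chamber_id = "C1", volume_l = 2)
  bg <- rbind(simulate_background_trace(cfg, "pre")$trace,
              simulate_background_trace(cfg, "post")$trace)
  res <- process_respirometry(sim$trace, bg, fish, chambers)
  expect_lt(abs(res$smr$smr - 85) / 85, 1e-6)
})
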