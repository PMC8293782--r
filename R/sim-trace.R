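# Trace simulation.
#
# Within a sealed (wait + measure) period the O2 concentration is generated
# by left-Riemann integration of the instantaneous consumption rate, so a
# constant rate produces an exactly linear decline -- matching the linear
# fitting model used downstream. The flush phase relaxes the chamber
# exponentially back towards air saturation with a 30 s time constant.

FLUSH_TAU_S <- 30

background_mo2_at <- function(cfg, t_abs_s) {
  pmax(0, cfg$background_mo2_start +
         cfg$background_mo2_slope * t_abs_s / 3600)
}

#' Simulate one intermittent-flow respirometry trial
#'
#' Generates the oxygen trace of a single fish over repeating
#' flush/wait/measure loops, together with a ground-truth record of each
#' loop's noise-free mass-specific MO2 and the simulated activity-bout
#' schedule.
#'
#' During sealed phases O2 declines at rate (fish MO2 + chamber background
#' MO2) / effective volume; fish MO2 is `true_smr * mass` except inside
#' activity bouts, where it is multiplied by `activity_multiplier`. Bout
#' onsets follow a Poisson process in time with fixed bout duration.
#' Gaussian sensor noise is added to every sample.
#'
#' @param cfg A [trial_sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{trace}{data.frame: `trial_id`, `chamber_id`, `time_s` (absolute
#'       experiment time), `o2_mg_per_l`, `phase` (flush/wait/measure),
#'       `loop_index`.}
#'     \item{truth}{data.frame per complete loop: `loop_index`, `mid_time_s`
#'       (mean of measure-phase sample times), `mo2_true` (noise-free
#'       mass-specific fish MO2 averaged over the measure phase, mg O2
#'       kg^-1 hr^-1; total mg O2 hr^-1 when `fish_mass` is 0),
#'       `bout_fraction` (fraction of measure samples inside a bout),
#'       `background_mo2_true` (mg O2 hr^-1 at the phase midpoint).}
#'     \item{bouts}{two-column matrix of merged bout intervals, trial time s.}
#'   }
#' @export
#' @examples
#' cfg <- trial_sim_config(trial_duration = 4200, sensor_noise_sd = 0, seed = 1)
#' sim <- simulate_trial_trace(cfg)
#' head(sim$truth)
simulate_trial_trace <- function(cfg) {
  stopifnot(inherits(cfg, "trial_sim_config"))
  with_seed(cfg$seed, {
    lp <- cfg$loop
    L <- loop_length(lp)
    dt <- cfg$sample_interval_s
    n_loops <- floor(cfg$trial_duration / L)
    v_eff <- cfg$chamber_volume - cfg$fish_mass / 1000
    if (v_eff <= 0) stop("non-positive effective volume")
    mass_kg <- cfg$fish_mass / 1000

    # activity bout schedule (Poisson onsets, fixed duration, merged)
    n_bouts <- if (cfg$activity_bout_rate > 0) {
      stats::rpois(1, cfg$activity_bout_rate * cfg$trial_duration / 3600)
    } else 0L
    bouts <- if (n_bouts > 0) {
      starts <- sort(stats::runif(n_bouts, 0, cfg$trial_duration))
      merge_intervals(starts, starts + cfg$bout_duration_s)
    } else merge_intervals(numeric(0), numeric(0))

    rel <- seq(0, L - dt, by = dt)
    phase_rel <- ifelse(rel < lp$flush_s, "flush",
                        ifelse(rel < lp$flush_s + lp$wait_s, "wait", "measure"))
    flush_idx <- which(phase_rel == "flush")
    seal_idx <- which(phase_rel != "flush")
    measure_in_seal <- which(rel[seal_idx] >= lp$flush_s + lp$wait_s)

    n_per_loop <- length(rel)
    o2 <- numeric(n_loops * n_per_loop)
    truth <- data.frame(loop_index = seq_len(n_loops), mid_time_s = NA_real_,
                        mo2_true = NA_real_, bout_fraction = NA_real_,
                        background_mo2_true = NA_real_)
    o2_cur <- cfg$o2_saturation

    for (i in seq_len(n_loops)) {
      t0 <- (i - 1) * L
      t_trial <- t0 + rel
      t_abs <- cfg$trial_start_s + t_trial

      o2_loop <- numeric(n_per_loop)
      o2_loop[flush_idx] <- cfg$o2_saturation +
        (o2_cur - cfg$o2_saturation) * exp(-rel[flush_idx] / FLUSH_TAU_S)
      o2_entry <- cfg$o2_saturation +
        (o2_cur - cfg$o2_saturation) * exp(-lp$flush_s / FLUSH_TAU_S)

      ts <- t_trial[seal_idx]
      fish_rate <- if (mass_kg > 0) {
        cfg$true_smr * mass_kg *
          (1 + (cfg$activity_multiplier - 1) * in_intervals(ts, bouts))
      } else rep(0, length(ts))
      bg_rate <- background_mo2_at(cfg, cfg$trial_start_s + ts)
      drop_per_step <- (fish_rate + bg_rate) * dt / 3600 / v_eff
      o2_seal <- o2_entry - c(0, cumsum(drop_per_step[-length(drop_per_step)]))
      o2_loop[seal_idx] <- o2_seal
      o2_cur <- o2_entry - sum(drop_per_step)

      o2[((i - 1) * n_per_loop + 1):(i * n_per_loop)] <- o2_loop

      m <- measure_in_seal
      truth$mid_time_s[i] <- cfg$trial_start_s + mean(ts[m])
      truth$mo2_true[i] <- if (mass_kg > 0) {
        mean(fish_rate[m]) / mass_kg
      } else mean(bg_rate[m])
      truth$bout_fraction[i] <- mean(in_intervals(ts[m], bouts))
      truth$background_mo2_true[i] <- background_mo2_at(
        cfg, cfg$trial_start_s + mean(ts[m]))
    }

    if (cfg$sensor_noise_sd > 0) {
      o2 <- o2 + stats::rnorm(length(o2), 0, cfg$sensor_noise_sd)
    }

    trace <- data.frame(
      trial_id = cfg$trial_id,
      chamber_id = cfg$chamber_id,
      time_s = cfg$trial_start_s + rep((seq_len(n_loops) - 1) * L, each = n_per_loop) +
        rep(rel, n_loops),
      o2_mg_per_l = o2,
      phase = rep(phase_rel, n_loops),
      loop_index = rep(seq_len(n_loops), each = n_per_loop),
      stringsAsFactors = FALSE
    )
    truth$trial_id <- cfg$trial_id
    truth$chamber_id <- cfg$chamber_id
    list(trace = trace, truth = truth, bouts = bouts)
  })
}

#' Simulate a background (blank chamber) respirometry segment
#'
#' Background respiration of the empty system is measured directly before
#' and after each trial with loops using a 900 s measurement phase. This
#' simulates one such segment: the O2 decline reflects only the chamber's
#' drifting background respiration (no fish).
#'
#' @param cfg A [trial_sim_config()] for the associated trial; its
#'   background, chamber, noise, and timing fields are reused.
#' @param when `"pre"` (segment ends where the trial starts) or `"post"`
#'   (segment starts where the trial ends).
#' @param n_loops Number of background loops in the segment.
#' @param bg_loop Loop timing for background measurements.
#' @return As [simulate_trial_trace()]; `truth$mo2_true` holds the noise-free
#'   background MO2 in mg O2 hr^-1. `trial_id` is suffixed `_pre` / `_post`.
#' @export
simulate_background_trace <- function(cfg, when = c("pre", "post"),
                                      n_loops = 2,
                                      bg_loop = loop_spec(measure_s = 900)) {
  stopifnot(inherits(cfg, "trial_sim_config"), n_loops >= 1)
  when <- match.arg(when)
  L <- loop_length(bg_loop)
  start_s <- if (when == "pre") {
    cfg$trial_start_s - n_loops * L
  } else {
    cfg$trial_start_s + cfg$trial_duration
  }
  bg_cfg <- cfg
  bg_cfg$fish_mass <- 0
  bg_cfg$true_smr <- 1          # unused when fish_mass = 0; keep invariant happy
  bg_cfg$activity_bout_rate <- 0
  bg_cfg$loop <- bg_loop
  bg_cfg$trial_duration <- n_loops * L
  bg_cfg$trial_start_s <- start_s
  bg_cfg$trial_id <- paste0(cfg$trial_id, "_", when)
  bg_cfg$seed <- derive_seed(cfg$seed, if (when == "pre") 1L else 2L)
  class(bg_cfg) <- "trial_sim_config"
  # the >= 5 loop invariant applies to trials at construction time;
  # background segments are short by design
  simulate_trial_trace(bg_cfg)
}
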