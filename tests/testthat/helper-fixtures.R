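# Shared fixture builders. Everything is generated in code at test time.

# A short, clean trial: 15 loops, no noise, no bouts, no background.
clean_trial_cfg <- function(seed = 1, ...) {
  args <- list(trial_duration = 6300, sensor_noise_sd = 0,
               activity_bout_rate = 0, background_mo2_start = 0,
               background_mo2_slope = 0, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(trial_sim_config, args)
}

# Minimal MO2 measure table for compute_smr() unit tests.
measures_fixture <- function(values, r_squared = 1, retained = TRUE) {
  data.frame(loop_index = seq_along(values),
             mo2_mass_specific = values,
             r_squared = rep_len(r_squared, length(values)),
             retained = rep_len(retained, length(values)),
             reason = NA_character_)
}

# A reduced pipeline configuration: fewer fish, shorter trials. Used for
# behavioural pipeline tests; acceptance-level checks use the defaults.
small_pipeline_cfg <- function(seed, out_dir = NULL, ...) {
  groups <- default_cohort_groups()
  groups$n <- c(2L, 2L, 4L, 2L, 2L)
  pipeline_config(seed = seed, out_dir = out_dir,
                  cohort = cohort_sim_config(groups = groups, seed = seed),
                  trial_duration_s = 6300, bg_loops_per_segment = 1, ...)
}
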