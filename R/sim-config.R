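#' Flush/wait/measure loop specification
#'
#' Timing of one intermittent-flow respirometry loop. Defaults follow the
#' standard trial regime: a 180 s flush phase (chamber re-aerated), a 30 s
#' wait phase (sealed, excluded from fitting), and a 210 s measurement phase
#' whose linear O2 decline yields one MO2 estimate. Background loops use a
#' 900 s measurement phase (`loop_spec(measure_s = 900)`).
#'
#' @param flush_s Flush duration, seconds.
#' @param wait_s Wait duration, seconds.
#' @param measure_s Measurement duration, seconds (>= 30).
#' @return An object of class `loop_spec`.
#' @export
#' @examples
#' loop_spec()                 # trial loops, 420 s total
#' loop_spec(measure_s = 900)  # background loops
loop_spec <- function(flush_s = 180, wait_s = 30, measure_s = 210) {
  stopifnot(flush_s > 0, wait_s > 0, measure_s >= 30)
  structure(list(flush_s = flush_s, wait_s = wait_s, measure_s = measure_s),
            class = "loop_spec")
}

#' Total duration of one loop, seconds
#' @param spec A [loop_spec()].
#' @return Numeric scalar.
#' @export
loop_length <- function(spec) {
  stopifnot(inherits(spec, "loop_spec"))
  spec$flush_s + spec$wait_s + spec$measure_s
}

#' Configuration for one simulated respirometry trial
#'
#' Ground-truth parameters for a single fish in a single chamber. The
#' simulated fish consumes oxygen at `true_smr` (mass-specific), elevated by
#' `activity_multiplier` during randomly timed activity bouts (a Poisson
#' process in time with fixed bout duration); the chamber itself consumes
#' oxygen at a linearly drifting background rate. Effective water volume is
#' the chamber volume minus the fish volume at density 1 g cm^-3.
#'
#' @param true_smr True standard metabolic rate, mg O2 kg^-1 hr^-1.
#' @param fish_mass Fish wet mass, g.
#' @param chamber_volume Chamber volume, L (must exceed fish volume).
#' @param trial_duration Trial length, s. Default 71000 (~19 h 43 min).
#' @param loop A [loop_spec()].
#' @param activity_bout_rate Bout initiation rate, bouts hr^-1.
#' @param activity_multiplier Multiplicative MO2 elevation during bouts (>= 1).
#' @param bout_duration_s Fixed bout duration, s.
#' @param background_mo2_start Chamber background respiration at experiment
#'   time 0, mg O2 hr^-1.
#' @param background_mo2_slope Linear drift of background respiration,
#'   mg O2 hr^-1 per hour of experiment time.
#' @param o2_saturation Air-saturated O2 concentration, mg L^-1 (9.0 at 18 C).
#' @param sensor_noise_sd Gaussian optode noise SD, mg L^-1.
#' @param sample_interval_s Sampling interval, s.
#' @param trial_start_s Absolute experiment time at which the trial starts, s
#'   (background drift runs on absolute time).
#' @param trial_id,chamber_id Identifiers carried into the trace.
#' @param seed Integer RNG seed. Required: simulated data must be reproducible.
#' @return An object of class `trial_sim_config`.
#' @export
trial_sim_config <- function(true_smr = 100,
                             fish_mass = 100,
                             chamber_volume = 2.0,
                             trial_duration = 71000,
                             loop = loop_spec(),
                             activity_bout_rate = 1,
                             activity_multiplier = 2,
                             bout_duration_s = 600,
                             background_mo2_start = 0.3,
                             background_mo2_slope = 0.01,
                             o2_saturation = 9.0,
                             sensor_noise_sd = 0.01,
                             sample_interval_s = 1,
                             trial_start_s = 0,
                             trial_id = "T01",
                             chamber_id = "C1",
                             seed) {
  if (missing(seed)) stop("`seed` is required: simulated trials must be reproducible")
  stopifnot(true_smr > 0, fish_mass >= 0, activity_multiplier >= 1,
            activity_bout_rate >= 0, bout_duration_s > 0,
            sensor_noise_sd >= 0, o2_saturation > 0, sample_interval_s > 0)
  if (chamber_volume <= fish_mass / 1000) {
    stop("chamber_volume must exceed fish volume (fish density 1 g cm^-3): ",
         "effective volume would be non-positive")
  }
  stopifnot(inherits(loop, "loop_spec"))
  if (trial_duration < 5 * loop_length(loop)) {
    stop("trial_duration must cover at least 5 loops")
  }
  structure(list(true_smr = true_smr, fish_mass = fish_mass,
                 chamber_volume = chamber_volume,
                 trial_duration = trial_duration, loop = loop,
                 activity_bout_rate = activity_bout_rate,
                 activity_multiplier = activity_multiplier,
                 bout_duration_s = bout_duration_s,
                 background_mo2_start = background_mo2_start,
                 background_mo2_slope = background_mo2_slope,
                 o2_saturation = o2_saturation,
                 sensor_noise_sd = sensor_noise_sd,
                 sample_interval_s = sample_interval_s,
                 trial_start_s = trial_start_s,
                 trial_id = trial_id, chamber_id = chamber_id,
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

#' Default cohort group table
#'
#' Five experimental cells: weight class at the start of the feeding
#' experiment crossed with habitat of origin (the 20-30 g class occurs in
#' both littoral and pelagic form). Final-mass means/SDs are the observed
#' end-of-experiment values the generator reproduces; initial mass is the
#' weight-class average used for approximate percent weight change.
#'
#' @return A data.frame with one row per group.
#' @export
default_cohort_groups <- function() {
  data.frame(
    group = c("juv_littoral", "20-30_littoral", "20-30_pelagic",
              "30-40_pelagic", "40-50_littoral"),
    weight_class = c("<20", "20-30", "20-30", "30-40", "40-50"),
    habitat = c("littoral", "littoral", "pelagic", "pelagic", "littoral"),
    n = c(4L, 4L, 11L, 4L, 5L),
    initial_mass_g = c(4, 25, 25, 35, 45),
    final_mass_mean_g = c(16.6, 56.2, 57.7, 40.4, 54.4),
    final_mass_sd_g = c(1.0, 7.3, 11.0, 23.1, 21.2),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a simulated fish cohort
#'
#' Statistical ground truth for the isotope side of the pipeline. Per fish:
#' final mass is drawn around its group mean; true mass-specific SMR follows
#' an allometric model of the group's initial (weight-class) mass plus a
#' habitat offset and between-fish noise; muscle TDFs are linear in true SMR
#' (negative slope for delta-13C, positive for delta-15N); liver TDFs are
#' independent of SMR. Tissue delta values are reconstructed as diet mean +
#' TDF, liver delta-13C is lipid-distorted by the exact inverse of the
#' normalization model given the drawn C:N, and instrument error is added.
#'
#' @param groups Group table, see [default_cohort_groups()].
#' @param smr_allometry List: `intercept`, `exponent` of the power law on
#'   initial weight-class mass (g), `pelagic_offset` (mg O2 kg^-1 hr^-1)
#'   added for pelagic fish, `residual_sd` between-fish SD.
#' @param muscle_d13c_tdf_model,muscle_d15n_tdf_model Lists with `intercept`
#'   (permil), `slope` (permil per mg O2 kg^-1 hr^-1) and `residual_sd`.
#' @param liver_tdf List with `d13c_mean`, `d13c_sd`, `d15n_mean`, `d15n_sd`;
#'   liver TDFs have zero SMR slope by construction.
#' @param diet List: `d13c_mean`, `d13c_sd`, `d15n_mean`, `d15n_sd`,
#'   `cn_ratio` of the chironomid diet.
#' @param muscle_cn_mean,muscle_cn_sd,liver_cn_mean,liver_cn_sd Tissue C:N
#'   mass-ratio distributions.
#' @param isotope_measurement_sd Named vector `c(d13c = , d15n = )`, permil.
#' @param lipid_params A [lipid_norm_params()] used for the liver lipid
#'   distortion (inverse of normalization).
#' @param seed Integer RNG seed (required).
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(groups = default_cohort_groups(),
                              smr_allometry = list(intercept = 125.8,
                                                   exponent = -0.179,
                                                   pelagic_offset = 10,
                                                   residual_sd = 8),
                              muscle_d13c_tdf_model = list(intercept = 6.2,
                                                           slope = -0.035,
                                                           residual_sd = 0.25),
                              muscle_d15n_tdf_model = list(intercept = -1.6,
                                                           slope = 0.043,
                                                           residual_sd = 0.25),
                              liver_tdf = list(d13c_mean = 1.1, d13c_sd = 0.35,
                                               d15n_mean = 1.0, d15n_sd = 0.45),
                              diet = list(d13c_mean = -30.6, d13c_sd = 0.5,
                                          d15n_mean = 14.0, d15n_sd = 3.7,
                                          cn_ratio = 4.7),
                              muscle_cn_mean = 3.2, muscle_cn_sd = 0.01,
                              liver_cn_mean = 4.4, liver_cn_sd = 0.6,
                              isotope_measurement_sd = c(d13c = 0.2, d15n = 0.3),
                              lipid_params = lipid_norm_params(),
                              seed) {
  if (missing(seed)) stop("`seed` is required: simulated cohorts must be reproducible")
  stopifnot(is.data.frame(groups), all(groups$n >= 1),
            muscle_d13c_tdf_model$slope <= 0, muscle_d15n_tdf_model$slope >= 0,
            muscle_d13c_tdf_model$residual_sd >= 0,
            muscle_d15n_tdf_model$residual_sd >= 0,
            liver_tdf$d13c_sd >= 0, liver_tdf$d15n_sd >= 0,
            diet$d13c_sd >= 0, diet$d15n_sd >= 0,
            muscle_cn_sd >= 0, liver_cn_sd >= 0,
            all(isotope_measurement_sd >= 0))
  structure(list(groups = groups, smr_allometry = smr_allometry,
                 muscle_d13c_tdf_model = muscle_d13c_tdf_model,
                 muscle_d15n_tdf_model = muscle_d15n_tdf_model,
                 liver_tdf = liver_tdf, diet = diet,
                 muscle_cn_mean = muscle_cn_mean, muscle_cn_sd = muscle_cn_sd,
                 liver_cn_mean = liver_cn_mean, liver_cn_sd = liver_cn_sd,
                 isotope_measurement_sd = isotope_measurement_sd,
                 lipid_params = lipid_params,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}
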