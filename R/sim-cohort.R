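#' Simulate a fish cohort with known isotope/metabolism ground truth
#'
#' Draws a cohort according to a [cohort_sim_config()]: per-fish final mass,
#' true mass-specific SMR (allometric in the group's initial weight-class
#' mass, plus habitat offset and between-fish noise), muscle TDFs linear in
#' true SMR, liver TDFs independent of SMR. Tissue delta values are then
#' reconstructed forward: delta = diet mean + TDF; liver delta-13C is
#' lipid-distorted by the exact inverse of the C:N lipid-normalization model
#' (only when the drawn C:N exceeds the normalization threshold, mirroring
#' how normalization is gated downstream), and instrument error is added
#' last.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A list:
#'   \describe{
#'     \item{fish}{per-fish table: `fish_id`, `trial_id`, `group`,
#'       `weight_class`, `habitat`, `initial_mass_g` (group class mean),
#'       `final_mass_g`, `length_mm`.}
#'     \item{tissue}{long tissue-sample table: `fish_id`, `tissue`,
#'       `d13c`, `d15n`, `cn_ratio` (as measured, i.e. lipid-distorted and
#'       noisy).}
#'     \item{diet}{one-row diet summary (`mean_d13c`, `sd_d13c`,
#'       `mean_d15n`, `sd_d15n`, `cn_ratio`).}
#'     \item{truth}{latent values per fish: true SMR, true TDFs, lipid-free
#'       liver delta-13C, drawn C:N ratios, configured group SMR mean.}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(seed = 1))
#' head(cohort$truth)
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(cfg$seed, {
    g <- cfg$groups
    if (any(g$n < 1)) stop("n_per_group must be >= 1 for every group")
    idx <- rep(seq_len(nrow(g)), g$n)
    n <- length(idx)
    fish_id <- sprintf("F%02d", seq_len(n))

    al <- cfg$smr_allometry
    group_smr_mean <- al$intercept * g$initial_mass_g^al$exponent +
      ifelse(g$habitat == "pelagic", al$pelagic_offset, 0)

    # fish grew over the experiment: final mass is bounded below by the
    # group's initial (weight-class average) mass
    final_mass <- pmax(g$initial_mass_g[idx],
                       stats::rnorm(n, g$final_mass_mean_g[idx],
                                    g$final_mass_sd_g[idx]))
    true_smr <- pmax(10, group_smr_mean[idx] +
                       stats::rnorm(n, 0, al$residual_sd))

    m13 <- cfg$muscle_d13c_tdf_model
    m15 <- cfg$muscle_d15n_tdf_model
    muscle_d13c_tdf <- m13$intercept + m13$slope * true_smr +
      stats::rnorm(n, 0, m13$residual_sd)
    muscle_d15n_tdf <- m15$intercept + m15$slope * true_smr +
      stats::rnorm(n, 0, m15$residual_sd)
    liver_d13c_tdf <- stats::rnorm(n, cfg$liver_tdf$d13c_mean, cfg$liver_tdf$d13c_sd)
    liver_d15n_tdf <- stats::rnorm(n, cfg$liver_tdf$d15n_mean, cfg$liver_tdf$d15n_sd)

    muscle_cn <- pmax(2.9, stats::rnorm(n, cfg$muscle_cn_mean, cfg$muscle_cn_sd))
    liver_cn <- pmax(2.9, stats::rnorm(n, cfg$liver_cn_mean, cfg$liver_cn_sd))

    diet <- cfg$diet
    muscle_d13c_true <- diet$d13c_mean + muscle_d13c_tdf
    muscle_d15n_true <- diet$d15n_mean + muscle_d15n_tdf
    liver_d13c_lipid_free <- diet$d13c_mean + liver_d13c_tdf
    liver_d15n_true <- diet$d15n_mean + liver_d15n_tdf
    # lipid distortion: exact inverse of the normalization model
    liver_d13c_raw <- lipid_distort_d13c(liver_d13c_lipid_free, liver_cn,
                                         cfg$lipid_params)

    ms <- cfg$isotope_measurement_sd
    tissue <- rbind(
      data.frame(fish_id = fish_id, tissue = "muscle",
                 d13c = muscle_d13c_true + stats::rnorm(n, 0, ms[["d13c"]]),
                 d15n = muscle_d15n_true + stats::rnorm(n, 0, ms[["d15n"]]),
                 cn_ratio = muscle_cn, stringsAsFactors = FALSE),
      data.frame(fish_id = fish_id, tissue = "liver",
                 d13c = liver_d13c_raw + stats::rnorm(n, 0, ms[["d13c"]]),
                 d15n = liver_d15n_true + stats::rnorm(n, 0, ms[["d15n"]]),
                 cn_ratio = liver_cn, stringsAsFactors = FALSE)
    )

    fish <- data.frame(
      fish_id = fish_id,
      trial_id = sprintf("T%02d", seq_len(n)),
      group = g$group[idx],
      weight_class = g$weight_class[idx],
      habitat = g$habitat[idx],
      initial_mass_g = g$initial_mass_g[idx],
      final_mass_g = final_mass,
      length_mm = round(10 * (final_mass / 0.0089)^(1 / 3.14)),
      stringsAsFactors = FALSE
    )

    truth <- data.frame(
      fish_id = fish_id, group = g$group[idx],
      group_smr_mean = group_smr_mean[idx],
      true_smr = true_smr,
      muscle_d13c_tdf = muscle_d13c_tdf, muscle_d15n_tdf = muscle_d15n_tdf,
      liver_d13c_tdf = liver_d13c_tdf, liver_d15n_tdf = liver_d15n_tdf,
      liver_d13c_lipid_free = liver_d13c_lipid_free,
      muscle_cn = muscle_cn, liver_cn = liver_cn,
      stringsAsFactors = FALSE
    )

    diet_out <- data.frame(mean_d13c = diet$d13c_mean, sd_d13c = diet$d13c_sd,
                           mean_d15n = diet$d15n_mean, sd_d15n = diet$d15n_sd,
                           cn_ratio = diet$cn_ratio)

    list(fish = fish, tissue = tissue, diet = diet_out, truth = truth,
         groups = g, group_smr_mean = stats::setNames(group_smr_mean, g$group))
  })
}
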