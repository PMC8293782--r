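# End-to-end orchestration: simulate -> SMR -> normalize -> TDF -> stats.

#' Pipeline configuration
#'
#' Bundles the cohort generator, per-trial simulation settings, all module
#' thresholds and the statistical options into one reproducible
#' configuration. Every threshold default matches the processing rules
#' documented in the respective module function.
#'
#' @param seed Master seed; per-trial seeds are derived deterministically.
#' @param out_dir Output directory; `NULL` returns results in memory only.
#' @param cohort A [cohort_sim_config()]; defaults to the standard cohort
#'   seeded from `seed`.
#' @param trial_duration_s Trial length, s.
#' @param loop,bg_loop Trial and background [loop_spec()]s.
#' @param bg_loops_per_segment Background loops in each pre/post segment.
#' @param chamber_volumes Named vector of chamber volumes, L; each fish is
#'   assigned the chamber whose volume is closest to ~15 mL per g fish
#'   (chambers size-matched to fish), and chambers run trials sequentially.
#' @param sensor_noise_sd,activity_bout_rate,activity_multiplier,bout_duration_s,background_mo2_start,background_mo2_slope,o2_saturation,sample_interval_s
#'   Trial simulation parameters, see [trial_sim_config()].
#' @param r2_min_bg,r2_keep,smr_fraction Respirometry thresholds, see
#'   [process_respirometry()].
#' @param lipid A [lipid_norm_params()].
#' @param equilibrium Optional [equilibrium_params()]; when supplied the
#'   equilibrium gate is evaluated and logged before TDFs are reported.
#' @param experiment_duration_days Feeding-experiment duration used by the
#'   equilibrium gate.
#' @param alpha Significance level for reporting.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL,
                            cohort = cohort_sim_config(seed = seed),
                            trial_duration_s = 71000,
                            loop = loop_spec(),
                            bg_loop = loop_spec(measure_s = 900),
                            bg_loops_per_segment = 2,
                            chamber_volumes = c(C1 = 0.5, C2 = 0.6,
                                                C3 = 0.8, C4 = 0.9),
                            sensor_noise_sd = 0.01,
                            activity_bout_rate = 1,
                            activity_multiplier = 2,
                            bout_duration_s = 600,
                            background_mo2_start = 0.3,
                            background_mo2_slope = 0.01,
                            o2_saturation = 9.0,
                            sample_interval_s = 1,
                            r2_min_bg = 0.1, r2_keep = 0.95,
                            smr_fraction = 0.10,
                            lipid = lipid_norm_params(),
                            equilibrium = NULL,
                            experiment_duration_days = 275,
                            alpha = 0.05) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] can be set from YAML; nested
#' `loop`, `bg_loop`, `chamber_volumes` and `lipid` sections are passed to
#' their constructors.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the file's value.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  args <- list()
  scalars <- c("seed", "out_dir", "trial_duration_s", "bg_loops_per_segment",
               "sensor_noise_sd", "activity_bout_rate", "activity_multiplier",
               "bout_duration_s", "background_mo2_start", "background_mo2_slope",
               "o2_saturation", "sample_interval_s", "r2_min_bg", "r2_keep",
               "smr_fraction", "experiment_duration_days", "alpha")
  for (s in intersect(scalars, names(y))) args[[s]] <- y[[s]]
  # note: [[ avoids partial name matching (bg_loop vs bg_loops_per_segment)
  if (!is.null(y[["loop"]])) args$loop <- do.call(loop_spec, y[["loop"]])
  if (!is.null(y[["bg_loop"]])) args$bg_loop <- do.call(loop_spec, y[["bg_loop"]])
  if (!is.null(y[["chamber_volumes"]])) {
    args$chamber_volumes <- unlist(y[["chamber_volumes"]])
  }
  if (!is.null(y[["lipid"]])) args$lipid <- do.call(lipid_norm_params, y[["lipid"]])
  if (!is.null(y[["equilibrium"]])) {
    args$equilibrium <- do.call(equilibrium_params, y[["equilibrium"]])
  }
  do.call(pipeline_config, args)
}

pipe_log <- function(stage, ...) {
  message(sprintf("[tdfmetab:%s] %s", stage, sprintf(...)))
}

assign_chambers <- function(fish, chamber_volumes, trial_duration_s,
                            bg_segment_s, gap_s = 3600) {
  target <- pmax(min(chamber_volumes), 0.015 * fish$final_mass_g)
  idx <- vapply(target, function(v) which.min(abs(chamber_volumes - v)), 0L)
  fish$chamber_id <- names(chamber_volumes)[idx]
  slot_len <- trial_duration_s + 2 * bg_segment_s + gap_s
  fish$trial_start_s <- NA_real_
  for (ch in unique(fish$chamber_id)) {
    rows <- which(fish$chamber_id == ch)
    fish$trial_start_s[rows] <- bg_segment_s + (seq_along(rows) - 1) * slot_len
  }
  fish
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Simulates a cohort and one respirometry trial (with pre/post background
#' segments) per fish, estimates SMR, lipid-normalizes tissue delta-13C,
#' computes TDFs (after evaluating the equilibrium gate when configured),
#' fits the statistical layer (five ANCOVAs with Bonferroni pairwise
#' comparisons, four TDF-on-SMR regressions, a littoral-vs-pelagic Welch
#' t-test on SMR in the shared weight class), and summarizes the cohort.
#' Deterministic given the configuration seed. When `out_dir` is set every
#' intermediate table, a text report, the resolved configuration and a log
#' are written there; partial outputs are retained if a stage fails.
#'
#' @param cfg A [pipeline_config()].
#' @return (Invisibly) a `tdf_pipeline_result` list: `cohort`, `smr`
#'   (per-fish), `measures`, `tdf`, `per_fish` (merged wide table),
#'   `ancovas`, `pairwise`, `regressions`, `welch`, `summary`,
#'   `equilibrium`, `qc`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- list()
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  save_csv <- function(x, name) {
    if (!is.null(cfg$out_dir)) write_csv_stable(x, file.path(cfg$out_dir, name))
  }

  pipe_log("simulate", "simulating cohort (seed %d)", cfg$seed)
  cohort <- simulate_cohort(cfg$cohort)
  out$cohort <- cohort
  save_csv(cohort$fish, "fish.csv")
  save_csv(cohort$tissue, "tissue.csv")
  save_csv(cohort$diet, "diet.csv")
  save_csv(cohort$truth, "truth.csv")

  bg_segment_s <- cfg$bg_loops_per_segment * loop_length(cfg$bg_loop)
  fish <- assign_chambers(cohort$fish, cfg$chamber_volumes,
                          cfg$trial_duration_s, bg_segment_s)

  pipe_log("simulate", "simulating %d respirometry trials", nrow(fish))
  traces <- vector("list", nrow(fish))
  bg_traces <- vector("list", 2 * nrow(fish))
  truth_loops <- vector("list", nrow(fish))
  for (i in seq_len(nrow(fish))) {
    tcfg <- trial_sim_config(
      true_smr = cohort$truth$true_smr[i],
      fish_mass = fish$final_mass_g[i],
      chamber_volume = cfg$chamber_volumes[[fish$chamber_id[i]]],
      trial_duration = cfg$trial_duration_s, loop = cfg$loop,
      activity_bout_rate = cfg$activity_bout_rate,
      activity_multiplier = cfg$activity_multiplier,
      bout_duration_s = cfg$bout_duration_s,
      background_mo2_start = cfg$background_mo2_start,
      background_mo2_slope = cfg$background_mo2_slope,
      o2_saturation = cfg$o2_saturation,
      sensor_noise_sd = cfg$sensor_noise_sd,
      sample_interval_s = cfg$sample_interval_s,
      trial_start_s = fish$trial_start_s[i],
      trial_id = fish$trial_id[i], chamber_id = fish$chamber_id[i],
      seed = derive_seed(cfg$seed, 10L, i)
    )
    sim <- simulate_trial_trace(tcfg)
    traces[[i]] <- sim$trace
    truth_loops[[i]] <- sim$truth
    bg_traces[[2 * i - 1]] <- simulate_background_trace(
      tcfg, "pre", n_loops = cfg$bg_loops_per_segment, bg_loop = cfg$bg_loop)$trace
    bg_traces[[2 * i]] <- simulate_background_trace(
      tcfg, "post", n_loops = cfg$bg_loops_per_segment, bg_loop = cfg$bg_loop)$trace
  }
  traces <- do.call(rbind, traces)
  bg_traces <- do.call(rbind, bg_traces)

  pipe_log("smr", "processing respirometry traces")
  chambers <- data.frame(chamber_id = names(cfg$chamber_volumes),
                         volume_l = unname(cfg$chamber_volumes))
  resp <- process_respirometry(traces, bg_traces, fish, chambers,
                               trial_spec = cfg$loop, bg_spec = cfg$bg_loop,
                               r2_min_bg = cfg$r2_min_bg,
                               r2_keep = cfg$r2_keep,
                               fraction = cfg$smr_fraction)
  out$smr <- resp$smr
  out$measures <- resp$measures
  out$qc <- resp$qc
  out$loop_truth <- do.call(rbind, truth_loops)
  n_excl <- sum(resp$smr$n_excl_nonpositive) + sum(resp$smr$n_excl_low_r2)
  if (n_excl > 0) {
    warning(sprintf("%d MO2 measures excluded across %d fish (see QC report)",
                    n_excl, nrow(resp$smr)), call. = FALSE)
  }
  save_csv(resp$smr, "smr.csv")
  save_csv(resp$measures, "mo2_measures.csv")

  # equilibrium gate before TDFs are reported
  if (!is.null(cfg$equilibrium)) {
    eq <- lapply(c(muscle = "muscle", liver = "liver"), function(tis) {
      predict_equilibrium_time(max(fish$final_mass_g), tis, cfg$equilibrium,
                               duration_days = cfg$experiment_duration_days)
    })
    for (tis in names(eq)) {
      pipe_log("tdf", "%s equilibrium window %.0f-%.0f d vs %d d experiment: %s",
               tis, eq[[tis]]$t_low_days, eq[[tis]]$t_high_days,
               cfg$experiment_duration_days,
               if (isTRUE(eq[[tis]]$equilibrated)) "equilibrated" else "NOT equilibrated")
    }
    out$equilibrium <- eq
  } else {
    pipe_log("tdf", "no equilibrium model configured; gate not evaluated")
    out$equilibrium <- NULL
  }

  pipe_log("tdf", "normalizing tissue delta-13C and computing TDFs")
  tissue_norm <- normalize_tissue(cohort$tissue, cfg$lipid)
  tdf <- compute_tdf(tissue_norm, cohort$diet)
  out$tdf <- tdf
  save_csv(tdf, "tdf.csv")

  # merged wide per-fish table
  wide <- fish[, c("fish_id", "group", "weight_class", "habitat",
                   "initial_mass_g", "final_mass_g")]
  for (tis in c("muscle", "liver")) {
    sub <- tdf[tdf$tissue == tis, c("fish_id", "delta13c", "delta15n")]
    names(sub) <- c("fish_id", paste0(tis, "_d13c_tdf"), paste0(tis, "_d15n_tdf"))
    wide <- merge(wide, sub, by = "fish_id", all.x = TRUE)
  }
  wide <- merge(wide, resp$smr[, c("fish_id", "smr")], by = "fish_id")
  wide <- wide[order(wide$fish_id), ]
  rownames(wide) <- NULL
  out$per_fish <- wide
  save_csv(wide, "per_fish.csv")

  pipe_log("stats", "fitting ANCOVAs, regressions and Welch t-test")
  responses <- c("muscle_d13c_tdf", "muscle_d15n_tdf",
                 "liver_d13c_tdf", "liver_d15n_tdf", "smr")
  ancovas <- lapply(stats::setNames(responses, responses), function(r) {
    fit_ancova(wide, r, "group", "final_mass_g")
  })
  pairwise <- lapply(ancovas, bonferroni_pairwise, alpha = cfg$alpha)
  regs <- lapply(stats::setNames(responses[1:4], responses[1:4]), function(r) {
    fit_regression(wide[[r]], wide$smr)
  })
  shared <- wide[wide$weight_class == "20-30", ]
  welch <- if (length(unique(shared$habitat)) == 2) {
    welch_t(shared$smr[shared$habitat == "littoral"],
            shared$smr[shared$habitat == "pelagic"])
  } else NULL
  out$ancovas <- ancovas
  out$pairwise <- pairwise
  out$regressions <- regs
  out$welch <- welch

  pipe_log("summary", "building cohort summary")
  summary_tbl <- summarize_cohort(wide)
  out$summary <- summary_tbl
  save_csv(summary_tbl, "summary.csv")

  if (!is.null(cfg$out_dir)) {
    writeLines(render_stats_report(out, cfg$alpha),
               file.path(cfg$out_dir, "stats_report.txt"))
    writeLines(out$qc, file.path(cfg$out_dir, "qc_report.txt"))
    resolved <- cfg
    resolved$cohort <- NULL # nested closures don't serialize usefully
    yaml::write_yaml(lapply(unclass(resolved), function(x) {
      if (inherits(x, "loop_spec") || inherits(x, "lipid_norm_params") ||
          inherits(x, "equilibrium_params")) unclass(x) else x
    }), file.path(cfg$out_dir, "resolved_config.yaml"))
  }
  pipe_log("done", "pipeline complete")
  invisible(structure(out, class = "tdf_pipeline_result"))
}

render_stats_report <- function(res, alpha) {
  lines <- c("tdfmetab statistical report", "")
  for (nm in names(res$ancovas)) {
    a <- res$ancovas[[nm]]
    lines <- c(lines, sprintf(
      "ANCOVA %s ~ group + final weight: F(%g, %g) = %.3f, p = %.4g; covariate F(%g, %g) = %.3f, p = %.4g",
      nm, a$factor_df[1], a$factor_df[2], a$factor_F, a$factor_p,
      a$covariate_df[1], a$covariate_df[2], a$covariate_F, a$covariate_p))
    lets <- res$pairwise[[nm]]$letters
    lines <- c(lines, paste0("  letters: ",
                             paste(names(lets), lets, sep = ":", collapse = "  ")))
  }
  lines <- c(lines, "")
  for (nm in names(res$regressions)) {
    r <- res$regressions[[nm]]
    lines <- c(lines, sprintf(
      "regression %s ~ SMR: slope = %.4g (t[%d] = %.3f, p = %.4g), R^2 = %.3f",
      nm, r$slope, r$df, r$t, r$p, r$r_squared))
  }
  if (!is.null(res$welch)) {
    w <- res$welch
    lines <- c(lines, "", sprintf(
      "Welch t-test SMR littoral vs pelagic (20-30 g): t[%.3f] = %.3f, p = %.4g",
      w$df, w$t, w$p))
  }
  lines
}

#' @export
print.tdf_pipeline_result <- function(x, ...) {
  cat("tdfmetab pipeline result:", nrow(x$per_fish), "fish\n")
  cat(render_stats_report(x, 0.05), sep = "\n")
  invisible(x)
}

#' Percent approximate weight change
#'
#' `100 * (final - initial) / initial`, using the group's assumed initial
#' mass (the weight-class average) when individual initial masses were not
#' recorded.
#'
#' @param final_mass,initial_mass Masses, g.
#' @return Percent change.
#' @export
#' @examples
#' percent_weight_change(16.6, 4) # 315
percent_weight_change <- function(final_mass, initial_mass) {
  if (any(initial_mass <= 0)) stop("initial mass must be positive")
  100 * (final_mass - initial_mass) / initial_mass
}

#' Per-group cohort summary
#'
#' Group-wise sample sizes and mean +/- SD of muscle and liver TDFs, SMR,
#' final mass, and approximate percent weight change (per fish against the
#' group's assumed initial mass, then averaged). Groups with a single fish
#' report SD as missing, not zero.
#'
#' @param per_fish Merged per-fish table as produced by [run_pipeline()]
#'   (columns `group`, `weight_class`, `habitat`, `initial_mass_g`,
#'   `final_mass_g`, `smr`, `muscle_d13c_tdf`, `muscle_d15n_tdf`,
#'   `liver_d13c_tdf`, `liver_d15n_tdf`).
#' @param initial_means Optional named vector of group initial masses, g;
#'   defaults to the `initial_mass_g` column. An error is raised if a group
#'   has no initial mean from either source.
#' @return data.frame, one row per group.
#' @export
summarize_cohort <- function(per_fish, initial_means = NULL) {
  needed <- c("group", "weight_class", "habitat", "final_mass_g", "smr",
              "muscle_d13c_tdf", "muscle_d15n_tdf", "liver_d13c_tdf",
              "liver_d15n_tdf")
  stopifnot(all(needed %in% names(per_fish)))
  if (is.null(initial_means)) {
    if (!"initial_mass_g" %in% names(per_fish)) {
      stop("supply `initial_means` or an `initial_mass_g` column")
    }
  } else {
    missing_g <- setdiff(unique(per_fish$group), names(initial_means))
    if (length(missing_g)) {
      stop("no initial mass mean for group(s): ", paste(missing_g, collapse = ", "))
    }
    per_fish$initial_mass_g <- initial_means[per_fish$group]
  }
  per_fish$pct_weight_change <- percent_weight_change(per_fish$final_mass_g,
                                                      per_fish$initial_mass_g)
  sd_or_na <- function(x) if (length(x) < 2) NA_real_ else sd(x)
  vars <- c("muscle_d13c_tdf", "muscle_d15n_tdf", "liver_d13c_tdf",
            "liver_d15n_tdf", "smr", "final_mass_g", "pct_weight_change")
  rows <- lapply(split(per_fish, per_fish$group), function(d) {
    row <- data.frame(group = d$group[1], weight_class = d$weight_class[1],
                      habitat = d$habitat[1], n = nrow(d),
                      stringsAsFactors = FALSE)
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(d[[v]])
      row[[paste0(v, "_sd")]] <- sd_or_na(d[[v]])
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$group, unique(per_fish$group))), ]
  rownames(out) <- NULL
  out
}
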