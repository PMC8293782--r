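# Respirometry processing: oxygen trace -> per-loop slope fits -> MO2 ->
# chamber-specific background correction -> mass-specific MO2 -> R^2 filter
# -> lowest-decile SMR.

#' Extract measurement-phase segments from an oxygen trace
#'
#' Uses the trace's `phase` / `loop_index` labels when present; otherwise
#' infers the flush/wait/measure schedule from the loop spec and the trace
#' start time (which requires regular sampling). Partial trailing loops
#' (fewer measure samples than a complete loop) are dropped.
#'
#' @param trace data.frame with `time_s`, `o2_mg_per_l`, optionally `phase`
#'   and `loop_index` (and `trial_id`, `chamber_id`, carried through).
#' @param spec A [loop_spec()]; used for schedule inference and to validate
#'   completeness.
#' @return data.frame of measure-phase samples with a `loop_index` column;
#'   zero rows (with a warning) if the trace holds no complete loop.
#' @export
segment_loops <- function(trace, spec = loop_spec()) {
  stopifnot(is.data.frame(trace), all(c("time_s", "o2_mg_per_l") %in% names(trace)))
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    stop("trace time must be strictly increasing")
  }
  if (all(c("phase", "loop_index") %in% names(trace))) {
    meas <- trace[trace$phase == "measure", , drop = FALSE]
  } else {
    dts <- diff(trace$time_s)
    dt <- stats::median(dts)
    if (any(abs(dts - dt) > 1e-6 * max(dt, 1))) {
      stop("cannot infer loop schedule: trace is unlabeled and irregularly sampled")
    }
    rel <- trace$time_s - trace$time_s[1]
    L <- loop_length(spec)
    loop_index <- floor(rel / L) + 1
    off <- rel - (loop_index - 1) * L
    meas <- trace[off >= spec$flush_s + spec$wait_s, , drop = FALSE]
    meas$loop_index <- loop_index[off >= spec$flush_s + spec$wait_s]
  }
  if (nrow(meas) == 0L) {
    warning("trace contains no measurement-phase samples")
    meas$loop_index <- integer(0)
    return(meas)
  }
  counts <- table(meas$loop_index)
  full <- max(counts)
  complete <- as.numeric(names(counts)[counts == full])
  if (length(complete) < length(counts)) {
    meas <- meas[meas$loop_index %in% complete, , drop = FALSE]
  }
  if (nrow(meas) == 0L) warning("no complete measurement loops in trace")
  rownames(meas) <- NULL
  meas
}

#' Ordinary least-squares slope of one measurement phase
#'
#' Fits dissolved O2 concentration on time (hours) for a single segment.
#' A zero-variance response yields slope 0 with R^2 defined as 0.
#'
#' @param segment data.frame with `time_s` and `o2_mg_per_l` for one
#'   measurement phase (>= 3 points).
#' @return One-row data.frame (a phase fit): `start_time_s`, `mid_time_s`,
#'   `slope` (mg O2 L^-1 hr^-1, negative = consumption), `intercept`
#'   (mg L^-1 at the phase start), `r_squared`, `n_points`.
#' @export
fit_phase_slope <- function(segment) {
  stopifnot(is.data.frame(segment),
            all(c("time_s", "o2_mg_per_l") %in% names(segment)))
  if (nrow(segment) < 3L) stop("a phase fit needs at least 3 points")
  t_hr <- (segment$time_s - segment$time_s[1]) / 3600
  y <- segment$o2_mg_per_l
  if (var(y) == 0) {
    slope <- 0; intercept <- y[1]; r2 <- 0
  } else {
    fit <- stats::lm(y ~ t_hr)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    # R^2 from residuals directly; summary.lm warns on noise-free segments
    r2 <- 1 - sum(resid(fit)^2) / sum((y - mean(y))^2)
  }
  data.frame(start_time_s = segment$time_s[1],
             mid_time_s = mean(segment$time_s),
             slope = slope, intercept = intercept,
             r_squared = r2, n_points = nrow(segment))
}

#' Fit all measurement-phase slopes of a trace
#'
#' Segments the trace with [segment_loops()] and applies
#' [fit_phase_slope()] per loop. Loops with fewer than 3 points are skipped
#' with reason code `too_few_points` in the `skipped` attribute.
#'
#' @inheritParams segment_loops
#' @return data.frame of phase fits, one row per complete loop, carrying
#'   `trial_id` / `chamber_id` if present in the trace.
#' @export
fit_phase_slopes <- function(trace, spec = loop_spec()) {
  meas <- segment_loops(trace, spec)
  ids <- intersect(c("trial_id", "chamber_id"), names(trace))
  if (nrow(meas) == 0L) {
    out <- data.frame(loop_index = integer(0), start_time_s = numeric(0),
                      mid_time_s = numeric(0), slope = numeric(0),
                      intercept = numeric(0), r_squared = numeric(0),
                      n_points = integer(0))
    for (id in ids) out[[id]] <- character(0)
    return(out)
  }
  skipped <- integer(0)
  fits <- lapply(split(meas, meas$loop_index), function(seg) {
    if (nrow(seg) < 3L) return(NULL)
    f <- fit_phase_slope(seg)
    f$loop_index <- seg$loop_index[1]
    for (id in ids) f[[id]] <- seg[[id]][1]
    f
  })
  keep <- !vapply(fits, is.null, logical(1))
  if (any(!keep)) skipped <- as.integer(names(fits)[!keep])
  out <- do.call(rbind, fits[keep])
  out <- out[order(out$loop_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(loop_index = skipped,
                                     reason = rep("too_few_points", length(skipped)))
  out
}

#' Convert phase-fit slopes to oxygen consumption rates
#'
#' `mo2_raw = -slope * (chamber_volume - fish_mass / 1000)`: the O2 decline
#' rate times the effective water volume (chamber minus fish volume at
#' density 1 g cm^-3), positive when oxygen declines.
#'
#' @param fits Phase-fit data.frame from [fit_phase_slopes()] (or a
#'   compatible one-row frame from [fit_phase_slope()]).
#' @param chamber_volume Chamber volume, L.
#' @param fish_mass Fish wet mass, g (0 for background segments).
#' @return The input with an `mo2_raw` column (mg O2 hr^-1) and a
#'   `time_s` column set to the phase midpoint.
#' @export
compute_mo2 <- function(fits, chamber_volume, fish_mass) {
  v_eff <- chamber_volume - fish_mass / 1000
  if (v_eff <= 0) {
    stop("non-positive effective volume for chamber ",
         paste(unique(fits$chamber_id), collapse = ", "),
         " (volume ", chamber_volume, " L, fish ", fish_mass, " g)")
  }
  fits$mo2_raw <- -fits$slope * v_eff
  fits$time_s <- fits$mid_time_s
  fits
}

#' Fit chamber-specific background respiration models
#'
#' Pools all pre- and post-trial background MO2 estimates, drops fits with
#' `r_squared <= r2_min` (the inclusion rule is R^2 > 0.1), and regresses
#' background MO2 on absolute experiment time (hours), grouped by chamber.
#' With fewer than 2 surviving points the chamber falls back to the mean of
#' what survives, or to zero (with a warning) when nothing does.
#' Predictions are clamped at >= 0.
#'
#' @param background_fits data.frame with `chamber_id`, `time_s`, `mo2_raw`,
#'   `r_squared` (from 900 s background measurement phases).
#' @param r2_min Exclusion threshold; background fits with R^2 below or at
#'   this value are excluded. Default 0.1.
#' @return An object of class `background_models`: a list of per-chamber
#'   models (`intercept` mg O2 hr^-1 at time 0, `slope` mg O2 hr^-1 per hr,
#'   `type` one of linear/mean/zero, `n_used`, `n_excluded`).
#' @export
fit_background_model <- function(background_fits, r2_min = 0.1) {
  stopifnot(all(c("chamber_id", "time_s", "mo2_raw", "r_squared") %in%
                  names(background_fits)))
  models <- lapply(split(background_fits, background_fits$chamber_id), function(d) {
    ok <- d$r_squared > r2_min
    n_used <- sum(ok); n_excluded <- sum(!ok)
    if (n_used >= 2L && var(d$time_s[ok]) > 0) {
      t_hr <- d$time_s[ok] / 3600
      fit <- stats::lm(d$mo2_raw[ok] ~ t_hr)
      list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
           type = "linear", n_used = n_used, n_excluded = n_excluded)
    } else if (n_used >= 1L) {
      list(intercept = mean(d$mo2_raw[ok]), slope = 0,
           type = "mean", n_used = n_used, n_excluded = n_excluded)
    } else {
      warning("no background fits survived the R^2 filter for chamber ",
              d$chamber_id[1], "; assuming zero background")
      list(intercept = 0, slope = 0, type = "zero",
           n_used = 0L, n_excluded = n_excluded)
    }
  })
  structure(models, class = "background_models", r2_min = r2_min)
}

#' Predict background respiration for a chamber at given times
#'
#' @param models A [fit_background_model()] result.
#' @param chamber_id Chamber identifier (scalar or vector).
#' @param time_s Absolute experiment time, seconds (recycled with
#'   `chamber_id`).
#' @return Background MO2 predictions, mg O2 hr^-1, clamped at >= 0.
#' @export
predict_background <- function(models, chamber_id, time_s) {
  stopifnot(inherits(models, "background_models"))
  n <- max(length(chamber_id), length(time_s))
  chamber_id <- rep_len(chamber_id, n); time_s <- rep_len(time_s, n)
  unknown <- setdiff(unique(chamber_id), names(models))
  if (length(unknown)) {
    stop("no background model for chamber(s): ", paste(unknown, collapse = ", "))
  }
  vapply(seq_len(n), function(i) {
    m <- models[[chamber_id[i]]]
    max(0, m$intercept + m$slope * time_s[i] / 3600)
  }, numeric(1))
}

#' Background-correct MO2 measures and convert to mass-specific rates
#'
#' Subtracts the fitted chamber background at each measure's time, then
#' divides by fish mass (kg). Measures that go non-positive after the
#' correction are flagged `nonpositive_after_correction` and excluded from
#' SMR downstream (excluded rather than clamped: clamping would bias the
#' lowest-decile mean downward).
#'
#' @param measures data.frame from [compute_mo2()] (columns `chamber_id`,
#'   `time_s`, `mo2_raw`, `r_squared`, ...).
#' @param models A [fit_background_model()] result.
#' @param fish_mass Fish wet mass, g (> 0).
#' @return The input with `mo2_background`, `mo2_corrected`,
#'   `mo2_mass_specific` (mg O2 kg^-1 hr^-1), `retained` (logical) and
#'   `reason` columns added.
#' @export
apply_background_correction <- function(measures, models, fish_mass) {
  stopifnot(fish_mass > 0)
  measures$mo2_background <- predict_background(models, measures$chamber_id,
                                                measures$time_s)
  measures$mo2_corrected <- measures$mo2_raw - measures$mo2_background
  measures$mo2_mass_specific <- measures$mo2_corrected / (fish_mass / 1000)
  bad <- measures$mo2_corrected <= 0
  measures$retained <- !bad
  measures$reason <- ifelse(bad, "nonpositive_after_correction", NA_character_)
  measures
}

#' Standard metabolic rate as the mean of the lowest decile of MO2
#'
#' Removes measures whose phase-fit R^2 is below `r2_threshold` (retention
#' rule: R^2 >= 0.95) or that carry an exclusion flag, then averages the
#' `k = max(1, floor(fraction * n_retained))` smallest mass-specific MO2
#' values (ties broken by loop order).
#'
#' @param measures data.frame from [apply_background_correction()].
#' @param r2_threshold Minimum phase-fit R^2 for retention (inclusive).
#' @param fraction Lowest fraction of retained measures to average.
#' @return An object of class `smr_result`: `smr` (mg O2 kg^-1 hr^-1),
#'   `fraction`, `n_total`, `n_retained`, `n_lowest_used`, and a named
#'   `exclusions` count vector.
#' @export
compute_smr <- function(measures, r2_threshold = 0.95, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  n_total <- nrow(measures)
  flagged <- !measures$retained
  low_r2 <- measures$r_squared < r2_threshold
  keep <- !flagged & !low_r2
  exclusions <- c(nonpositive_after_correction = sum(flagged),
                  low_r_squared = sum(low_r2 & !flagged))
  if (!any(keep)) {
    stop("no MO2 measures retained for SMR (",
         paste(names(exclusions), exclusions, sep = " = ", collapse = ", "), ")")
  }
  vals <- measures$mo2_mass_specific[keep]
  loops <- if ("loop_index" %in% names(measures)) {
    measures$loop_index[keep]
  } else seq_along(vals)
  n_ret <- length(vals)
  k <- max(1L, floor(fraction * n_ret))
  o <- order(vals, loops)
  lowest <- vals[o][seq_len(k)]
  structure(list(smr = mean(lowest), fraction = fraction,
                 n_total = n_total, n_retained = n_ret, n_lowest_used = k,
                 exclusions = exclusions, lowest_values = lowest),
            class = "smr_result")
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf("SMR: %.3f mg O2 kg^-1 hr^-1 (mean of lowest %d of %d retained / %d total loops)\n",
              x$smr, x$n_lowest_used, x$n_retained, x$n_total))
  excl <- x$exclusions[x$exclusions > 0]
  if (length(excl)) {
    cat("excluded:", paste(names(excl), excl, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Process a set of respirometry trials end to end
#'
#' Full chain for a batch of fish: per-trial phase slopes and MO2, pooled
#' chamber-specific background regression from the pre/post background
#' segments, background correction, mass-specific conversion, R^2 filter
#' and lowest-decile SMR per fish.
#'
#' @param traces Trial oxygen traces: one data.frame (long) with columns
#'   `trial_id`, `chamber_id`, `time_s`, `o2_mg_per_l`, `phase`,
#'   `loop_index`.
#' @param bg_traces Background traces, same columns; `trial_id` values need
#'   not match the trials (only `chamber_id` and time matter).
#' @param fish Per-fish table: `fish_id`, `trial_id`, `chamber_id`,
#'   `final_mass_g`.
#' @param chambers Chamber metadata: `chamber_id`, `volume_l`.
#' @param trial_spec,bg_spec Loop specs for trial and background loops.
#' @param r2_min_bg Background-fit inclusion threshold (R^2 > this value).
#' @param r2_keep Phase-fit retention threshold (R^2 >= this value).
#' @param fraction Lowest fraction averaged for SMR.
#' @return A list: `smr` (per-fish data.frame with SMR and filter
#'   bookkeeping), `measures` (all per-loop MO2 rows with retention flags),
#'   `background_models`, and `qc` (character vector of exclusion tallies).
#' @export
process_respirometry <- function(traces, bg_traces, fish, chambers,
                                 trial_spec = loop_spec(),
                                 bg_spec = loop_spec(measure_s = 900),
                                 r2_min_bg = 0.1, r2_keep = 0.95,
                                 fraction = 0.10) {
  stopifnot(all(c("fish_id", "trial_id", "chamber_id", "final_mass_g") %in% names(fish)),
            all(c("chamber_id", "volume_l") %in% names(chambers)))
  vol <- stats::setNames(chambers$volume_l, chambers$chamber_id)

  bg_fits <- do.call(rbind, lapply(split(bg_traces, bg_traces$trial_id), function(tr) {
    f <- fit_phase_slopes(tr, bg_spec)
    compute_mo2(f, vol[[f$chamber_id[1]]], fish_mass = 0)
  }))
  bg_models <- fit_background_model(bg_fits, r2_min = r2_min_bg)

  all_measures <- list()
  smr_rows <- list()
  for (i in seq_len(nrow(fish))) {
    fr <- fish[i, ]
    tr <- traces[traces$trial_id == fr$trial_id, , drop = FALSE]
    if (nrow(tr) == 0L) stop("no trace for trial ", fr$trial_id)
    fits <- fit_phase_slopes(tr, trial_spec)
    meas <- compute_mo2(fits, vol[[fr$chamber_id]], fr$final_mass_g)
    meas <- apply_background_correction(meas, bg_models, fr$final_mass_g)
    meas$fish_id <- fr$fish_id
    res <- compute_smr(meas, r2_threshold = r2_keep, fraction = fraction)
    all_measures[[i]] <- meas
    smr_rows[[i]] <- data.frame(
      fish_id = fr$fish_id, trial_id = fr$trial_id, chamber_id = fr$chamber_id,
      final_mass_g = fr$final_mass_g, smr = res$smr, fraction = res$fraction,
      n_total_loops = res$n_total, n_retained = res$n_retained,
      n_lowest_used = res$n_lowest_used,
      n_excl_nonpositive = res$exclusions[["nonpositive_after_correction"]],
      n_excl_low_r2 = res$exclusions[["low_r_squared"]],
      stringsAsFactors = FALSE
    )
  }
  smr <- do.call(rbind, smr_rows)
  measures <- do.call(rbind, all_measures)
  rownames(smr) <- rownames(measures) <- NULL
  qc <- c(
    sprintf("fish processed: %d", nrow(smr)),
    sprintf("loops total: %d, retained: %d", sum(smr$n_total_loops), sum(smr$n_retained)),
    sprintf("excluded nonpositive after correction: %d", sum(smr$n_excl_nonpositive)),
    sprintf("excluded low R^2 (< %.2f): %d", r2_keep, sum(smr$n_excl_low_r2)),
    sprintf("background models: %s",
            paste(sprintf("%s[%s, n=%d]", names(bg_models),
                          vapply(bg_models, `[[`, "", "type"),
                          vapply(bg_models, `[[`, 0L, "n_used")), collapse = ", "))
  )
  list(smr = smr, measures = measures, background_models = bg_models, qc = qc)
}
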