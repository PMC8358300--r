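#' Synthetic sway cohort
#'
#' A seeded stand-in for a six-condition posturography study: 23 participants
#' x 6 conditions x 3 trials of 20 s COP sway at 200 Hz. Each trial's AP and
#' ML series are independently generated as zero-phase low-pass-filtered
#' Gaussian white noise, rescaled to a per-condition target RMS amplitude
#' modulated by a shared multiplicative participant effect (lognormal, scale
#' `tau`) and per-trial lognormal noise. Amplitude steers the distance /
#' velocity / area measures; the filter cutoff steers the mean-frequency
#' measures, so the two measure families can be calibrated independently.
#' This is a statistical stand-in, not a biomechanical model of sway.
#'
#' @name synthetic_data
NULL

#' Sway generator parameters
#'
#' @param conditions Data.frame with one row per condition and columns
#'   `condition`, `amp_ap`, `amp_ml` (target RMS amplitude, mm), `cutoff_ap`,
#'   `cutoff_ml` (low-pass cutoff, Hz).
#' @param tau Participant random-effect scale on the log-amplitude (log-mm);
#'   default 0.25.
#' @param trial_cv Per-trial lognormal noise scale (fraction); default 0.1.
#' @param sampling_rate Hz (default 200).
#' @param duration Trial length in seconds (default 20).
#' @return Object of class `sway_params`.
#' @export
sway_params <- function(conditions, tau = 0.25, trial_cv = 0.1,
                        sampling_rate = 200, duration = 20) {
  need <- c("condition", "amp_ap", "amp_ml", "cutoff_ap", "cutoff_ml")
  miss <- setdiff(need, names(conditions))
  if (length(miss) > 0L) stop("conditions missing columns: ",
                              paste(miss, collapse = ", "))
  amps <- c(conditions$amp_ap, conditions$amp_ml)
  cuts <- c(conditions$cutoff_ap, conditions$cutoff_ml)
  nyq <- sampling_rate / 2
  if (any(!is.finite(amps)) || any(amps <= 0)) {
    stop("target RMS amplitudes must be positive")
  }
  if (any(!is.finite(cuts)) || any(cuts <= 0) || any(cuts >= nyq)) {
    stop(sprintf("cutoffs must lie in (0, %g) Hz", nyq))
  }
  if (tau < 0 || trial_cv < 0) stop("tau and trial_cv must be >= 0")
  structure(
    list(conditions = conditions[order(conditions$condition), , drop = FALSE],
         tau = tau, trial_cv = trial_cv,
         sampling_rate = sampling_rate, duration = duration),
    class = "sway_params"
  )
}

#' Published condition-level measure targets
#'
#' Condition means (and SDs) of the seven COP measures across the six
#' sensory-organization conditions, as reported for the reference cohort of
#' 23 healthy young adults. Used as calibration targets for the generator
#' and as the comparison layout in reports.
#'
#' @return Data.frame with one row per condition.
#' @export
cop_condition_targets <- function() {
  path <- system.file("extdata", "cop_condition_targets.csv",
                      package = "posturo")
  utils::read.csv(path)
}

#' Default (calibrated) sway parameters
#'
#' Loads the versioned parameter asset produced by
#' [calibrate_sway_params()] against [cop_condition_targets()].
#'
#' @return A [sway_params()] object.
#' @export
default_sway_params <- function() {
  asset <- read_asset("sway_params_default.yaml")
  conds <- do.call(rbind, lapply(asset$conditions, as.data.frame))
  sway_params(conds, tau = asset$tau, trial_cv = asset$trial_cv,
              sampling_rate = asset$sampling_rate,
              duration = asset$duration)
}

# Deterministic per-trial seed derivation (kept below 2^31): a Lehmer step
# on the cohort seed plus fixed strides per participant/condition/trial.
derive_seed <- function(seed, participant = 0L, condition = 0L, trial = 0L) {
  s <- seed %% 2147483647
  s <- (s * 48271) %% 2147483647
  s <- (s + participant * 100003 + condition * 10007 + trial * 101) %%
    2147483647
  as.integer(s) + 1L
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

filtered_noise <- function(n, cutoff, fs) {
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  signal::filtfilt(bf, stats::rnorm(n))
}

#' Generate one synthetic sway trial
#'
#' AP and ML are independent zero-phase low-pass-filtered Gaussian noise
#' series, centered and rescaled so the RMS equals
#' `amp * participant_effect * trial_factor` exactly. Fully deterministic
#' given `(params, condition, effects, seed)`.
#'
#' @param params A [sway_params()] object.
#' @param condition Condition number (must exist in `params$conditions`).
#' @param participant_effect Multiplicative amplitude effect (default 1).
#' @param trial_factor Multiplicative per-trial factor (default 1).
#' @param seed Integer seed.
#' @return A centered [cop_trajectory()].
#' @export
generate_trial <- function(params, condition, participant_effect = 1,
                           trial_factor = 1, seed = 1L) {
  stopifnot(inherits(params, "sway_params"))
  row <- params$conditions[params$conditions$condition == condition, ,
                           drop = FALSE]
  if (nrow(row) != 1L) stop("unknown condition: ", condition)
  fs <- params$sampling_rate
  n <- round(params$duration * fs)
  scale <- participant_effect * trial_factor
  with_seed(seed, {
    ap <- filtered_noise(n, row$cutoff_ap, fs)
    ml <- filtered_noise(n, row$cutoff_ml, fs)
    ap <- ap - mean(ap); ml <- ml - mean(ml)
    ap <- ap * (row$amp_ap * scale) / sqrt(mean(ap^2))
    ml <- ml * (row$amp_ml * scale) / sqrt(mean(ml^2))
    cop_trajectory(ap - mean(ap), ml - mean(ml), fs, centered = TRUE)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws one lognormal amplitude effect per participant (shared across all
#' of that participant's conditions and trials, inducing the within-subject
#' correlation the repeated-measures statistics exploit), then generates the
#' full factorial of conditions x trials.
#'
#' @param params A [sway_params()] object (default the calibrated asset).
#' @param n_participants Number of participants (default 23).
#' @param trials_per_condition Trials per condition (default 3).
#' @param seed Integer cohort seed.
#' @return Object of class `sway_cohort`: `trials` (list of labeled
#'   [cop_trajectory()]), `index` (data.frame participant/condition/trial),
#'   `participant_effects`, `params`, `seed`.
#' @export
generate_cohort <- function(params = default_sway_params(),
                            n_participants = 23, trials_per_condition = 3,
                            seed = 1L) {
  stopifnot(inherits(params, "sway_params"), n_participants >= 1)
  effects <- with_seed(derive_seed(seed), {
    exp(stats::rnorm(n_participants, 0, params$tau))
  })
  conds <- params$conditions$condition
  idx <- expand.grid(trial = seq_len(trials_per_condition),
                     condition = conds,
                     participant = seq_len(n_participants))
  idx <- idx[, c("participant", "condition", "trial")]
  trials <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    p <- idx$participant[i]; cc <- idx$condition[i]; tt <- idx$trial[i]
    s <- derive_seed(seed, p, cc, tt)
    tf <- if (params$trial_cv > 0) {
      with_seed(s + 1L, exp(stats::rnorm(1, 0, params$trial_cv)))
    } else 1
    tr <- generate_trial(params, cc, effects[p], tf, seed = s)
    attr(tr, "participant") <- p
    attr(tr, "condition") <- cc
    attr(tr, "trial") <- tt
    trials[[i]] <- tr
  }
  structure(
    list(trials = trials, index = idx, participant_effects = effects,
         params = params, seed = seed),
    class = "sway_cohort"
  )
}

#' @export
print.sway_cohort <- function(x, ...) {
  cat(sprintf("Synthetic sway cohort: %d participants, %d trials (seed %d)\n",
              length(x$participant_effects), length(x$trials), x$seed))
  invisible(x)
}

#' Compute the measure battery for every trial of a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @return Long measures data.frame
#'   (`participant,condition,trial,measure,value,flag`), the canonical
#'   hand-off to the statistics layer.
#' @export
cohort_measures <- function(cohort) {
  stopifnot(inherits(cohort, "sway_cohort"))
  batteries <- lapply(cohort$trials, measure_battery)
  measures_long(batteries, cohort$index$participant)
}

#' Calibrate generator parameters against condition-level targets
#'
#' Iterative moment matching: simulate a small cohort without participant or
#' trial noise, compare the computed condition means of MeanAP/MeanML and
#' MfAP/MfML to the targets, and update amplitudes and cutoffs
#' multiplicatively until all four are within `tol` relative error (the
#' velocity and area measures follow from the same amplitude/bandwidth
#' parameters and are not matched separately). Matches first moments only.
#'
#' @param targets Data.frame with columns `condition`, `mean_ap`, `mean_ml`,
#'   `mf_ap`, `mf_ml` (default [cop_condition_targets()]).
#' @param tol Relative tolerance on the matched means (default 0.02).
#' @param max_iter Iteration budget (default 12).
#' @param n_participants,trials_per_condition Simulation size per iteration.
#' @param seed Calibration seed.
#' @param tau,trial_cv Noise scales written into the returned params.
#' @return A calibrated [sway_params()]; attribute `calibration` holds the
#'   iteration diagnostics (final relative errors, converged flag). Fails
#'   with a diagnostic error if any target is non-positive; a non-converged
#'   search returns with `converged = FALSE` in the diagnostics.
#' @export
calibrate_sway_params <- function(targets = cop_condition_targets(),
                                  tol = 0.02, max_iter = 15,
                                  n_participants = 24,
                                  trials_per_condition = 3,
                                  seed = 20201L, tau = 0.25,
                                  trial_cv = 0.1) {
  need <- c("condition", "mean_ap", "mean_ml", "mf_ap", "mf_ml")
  miss <- setdiff(need, names(targets))
  if (length(miss) > 0L) stop("targets missing columns: ",
                              paste(miss, collapse = ", "))
  tv <- as.matrix(targets[, need[-1]])
  if (any(!is.finite(tv)) || any(tv <= 0)) {
    stop("calibration targets must all be positive")
  }
  # Gaussian marginal: mean|x| = RMS * sqrt(2/pi); cutoff starts at the
  # target mean frequency and is refined multiplicatively.
  conds <- data.frame(
    condition = targets$condition,
    amp_ap = targets$mean_ap * sqrt(pi / 2),
    amp_ml = targets$mean_ml * sqrt(pi / 2),
    cutoff_ap = targets$mf_ap,
    cutoff_ml = targets$mf_ml
  )
  rel_err <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    par_it <- sway_params(conds, tau = 0, trial_cv = 0)
    cohort <- generate_cohort(par_it, n_participants = n_participants,
                              trials_per_condition = trials_per_condition,
                              seed = seed + it)
    long <- cohort_measures(cohort)
    est <- stats::aggregate(value ~ condition + measure, data = long, FUN = mean)
    get_est <- function(msr) {
      e <- est[est$measure == msr, ]
      e$value[match(targets$condition, e$condition)]
    }
    em <- cbind(get_est("mean_ap"), get_est("mean_ml"),
                get_est("mf_ap"), get_est("mf_ml"))
    rel_err <- abs(em - tv) / tv
    if (max(rel_err) <= tol) { converged <- TRUE; break }
    conds$amp_ap <- conds$amp_ap * tv[, 1] / em[, 1]
    conds$amp_ml <- conds$amp_ml * tv[, 2] / em[, 2]
    conds$cutoff_ap <- conds$cutoff_ap * tv[, 3] / em[, 3]
    conds$cutoff_ml <- conds$cutoff_ml * tv[, 4] / em[, 4]
  }
  out <- sway_params(conds, tau = tau, trial_cv = trial_cv)
  attr(out, "calibration") <- list(
    converged = converged, iterations = it, tol = tol,
    max_rel_err = max(rel_err),
    rel_err = structure(rel_err,
                        dimnames = list(targets$condition,
                                        c("mean_ap", "mean_ml",
                                          "mf_ap", "mf_ml")))
  )
  if (!converged) {
    warning(sprintf(
      "calibration did not reach tol = %g in %d iterations (max rel err %.3f)",
      tol, max_iter, max(rel_err)))
  }
  out
}

#' Write calibrated parameters as a versioned YAML asset
#'
#' @param params A [sway_params()] object.
#' @param path Output YAML path.
#' @export
write_sway_params <- function(params, path) {
  stopifnot(inherits(params, "sway_params"))
  asset <- list(
    version = 1,
    tau = params$tau, trial_cv = params$trial_cv,
    sampling_rate = params$sampling_rate, duration = params$duration,
    conditions = lapply(seq_len(nrow(params$conditions)), function(i) {
      as.list(params$conditions[i, ])
    })
  )
  yaml::write_yaml(asset, path)
  invisible(path)
}

#' Visual-conflict surround motion profile
#'
#' Angle of the moving VR surround panels in the anteroposterior direction:
#' a sinusoid `theta(t) = A sin(2 pi f t)` whose frequency
#' `f = Vmax / (2 pi A)` is implied by the peak angle `A` (degrees) and the
#' peak angular velocity `Vmax` (degrees/s). Defaults A = 20 deg,
#' Vmax = 15 deg/s give f ~= 0.1194 Hz.
#'
#' @param amplitude Peak angle A in degrees (> 0), default 20.
#' @param peak_velocity Peak angular velocity in degrees/s (> 0), default 15.
#' @param duration Series length in seconds (default 60).
#' @param sampling_rate Hz (default 200).
#' @return List of class `surround_motion`: `time` (s), `angle` (degrees),
#'   `frequency` (Hz), `amplitude`, `peak_velocity`, `sampling_rate`.
#' @export
surround_motion <- function(amplitude = 20, peak_velocity = 15,
                            duration = 60, sampling_rate = 200) {
  if (!is.numeric(amplitude) || amplitude <= 0) stop("amplitude must be > 0")
  if (!is.numeric(peak_velocity) || peak_velocity <= 0) {
    stop("peak_velocity must be > 0")
  }
  f <- peak_velocity / (2 * pi * amplitude)
  t <- seq(0, duration, by = 1 / sampling_rate)
  structure(
    list(time = t, angle = amplitude * sin(2 * pi * f * t), frequency = f,
         amplitude = amplitude, peak_velocity = peak_velocity,
         sampling_rate = sampling_rate),
    class = "surround_motion"
  )
}

#' Back-compute a force-plate recording from a COP trajectory
#'
#' Inverse of [compute_cop()] under a constant vertical load and zero shear
#' (`fx = fy = 0`, `h = 0`): `my = -AP * fz / 1000`, `mx = ML * fz / 1000`.
#' Lets synthetic cohorts exercise the full force-plate ingestion path.
#'
#' @param traj A [cop_trajectory()].
#' @param fz Constant vertical load in newtons (default 700, a plausible
#'   body weight).
#' @return A [force_plate_recording()].
#' @export
as_force_recording <- function(traj, fz = 700) {
  stopifnot(inherits(traj, "cop_trajectory"))
  n <- length(traj$ap)
  zeros <- numeric(n)
  force_plate_recording(
    fx = zeros, fy = zeros, fz = rep(fz, n),
    mx = traj$ml / 1000 * fz,
    my = -traj$ap / 1000 * fz,
    mz = zeros,
    sampling_rate = traj$sampling_rate
  )
}
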