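#' Stabilometric measures
#'
#' The seven-measure battery summarising one COP trial: directional mean
#' distance (MeanAP, MeanML, mm), directional mean velocity (VelAP, VelML,
#' mm/s), the 95% confidence ellipse sway area (mm^2), and directional mean
#' sway frequency (MfAP, MfML, Hz). All require a centered trajectory;
#' centering is never applied silently.
#'
#' @name stabilometry
NULL

check_centered <- function(traj) {
  if (!inherits(traj, "cop_trajectory")) stop("expected a cop_trajectory")
  if (!traj$centered) {
    stop("trajectory is not centered; call center_trajectory() or ",
         "preprocess_trajectory() first")
  }
}

axis_series <- function(traj, axis) {
  axis <- match.arg(tolower(axis), c("ap", "ml"))
  traj[[axis]]
}

#' Mean distance from the mean COP
#'
#' Average absolute displacement from the mean COP along one axis:
#' `mean(|x_i|)` on the centered series.
#'
#' @param traj A centered [cop_trajectory()] with at least 2 samples.
#' @param axis `"ap"` or `"ml"`.
#' @return Mean distance in mm (non-negative).
#' @export
mean_distance <- function(traj, axis) {
  check_centered(traj)
  x <- axis_series(traj, axis)
  if (length(x) < 2L) stop("need at least 2 samples")
  mean(abs(x))
}

#' Mean COP velocity
#'
#' Total excursion (sum of absolute sample-to-sample increments) divided by
#' the trial duration `(N - 1)/sampling_rate`: path length has `N - 1`
#' increments.
#'
#' @inheritParams mean_distance
#' @return Mean velocity in mm/s (non-negative).
#' @export
mean_velocity <- function(traj, axis) {
  if (!inherits(traj, "cop_trajectory")) stop("expected a cop_trajectory")
  x <- axis_series(traj, axis)
  if (length(x) < 2L) stop("need at least 2 samples to compute velocity")
  sum(abs(diff(x))) / ((length(x) - 1L) / traj$sampling_rate)
}

#' 95% confidence ellipse sway area
#'
#' Area of the bivariate prediction ellipse expected to enclose ~95% of COP
#' points: `2 * pi * F * sqrt(s_ap^2 * s_ml^2 - s_apml^2)`, where `F` is the
#' 0.95 quantile of the F(2, N-2) distribution (about 3.00 for large N) and
#' the s terms are the sample (co)variances of the centered path. Semi-axis
#' lengths are `sqrt(2 * F * lambda_i)` for the covariance eigenvalues
#' `lambda_i`, and the orientation is the angle of the major axis from the
#' ML axis.
#'
#' @param traj A centered [cop_trajectory()] with at least 3 samples.
#' @param conf Ellipse coverage level (default 0.95).
#' @return A list of class `cop_ellipse`: `area` (mm^2), `semi_axes`
#'   (major, minor, mm), `angle_rad`, `cov` (2x2), `f_crit`, and a
#'   `degenerate` flag. A collinear path yields `degenerate = TRUE` with
#'   area 0.
#' @export
ellipse_area_95 <- function(traj, conf = 0.95) {
  check_centered(traj)
  n <- length(traj$ap)
  if (n < 3L) stop("need at least 3 samples for the confidence ellipse")
  S <- stats::cov(cbind(traj$ap, traj$ml))
  f_crit <- stats::qf(conf, 2, n - 2)
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  scale2 <- max(S[1, 1], S[2, 2])
  degenerate <- !is.finite(det_s) || det_s <= 0 ||
    (scale2 > 0 && det_s / scale2^2 < 1e-12)
  if (degenerate) {
    return(structure(list(area = 0, semi_axes = c(NA_real_, NA_real_),
                          angle_rad = NA_real_, cov = S, f_crit = f_crit,
                          n = n, degenerate = TRUE),
                     class = "cop_ellipse"))
  }
  eig <- eigen(S, symmetric = TRUE)
  semi <- sqrt(2 * f_crit * eig$values)
  angle <- atan2(eig$vectors[1, 1], eig$vectors[2, 1])
  structure(
    list(area = 2 * pi * f_crit * sqrt(det_s),
         semi_axes = semi, angle_rad = angle, cov = S, f_crit = f_crit,
         n = n, degenerate = FALSE),
    class = "cop_ellipse"
  )
}

#' @export
print.cop_ellipse <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate (collinear) COP path: ellipse area 0\n")
  } else {
    cat(sprintf(
      "95%% confidence ellipse: area %.2f mm^2, semi-axes %.2f x %.2f mm\n",
      x$area, x$semi_axes[1], x$semi_axes[2]))
  }
  invisible(x)
}

#' Directional mean sway frequency
#'
#' Frequency (Hz) of the sinusoid whose path length matches the observed
#' directional excursion relative to the mean distance, in the directional
#' convention `Mf = Vel / (4 * sqrt(2) * MeanDist)`. For a pure sinusoid of
#' frequency f this evaluates to `(pi / (2 * sqrt(2))) * f ~= 1.1107 f`.
#' A zero mean distance (constant series) makes the measure undefined and
#' returns `NA` rather than failing.
#'
#' @inheritParams mean_distance
#' @param const Denominator constant; default `4 * sqrt(2)` (directional
#'   convention). Exposed for sensitivity analysis only.
#' @return Mean frequency in Hz, or `NA_real_` when undefined.
#' @export
mean_frequency <- function(traj, axis, const = 4 * sqrt(2)) {
  check_centered(traj)
  md <- mean_distance(traj, axis)
  if (md == 0) return(NA_real_)
  mean_velocity(traj, axis) / (const * md)
}

#' Compute the full measure battery for one trial
#'
#' @param traj A preprocessed (centered) [cop_trajectory()].
#' @param condition,trial Optional labels attached to the result (taken from
#'   the trajectory's attributes when present).
#' @inheritParams mean_frequency
#' @return An object of class `measure_battery`: named list with `mean_ap`,
#'   `mean_ml`, `vel_ap`, `vel_ml`, `area95`, `mf_ap`, `mf_ml` plus
#'   `n_samples`, `duration`, labels, and a character vector `flags` naming
#'   any undefined measures.
#' @export
measure_battery <- function(traj, condition = attr(traj, "condition"),
                            trial = attr(traj, "trial"),
                            const = 4 * sqrt(2)) {
  check_centered(traj)
  ell <- ellipse_area_95(traj)
  out <- list(
    mean_ap = mean_distance(traj, "ap"),
    mean_ml = mean_distance(traj, "ml"),
    vel_ap = mean_velocity(traj, "ap"),
    vel_ml = mean_velocity(traj, "ml"),
    area95 = ell$area,
    mf_ap = mean_frequency(traj, "ap", const = const),
    mf_ml = mean_frequency(traj, "ml", const = const),
    n_samples = length(traj$ap),
    duration = traj$duration,
    condition = if (is.null(condition)) NA_integer_ else condition,
    trial = if (is.null(trial)) NA_integer_ else trial
  )
  flags <- character(0)
  if (is.na(out$mf_ap)) flags <- c(flags, "mf_ap_undefined")
  if (is.na(out$mf_ml)) flags <- c(flags, "mf_ml_undefined")
  if (ell$degenerate) flags <- c(flags, "area_degenerate")
  out$flags <- flags
  class(out) <- "measure_battery"
  out
}

#' @export
print.measure_battery <- function(x, ...) {
  cat(sprintf(
    paste0("COP measures (%d samples, %.2f s):\n",
           "  MeanAP %.3f mm   MeanML %.3f mm\n",
           "  VelAP  %.3f mm/s VelML  %.3f mm/s\n",
           "  95%%Area %.3f mm^2  MfAP %.4f Hz  MfML %.4f Hz\n"),
    x$n_samples, x$duration, x$mean_ap, x$mean_ml, x$vel_ap, x$vel_ml,
    x$area95, x$mf_ap, x$mf_ml))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

measure_fields <- c("mean_ap", "mean_ml", "vel_ap", "vel_ml",
                    "area95", "mf_ap", "mf_ml")

#' Aggregate trial batteries into one participant-condition battery
#'
#' Per-field arithmetic mean across trials. Undefined-measure flags
#' propagate: if any trial's measure is undefined, the aggregate field is
#' `NA` and carries the flag.
#'
#' @param batteries Non-empty list of [measure_battery()] objects from the
#'   same participant and condition.
#' @return A `measure_battery` with averaged fields.
#' @export
aggregate_batteries <- function(batteries) {
  if (length(batteries) == 0L) stop("cannot aggregate an empty trial list")
  stopifnot(all(vapply(batteries, inherits, logical(1), "measure_battery")))
  out <- batteries[[1L]]
  for (f in measure_fields) {
    vals <- vapply(batteries, function(b) b[[f]], numeric(1))
    out[[f]] <- if (anyNA(vals)) NA_real_ else mean(vals)
  }
  out$n_samples <- sum(vapply(batteries, function(b) b$n_samples, numeric(1)))
  out$duration <- sum(vapply(batteries, function(b) b$duration, numeric(1)))
  out$trial <- NA_integer_
  out$flags <- sort(unique(unlist(lapply(batteries, function(b) b$flags))))
  out
}

#' Convert batteries to the long measures table
#'
#' The canonical long-format hand-off to the statistics layer: one row per
#' (participant, condition, trial, measure) with a `flag` column.
#'
#' @param batteries List of [measure_battery()] objects.
#' @param participants Vector of participant ids, one per battery.
#' @return A data.frame with columns
#'   `participant,condition,trial,measure,value,flag`.
#' @export
measures_long <- function(batteries, participants) {
  stopifnot(length(batteries) == length(participants))
  rows <- lapply(seq_along(batteries), function(i) {
    b <- batteries[[i]]
    data.frame(
      participant = participants[i],
      condition = b$condition,
      trial = b$trial,
      measure = measure_fields,
      value = vapply(b[measure_fields], identity, numeric(1)),
      flag = vapply(measure_fields, function(f) {
        if (f %in% c("mf_ap", "mf_ml") && is.na(b[[f]])) "undefined"
        else if (f == "area95" && "area_degenerate" %in% b$flags) "degenerate"
        else ""
      }, character(1)),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}
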