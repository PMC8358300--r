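#' Force-plate recording
#'
#' Container for raw force-plate channels sampled at a uniform rate. Forces
#' are in newtons, moments in newton-meters about the plate's sensor origin,
#' which may sit a vertical distance `h` below the plate surface (AMTI-class
#' plates report moments about a sub-surface origin).
#'
#' @param fx,fy,fz Force channels (N). `fz` is the vertical load.
#' @param mx,my,mz Moment channels (N·m).
#' @param sampling_rate Sampling frequency in Hz (must be > 0).
#' @param time Optional time vector in seconds; if supplied it must be
#'   strictly increasing and uniform at `1/sampling_rate` within 1e-6 s.
#' @param h Vertical distance (m) from the plate surface to the sensor
#'   origin. Default 0 (surface-origin plate).
#' @param axis_map Mapping from plate COP components to body axes. A list
#'   with entries `ap` and `ml`, each `"x"` or `"y"` (which plate component
#'   feeds that body axis), and `ap_sign`/`ml_sign` (+1 or -1). The plate
#'   components are COPx = (-My - Fx*h)/Fz and COPy = (Mx - Fy*h)/Fz. The
#'   default maps AP to COPx and ML to COPy with positive signs.
#' @return An object of class `force_plate_recording`.
#' @seealso [compute_cop()]
#' @export
force_plate_recording <- function(fx, fy, fz, mx, my, mz, sampling_rate,
                                  time = NULL, h = 0,
                                  axis_map = default_axis_map()) {
  chans <- list(fx = fx, fy = fy, fz = fz, mx = mx, my = my, mz = mz)
  lens <- vapply(chans, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("force/moment channels differ in length: ",
         paste(sprintf("%s=%d", names(lens), lens), collapse = ", "))
  }
  n <- lens[[1L]]
  if (n < 2L) stop("a recording needs at least 2 samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)")
  }
  if (is.null(time)) {
    time <- (seq_len(n) - 1L) / sampling_rate
  } else {
    if (length(time) != n) stop("time vector length does not match channels")
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (any(abs(dt - 1 / sampling_rate) > 1e-6)) {
      stop("time is not uniform at 1/sampling_rate (tolerance 1e-6 s)")
    }
  }
  axis_map <- validate_axis_map(axis_map)
  structure(
    list(time = as.numeric(time),
         fx = as.numeric(fx), fy = as.numeric(fy), fz = as.numeric(fz),
         mx = as.numeric(mx), my = as.numeric(my), mz = as.numeric(mz),
         sampling_rate = sampling_rate, h = h, axis_map = axis_map),
    class = "force_plate_recording"
  )
}

#' @rdname force_plate_recording
#' @export
default_axis_map <- function() {
  list(ap = "x", ml = "y", ap_sign = 1, ml_sign = 1)
}

validate_axis_map <- function(axis_map) {
  stopifnot(is.list(axis_map))
  am <- utils::modifyList(default_axis_map(), axis_map)
  if (!am$ap %in% c("x", "y") || !am$ml %in% c("x", "y") || am$ap == am$ml) {
    stop("axis_map$ap and axis_map$ml must be 'x' and 'y' (one each)")
  }
  if (!am$ap_sign %in% c(-1, 1) || !am$ml_sign %in% c(-1, 1)) {
    stop("axis_map signs must be +1 or -1")
  }
  am
}

#' COP trajectory
#'
#' A 2-D center-of-pressure path in millimeters: anteroposterior (AP,
#' front-back) and mediolateral (ML, side-to-side) displacement series at a
#' uniform sampling rate. Most stabilometric measures require a *centered*
#' trajectory (per-axis mean removed); see [center_trajectory()].
#'
#' @param ap,ml Displacement series in mm (equal length).
#' @param sampling_rate Sampling frequency in Hz.
#' @param centered Logical; whether the per-axis means have been removed.
#' @return An object of class `cop_trajectory` with fields `ap`, `ml`,
#'   `sampling_rate`, `centered` and a `duration` of `(n - 1)/sampling_rate`
#'   seconds.
#' @export
cop_trajectory <- function(ap, ml, sampling_rate, centered = FALSE) {
  if (length(ap) != length(ml)) {
    stop("ap and ml series differ in length (", length(ap), " vs ",
         length(ml), ")")
  }
  if (length(ap) < 1L) stop("empty trajectory")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  if (isTRUE(centered)) {
    if (abs(mean(ap)) > 1e-9 || abs(mean(ml)) > 1e-9) {
      stop("trajectory marked centered but axis means exceed 1e-9 mm")
    }
  }
  structure(
    list(ap = as.numeric(ap), ml = as.numeric(ml),
         sampling_rate = sampling_rate,
         duration = (length(ap) - 1L) / sampling_rate,
         centered = isTRUE(centered)),
    class = "cop_trajectory"
  )
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf("COP trajectory: %d samples @ %g Hz (%.3f s)%s\n",
              length(x$ap), x$sampling_rate, x$duration,
              if (x$centered) ", centered" else ""))
  invisible(x)
}

#' Derive the COP trajectory from force-plate channels
#'
#' Applies the moment-balance formula for a plate whose sensor origin sits a
#' vertical distance `h` below the surface: COPx = (-My - Fx*h)/Fz and
#' COPy = (Mx - Fy*h)/Fz (meters), then maps the two components onto the AP
#' and ML body axes through the recording's `axis_map` and converts to mm.
#' The result is *uncentered*; call [center_trajectory()] (or
#' [preprocess_trajectory()]) before computing measures.
#'
#' @param rec A [force_plate_recording()].
#' @param fz_min Unloaded-plate guard: every sample must satisfy
#'   `|fz| > fz_min` (N). Default 10 N.
#' @return An uncentered [cop_trajectory()] in mm.
#' @examples
#' rec <- force_plate_recording(fx = c(0, 0), fy = c(0, 0),
#'                              fz = c(700, 700), mx = c(1.4, 1.4),
#'                              my = c(-3.5, -3.5), mz = c(0, 0),
#'                              sampling_rate = 200)
#' traj <- compute_cop(rec)  # AP = 5 mm, ML = 2 mm at every sample
#' @export
compute_cop <- function(rec, fz_min = 10) {
  stopifnot(inherits(rec, "force_plate_recording"))
  bad <- which(abs(rec$fz) <= fz_min)
  if (length(bad) > 0L) {
    stop(sprintf(
      "unloaded plate: |fz| <= %g N at sample %d (%d offending samples)",
      fz_min, bad[1L], length(bad)))
  }
  cop <- list(
    x = (-rec$my - rec$fx * rec$h) / rec$fz,
    y = ( rec$mx - rec$fy * rec$h) / rec$fz
  )
  am <- rec$axis_map
  cop_trajectory(
    ap = am$ap_sign * cop[[am$ap]] * 1000,
    ml = am$ml_sign * cop[[am$ml]] * 1000,
    sampling_rate = rec$sampling_rate,
    centered = FALSE
  )
}

#' Center a COP trajectory
#'
#' Removes the per-axis mean so distances are measured from the mean COP.
#' Idempotent: centering a centered trajectory changes nothing.
#'
#' @param traj A [cop_trajectory()].
#' @return The centered trajectory with `centered = TRUE`.
#' @export
center_trajectory <- function(traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  cop_trajectory(
    ap = traj$ap - mean(traj$ap),
    ml = traj$ml - mean(traj$ml),
    sampling_rate = traj$sampling_rate,
    centered = TRUE
  )
}

#' Trial schedule for a multi-condition protocol
#'
#' Describes the timing grid of a sensory-organization session: by default
#' 6 conditions x 3 trials of 20 s with 5-s breaks between consecutive
#' trials.
#'
#' @param n_conditions Number of conditions (default 6).
#' @param trials_per_condition Trials per condition (default 3).
#' @param trial_duration Trial length in seconds (default 20).
#' @param inter_trial_break Break between consecutive trials in seconds
#'   (default 5).
#' @return An object of class `trial_schedule`; its `total_duration` field
#'   gives the full session length in seconds.
#' @export
trial_schedule <- function(n_conditions = 6, trials_per_condition = 3,
                           trial_duration = 20, inter_trial_break = 5) {
  vals <- c(n_conditions, trials_per_condition, trial_duration,
            inter_trial_break)
  if (any(!is.finite(vals)) || any(vals[1:3] <= 0) || inter_trial_break < 0) {
    stop("schedule fields must be positive (break may be 0)")
  }
  n_trials <- n_conditions * trials_per_condition
  structure(
    list(n_conditions = n_conditions,
         trials_per_condition = trials_per_condition,
         trial_duration = trial_duration,
         inter_trial_break = inter_trial_break,
         total_duration = n_trials * trial_duration +
           (n_trials - 1) * inter_trial_break),
    class = "trial_schedule"
  )
}

#' Segment a continuous recording into labeled trial windows
#'
#' Cuts a continuous COP trajectory (or force-plate recording, which is first
#' passed through [compute_cop()]) into per-trial windows. Windows follow the
#' half-open convention `[t0, t0 + trial_duration)` at integer sample
#' boundaries, so each trial holds exactly `round(trial_duration *
#' sampling_rate)` samples and no sample is shared between trials.
#'
#' Without explicit `start_times`, trials are laid out on the schedule grid:
#' trial k (0-based, condition-major) starts at
#' `k * (trial_duration + inter_trial_break)` seconds. With explicit markers,
#' one window per marker is cut and labels follow the schedule enumeration.
#'
#' @param x A [cop_trajectory()] or [force_plate_recording()].
#' @param schedule A [trial_schedule()].
#' @param start_times Optional explicit trial-onset times in seconds;
#'   overlapping windows are an error.
#' @return A list of uncentered-state-preserving [cop_trajectory()] objects,
#'   each carrying `condition` and `trial` attributes (conditions enumerate
#'   1..n_conditions, trials 1..trials_per_condition).
#' @export
segment_trials <- function(x, schedule = trial_schedule(),
                           start_times = NULL) {
  if (inherits(x, "force_plate_recording")) x <- compute_cop(x)
  stopifnot(inherits(x, "cop_trajectory"), inherits(schedule, "trial_schedule"))
  fs <- x$sampling_rate
  n <- length(x$ap)
  win <- round(schedule$trial_duration * fs)

  if (is.null(start_times)) {
    k <- schedule$n_conditions * schedule$trials_per_condition
    start_times <- (seq_len(k) - 1L) *
      (schedule$trial_duration + schedule$inter_trial_break)
  } else {
    st <- sort(start_times)
    if (any(diff(st) < schedule$trial_duration)) {
      stop("overlapping trial windows: markers closer than trial_duration")
    }
  }
  start_idx <- round(start_times * fs) + 1L
  end_idx <- start_idx + win - 1L
  if (any(end_idx > n)) {
    need <- max(start_times) + schedule$trial_duration
    stop(sprintf(
      "recording too short: need %.2f s, have %.4f s",
      need, n / fs))
  }
  tpc <- schedule$trials_per_condition
  out <- vector("list", length(start_times))
  for (i in seq_along(start_times)) {
    idx <- start_idx[i]:end_idx[i]
    tr <- cop_trajectory(x$ap[idx], x$ml[idx], fs, centered = FALSE)
    attr(tr, "condition") <- ((i - 1L) %/% tpc) + 1L
    attr(tr, "trial") <- ((i - 1L) %% tpc) + 1L
    out[[i]] <- tr
  }
  out
}

#' Preprocess a COP trajectory
#'
#' Optional zero-phase low-pass filtering (4th-order Butterworth applied
#' forward and backward via [signal::filtfilt()]) followed by centering.
#' The default applies *no* filter, only centering, which reproduces raw
#' stabilogram processing; a filter can be enabled for noisy hardware.
#'
#' @param traj A [cop_trajectory()].
#' @param filter_spec `NULL` (no filtering, the default) or a list with
#'   `cutoff` (Hz, must be below Nyquist) and optional `order` (default 4).
#' @return A centered [cop_trajectory()].
#' @export
preprocess_trajectory <- function(traj, filter_spec = NULL) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (!is.null(filter_spec)) {
    cutoff <- filter_spec$cutoff
    ord <- if (is.null(filter_spec$order)) 4L else filter_spec$order
    nyq <- traj$sampling_rate / 2
    if (is.null(cutoff) || !is.numeric(cutoff) || cutoff <= 0 ||
        cutoff >= nyq) {
      stop(sprintf("filter cutoff must lie in (0, %g) Hz (Nyquist)", nyq))
    }
    bf <- signal::butter(ord, cutoff / nyq, type = "low")
    traj <- cop_trajectory(
      ap = signal::filtfilt(bf, traj$ap),
      ml = signal::filtfilt(bf, traj$ml),
      sampling_rate = traj$sampling_rate,
      centered = FALSE
    )
  }
  center_trajectory(traj)
}

# ---- CSV input/output ------------------------------------------------------

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a force-plate CSV
#'
#' Expects header-named columns `time,fx,fy,fz,mx,my,mz` in SI units
#' (seconds, newtons, newton-meters); comma or tab separated (auto-detected).
#'
#' @param path File path.
#' @param sampling_rate Hz; if `NULL`, inferred from the median time step.
#' @inheritParams force_plate_recording
#' @return A [force_plate_recording()].
#' @export
read_force_csv <- function(path, sampling_rate = NULL, h = 0,
                           axis_map = default_axis_map()) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path))
  need <- c("time", "fx", "fy", "fz", "mx", "my", "mz")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("force CSV missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / stats::median(diff(df$time))
  }
  force_plate_recording(fx = df$fx, fy = df$fy, fz = df$fz,
                        mx = df$mx, my = df$my, mz = df$mz,
                        sampling_rate = sampling_rate, time = df$time,
                        h = h, axis_map = axis_map)
}

#' Read / write a COP CSV
#'
#' Column convention `time_s,cop_ap_mm,cop_ml_mm`.
#'
#' @param path File path.
#' @param sampling_rate Hz; if `NULL`, inferred from the median time step.
#' @return `read_cop_csv()` returns an uncentered [cop_trajectory()];
#'   `write_cop_csv()` invisibly returns `path`.
#' @export
read_cop_csv <- function(path, sampling_rate = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path))
  need <- c("time_s", "cop_ap_mm", "cop_ml_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("COP CSV missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(diff(df$time_s))
  cop_trajectory(df$cop_ap_mm, df$cop_ml_mm, sampling_rate)
}

#' @rdname read_cop_csv
#' @param traj A [cop_trajectory()] to write.
#' @export
write_cop_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cop_trajectory"))
  n <- length(traj$ap)
  df <- data.frame(
    time_s = (seq_len(n) - 1L) / traj$sampling_rate,
    cop_ap_mm = traj$ap,
    cop_ml_mm = traj$ml
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
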