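test_that("COP derivation matches the moment-balance formula", {
  rec <- force_plate_recording(fx = c(0, 0), fy = c(0, 0), fz = c(700, 700),
                               mx = c(1.4, 1.4), my = c(-3.5, -3.5),
                               mz = c(0, 0), sampling_rate = 200)
  tr <- compute_cop(rec)
  expect_equal(tr$ap, c(5, 5))
  expect_equal(tr$ml, c(2, 2))
  expect_false(tr$centered)

  # sensor-origin offset: AP = (-my - fx*h)/fz
  rec2 <- force_plate_recording(fx = c(70, 70), fy = c(0, 0),
                                fz = c(700, 700), mx = c(0, 0),
                                my = c(-3.5, -3.5), mz = c(0, 0),
                                sampling_rate = 200, h = 0.01)
  expect_equal(compute_cop(rec2)$ap, c(4, 4))

  # all moments zero -> identically zero path
  rec0 <- force_plate_recording(fx = c(0, 0), fy = c(0, 0), fz = c(700, 700),
                                mx = c(0, 0), my = c(0, 0), mz = c(0, 0),
                                sampling_rate = 200)
  tr0 <- compute_cop(rec0)
  expect_equal(tr0$ap, c(0, 0))
  expect_equal(tr0$ml, c(0, 0))
})

test_that("COP derivation is homogeneous in the moments and guards fz", {
  set.seed(3)
  n <- 50
  mk <- function(scale) force_plate_recording(
    fx = numeric(n), fy = numeric(n), fz = rep(700, n),
    mx = scale * sin(1:n), my = scale * cos(1:n), mz = numeric(n),
    sampling_rate = 200)
  t1 <- compute_cop(mk(1)); t3 <- compute_cop(mk(3))
  expect_equal(t3$ap, 3 * t1$ap)
  expect_equal(t3$ml, 3 * t1$ml)

  bad <- force_plate_recording(fx = c(0, 0), fy = c(0, 0), fz = c(700, 5),
                               mx = c(0, 0), my = c(0, 0), mz = c(0, 0),
                               sampling_rate = 200)
  expect_error(compute_cop(bad), "unloaded plate.*sample 2")
})

test_that("axis_map can swap components and flip signs", {
  rec <- force_plate_recording(
    fx = c(0, 0), fy = c(0, 0), fz = c(700, 700),
    mx = c(1.4, 1.4), my = c(-3.5, -3.5), mz = c(0, 0),
    sampling_rate = 200,
    axis_map = list(ap = "y", ml = "x", ml_sign = -1))
  tr <- compute_cop(rec)
  expect_equal(tr$ap, c(2, 2))
  expect_equal(tr$ml, c(-5, -5))
  expect_error(
    force_plate_recording(fx = 0:1, fy = 0:1, fz = c(700, 700), mx = 0:1,
                          my = 0:1, mz = 0:1, sampling_rate = 200,
                          axis_map = list(ap = "x", ml = "x")),
    "axis_map")
})

test_that("recording validation rejects malformed inputs", {
  expect_error(force_plate_recording(fx = 1:3, fy = 1:2, fz = c(700, 700),
                                     mx = 1:2, my = 1:2, mz = 1:2,
                                     sampling_rate = 200),
               "differ in length")
  expect_error(force_plate_recording(fx = 1:2, fy = 1:2, fz = c(700, 700),
                                     mx = 1:2, my = 1:2, mz = 1:2,
                                     sampling_rate = 200,
                                     time = c(0, 0.004)),
               "not uniform")
  expect_error(force_plate_recording(fx = 1:2, fy = 1:2, fz = c(700, 700),
                                     mx = 1:2, my = 1:2, mz = 1:2,
                                     sampling_rate = -1),
               "sampling_rate")
})

test_that("centering removes the mean, is idempotent, and maps constants to zero", {
  tr <- cop_trajectory(c(1, 2, 3), c(5, 5, 5), 200)
  c1 <- center_trajectory(tr)
  expect_equal(c1$ap, c(-1, 0, 1))
  expect_equal(c1$ml, c(0, 0, 0))
  expect_true(c1$centered)
  c2 <- center_trajectory(c1)
  expect_equal(c2$ap, c1$ap)
  expect_equal(c2$ml, c1$ml)
})

test_that("segmentation follows the half-open schedule grid", {
  fs <- 200
  sched <- trial_schedule()  # 6 x 3 x 20 s, 5-s breaks
  n <- round(sched$total_duration * fs) + 1L
  x <- cop_trajectory(seq_len(n), seq_len(n), fs)
  trials <- segment_trials(x, sched)
  expect_length(trials, 18L)
  expect_true(all(vapply(trials, function(t) length(t$ap), numeric(1)) ==
                    round(20 * fs)))
  labs <- t(vapply(trials, function(t) c(attr(t, "condition"),
                                         attr(t, "trial")), numeric(2)))
  expect_equal(labs[, 1], rep(1:6, each = 3))
  expect_equal(labs[, 2], rep(1:3, times = 6))

  # windows partition: no sample index appears twice
  idx <- unlist(lapply(seq_along(trials), function(i) {
    start <- round(((i - 1) * 25) * fs) + 1
    start:(start + 20 * fs - 1)
  }))
  expect_equal(anyDuplicated(idx), 0L)
  # trial content matches the source samples exactly
  expect_equal(trials[[2]]$ap, x$ap[(25 * fs + 1):(45 * fs)])
})

test_that("segmentation with markers and degenerate inputs", {
  fs <- 100
  x <- cop_trajectory(rnorm(70 * fs + 1), rnorm(70 * fs + 1), fs)
  one_cond <- trial_schedule(n_conditions = 1)
  trials <- segment_trials(x, one_cond)
  expect_length(trials, 3L)

  marked <- segment_trials(x, one_cond, start_times = c(0, 25, 50))
  expect_length(marked, 3L)
  expect_error(segment_trials(x, one_cond, start_times = c(0, 10, 50)),
               "overlapping")

  short <- cop_trajectory(rnorm(10 * fs), rnorm(10 * fs), fs)
  expect_error(segment_trials(short, trial_schedule()), "too short")
})

test_that("preprocessing defaults to centering only; optional filter shapes spectrum", {
  fs <- 200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  tr <- cop_trajectory(sin(2 * pi * 1 * t) + 2, cos(2 * pi * 1 * t), fs)
  def <- preprocess_trajectory(tr)
  ctr <- center_trajectory(tr)
  expect_equal(def$ap, ctr$ap)
  expect_equal(def$ml, ctr$ml)

  # 10 Hz low-pass: 1 Hz passes (within 1%), 50 Hz attenuated > 90% in RMS
  lo <- cop_trajectory(sin(2 * pi * 1 * t), sin(2 * pi * 50 * t), fs)
  f10 <- preprocess_trajectory(lo, filter_spec = list(cutoff = 10))
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(f10$ap), rms(center_trajectory(lo)$ap), tolerance = 0.01)
  expect_lt(rms(f10$ml), 0.1 * rms(center_trajectory(lo)$ml))

  expect_error(preprocess_trajectory(lo, filter_spec = list(cutoff = 120)),
               "Nyquist")
})

test_that("force and COP CSV readers round-trip, with dialect detection", {
  fs <- 200
  tr <- gaussian_traj(n = 100, fs = fs, seed = 11)
  f <- tempfile(fileext = ".csv")
  write_cop_csv(tr, f)
  back <- read_cop_csv(f)
  expect_equal(back$ap, tr$ap, tolerance = 1e-12)
  expect_equal(back$sampling_rate, fs, tolerance = 1e-9)

  # force CSV (tab-separated) through the full ingestion path
  rec <- as_force_recording(tr)
  df <- data.frame(time = rec$time, fx = rec$fx, fy = rec$fy, fz = rec$fz,
                   mx = rec$mx, my = rec$my, mz = rec$mz)
  ft <- tempfile(fileext = ".tsv")
  write.table(df, ft, sep = "\t", row.names = FALSE, quote = FALSE)
  rec2 <- read_force_csv(ft)
  tr2 <- compute_cop(rec2)
  expect_equal(tr2$ap, tr$ap, tolerance = 1e-9)
  expect_equal(tr2$ml, tr$ml, tolerance = 1e-9)

  expect_error(read_force_csv(f), "missing columns")
})
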