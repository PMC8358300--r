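# Independent brute-force recomputation of every stabilometric measure,
# written as literal loops over the definitions. This code path shares
# nothing with the package implementation beyond base arithmetic and is the
# reference the vectorised implementation is checked against.
oracle_battery <- function(ap, ml, fs) {
  n <- length(ap)
  ap <- ap - sum(ap) / n
  ml <- ml - sum(ml) / n

  mdist <- function(x) {
    s <- 0
    for (v in x) s <- s + abs(v)
    s / length(x)
  }
  mvel <- function(x) {
    s <- 0
    for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
    s / ((length(x) - 1) / fs)
  }
  sap2 <- 0; sml2 <- 0; sapml <- 0
  for (i in seq_len(n)) {
    sap2 <- sap2 + ap[i]^2
    sml2 <- sml2 + ml[i]^2
    sapml <- sapml + ap[i] * ml[i]
  }
  sap2 <- sap2 / (n - 1); sml2 <- sml2 / (n - 1); sapml <- sapml / (n - 1)
  f_crit <- qf(0.95, 2, n - 2)
  area <- 2 * pi * f_crit * sqrt(sap2 * sml2 - sapml^2)

  m_ap <- mdist(ap); m_ml <- mdist(ml)
  v_ap <- mvel(ap); v_ml <- mvel(ml)
  list(
    mean_ap = m_ap, mean_ml = m_ml, vel_ap = v_ap, vel_ml = v_ml,
    area95 = area,
    mf_ap = if (m_ap > 0) v_ap / (4 * sqrt(2) * m_ap) else NA_real_,
    mf_ml = if (m_ml > 0) v_ml / (4 * sqrt(2) * m_ml) else NA_real_
  )
}

# Sinusoidal trajectory over an integer number of cycles (half-open grid).
sinusoid_traj <- function(amp_ap = 10, amp_ml = 10, f = 1, fs = 200,
                          duration = 20, phase_ml = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  center_trajectory(cop_trajectory(
    amp_ap * sin(2 * pi * f * t),
    amp_ml * sin(2 * pi * f * t + phase_ml), fs))
}

gaussian_traj <- function(n = 4000, sd_ap = 1, sd_ml = 1, fs = 200,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  center_trajectory(cop_trajectory(rnorm(n, 0, sd_ap), rnorm(n, 0, sd_ml), fs))
}

# Fraction of a trajectory's points inside a fitted confidence ellipse
# (Mahalanobis distance against 2 * F threshold).
ellipse_coverage <- function(ell, traj) {
  si <- solve(ell$cov)
  x <- cbind(traj$ap, traj$ml)
  d2 <- rowSums((x %*% si) * x)
  mean(d2 <= 2 * ell$f_crit)
}

# Small calibrated cohort measures table, memoised per test session.
cached_cohort_long <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) {
      cache <<- cohort_measures(generate_cohort(seed = seed))
    }
    cache
  }
})
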