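test_that("normality screen behaves on normal, bimodal, and constant samples", {
  normal_hits <- 0L; bimodal_hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    if (normality_screen(rnorm(23))$p_value > 0.05) {
      normal_hits <- normal_hits + 1L
    }
    spikes <- sample(c(-10, 10), 23, replace = TRUE) + rnorm(23, 0, 0.5)
    if (normality_screen(spikes)$p_value < 0.05) {
      bimodal_hits <- bimodal_hits + 1L
    }
  }
  expect_gte(normal_hits, 90L)
  expect_gte(bimodal_hits, 90L)

  const <- normality_screen(rep(3, 23))
  expect_true(const$degenerate)
  expect_error(normality_screen(c(1, 2)), "3 <= n")
})

test_that("Friedman statistic equals hand values and base R on ranked blocks", {
  concordant <- matrix(c(1, 2, 3, 10, 20, 30, 0.1, 0.2, 0.3),
                       nrow = 3, byrow = TRUE)
  res <- friedman_omnibus(concordant)
  expect_equal(res$chi2_f, 6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(6, 2, lower.tail = FALSE))

  # constant-within-block table: statistic 0, p 1 under tie correction
  flat <- matrix(5, nrow = 4, ncol = 3)
  res0 <- friedman_omnibus(flat)
  expect_equal(res0$chi2_f, 0)
  expect_equal(res0$p_value, 1)

  # agreement with stats::friedman.test on random data with and without ties
  set.seed(2024)
  for (rep in 1:10) {
    m <- matrix(rnorm(23 * 6), 23, 6)
    if (rep > 5) m <- round(m, 1)  # force ties
    expect_equal(friedman_omnibus(m)$chi2_f,
                 unname(friedman.test(m)$statistic), tolerance = 1e-12)
    expect_equal(friedman_omnibus(m)$p_value,
                 friedman.test(m)$p.value, tolerance = 1e-12)
  }
})

test_that("Friedman is invariant to column permutation and monotone transforms", {
  set.seed(5)
  m <- matrix(rexp(20 * 4), 20, 4)
  base <- friedman_omnibus(m)$chi2_f
  expect_equal(friedman_omnibus(m[, c(3, 1, 4, 2)])$chi2_f, base)
  expect_equal(friedman_omnibus(exp(m))$chi2_f, base)
  expect_equal(friedman_omnibus(t(apply(m, 1, function(r) r^3)))$chi2_f, base)

  m[3, 2] <- NA
  expect_error(friedman_omnibus(m), "missing cells.*\\(3,2\\)")
})

test_that("Wilcoxon signed-rank: exact enumeration, symmetry, degenerate cases", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_equal(res$W, 15)
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$method, "exact")
  expect_equal(res$n_effective, 5L)

  # matches base R exact p on tie-free data
  set.seed(8)
  for (rep in 1:10) {
    d <- rnorm(10)
    mine <- wilcoxon_signed_rank(d, rep(0, 10), mode = "exact")
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }

  # sign flip: same p, same |z|
  d <- c(0.3, -1.2, 2.5, 0.7, -0.1, 1.1, 0.4)
  a <- wilcoxon_signed_rank(d, rep(0, 7))
  b <- wilcoxon_signed_rank(-d, rep(0, 7))
  expect_equal(a$p_value, b$p_value)
  expect_equal(abs(a$z_value), abs(b$z_value))

  # identical samples -> degenerate flagged result
  x <- rnorm(9)
  dg <- wilcoxon_signed_rank(x, x)
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
  expect_equal(dg$n_effective, 0L)
})

test_that("zero differences are discarded by default, kept under Pratt", {
  a <- c(5, 5, 5, 1, 2, 3, 4)
  b <- c(5, 5, 5, 0, 0, 0, 0)
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$n_effective, 4L)
  expect_equal(res$n_pairs, 7L)
  pratt <- wilcoxon_signed_rank(a, b, zero_method = "pratt")
  expect_equal(pratt$n_effective, 4L)
  # Pratt ranks |d| including zeros, so the rank sum is larger
  expect_gt(pratt$W, res$W)
})

test_that("exact and normal-approximation p-values agree for 8 <= n <= 15", {
  # the continuity-corrected approximation tracks the exact enumeration;
  # the uncorrected default is close but systematically anti-conservative
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(8:15, 1)
    d <- rnorm(n, mean = runif(1, -0.5, 0.5))
    pe <- wilcoxon_signed_rank(d, rep(0, n), mode = "exact")$p_value
    pa <- wilcoxon_signed_rank(d, rep(0, n), mode = "approx",
                               correct = TRUE)$p_value
    expect_lt(abs(pe - pa), 0.03)
  }
})

test_that("z matches the tie-corrected normal approximation used by SPSS-style tools", {
  set.seed(12)
  d <- round(rnorm(25), 1)  # ties likely
  res <- wilcoxon_signed_rank(d, rep(0, 25), mode = "approx")
  ref <- wilcox.test(d, exact = FALSE, correct = FALSE)
  # base R computes the same two-sided asymptotic p (zeros discarded, tie
  # corrected, no continuity correction)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(2 * pnorm(-abs(res$z_value)), res$p_value, tolerance = 1e-12)
})

test_that("permutation oracle reproduces exact Wilcoxon p and null behavior", {
  expect_equal(wilcoxon_permutation_p(c(1, 2, 3, 4, 5), rep(0, 5)), 0.0625)
  expect_equal(wilcoxon_permutation_p(c(2, 4), c(2, 4)), 1)

  # agreement with the exact test across random tie-free contrasts
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    d <- rnorm(n)
    expect_equal(wilcoxon_permutation_p(d, rep(0, n)),
                 wilcoxon_signed_rank(d, rep(0, n), mode = "exact")$p_value,
                 tolerance = 1e-12)
  }

  # null p-values behave like a (conservative, discrete) uniform
  ps <- vapply(1:300, function(s) {
    set.seed(s + 5000)
    d <- rnorm(12)
    wilcoxon_permutation_p(d, rep(0, 12))
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.5)) {
    expect_lte(mean(ps <= alpha), alpha + 0.05)
    expect_gte(mean(ps <= alpha), alpha - 0.06)
  }
})

test_that("Rosenthal effect size r = |Z|/sqrt(n)", {
  expect_equal(effect_size_r(2.4, 16), 0.6)
  expect_equal(effect_size_r(0, 23), 0)
  expect_equal(effect_size_r(-2.973, 23), 0.6199, tolerance = 1e-4)
  expect_error(effect_size_r(1, 0), "positive")

  # never exceeds the enumerable maximum |Z| for given n
  for (n in c(5, 10, 15)) {
    d <- seq_len(n)
    z <- wilcoxon_signed_rank(d, rep(0, n))$z_value
    expect_lte(effect_size_r(z, n), abs(z) / sqrt(n) + 1e-12)
  }
})

test_that("run_contrasts produces the four planned contrasts per measure", {
  long <- cached_cohort_long()
  ct <- run_contrasts(long)
  expect_equal(nrow(ct), 4 * 7)
  expect_setequal(unique(ct$contrast),
                  c("2_vs_1", "4_vs_1", "5_vs_1", "6_vs_5"))
  expect_true(all(ct$effect_r >= 0 & ct$effect_r <= 1))
  expect_true(all(ct$p_value > 0 & ct$p_value <= 1))

  # the foam contrasts on the calibrated cohort are strong
  foam <- ct[ct$measure == "mean_ap" & ct$contrast %in% c("4_vs_1", "5_vs_1"), ]
  expect_true(all(foam$p_value < 0.05))
  expect_true(all(foam$z > 0))
  expect_true(all(foam$effect_r >= 0.5))
})

test_that("a duplicated condition yields a degenerate flagged contrast", {
  long <- cached_cohort_long()
  dup <- long
  rows2 <- dup$condition == 2
  key <- paste(dup$participant, dup$trial, dup$measure)
  ref <- dup[dup$condition == 1, ]
  dup$value[rows2] <- ref$value[match(key[rows2],
                                      paste(ref$participant, ref$trial,
                                            ref$measure))]
  ct <- run_contrasts(dup)
  c21 <- ct[ct$contrast == "2_vs_1", ]
  expect_true(all(c21$flag == "degenerate"))
  expect_true(all(c21$p_value == 1))
  expect_true(all(c21$effect_r == 0))
})

test_that("flagged values are excluded listwise with counts reported", {
  long <- cached_cohort_long()
  long$flag[long$participant == 3 & long$condition == 1 &
              long$measure == "mf_ap"] <- "undefined"
  ct <- run_contrasts(long)
  r <- ct[ct$measure == "mf_ap" & ct$contrast == "4_vs_1", ]
  expect_equal(r$n_excluded, 1L)
  expect_equal(r$n_effective + r$n_excluded,
               length(unique(long$participant)))
  om <- run_omnibus(long)
  expect_equal(om$n_excluded[om$measure == "mf_ap"], 1L)
})

test_that("type-I error of the contrast is near nominal on null data", {
  # measure-level null cohorts: shared participant effect, no condition
  # effect; 1000 seeded replicates at alpha = 0.05
  rejections <- 0L
  for (s in 1:1000) {
    set.seed(s)
    eff <- exp(rnorm(23, 0, 0.25))
    a <- eff * exp(rnorm(23, 0, 0.3))
    b <- eff * exp(rnorm(23, 0, 0.3))
    if (wilcoxon_signed_rank(a, b)$p_value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_gte(rejections / 1000, 0.03)
  expect_lte(rejections / 1000, 0.07)
})
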