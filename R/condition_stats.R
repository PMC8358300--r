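#' Normality screen
#'
#' Shapiro-Wilk test on one condition's sample, reported for descriptive
#' purposes only; the analysis pipeline is nonparametric regardless of the
#' outcome. A constant sample is flagged degenerate instead of failing.
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @return List with `W`, `p_value`, `n`, `degenerate`.
#' @export
normality_screen <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(values) == 0) {
    return(list(W = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value, n = n,
       degenerate = FALSE)
}

#' Friedman omnibus test over repeated conditions
#'
#' Within-block (participant) midranks across k conditions, with the
#' tie-corrected statistic
#' `chi2_F = (k - 1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` where `R_j` are
#' column rank sums, `A` the sum of squared ranks and `C = n k (k+1)^2 / 4`.
#' Without ties this reduces to the classic
#' `12/(n k (k+1)) * sum R_j^2 - 3 n (k+1)`. When every block is constant
#' (A == C) the statistic is defined as 0 with p = 1. The p-value uses the
#' chi-squared(k-1) asymptotic.
#'
#' @param table Numeric matrix or data.frame, rows = blocks (participants),
#'   columns = conditions. Must be complete (no NA).
#' @return Object of class `friedman_omnibus`: `chi2_f`, `df`, `p_value`,
#'   `k`, `n`.
#' @export
friedman_omnibus <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("table must be numeric")
  if (ncol(m) < 3L) stop("Friedman test needs k >= 3 conditions")
  if (nrow(m) < 2L) stop("Friedman test needs at least 2 blocks")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete blocks; missing cells at (block, condition): ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "))
  }
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1L, rank))
  rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  ss <- sum((rj - n * (k + 1) / 2)^2)
  chi2 <- if (A - C <= .Machine$double.eps * A) 0 else (k - 1) * ss / (A - C)
  structure(
    list(chi2_f = chi2, df = k - 1,
         p_value = stats::pchisq(chi2, k - 1, lower.tail = FALSE),
         k = k, n = n),
    class = "friedman_omnibus"
  )
}

#' @export
print.friedman_omnibus <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4f, df = %d, p = %.4g (n = %d, k = %d)\n",
              x$chi2_f, x$df, x$p_value, x$n, x$k))
  invisible(x)
}

signed_rank_prep <- function(d, zero_method = c("discard", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (zero_method == "discard") {
    dz <- d[d != 0]
    r <- rank(abs(dz))
    list(d = dz, r = r, n = length(dz), n_zero = sum(d == 0),
         mu = length(dz) * (length(dz) + 1) / 4,
         sigma2_base = length(dz) * (length(dz) + 1) *
           (2 * length(dz) + 1) / 24,
         tie_table = table(r))
  } else {
    # Pratt: rank |d| including zeros, then drop the zero ranks
    r_all <- rank(abs(d))
    keep <- d != 0
    n <- length(d); n0 <- sum(!keep)
    list(d = d[keep], r = r_all[keep], n = sum(keep), n_zero = n0,
         mu = (n * (n + 1) - n0 * (n0 + 1)) / 4,
         sigma2_base = (n * (n + 1) * (2 * n + 1) -
                          n0 * (n0 + 1) * (2 * n0 + 1)) / 24,
         tie_table = table(r_all[keep]))
  }
}

#' Wilcoxon signed-rank test for a paired contrast
#'
#' Paired two-sided signed-rank test with explicit zero-difference handling
#' (discard by default, Pratt optionally), midranks on tied |d|, exact sign
#' enumeration of all 2^n patterns when the effective n is small, and a
#' tie-corrected normal-approximation z reported in both modes (no
#' continuity correction by default). Differences are taken as `a - b`.
#'
#' @param a,b Paired numeric samples of equal length.
#' @param mode `"auto"` (exact when `n_effective <= exact_limit`), `"exact"`,
#'   or `"approx"`.
#' @param zero_method `"discard"` (classic) or `"pratt"`.
#' @param correct Apply a 0.5 continuity correction to z (default FALSE).
#' @param exact_limit Largest `n_effective` for exact enumeration in auto
#'   mode (default 15).
#' @return Object of class `comparison_result`: `W` (positive-rank sum),
#'   `z_value`, `p_value`, `n_pairs`, `n_effective`, `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(a, b, mode = c("auto", "exact", "approx"),
                                 zero_method = c("discard", "pratt"),
                                 correct = FALSE, exact_limit = 15L) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("paired samples differ in length")
  if (length(a) < 1L) stop("empty samples")
  ok <- !(is.na(a) | is.na(b))
  d <- a[ok] - b[ok]
  n_pairs <- length(d)

  prep <- signed_rank_prep(d, zero_method)
  if (prep$n == 0L) {
    return(structure(
      list(W = 0, z_value = 0, p_value = 1, n_pairs = n_pairs,
           n_effective = 0L, method = "degenerate", degenerate = TRUE),
      class = "comparison_result"))
  }
  W <- sum(prep$r[prep$d > 0])

  ties <- as.numeric(prep$tie_table)
  sigma2 <- prep$sigma2_base - sum(ties^3 - ties) / 48
  num <- W - prep$mu
  if (correct && sigma2 > 0) num <- num - sign(num) * 0.5
  z <- if (sigma2 > 0) num / sqrt(sigma2) else 0

  use_exact <- mode == "exact" || (mode == "auto" && prep$n <= exact_limit)
  if (use_exact) {
    p <- exact_signed_rank_p(prep$r, W)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approx"
  }
  structure(
    list(W = W, z_value = z, p_value = min(1, p), n_pairs = n_pairs,
         n_effective = prep$n, method = method, degenerate = FALSE),
    class = "comparison_result"
  )
}

# Exact two-sided p by enumerating all 2^n sign assignments over the
# observed (possibly tied) ranks: p = 2 * min(P(W <= w), P(W >= w)), capped
# at 1.
exact_signed_rank_p <- function(ranks, w_obs) {
  n <- length(ranks)
  if (n > 20L) stop("exact enumeration limited to n <= 20")
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% ranks)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W = %g, z = %.3f, p = %.4g (n_eff = %d/%d)\n",
              x$method, x$W, x$z_value, x$p_value, x$n_effective, x$n_pairs))
  invisible(x)
}

#' Rosenthal effect size for a rank-based paired test
#'
#' `r = |Z| / sqrt(n)`, dimensionless.
#'
#' @param z_value Standard-normal-scale test statistic.
#' @param n Sample size (number of pairs), n >= 1.
#' @return Effect size r in `[0, 1]` for attainable z.
#' @export
effect_size_r <- function(z_value, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count")
  }
  abs(z_value) / sqrt(n)
}

#' Build a participant x condition measure table
#'
#' Pivots the long measures table (participant, condition, trial, measure,
#' value, flag) for one measure into the complete-block matrix the omnibus
#' and contrast tests consume. Trials are averaged per participant-condition;
#' any flagged/undefined trial makes that cell NA.
#'
#' @param long Long measures data.frame as produced by [measures_long()].
#' @param measure One of the seven measure names.
#' @return Numeric matrix, rows = participants, columns = conditions.
#' @export
measure_table <- function(long, measure) {
  stopifnot(measure %in% long$measure)
  d <- long[long$measure == measure, , drop = FALSE]
  d$value[d$flag != ""] <- NA_real_
  parts <- sort(unique(d$participant))
  conds <- sort(unique(d$condition))
  m <- matrix(NA_real_, length(parts), length(conds),
              dimnames = list(parts, paste0("cond", conds)))
  for (i in seq_along(parts)) {
    for (j in seq_along(conds)) {
      v <- d$value[d$participant == parts[i] & d$condition == conds[j]]
      if (length(v) > 0L) m[i, j] <- if (anyNA(v)) NA_real_ else mean(v)
    }
  }
  m
}

#' Default a-priori condition contrasts
#'
#' The four planned pairwise comparisons: condition 2 vs 1 (somatosensory),
#' 4 vs 1 (visual), 5 vs 1 and 6 vs 5 (vestibular).
#' @return List of length-2 integer vectors `c(condition_a, condition_b)`.
#' @export
default_contrasts <- function() {
  list(c(2L, 1L), c(4L, 1L), c(5L, 1L), c(6L, 5L))
}

#' Run the planned pairwise contrasts for every measure
#'
#' For each measure and each contrast `(a, b)` runs
#' [wilcoxon_signed_rank()] on the paired per-participant values (a minus
#' b), computing the Rosenthal effect size from the approximation z with
#' `n` = pairs entering the contrast. Participants with a flagged/missing
#' value in either condition are excluded listwise per contrast, and the
#' exclusion count is reported. No multiplicity adjustment is applied (the
#' contrasts are a priori); downstream reports carry an explicit caveat.
#'
#' @param long Long measures data.frame ([measures_long()] format).
#' @param contrasts List of `c(condition_a, condition_b)` pairs.
#' @param alpha Significance level carried into the output (default 0.05).
#' @inheritParams wilcoxon_signed_rank
#' @return A data.frame with one row per measure x contrast: `measure`,
#'   `contrast`, `W`, `z`, `p_value`, `effect_r`, `n_effective`,
#'   `n_excluded`, `significant`, `flag`.
#' @export
run_contrasts <- function(long, contrasts = default_contrasts(),
                          alpha = 0.05, zero_method = "discard",
                          mode = "auto") {
  measures <- intersect(measure_fields, unique(long$measure))
  conds_avail <- sort(unique(long$condition))
  rows <- list()
  for (msr in measures) {
    tab <- measure_table(long, msr)
    for (ct in contrasts) {
      ca <- paste0("cond", ct[1]); cb <- paste0("cond", ct[2])
      if (!all(c(ca, cb) %in% colnames(tab))) {
        stop(sprintf("missing condition column for contrast %d vs %d",
                     ct[1], ct[2]))
      }
      a <- tab[, ca]; b <- tab[, cb]
      keep <- !(is.na(a) | is.na(b))
      res <- wilcoxon_signed_rank(a[keep], b[keep], mode = mode,
                                  zero_method = zero_method)
      r <- effect_size_r(res$z_value, max(1L, res$n_pairs))
      rows[[length(rows) + 1L]] <- data.frame(
        measure = msr,
        contrast = sprintf("%d_vs_%d", ct[1], ct[2]),
        W = res$W, z = res$z_value, p_value = res$p_value,
        effect_r = if (res$degenerate) 0 else r,
        n_effective = res$n_effective,
        n_excluded = sum(!keep),
        significant = !res$degenerate && res$p_value < alpha,
        flag = if (res$degenerate) "degenerate" else "",
        row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "adjustment") <- "none (a-priori contrasts; interpret with care)"
  out
}

#' Run the Friedman omnibus for every measure
#'
#' @inheritParams run_contrasts
#' @return Data.frame with one row per measure: `measure`, `chi2_f`, `df`,
#'   `p_value`, `n`, `k`, `n_excluded`.
#' @export
run_omnibus <- function(long) {
  measures <- intersect(measure_fields, unique(long$measure))
  rows <- lapply(measures, function(msr) {
    tab <- measure_table(long, msr)
    keep <- stats::complete.cases(tab)
    res <- friedman_omnibus(tab[keep, , drop = FALSE])
    data.frame(measure = msr, chi2_f = res$chi2_f, df = res$df,
               p_value = res$p_value, n = res$n, k = res$k,
               n_excluded = sum(!keep), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Sign-flip permutation p-value for a paired contrast
#'
#' Independent verification oracle for [wilcoxon_signed_rank()]: permutes the
#' signs of the nonzero paired differences and compares the signed-rank sum
#' `T = sum(sign(d) * rank|d|)` against its permutation distribution,
#' two-sided (`P(|T*| >= |T_obs|)`). With `n_perm = NULL` and few enough
#' pairs, all 2^n sign patterns are enumerated and the p-value is exact.
#'
#' @param a,b Paired samples.
#' @param n_perm Number of random sign flips; `NULL` enumerates fully when
#'   `n <= 15` (errors otherwise).
#' @param seed Seed for random permutations.
#' @return Permutation p-value in (0, 1].
#' @export
wilcoxon_permutation_p <- function(a, b, n_perm = NULL, seed = 1L) {
  if (length(a) != length(b)) stop("paired samples differ in length")
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  t_obs <- sum(sign(d) * r)
  if (is.null(n_perm)) {
    if (n > 15L) stop("full enumeration limited to n <= 15; pass n_perm")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_all <- as.numeric(signs %*% r)
    mean(abs(t_all) >= abs(t_obs) - 1e-9)
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      if (abs(sum(s * r)) >= abs(t_obs) - 1e-9) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  }
}
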