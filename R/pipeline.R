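#' Run configuration
#'
#' Reads and validates the YAML run configuration consumed by the pipeline
#' entry points. Recognised blocks: `acquisition` (sampling_rate, axis_map,
#' h, filter), `measures` (ellipse quantile, frequency constant),
#' `stats` (alpha, contrasts), `synthetic` (n_participants,
#' trials_per_condition, params overrides), `seed`, `output`.
#'
#' @param path YAML file path, or `NULL` for the validated defaults.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    acquisition = list(sampling_rate = 200, h = 0, filter = NULL),
    measures = list(ellipse_conf = 0.95, mf_const = 4 * sqrt(2)),
    stats = list(alpha = 0.05,
                 contrasts = list(c(2L, 1L), c(4L, 1L), c(5L, 1L), c(6L, 5L))),
    synthetic = list(n_participants = 23L, trials_per_condition = 3L),
    seed = 1L
  )
  cfg <- defaults
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    cfg <- utils::modifyList(defaults, raw)
    # modifyList cannot overwrite a list with an empty one; honour an
    # explicit (possibly empty) contrast list verbatim
    if (!is.null(raw$stats) && "contrasts" %in% names(raw$stats)) {
      cfg$stats$contrasts <- raw$stats$contrasts
    }
  }
  a <- cfg$stats$alpha
  if (!is.numeric(a) || a <= 0 || a >= 1) stop("stats$alpha must be in (0, 1)")
  if (length(cfg$stats$contrasts) == 0L) stop("contrast list must be non-empty")
  cfg$stats$contrasts <- lapply(cfg$stats$contrasts, as.integer)
  class(cfg) <- "run_config"
  cfg
}

#' Analyze a cohort's measures end-to-end
#'
#' From the long measures table: per-condition mean (SD) table for every
#' measure, Friedman omnibus per measure, the planned Wilcoxon contrasts
#' with Rosenthal effect sizes, and provenance. Deterministic given inputs.
#'
#' @param long Long measures data.frame (see [measures_long()]).
#' @param config A [read_run_config()] object.
#' @return Object of class `study_report` with elements `condition_table`,
#'   `omnibus`, `contrasts`, `normality`, `provenance`.
#' @export
analyze_cohort <- function(long, config = read_run_config()) {
  need <- c("participant", "condition", "trial", "measure", "value", "flag")
  miss <- setdiff(need, names(long))
  if (length(miss) > 0L) stop("measures table missing columns: ",
                              paste(miss, collapse = ", "))
  if (nrow(long) == 0L) stop("empty measures table")
  measures <- intersect(measure_fields, unique(long$measure))
  conds <- sort(unique(long$condition))

  rows <- list(); norm_rows <- list()
  for (msr in measures) {
    tab <- measure_table(long, msr)
    for (j in seq_along(conds)) {
      vals <- tab[, paste0("cond", conds[j])]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = msr, condition = conds[j],
        mean = mean(vals, na.rm = TRUE),
        sd = stats::sd(vals, na.rm = TRUE),
        n = sum(!is.na(vals)), n_flagged = sum(is.na(vals)),
        row.names = NULL)
      ns <- tryCatch(normality_screen(vals[!is.na(vals)]),
                     error = function(e) list(W = NA, p_value = NA,
                                              degenerate = TRUE))
      norm_rows[[length(norm_rows) + 1L]] <- data.frame(
        measure = msr, condition = conds[j], W = ns$W,
        p_value = ns$p_value, degenerate = isTRUE(ns$degenerate),
        row.names = NULL)
    }
  }
  report <- structure(
    list(
      condition_table = do.call(rbind, rows),
      omnibus = run_omnibus(long),
      contrasts = run_contrasts(long, contrasts = config$stats$contrasts,
                                alpha = config$stats$alpha),
      normality = do.call(rbind, norm_rows),
      provenance = list(
        seed = config$seed, alpha = config$stats$alpha,
        adjustment = "none (a-priori contrasts); interpret p-values with care",
        package_version = as.character(utils::packageVersion("posturo")),
        n_participants = length(unique(long$participant)))
    ),
    class = "study_report"
  )
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", x$provenance$n_participants, "participants\n\n")
  cat(format_condition_table(x$condition_table), sep = "\n")
  cat("\nFriedman omnibus:\n")
  print(x$omnibus, digits = 4)
  cat("\nPlanned contrasts (alpha =", x$provenance$alpha, ", no adjustment):\n")
  print(x$contrasts, digits = 4)
  invisible(x)
}

# Mean (SD) layout, one row per measure, one column per condition; values at
# 2 decimals (the conventional reporting precision for mm / mm^2 / Hz).
format_condition_table <- function(ct) {
  measures <- unique(ct$measure)
  conds <- sort(unique(ct$condition))
  header <- paste0("measure", paste0("\tcond", conds, collapse = ""))
  body <- vapply(measures, function(m) {
    cells <- vapply(conds, function(cc) {
      r <- ct[ct$measure == m & ct$condition == cc, ]
      sprintf("%.2f (%.2f)", r$mean, r$sd)
    }, character(1))
    paste0(m, "\t", paste(cells, collapse = "\t"))
  }, character(1))
  c(header, body)
}

#' Write report artifacts to disk
#'
#' Writes `measures.csv` (the input long table), `condition_table.csv`,
#' `omnibus.csv`, `contrasts.csv`, `report.md` (mean-(SD) layout with
#' significance markers) and `report.json` (full precision). Output is
#' byte-deterministic for identical inputs.
#'
#' @param report A [analyze_cohort()] result.
#' @param long The long measures table the report was built from.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_report <- function(report, long, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    measures = file.path(dir, "measures.csv"),
    condition_table = file.path(dir, "condition_table.csv"),
    omnibus = file.path(dir, "omnibus.csv"),
    contrasts = file.path(dir, "contrasts.csv"),
    md = file.path(dir, "report.md"),
    json = file.path(dir, "report.json")
  )
  utils::write.csv(long, paths["measures"], row.names = FALSE, quote = FALSE)
  utils::write.csv(report$condition_table, paths["condition_table"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$omnibus, paths["omnibus"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$contrasts, paths["contrasts"], row.names = FALSE,
                   quote = FALSE)

  md <- c(
    "# COP condition report", "",
    sprintf("Participants: %d; alpha = %g; multiplicity adjustment: none",
            report$provenance$n_participants, report$provenance$alpha),
    "", "## Measures by condition, mean (SD)", "",
    format_condition_table(report$condition_table), "",
    "## Friedman omnibus", "",
    sprintf("- %s: chi2 = %.2f (df %d), p = %.4g",
            report$omnibus$measure, report$omnibus$chi2_f,
            report$omnibus$df, report$omnibus$p_value),
    "", "## Planned contrasts", "",
    sprintf("- %s %s: z = %.2f, p = %.4g, r = %.2f (n_eff %d)%s",
            report$contrasts$measure, report$contrasts$contrast,
            report$contrasts$z, report$contrasts$p_value,
            report$contrasts$effect_r, report$contrasts$n_effective,
            ifelse(report$contrasts$significant, " *", "")),
    "",
    "Contrasts are a priori and unadjusted; interpret p-values accordingly."
  )
  writeLines(md, paths["md"])
  jsonlite::write_json(
    list(condition_table = report$condition_table,
         omnibus = report$omnibus, contrasts = report$contrasts,
         normality = report$normality, provenance = report$provenance),
    paths["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate a cohort and write it to disk
#'
#' Writes one long COP CSV (`cop_trials.csv`: participant, condition, trial,
#' time_s, cop_ap_mm, cop_ml_mm) plus a ground-truth parameter sidecar
#' (`sway_params.yaml`) and the cohort index (`index.csv`).
#'
#' @param dir Output directory.
#' @param params,n_participants,trials_per_condition,seed Passed to
#'   [generate_cohort()].
#' @return Invisibly, the cohort object.
#' @export
simulate_cohort_csv <- function(dir, params = default_sway_params(),
                                n_participants = 23,
                                trials_per_condition = 3, seed = 1L) {
  cohort <- generate_cohort(params, n_participants = n_participants,
                            trials_per_condition = trials_per_condition,
                            seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- round(params$duration * params$sampling_rate)
  tfun <- function(tr, what) rep(attr(tr, what), length(tr$ap))
  df <- data.frame(
    participant = unlist(lapply(cohort$trials, tfun, "participant")),
    condition = unlist(lapply(cohort$trials, tfun, "condition")),
    trial = unlist(lapply(cohort$trials, tfun, "trial")),
    time_s = rep((seq_len(n) - 1) / params$sampling_rate,
                 length(cohort$trials)),
    cop_ap_mm = unlist(lapply(cohort$trials, `[[`, "ap")),
    cop_ml_mm = unlist(lapply(cohort$trials, `[[`, "ml"))
  )
  utils::write.csv(df, file.path(dir, "cop_trials.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$index, file.path(dir, "index.csv"),
                   row.names = FALSE, quote = FALSE)
  write_sway_params(params, file.path(dir, "sway_params.yaml"))
  invisible(cohort)
}

#' Score a responses CSV file
#'
#' Batch-scores a long-format questionnaire responses CSV
#' (`participant,instrument,item,rating`), writes the scores CSV with a
#' summary row (mean and SD per instrument/scale) appended, and an errors
#' sidecar for invalid response vectors.
#'
#' @param path Input responses CSV.
#' @param out Output scores CSV path; the errors sidecar (if any) is written
#'   next to it with suffix `_errors.csv`.
#' @return Invisibly, the scores data.frame (without summary rows).
#' @export
score_responses_file <- function(path, out) {
  responses <- utils::read.csv(path)
  res <- score_responses(responses)
  scores <- res$scores
  summaries <- do.call(rbind, lapply(
    split(scores, list(scores$instrument, scores$scale), drop = TRUE),
    function(d) data.frame(
      participant = c("mean", "sd"), instrument = d$instrument[1],
      scale = d$scale[1],
      score = c(mean(d$score), stats::sd(d$score)), row.names = NULL)
  ))
  all_rows <- rbind(
    data.frame(participant = as.character(scores$participant),
               instrument = scores$instrument, scale = scores$scale,
               score = scores$score),
    summaries)
  utils::write.csv(all_rows, out, row.names = FALSE, quote = FALSE)
  if (nrow(res$errors) > 0L) {
    utils::write.csv(res$errors,
                     sub("\\.csv$", "_errors.csv", out),
                     row.names = FALSE)
  }
  invisible(scores)
}
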