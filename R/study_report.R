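# Study-level analysis: orchestrates the group summaries, rank tests,
# longitudinal deltas and predictive correlations over a quantified cohort.

#' Run the full cohort analysis
#'
#' Takes a simulated cohort (or an already-quantified table from
#' [quantify_cohort()]) and produces the study report: per-group
#' median/IQR summaries of uptake and mean lung density at every
#' timepoint, Kruskal-Wallis tests across groups per timepoint with
#' Dunn-Bonferroni post-hoc matrices, within-subject delta metrics between
#' `t0` and `t1` with their own group comparisons, and the per-group
#' predictive correlations of baseline uptake with density progression.
#' The analysis of a quantified table is fully deterministic.
#'
#' @param cohort a `fibropet_cohort` or a [quantify_cohort()] data.frame.
#' @param thresholds,window quantification settings (used only when a raw
#'   cohort is supplied).
#' @param t0,t1 days bounding the longitudinal delta metrics; skipped when
#'   the data lack either day.
#' @param metrics columns summarised per group and timepoint.
#' @return An object of class `study_report` with elements `summary`
#'   (data.frame: group, day, metric, n, median, q1, q3), `tests` (per-day
#'   Kruskal-Wallis + post-hoc on uptake and MLD), `deltas`, `delta_tests`,
#'   `correlations`, and the quantified `data`.
#' @export
run_study_analysis <- function(cohort, thresholds = density_thresholds(),
                               window = c(15, 75), t0 = 8, t1 = 22,
                               metrics = c("uptake", "mld", "aerated",
                                           "dense", "lung_to_blood",
                                           "lung_to_muscle",
                                           "excreted_pct_id")) {
  data <- if (inherits(cohort, "fibropet_cohort"))
    quantify_cohort(cohort, thresholds, window) else cohort
  stopifnot(all(c("subject_id", "group", "day") %in% names(data)))
  metrics <- intersect(metrics, names(data))
  days <- sort(unique(data$day))
  groups <- unique(data$group)

  summ <- do.call(rbind, lapply(days, function(d) {
    do.call(rbind, lapply(groups, function(g) {
      do.call(rbind, lapply(metrics, function(m) {
        v <- data[[m]][data$group == g & data$day == d]
        v <- v[!is.na(v)]
        if (!length(v)) return(NULL)
        mi <- median_iqr(v)
        data.frame(group = g, day = d, metric = m, n = length(v),
                   median = mi$median, q1 = mi$q1, q3 = mi$q3)
      }))
    }))
  }))
  rownames(summ) <- NULL

  per_day_test <- function(metric, d) {
    gl <- lapply(groups, function(g) {
      v <- data[[metric]][data$group == g & data$day == d]
      v[!is.na(v)]
    })
    names(gl) <- groups
    gl <- gl[lengths(gl) > 0]
    if (length(gl) < 2) return(NULL)
    kw <- kruskal_wallis(gl)
    kw$post_hoc <- dunn_bonferroni(gl)
    kw
  }
  tests <- list()
  for (d in days) {
    tests[[paste0("D", d)]] <- list(uptake = per_day_test("uptake", d),
                                    mld = per_day_test("mld", d))
  }

  deltas <- delta_tests <- correlations <- NULL
  if (all(c(t0, t1) %in% days)) {
    du <- delta_longitudinal(data, "uptake", t0, t1)
    dm <- delta_longitudinal(data, "mld", t0, t1)
    deltas <- rbind(du, dm)
    dtest <- function(dd) {
      gl <- split(dd$delta, dd$group)[unique(dd$group)]
      if (length(gl) < 2) return(NULL)
      kw <- kruskal_wallis(gl)
      kw$post_hoc <- dunn_bonferroni(gl)
      kw
    }
    delta_tests <- list(uptake = dtest(du), mld = dtest(dm))
    correlations <- suppressWarnings(
      predictive_correlation(data, baseline_day = t0, t0 = t0, t1 = t1))
  }

  structure(list(summary = summ, tests = tests, deltas = deltas,
                 delta_tests = delta_tests, correlations = correlations,
                 data = data, days = days, groups = groups),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d groups x %d timepoints, %d subjects\n",
              length(x$groups), length(x$days),
              length(unique(x$data$subject_id))))
  up <- x$summary[x$summary$metric == "uptake", ]
  if (nrow(up)) {
    cat("\nWhole-lung uptake (%ID/g), median [IQR]:\n")
    for (d in x$days) {
      cat(sprintf("  D%-3d", d))
      for (g in x$groups) {
        r <- up[up$group == g & up$day == d, ]
        if (nrow(r))
          cat(sprintf("  %s %.2f [%.2f-%.2f]", g, r$median, r$q1, r$q3))
      }
      kw <- x$tests[[paste0("D", d)]]$uptake
      if (!is.null(kw))
        cat(sprintf("  (KW p = %.3g %s)", kw$p_value,
                    signif_stars(kw$p_value)))
      cat("\n")
    }
  }
  if (!is.null(x$correlations) && length(x$correlations)) {
    cat("\nPredictive correlations (baseline uptake vs density change):\n")
    for (g in names(x$correlations)) {
      r <- x$correlations[[g]]
      cat(sprintf("  %-16s rho = %+.3f, p = %.3g %s (n = %d)\n", g,
                  r$rho, r$p_value, signif_stars(r$p_value), r$n))
    }
  }
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  object$summary
}

#' Write a study report to disk
#'
#' Emits `summary.csv` (group, day, metric, n, median, q1, q3),
#' `tests.json` (per-day Kruskal-Wallis p-values and Bonferroni-adjusted
#' post-hoc matrices) and `correlations.csv`.
#'
#' @param report a [run_study_analysis()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  tests <- lapply(report$tests, function(day) {
    lapply(day, function(t) {
      if (is.null(t)) return(NULL)
      list(test = t$test, statistic = t$statistic, p_value = t$p_value,
           post_hoc_p_adjusted = t$post_hoc$p_adjusted)
    })
  })
  jsonlite::write_json(tests, file.path(dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       matrix = "rowmajor")
  if (!is.null(report$correlations)) {
    cr <- do.call(rbind, lapply(names(report$correlations), function(g) {
      r <- report$correlations[[g]]
      data.frame(group = g, method = r$method, rho = r$rho,
                 p_value = r$p_value, n = r$n)
    }))
    utils::write.csv(cr, file.path(dir, "correlations.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
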