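# Nonparametric statistical layer: median/IQR summaries, Mann-Whitney,
# Kruskal-Wallis with Dunn-Bonferroni post-hoc, Spearman correlation, and
# the longitudinal delta / predictive-correlation analyses.

#' Median and interquartile range
#'
#' Quartiles use linear interpolation (R's default type-7 rule); this
#' convention is fixed and documented because "interquartile range" admits
#' several definitions.
#'
#' @param values numeric vector, length >= 1.
#' @return list with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  if (!length(values)) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Significance stars
#'
#' @param p p-value(s).
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `""` otherwise.
#' @export
signif_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***"
    else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

new_group_comparison <- function(test, statistic, p_value, labels, sizes,
                                 p_method, post_hoc = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), groups = labels, n = sizes,
                 p_method = p_method, post_hoc = post_hoc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g %s (%s)\n",
              x$test, x$statistic, x$p_value, signif_stars(x$p_value),
              x$p_method))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' U statistic with mid-rank ties. The two-sided p-value is exact
#' (equivalent to full enumeration of group labelings) when the combined
#' sample size is at most 14 and there are no ties; otherwise a
#' tie-corrected normal approximation is used.
#'
#' @param a,b numeric samples (each non-empty).
#' @param mode `"auto"` (default rule above), `"exact"` or
#'   `"normal_approx"`.
#' @return A `group_comparison` with the U statistic of `a`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("empty group")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode,
    auto = (length(a) + length(b) <= 14) && !ties,
    exact = TRUE,
    normal_approx = FALSE)
  if (exact && ties) stop("exact mode requires tie-free data")
  w <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  new_group_comparison("Mann-Whitney", w$statistic, w$p.value,
                       c("a", "b"), c(length(a), length(b)),
                       if (exact) "exact" else "normal approximation")
}

# tie-corrected Kruskal-Wallis H from pooled ranks and a grouping factor
kw_H <- function(ranks, grp, n_total) {
  rs <- tapply(ranks, grp, sum)
  ns <- tapply(ranks, grp, length)
  h <- 12 / (n_total * (n_total + 1)) * sum(rs^2 / ns) - 3 * (n_total + 1)
  tie <- table(ranks)
  corr <- 1 - sum(tie^3 - tie) / (n_total^3 - n_total)
  h / corr
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square p-value on k-1 degrees of freedom.
#' For small studies (`exact = TRUE`, total n <= 8) the p-value is instead
#' computed by full enumeration of all distinct assignments of the pooled
#' observations to the groups.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3).
#' @param exact compute the enumeration p-value.
#' @return A `group_comparison` with statistic H.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (length(groups) < 2) stop("fewer than 2 groups")
  if (any(!lengths(groups))) stop("empty group")
  n <- sum(lengths(groups))
  if (n < 3) stop("need total n >= 3")
  k <- stats::kruskal.test(groups)
  p_method <- "chi-square approximation"
  p <- k$p.value
  if (exact) {
    if (n > 8) stop("exact enumeration supported for total n <= 8")
    pooled <- unlist(groups)
    ranks <- rank(pooled)
    sizes <- lengths(groups)
    grp <- rep(seq_along(groups), sizes)
    h_obs <- kw_H(ranks, grp, n)
    h_all <- kw_assignment_stats(ranks, sizes, n)
    p <- mean(h_all >= h_obs - 1e-9)
    p_method <- "exact enumeration"
  }
  labs <- if (!is.null(names(groups))) names(groups)
          else paste0("g", seq_along(groups))
  new_group_comparison("Kruskal-Wallis", k$statistic, p, labs,
                       lengths(groups), p_method)
}

# H statistics over every distinct assignment of the pooled ranks to
# groups of the given sizes (recursive combination enumeration)
kw_assignment_stats <- function(ranks, sizes, n_total) {
  out <- numeric(0)
  recurse <- function(remaining, gi, grp_assign) {
    if (gi == length(sizes)) {
      grp_assign[remaining] <- gi
      out[[length(out) + 1]] <<- kw_H(ranks, grp_assign, n_total)
      return(invisible())
    }
    cmb <- utils::combn(remaining, sizes[gi])
    for (j in seq_len(ncol(cmb))) {
      ga <- grp_assign
      ga[cmb[, j]] <- gi
      recurse(setdiff(remaining, cmb[, j]), gi + 1L, ga)
    }
  }
  recurse(seq_len(n_total), 1L, integer(n_total))
  out
}

#' Dunn's post-hoc test with Bonferroni adjustment
#'
#' Pairwise z statistics on the pooled mid-ranks with tie correction — the
#' standard rank-based follow-up to a Kruskal-Wallis test. Each two-sided
#' p-value is multiplied by the number of comparisons and clipped at 1.
#'
#' @param groups list of numeric vectors (as for [kruskal_wallis()]).
#' @return An object of class `dunn_posthoc`: matrices `z`, `p_raw` and
#'   `p_adjusted` indexed by group pairs.
#' @export
dunn_bonferroni <- function(groups) {
  if (length(groups) < 2) stop("fewer than 2 groups")
  if (any(!lengths(groups))) stop("empty group")
  pooled <- unlist(groups)
  n <- length(pooled)
  ranks <- rank(pooled)
  grp <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(ranks, grp, mean)
  ns <- lengths(groups)
  tie <- table(ranks)
  tie_term <- sum(tie^3 - tie) / (12 * (n - 1))
  k <- length(groups)
  labs <- if (!is.null(names(groups))) names(groups) else paste0("g", 1:k)
  z <- p_raw <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  m <- k * (k - 1) / 2
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ns[i] + 1 / ns[j]))
    zij <- (rbar[i] - rbar[j]) / se
    z[i, j] <- z[j, i] <- zij
    p_raw[i, j] <- p_raw[j, i] <- 2 * stats::pnorm(-abs(zij))
  }
  structure(list(z = z, p_raw = p_raw,
                 p_adjusted = pmin(p_raw * m, 1), comparisons = m),
            class = "dunn_posthoc")
}

#' @export
print.dunn_posthoc <- function(x, ...) {
  cat("<dunn_posthoc> Bonferroni-adjusted pairwise p-values:\n")
  print(round(x$p_adjusted, 4))
  invisible(x)
}

# all permutations of a vector (n <= 8 in practice)
all_permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- vector("list", factorial(length(v)))
  pos <- 0L
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) {
      pos <- pos + 1L
      out[[pos]] <- c(v[i], p)
    }
  }
  out
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of the mid-ranks. The two-sided p-value
#' is computed by full permutation enumeration for n <= 8 (and tie-free
#' data), otherwise by the t approximation on n - 2 degrees of freedom.
#' Constant input yields an undefined (`NA`) rho.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param labels optional length-2 character vector naming x and y.
#' @return An object of class `correlation_result` with `method`, `rho`,
#'   `p_value`, `n` and the labels.
#' @export
spearman_cor <- function(x, y, labels = c("x", "y")) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  res <- structure(list(method = "spearman", rho = NA_real_,
                        p_value = NA_real_, n = n,
                        x_label = labels[1], y_label = labels[2],
                        p_method = "none"),
                   class = "correlation_result")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: rho undefined")
    return(res)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 8 && !ties) {
    perms <- all_permutations(ry)
    r_all <- vapply(perms, function(p) stats::cor(rx, p), numeric(1))
    p <- mean(abs(r_all) >= abs(rho) - 1e-12)
    p_method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    p_method <- "t approximation"
  }
  res$rho <- rho; res$p_value <- p; res$p_method <- p_method
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s rho(%s, %s) = %.3f, p = %.4g %s (n = %d)\n",
              x$method, x$x_label, x$y_label, x$rho, x$p_value,
              signif_stars(x$p_value), x$n))
  invisible(x)
}

#' Within-subject longitudinal change
#'
#' Computes `metric(t1) - metric(t0)` per subject from a quantified cohort
#' table ([quantify_cohort()]). Applied to the window uptake this is the
#' progression metric Delta-uptake(D8-D22); applied to mean lung density it
#' is Delta-CT(D8-D22).
#'
#' @param data data.frame with columns `subject_id`, `group`, `day` and the
#'   metric column.
#' @param metric column name, e.g. `"uptake"` or `"mld"`.
#' @param t0,t1 study days, `t1 > t0`.
#' @return data.frame with `subject_id`, `group`, `metric`, `t0`, `t1`,
#'   `delta`.
#' @export
delta_longitudinal <- function(data, metric = "uptake", t0 = 8, t1 = 22) {
  stopifnot(t1 > t0, metric %in% names(data))
  subs <- unique(data$subject_id)
  out <- lapply(subs, function(s) {
    d <- data[data$subject_id == s, ]
    v0 <- d[[metric]][d$day == t0]
    v1 <- d[[metric]][d$day == t1]
    if (!length(v0) || !length(v1))
      stop("missing timepoint for subject ", s)
    data.frame(subject_id = s, group = d$group[1], metric = metric,
               t0 = t0, t1 = t1, delta = v1 - v0)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Predictive correlation of baseline uptake with outcome change
#'
#' Per group, correlates the baseline tracer uptake (default: whole-lung
#' %ID/g at day 8) with the subsequent change in an outcome metric
#' (default: mean lung density change from day 8 to day 22). In an
#' untreated progressive cohort the correlation is positive — lungs hotter
#' at baseline progress more; under an effective anti-fibrotic it turns
#' negative — lungs hotter at baseline regress more.
#'
#' @param data a [quantify_cohort()] table.
#' @param baseline_metric,baseline_day definition of the predictor.
#' @param outcome_metric,t0,t1 definition of the outcome change.
#' @param groups groups to analyse; default all groups in `data`.
#' @param min_n groups with fewer subjects are skipped with a warning.
#' @return named list of `correlation_result` objects.
#' @export
predictive_correlation <- function(data, baseline_metric = "uptake",
                                   baseline_day = 8,
                                   outcome_metric = "mld",
                                   t0 = 8, t1 = 22,
                                   groups = unique(data$group),
                                   min_n = 3) {
  out <- list()
  deltas <- delta_longitudinal(data, outcome_metric, t0, t1)
  for (g in groups) {
    base <- data[data$group == g & data$day == baseline_day, ]
    dd <- deltas[deltas$group == g, ]
    m <- merge(base[, c("subject_id", baseline_metric)],
               dd[, c("subject_id", "delta")], by = "subject_id")
    if (nrow(m) < min_n) {
      warning("group '", g, "' skipped: fewer than ", min_n, " subjects")
      next
    }
    out[[g]] <- spearman_cor(m[[baseline_metric]], m$delta,
                             labels = c(
                               sprintf("%s@D%d", baseline_metric,
                                       baseline_day),
                               sprintf("delta_%s_D%d-D%d", outcome_metric,
                                       t0, t1)))
  }
  out
}
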