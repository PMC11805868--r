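#' Two-sample test selection policy
#'
#' Encodes the published analysis logic: both the Shapiro-Wilk and the
#' D'Agostino-Pearson omnibus tests screen each group for normality; if any
#' screen rejects (or a group is constant, or too small to screen), the
#' Mann-Whitney test is used; otherwise Student's t, switching to Welch's
#' correction when an F-ratio test finds unequal variances.
#'
#' @param normality_alpha level for the normality screens.
#' @param variance_alpha level of the F-ratio test that triggers Welch.
#' @param alpha significance level for the selected test.
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(normality_alpha = 0.05, variance_alpha = 0.05,
                             alpha = 0.05) {
  vals <- c(normality_alpha, variance_alpha, alpha)
  if (any(vals <= 0 | vals >= 1)) stop("thresholds must lie in (0, 1)")
  structure(list(normality_alpha = normality_alpha,
                 variance_alpha = variance_alpha, alpha = alpha),
            class = "selection_policy")
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the z-transformed sample skewness (D'Agostino 1970) and
#' kurtosis (Anscombe-Glynn 1983) into `K^2 = z_s^2 + z_k^2`, referred to a
#' chi-squared distribution with 2 degrees of freedom. Requires `n >= 8`.
#'
#' @param x numeric sample.
#' @return A list of class `htest` with the `K^2` statistic and p-value.
#' @export
dagostino_pearson_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("dagostino_pearson_test requires n >= 8")
  if (stats::sd(x) == 0) stop("sample is constant")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)

  # skewness z (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * asinh(y / alpha)

  # kurtosis z (Anscombe & Glynn 1983)
  g2 <- m4 / m2^2
  eg2 <- 3 * (n - 1) / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eg2) / sqrt(vg2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  structure(list(statistic = c(K2 = k2),
                 p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 method = "D'Agostino-Pearson omnibus normality test",
                 data.name = deparse(substitute(x)),
                 z = c(skew = z_skew, kurtosis = z_kurt)),
            class = "htest")
}

normality_screen <- function(x, policy) {
  n <- length(x)
  if (stats::sd(x) == 0) {
    return(list(normal = FALSE, trail = "constant group: normality screen not applicable, treated as non-normal"))
  }
  sw <- stats::shapiro.test(x)
  trail <- sprintf("Shapiro-Wilk p = %.4g", sw$p.value)
  normal <- sw$p.value >= policy$normality_alpha
  if (n >= 8L) {
    dp <- dagostino_pearson_test(x)
    trail <- c(trail, sprintf("D'Agostino-Pearson p = %.4g", dp$p.value))
    normal <- normal && dp$p.value >= policy$normality_alpha
  } else {
    trail <- c(trail, "n < 8: D'Agostino-Pearson skipped")
  }
  list(normal = normal, trail = trail)
}

# Two-sided Mann-Whitney U: exact when tie-free and groups are <= 50,
# otherwise the tie-corrected normal approximation. The reported statistic
# is U for the first group.
mann_whitney_test <- function(groupA, groupB) {
  ties <- anyDuplicated(c(groupA, groupB)) > 0
  exact <- max(length(groupA), length(groupB)) <= 50L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

new_test_result <- function(test_name, statistic, df, p_value, labels, ns,
                            policy, trail, degenerate = FALSE) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, group_labels = labels, n_per_group = ns,
                 significant = !degenerate && is.finite(p_value) &&
                   p_value < policy$alpha,
                 degenerate = degenerate, decision_trail = trail),
            class = "necsim_test")
}

#' @export
print.necsim_test <- function(x, ...) {
  cat(sprintf("<necsim_test> %s: statistic = %.4g%s, p = %.4g%s (%s vs %s, n = %d/%d)\n",
              x$test_name, x$statistic,
              if (is.null(x$df) || all(is.na(x$df))) "" else
                sprintf(", df = %s", paste(round(x$df, 2), collapse = ", ")),
              x$p_value, if (x$significant) " *" else "",
              x$group_labels[1], x$group_labels[2],
              x$n_per_group[1], x$n_per_group[2]))
  invisible(x)
}

#' Run the policy-selected two-sample comparison
#'
#' Screens both groups for normality, then runs the Mann-Whitney test (any
#' screen failing), Welch's t (screens pass, variances unequal by F-ratio)
#' or Student's t. Two-sided throughout. The Mann-Whitney branch is exact
#' for groups of at most 50 without ties, otherwise the tie-corrected
#' normal approximation. Degenerate input (both groups constant) is flagged, not
#' raised.
#'
#' @param groupA,groupB numeric samples (each `n >= 3`).
#' @param policy a [selection_policy()].
#' @param labels length-2 character group labels.
#' @return A `necsim_test` result carrying the decision trail.
#' @export
choose_and_run <- function(groupA, groupB, policy = selection_policy(),
                           labels = c("A", "B")) {
  groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
  ns <- c(length(groupA), length(groupB))
  if (any(ns < 3L)) stop("each group needs at least 3 observations")

  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    same <- isTRUE(all.equal(groupA[1], groupB[1]))
    return(new_test_result("degenerate", NA_real_, NA_real_,
                           if (same) 1 else 0, labels, ns, policy,
                           "both groups constant: degenerate comparison",
                           degenerate = TRUE))
  }

  scrA <- normality_screen(groupA, policy)
  scrB <- normality_screen(groupB, policy)
  trail <- c(paste0(labels[1], ": ", paste(scrA$trail, collapse = "; ")),
             paste0(labels[2], ": ", paste(scrB$trail, collapse = "; ")))

  if (!scrA$normal || !scrB$normal) {
    wt <- mann_whitney_test(groupA, groupB)
    trail <- c(trail, sprintf("normality failed -> Mann-Whitney (%s)",
                              if (wt$exact) "exact" else "normal approx., tie-corrected"))
    return(new_test_result("mann_whitney", wt$statistic, NA_real_,
                           wt$p_value, labels, ns, policy, trail))
  }

  ft <- stats::var.test(groupA, groupB)
  welch <- ft$p.value < policy$variance_alpha
  trail <- c(trail, sprintf("F-ratio p = %.4g -> %s t-test", ft$p.value,
                            if (welch) "Welch" else "Student"))
  tt <- stats::t.test(groupA, groupB, var.equal = !welch)
  new_test_result(if (welch) "welch_t" else "student_t",
                  unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  labels, ns, policy, trail)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`. Always at least the raw p; equal to it when
#' `m = 1`.
#'
#' @param p raw p-value(s).
#' @param m number of comparisons.
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Per-timepoint group comparison of a microdialysis timecourse
#'
#' For a tidy percent-of-baseline table (columns `mouse_id`, `condition`,
#' `time_post_min`, `pct_baseline`, two conditions), runs the
#' policy-selected test at every post-injection timepoint and attaches
#' Sidak-adjusted p-values with `m` = number of timepoints. When every
#' condition-by-timepoint cell passes the normality screens, a two-way
#' mixed-design ANOVA (condition between, timepoint repeated within mouse)
#' is added. Mice missing any timepoint are excluded listwise (count
#' logged).
#'
#' @param series tidy data frame as above.
#' @param policy a [selection_policy()].
#' @return An object of class `timecourse_comparison`: list with
#'   `per_timepoint` (named list of `necsim_test`, Sidak-adjusted p in
#'   `$sidak_p`), `m`, `rm_anova` (a `necsim_test` or `NULL`), and
#'   `n_excluded`.
#' @export
timecourse_comparison <- function(series, policy = selection_policy()) {
  conds <- sort(unique(series$condition))
  if (length(conds) != 2L) stop("series must contain exactly two conditions")
  times <- sort(unique(series$time_post_min))
  for (cond in conds) {
    tc <- sort(unique(series$time_post_min[series$condition == cond]))
    if (!identical(tc, times)) stop("timepoint grids differ between groups")
  }
  # listwise exclusion of mice missing any timepoint (unit = condition x mouse)
  unit <- interaction(series$condition, series$mouse_id, drop = TRUE)
  counts <- table(unit)
  complete <- names(counts)[counts == length(times)]
  n_excluded <- sum(counts != length(times))
  series <- series[unit %in% complete, ]

  m <- length(times)
  per_tp <- lapply(times, function(tp) {
    sub <- series[series$time_post_min == tp, ]
    res <- choose_and_run(sub$pct_baseline[sub$condition == conds[1]],
                          sub$pct_baseline[sub$condition == conds[2]],
                          policy, labels = conds)
    res$sidak_p <- sidak_adjust(res$p_value, m)
    res
  })
  names(per_tp) <- paste0("t", times)

  all_normal <- all(vapply(times, function(tp) {
    all(vapply(conds, function(cond) {
      v <- series$pct_baseline[series$time_post_min == tp &
                                 series$condition == cond]
      normality_screen(v, policy)$normal
    }, logical(1)))
  }, logical(1)))

  rm_anova <- NULL
  if (all_normal) {
    df <- series
    df$time_f <- factor(df$time_post_min)
    df$mouse_uid <- interaction(df$condition, df$mouse_id, drop = TRUE)
    fit <- stats::aov(pct_baseline ~ condition * time_f +
                        Error(mouse_uid / time_f), data = df)
    tab <- summary(fit)
    between <- tab[["Error: mouse_uid"]][[1L]]
    row <- grep("^condition", trimws(rownames(between)))[1L]
    rm_anova <- new_test_result(
      "rm_anova", between[row, "F value"],
      c(between[row, "Df"], between[nrow(between), "Df"]),
      between[row, "Pr(>F)"], conds,
      c(length(unique(df$mouse_uid[df$condition == conds[1]])),
        length(unique(df$mouse_uid[df$condition == conds[2]]))),
      policy, "all cells normal -> mixed-design RM-ANOVA (condition between, time within)")
  }

  structure(list(per_timepoint = per_tp, m = m, rm_anova = rm_anova,
                 n_excluded = n_excluded, times = times),
            class = "timecourse_comparison")
}

#' @export
print.timecourse_comparison <- function(x, ...) {
  cat(sprintf("<timecourse_comparison> %d timepoints\n", x$m))
  for (nm in names(x$per_timepoint)) {
    r <- x$per_timepoint[[nm]]
    cat(sprintf("  %s: %s p = %.4g (Sidak %.4g)%s\n", nm, r$test_name,
                r$p_value, r$sidak_p, if (r$significant) " *" else ""))
  }
  if (!is.null(x$rm_anova)) {
    cat(sprintf("  RM-ANOVA condition effect: F = %.3g, p = %.4g\n",
                x$rm_anova$statistic, x$rm_anova$p_value))
  }
  invisible(x)
}

#' Baseline equivalence between conditions
#'
#' Policy-selected two-sample test of the per-mouse baseline means across
#' conditions, with group means +/- SEM attached.
#'
#' @param series tidy dialysis table for one region (must carry
#'   `baseline_pg`).
#' @param policy a [selection_policy()].
#' @return A `necsim_test` with a `group_means` data frame attached.
#' @export
baseline_equivalence <- function(series, policy = selection_policy()) {
  conds <- sort(unique(series$condition))
  if (length(conds) != 2L) stop("series must contain exactly two conditions")
  base <- unique(series[, c("mouse_id", "condition", "baseline_pg")])
  g1 <- base$baseline_pg[base$condition == conds[1]]
  g2 <- base$baseline_pg[base$condition == conds[2]]
  res <- choose_and_run(g1, g2, policy, labels = conds)
  res$group_means <- data.frame(
    condition = conds, mean = c(mean(g1), mean(g2)),
    sem = c(stats::sd(g1) / sqrt(length(g1)),
            stats::sd(g2) / sqrt(length(g2))))
  res
}
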