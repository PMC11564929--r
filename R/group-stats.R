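#' Choose the group-comparison family by formal normality testing
#'
#' Runs a Shapiro-Wilk test on every group; when all groups are consistent
#' with normality at `alpha`, the parametric branch (one-way ANOVA with
#' Dunnett's many-to-one comparisons) is selected, otherwise the rank-based
#' branch (Kruskal-Wallis with Dunn's comparisons). A Brown-Forsythe
#' (median-centred Levene) statistic is reported as a homoscedasticity
#' diagnostic only; it does not influence the gate.
#'
#' @param values numeric metric values.
#' @param group group label per value (the wild-type control is one group).
#' @param alpha Shapiro-Wilk significance level for the gate.
#'
#' @return List with `choice` (`"anova_dunnett"` or `"kw_dunn"`),
#'   `shapiro_p` per group, `brown_forsythe` diagnostic and `alpha`.
#' @export
normality_gate <- function(values, group, alpha = 0.05) {
  g <- split(values, group)
  ns <- vapply(g, length, integer(1))
  if (any(ns < 3)) {
    stop(sprintf("group(s) %s have n < 3; cannot test normality",
                 paste(names(ns)[ns < 3], collapse = ", ")))
  }
  sw <- vapply(g, function(v) {
    if (stats::sd(v) == 0) {
      stop("a group is constant; the Shapiro-Wilk statistic is undefined")
    }
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  bf <- car::leveneTest(values ~ factor(group), center = stats::median)
  list(choice = if (all(sw > alpha)) "anova_dunnett" else "kw_dunn",
       shapiro_p = sw,
       brown_forsythe = list(F = bf[1, "F value"], p = bf[1, "Pr(>F)"]),
       alpha = alpha)
}

significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) "" else if (x < 1e-4) "****" else if (x < 1e-3) "***"
    else if (x < 0.01) "**" else if (x < 0.05) "*" else ""
  }, character(1))
}

#' Compare every variant group to the wild-type control
#'
#' Many-to-one adjusted p-values against the control group: Dunnett's
#' multivariate-t adjustment on the one-way ANOVA fit, or rank-based Dunn
#' z-tests with a family-size (Bonferroni) adjustment over the
#' variant-vs-control comparisons.
#'
#' @param values numeric metric values.
#' @param group group label per value.
#' @param control control group label (must be present).
#' @param choice test family, typically from [normality_gate()].
#'
#' @return A `group_comparison`: data frame with per-variant `n`, `mean`,
#'   `sem`, `p_adj`, `stars`, plus attributes `test_used` and `control`.
#' @export
compare_to_control <- function(values, group, control = "WT",
                               choice = c("anova_dunnett", "kw_dunn")) {
  choice <- match.arg(choice)
  group <- as.character(group)
  if (!control %in% group) stop(sprintf("control group '%s' missing", control))
  lv <- c(control, setdiff(unique(group), control))
  g <- factor(group, levels = lv)
  p_adj <- if (choice == "anova_dunnett") {
    dat <- data.frame(y = values, g = g)
    fit <- stats::aov(y ~ g, data = dat)
    cmp <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    unname(summary(cmp)$test$pvalues)
  } else {
    dunn_vs_control(values, g)
  }
  per <- split(values, g)
  out <- data.frame(
    variant = lv[-1],
    n = vapply(per[-1], length, integer(1)),
    mean = vapply(per[-1], mean, numeric(1)),
    sem = vapply(per[-1], function(v) stats::sd(v) / sqrt(length(v)),
                 numeric(1)),
    p_adj = p_adj)
  out$stars <- significance_stars(out$p_adj)
  rownames(out) <- NULL
  structure(out, test_used = choice, control = control,
            control_n = length(per[[1]]), control_mean = mean(per[[1]]),
            class = c("group_comparison", "data.frame"))
}

# Dunn's rank-based many-to-one z tests, tie-corrected, with Bonferroni
# adjustment over the k variant-vs-control comparisons.
dunn_vs_control <- function(values, g) {
  r <- rank(values)
  n_tot <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  v0 <- n_tot * (n_tot + 1) / 12 - tie_term
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  k <- nlevels(g) - 1
  z <- (mr[-1] - mr[1]) / sqrt(v0 * (1 / ns[-1] + 1 / ns[1]))
  pmin(1, 2 * stats::pnorm(-abs(z)) * k)
}

#' Per-timepoint comparison of variant time courses to the control
#'
#' For every timepoint on the shared frame grid, the per-field values of
#' each variant are compared to the control's with Dunnett's many-to-one
#' adjustment; the returned mask (adjusted p < `alpha`) is the data behind
#' "significant difference" bars over a time-course plot. A
#' Geisser-Greenhouse-corrected split-plot omnibus test (no sphericity
#' assumption) is attached as a diagnostic.
#'
#' @param traces long data frame with columns `variant`, `field_id`,
#'   `time_s`, `value`; all fields must share the frame grid.
#' @param control control variant label.
#' @param alpha per-timepoint significance level after adjustment.
#'
#' @return List with `mask` (data frame `variant`, `time_s`, `p_adj`,
#'   `significant`) and `omnibus` diagnostics (GG epsilon and corrected
#'   p for the group x time interaction).
#' @export
pointwise_timecourse_comparison <- function(traces, control = "WT",
                                            alpha = 0.05) {
  need <- c("variant", "field_id", "time_s", "value")
  if (!all(need %in% names(traces))) {
    stop("traces must have columns variant, field_id, time_s, value")
  }
  grids <- split(traces$time_s, traces$field_id)
  ref <- sort(unique(grids[[1]]))
  for (gd in grids) {
    if (!isTRUE(all.equal(sort(unique(gd)), ref))) {
      stop("fields do not share one frame grid")
    }
  }
  if (length(setdiff(unique(traces$variant), control)) < 1) {
    stop("need at least one variant besides the control")
  }
  rows <- lapply(ref, function(tp) {
    d <- traces[traces$time_s == tp, ]
    cmp <- compare_to_control(d$value, d$variant, control = control,
                              choice = "anova_dunnett")
    data.frame(variant = cmp$variant, time_s = tp, p_adj = cmp$p_adj)
  })
  mask <- do.call(rbind, rows)
  mask$significant <- mask$p_adj < alpha
  list(mask = mask[order(mask$variant, mask$time_s), ],
       omnibus = gg_omnibus(traces, ref))
}

# Split-plot (groups x repeated timepoints) omnibus with Geisser-Greenhouse
# correction, reported as a diagnostic alongside the pointwise comparisons.
gg_omnibus <- function(traces, ref) {
  wide <- stats::reshape(
    traces[order(traces$field_id, traces$time_s),
           c("field_id", "variant", "time_s", "value")],
    idvar = c("field_id", "variant"), timevar = "time_s",
    direction = "wide")
  y <- as.matrix(wide[, -(1:2)])
  grp <- factor(wide$variant)
  n_t <- ncol(y)
  n_s <- nrow(y)
  k <- nlevels(grp)
  if (n_t < 2 || n_s <= k) return(NULL)  # no within-subject factor to test
  grand <- mean(y)
  subj_m <- rowMeans(y)
  time_m <- colMeans(y)
  grp_m <- as.vector(tapply(subj_m, grp, mean))
  cell_m <- matrix(apply(y, 2, function(col) tapply(col, grp, mean)),
                   nrow = k)
  ns <- as.vector(table(grp))
  ss_time <- n_s * sum((time_m - grand)^2)
  ss_gxt <- sum(ns * (cell_m - outer(grp_m, time_m, "+") + grand)^2)
  gi <- as.integer(grp)
  resid <- y - cell_m[gi, , drop = FALSE] - subj_m + grp_m[gi]
  ss_err <- sum(resid^2)
  df_time <- n_t - 1
  df_gxt <- (k - 1) * (n_t - 1)
  df_err <- (n_s - k) * (n_t - 1)
  # pooled within-group covariance over time, double-centred for epsilon
  s_pool <- Reduce(`+`, lapply(levels(grp), function(lv) {
    yy <- y[grp == lv, , drop = FALSE]
    stats::cov(yy) * (nrow(yy) - 1)
  })) / (n_s - k)
  dc <- sweep(sweep(s_pool, 1, rowMeans(s_pool)), 2, colMeans(s_pool)) +
    mean(s_pool)
  eps <- sum(diag(dc))^2 / ((n_t - 1) * sum(dc^2))
  eps <- min(max(eps, 1 / (n_t - 1)), 1)
  f_time <- (ss_time / df_time) / (ss_err / df_err)
  f_gxt <- (ss_gxt / df_gxt) / (ss_err / df_err)
  list(gg_epsilon = eps,
       p_time_gg = stats::pf(f_time, eps * df_time, eps * df_err,
                             lower.tail = FALSE),
       p_interaction_gg = stats::pf(f_gxt, eps * df_gxt, eps * df_err,
                                    lower.tail = FALSE))
}
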