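# cache of full permutation matrices for exact enumeration (n! x n)
.perm_cache <- new.env(parent = emptyenv())

perm_matrix <- function(n) {
  key <- as.character(n)
  if (is.null(.perm_cache[[key]])) {
    .perm_cache[[key]] <- e1071::permutations(n)
  }
  .perm_cache[[key]]
}

# evaluate thunk under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average-ranked vectors (ties receive average
#' ranks).
#'
#' @param x,y numeric vectors of equal length (n >= 3), no missing values.
#' @return Spearman's rho.
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values must be dropped upstream")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(rx, ry)
}

# Two-sided permutation p-value for cor(a, b) under permutation of b.
# Exact enumeration of all n! permutations when n <= exact_max, Monte-Carlo
# with add-one correction otherwise. |r*| >= |r_obs| is counted at
# tolerance 1e-12 so that permutations tying the observed statistic are
# extreme.
perm_cor_p <- function(a, b, n_perm = 10000, seed = NULL, exact_max = 8) {
  n <- length(a)
  ac <- a - mean(a)
  bc <- b - mean(b)
  den <- sqrt(sum(ac^2)) * sqrt(sum(bc^2))
  r_obs <- sum(ac * bc) / den
  if (n <= exact_max) {
    p_mat <- perm_matrix(n)
    r_star <- as.vector(matrix(bc[p_mat], nrow(p_mat)) %*% ac) / den
    p <- mean(abs(r_star) >= abs(r_obs) - 1e-12)
    list(r = r_obs, p = p, method = "exact", n_perm = nrow(p_mat))
  } else {
    if (n_perm < 100) stop("n_perm must be >= 100 in Monte-Carlo mode")
    r_star <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) sum(ac * bc[sample.int(n)]) / den, numeric(1))
    })
    p <- (sum(abs(r_star) >= abs(r_obs) - 1e-12) + 1) / (n_perm + 1)
    list(r = r_obs, p = p, method = "monte_carlo", n_perm = n_perm)
  }
}

#' Permutation test for a Spearman correlation
#'
#' Two-sided p-value for the null hypothesis of exchangeability of `y`
#' against `x`. All `n!` permutations are enumerated exactly when
#' `n <= exact_max` (`p = #{|r*| >= |r_obs|} / n!`); otherwise a
#' Monte-Carlo sample of permutations is used with the add-one correction
#' `p = (#{|r*| >= |r_obs|} + 1) / (n_perm + 1)`.
#'
#' @inheritParams spearman_r
#' @param n_perm Monte-Carlo permutation count (>= 100).
#' @param seed optional seed for the Monte-Carlo draw.
#' @param exact_max largest n for exact enumeration.
#'
#' @return List with `r` (Spearman's rho), `p`, `method`, `n_perm`.
#' @export
permutation_p <- function(x, y, n_perm = 10000, seed = NULL, exact_max = 8) {
  r <- spearman_r(x, y)  # validates input
  out <- perm_cor_p(rank(x), rank(y), n_perm = n_perm, seed = seed,
                    exact_max = exact_max)
  out$r <- r
  out
}

#' Age-controlled partial Spearman correlation with permutation p-value
#'
#' Ranks `x`, `y` and `age`, residualizes the x- and y-ranks on the
#' age-ranks by least squares, and correlates the residuals. The p-value
#' permutes the y-residuals (Freedman-Lane style) under the same
#' exact/Monte-Carlo rules as [permutation_p()]. If the y-ranks are an
#' exact function of the age-ranks the residuals vanish and the partial
#' correlation is 0 by convention (p = 1).
#'
#' @inheritParams permutation_p
#' @param age covariate (years); must vary.
#'
#' @return List with `r` (partial rho), `p`, `method`, `n_perm`.
#' @export
partial_spearman_age <- function(x, y, age, n_perm = 10000, seed = NULL,
                                 exact_max = 8) {
  n <- length(x)
  if (length(y) != n || length(age) != n) stop("x, y, age must share length")
  if (n < 5) stop("need n >= 5 for an age-controlled correlation")
  if (anyNA(x) || anyNA(y) || anyNA(age)) {
    stop("missing values must be dropped upstream")
  }
  if (stats::sd(age) == 0) stop("age is constant; cannot control for it")
  rx <- rank(x); ry <- rank(y); ra <- rank(age)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero variance: correlation undefined")
  }
  res_x <- stats::resid(stats::lm(rx ~ ra))
  res_y <- stats::resid(stats::lm(ry ~ ra))
  tol <- 1e-10 * n
  if (sqrt(sum(res_x^2)) < tol || sqrt(sum(res_y^2)) < tol) {
    return(list(r = 0, p = 1, method = "degenerate", n_perm = 0L))
  }
  perm_cor_p(res_x, res_y, n_perm = n_perm, seed = seed,
             exact_max = exact_max)
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Sorts the family of p-values ascending, finds the largest `i` with
#' `p_(i) <= (i/m) * q`, and flags tests 1..i significant. Returns the
#' flags in input order together with the data-dependent cutoff `p_(i)`.
#'
#' @param pvals p-value family (all in `[0, 1]`).
#' @param q target false discovery rate.
#'
#' @return List with `significant` (logical, input order), `cutoff`
#'   (largest significant p, `NA` if none) and `n_significant`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value family")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- length(pvals)
  o <- order(pvals)
  ok <- which(pvals[o] <= seq_len(m) / m * q)
  flags <- rep(FALSE, m)
  cutoff <- NA_real_
  if (length(ok)) {
    k <- max(ok)
    flags[o[seq_len(k)]] <- TRUE
    cutoff <- pvals[o][k]
  }
  list(significant = flags, cutoff = cutoff, n_significant = sum(flags))
}

#' Full functional-metric x phenotype-measure correlation family
#'
#' Computes the matrix of permutation Spearman correlations between the
#' three functional metrics (initial exocytic rate, tau, % fused by 200 AP)
#' and the phenotype measures, using age-controlled partial correlations
#' for the designated measures (CVI total and DBC self-injury by default;
#' the other measures are age-standardised scores), then applies BH-FDR
#' across all computed cells. Pairs with missing phenotype data are dropped
#' per cell; a cell with fewer than 4 complete pairs (5 when
#' age-controlled) is reported as not computed rather than erroring.
#'
#' @param metrics_table data frame with `variant` and the functional
#'   metrics `initial_rate`, `tau_s`, `frac_fused_200AP_pct` (one row per
#'   variant, field-mean values).
#' @param phenotype_table data frame with `variant`, phenotype measure
#'   columns and `age`.
#' @param measures phenotype measure columns to test.
#' @param age_controlled measures whose correlations control for age.
#' @param n_perm,seed,q see [permutation_p()] and [bh_fdr()].
#'
#' @return Data frame, one row per (measure, metric) cell: `measure`,
#'   `metric`, `n`, `r`, `p`, `age_controlled`, `computed`,
#'   `significant_bh`; BH cutoff as attribute `bh_cutoff`.
#' @export
run_correlation_family <- function(metrics_table, phenotype_table,
                                   measures = c("VABS_communication",
                                                "VABS_motor", "CVI_total",
                                                "movement_disorder_count",
                                                "DBC_self_injury"),
                                   age_controlled = c("CVI_total",
                                                      "DBC_self_injury"),
                                   n_perm = 10000, seed = NULL, q = 0.05) {
  metric_cols <- c("initial_rate", "tau_s", "frac_fused_200AP_pct")
  if (!all(metric_cols %in% names(metrics_table))) {
    stop("metrics_table must contain ", paste(metric_cols, collapse = ", "))
  }
  dat <- merge(metrics_table, phenotype_table, by = "variant")
  if (nrow(dat) < 5) stop("need >= 5 variants with functional metrics")
  rows <- list()
  for (ms in measures) {
    for (mt in metric_cols) {
      ctl <- ms %in% age_controlled
      keep <- stats::complete.cases(dat[, c(mt, ms,
                                            if (ctl) "age" else NULL)])
      d <- dat[keep, ]
      n_min <- if (ctl) 5L else 4L
      row <- data.frame(measure = ms, metric = mt, n = nrow(d),
                        r = NA_real_, p = NA_real_, age_controlled = ctl,
                        computed = FALSE)
      if (nrow(d) >= n_min) {
        res <- tryCatch({
          if (ctl) {
            partial_spearman_age(d[[mt]], d[[ms]], d$age,
                                 n_perm = n_perm, seed = seed)
          } else {
            permutation_p(d[[mt]], d[[ms]], n_perm = n_perm, seed = seed)
          }
        }, error = function(e) NULL)
        if (!is.null(res)) {
          row$r <- res$r
          row$p <- res$p
          row$computed <- TRUE
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$significant_bh <- FALSE
  comp <- which(out$computed)
  cutoff <- NA_real_
  if (length(comp)) {
    bh <- bh_fdr(out$p[comp], q = q)
    out$significant_bh[comp] <- bh$significant
    cutoff <- bh$cutoff
  }
  structure(out, bh_cutoff = cutoff, q = q)
}
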