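test_that("spearman_r is rank-Pearson with average ranks", {
  expect_equal(spearman_r(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_r(1:4, c(40, 30, 20, 10)), -1)
  # brute-force oracle: Pearson on explicit ranks
  x <- 1:5; y <- c(1, 3, 2, 5, 4)
  oracle <- sum((rank(x) - 3) * (rank(y) - 3)) /
    sqrt(sum((rank(x) - 3)^2) * sum((rank(y) - 3)^2))
  expect_equal(spearman_r(x, y), oracle)
  expect_equal(oracle, 0.8)
  # invariance under strictly monotone transforms
  set.seed(41)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(spearman_r(exp(a), b^3 + 5 * b), spearman_r(a, b))
  expect_error(spearman_r(rep(1, 5), 1:5), "zero variance")
  expect_error(spearman_r(c(1, NA, 3, 4), 1:4), "missing")
})

test_that("exact permutation p-values match full enumeration", {
  expect_equal(permutation_p(1:4, c(2, 5, 9, 11))$p, 2 / 24)
  expect_equal(permutation_p(1:3, c(1, 5, 9))$p, 2 / 6)
  res <- permutation_p(1:4, c(2, 5, 9, 11))
  expect_equal(res$method, "exact")
  expect_equal(res$n_perm, 24)
})

test_that("Monte-Carlo p agrees with exact enumeration within 3 binomial SEs", {
  set.seed(42)
  x <- rnorm(8); y <- x + rnorm(8, sd = 1.5)
  p_exact <- permutation_p(x, y)$p
  p_mc <- permutation_p(x, y, n_perm = 10000, seed = 99, exact_max = 0)$p
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(p_mc - p_exact), 3 * se + 2 / 10001)
  expect_error(permutation_p(x, y, n_perm = 50, exact_max = 0), "n_perm")
  # MC mode is reproducible under a seed and leaves the RNG state alone
  set.seed(1); before <- rnorm(1)
  p1 <- permutation_p(x, y, seed = 7, exact_max = 0)$p
  p2 <- permutation_p(x, y, seed = 7, exact_max = 0)$p
  expect_identical(p1, p2)
})

test_that("age-controlled partial correlation removes the confound", {
  set.seed(43)
  n <- 60
  age <- runif(n, 3, 20)
  # x and y both pure monotone functions of age: marginal ~1, partial ~0
  x <- age^2; y <- log(age)
  expect_gt(spearman_r(x, y), 0.99)
  res <- partial_spearman_age(x, y, age, n_perm = 500, seed = 2)
  expect_lt(abs(res$r), 0.05)
  # y identical to age: residuals vanish, partial rho 0 by convention
  expect_equal(partial_spearman_age(rnorm(8), age[1:8], age[1:8])$r, 0)
  # age unrelated to either: partial ~ marginal
  x2 <- rnorm(n); y2 <- x2 + rnorm(n)
  marg <- spearman_r(x2, y2)
  part <- partial_spearman_age(x2, y2, runif(n, 3, 20),
                               n_perm = 500, seed = 3)$r
  expect_lt(abs(part - marg), 0.1)
  expect_error(partial_spearman_age(rnorm(8), rnorm(8), rep(5, 8)),
               "constant")
  expect_error(partial_spearman_age(rnorm(4), rnorm(4), runif(4)), "n >= 5")
})

test_that("BH step-up flags match the step-up definition and p.adjust", {
  expect_equal(bh_fdr(rep(1, 6))$n_significant, 0)
  expect_true(bh_fdr(0.01)$significant)
  set.seed(44)
  p <- c(runif(10, 0, 0.02), runif(10))
  bh <- bh_fdr(p, q = 0.05)
  # independent route: adjusted p-values from stats::p.adjust
  expect_equal(bh$significant, p.adjust(p, "BH") <= 0.05)
  # monotone in q: lowering q never adds flags
  for (q2 in c(0.01, 0.025)) {
    expect_true(all(bh_fdr(p, q2)$significant <= bh$significant))
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the reported clinical p-value family replays to the flagged cells", {
  tab <- clinical_correlation_table()
  expect_equal(nrow(tab), 15)
  bh <- bh_fdr(tab$p, q = 0.05)
  expect_identical(bh$significant, tab$asterisk)
  flagged <- tab[bh$significant, c("measure", "metric")]
  expect_setequal(
    paste(flagged$measure, flagged$metric),
    c("VABS_motor initial_rate", "VABS_motor tau_s",
      "VABS_motor frac_fused_200AP_pct",
      "VABS_communication frac_fused_200AP_pct"))
})

test_that("the correlation family flags a deterministic link and nothing it shouldn't", {
  # graded deficit: all three metrics mutually monotone across 8 variants
  vm <- data.frame(variant = paste0("V", 1:8),
                   initial_rate = seq(0.005, 0.030, length.out = 8),
                   tau_s = seq(45, 20, length.out = 8),
                   frac_fused_200AP_pct = seq(12, 35, length.out = 8))
  link <- phenotype_link(
    links = data.frame(measure = "VABS_motor",
                       metric = "frac_fused_200AP_pct", slope = 0.8,
                       intercept = 30),
    noise_sd = 1.5,
    null_measures = c("VABS_communication", "CVI_total",
                      "movement_disorder_count", "DBC_self_injury"),
    null_base = c(VABS_communication = 60, CVI_total = 20,
                  movement_disorder_count = 2, DBC_self_injury = 4))
  ph <- simulate_cohort_phenotypes(vm, link, seed = 3)
  res <- run_correlation_family(vm, ph, seed = 3)
  motor <- res$measure == "VABS_motor"
  expect_true(all(res$significant_bh[motor]))
  expect_false(any(res$significant_bh[!motor]))
  # row order invariance
  perm <- sample(nrow(vm))
  res2 <- run_correlation_family(vm[perm, ], ph, seed = 3)
  key <- paste(res$measure, res$metric)
  key2 <- paste(res2$measure, res2$metric)
  expect_equal(res$p[order(key)], res2$p[order(key2)])
  expect_equal(res$r[order(key)], res2$r[order(key2)])
})

test_that("cells with too few complete pairs are reported, not raised", {
  vm <- data.frame(variant = paste0("V", 1:6),
                   initial_rate = seq(0.005, 0.03, length.out = 6),
                   tau_s = seq(45, 20, length.out = 6),
                   frac_fused_200AP_pct = seq(12, 35, length.out = 6))
  ph <- simulate_cohort_phenotypes(vm, seed = 6)
  ph$DBC_self_injury[1:3] <- NA  # only 3 complete pairs remain
  res <- run_correlation_family(vm, ph, seed = 6)
  dbc <- res[res$measure == "DBC_self_injury", ]
  expect_true(all(!dbc$computed))
  expect_true(all(is.na(dbc$p)))
  expect_true(all(res$computed[res$measure == "VABS_motor"]))
})
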