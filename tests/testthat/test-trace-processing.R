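test_that("background bleach fit recovers the generating exponential", {
  t <- seq(-5, 139, by = 1)
  noiseless <- roi_trace("bg", "background", t, 50 * exp(-(t + 5) / 600))
  m <- fit_background_bleach(noiseless, nh4cl_onset = 140)
  expect_equal(m$a, 50, tolerance = 1e-6)
  expect_equal(m$b, 1 / 600, tolerance = 1e-6)

  flat <- roi_trace("bg", "background", t, rep(25, length(t)))
  expect_equal(fit_background_bleach(flat, 140)$b, 0)

  zero <- roi_trace("bg", "background", t, rep(0, length(t)))
  expect_error(fit_background_bleach(zero, 140), "zero")
  expect_error(
    fit_background_bleach(roi_trace("bg", "background", 0:5, 6:1), 5),
    ">= 10 frames")
})

test_that("noisy bleach-rate recovery is within 15% of truth (median over seeds)", {
  t <- seq(-5, 139, by = 1)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    y <- 50 * exp(-(t + 5) / 600) + rnorm(length(t), sd = 2)
    m <- fit_background_bleach(roi_trace("bg", "background", t, y), 140)
    abs(m$b - 1 / 600) / (1 / 600)
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("bleach correction undoes the generative decay", {
  pr <- protocol_pool_1200ap()
  gt <- bouton_ground_truth()
  # b = 0 is the identity
  tr <- simulate_bouton_trace(gt, pr, quiet_noise(0))
  m0 <- structure(list(a = 1, b = 0, fit_window = c(-5, 140), rss = 0,
                       n_frames = 0), class = "bleach_model")
  expect_equal(apply_bleach_correction(tr, m0)$intensity, tr$intensity)
  # exact rate: corrected trace equals the bleach-free generative trace
  nm <- noise_model(sigma_rel = 0, background_level = 0, bleach_tau = 600)
  bleached <- simulate_bouton_trace(gt, pr, nm)
  m <- structure(list(a = 1, b = 1 / 600, fit_window = c(-5, 140), rss = 0,
                      n_frames = 0), class = "bleach_model")
  corrected <- apply_bleach_correction(bleached, m)
  ref <- simulate_bouton_trace(gt, pr, quiet_noise(0))
  rmse <- sqrt(mean((corrected$intensity - ref$intensity)^2))
  expect_lt(rmse / mean(ref$intensity), 0.005)
  expect_error(apply_bleach_correction(corrected, m), "already")
})

test_that("corrected background has no residual trend", {
  pr <- protocol_pool_1200ap()
  set.seed(21)
  bgs <- lapply(1:4, function(i) {
    simulate_background_trace(pr, noise_model(0.02, 50, 600),
                              sprintf("bg_%d", i))
  })
  m <- fit_background_bleach(bgs, pr$nh4cl_onset)
  t <- bgs[[1]]$time_s
  mean_bg <- rowMeans(vapply(bgs, function(tr) tr$intensity,
                             numeric(length(t))))
  corr <- mean_bg * exp(m$b * (t - t[1]))
  pre <- t < pr$nh4cl_onset
  ci <- confint(lm(corr[pre] ~ t[pre]))[2, ]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("dF/F0 uses the mean of the 5 pre-stimulation frames", {
  mk <- function(vals) roi_trace("r", "synaptic", seq(-5, length(vals) - 6),
                                 vals)
  tr <- compute_dff(mk(c(100, 100, 100, 100, 100, 120, 150)), 0)
  expect_equal(tr$intensity[7], 0.5)
  expect_true(has_flag(tr, "dff"))

  const <- compute_dff(mk(rep(80, 10)), 0)
  expect_equal(const$intensity, rep(0, 10))

  tr2 <- compute_dff(mk(c(90, 100, 110, 100, 100, 200)), 0)
  expect_equal(tr2$intensity[6], 1.0)

  expect_error(compute_dff(tr, 0), "already")
  expect_error(compute_dff(mk(c(0, 0, 0, 0, 0, 10)), 0), "F0")
  expect_error(compute_dff(roi_trace("r", "synaptic", 0:9, 1:10), 0),
               ">= 5 frames")
})

test_that("ROI screen requires both stimulation and NH4Cl responses", {
  pr <- protocol_pool_1200ap()
  gt_live <- bouton_ground_truth()
  gt_dead <- bouton_ground_truth(responsive = FALSE)
  mk_dff <- function(gt, id) {
    compute_dff(simulate_bouton_trace(gt, pr, quiet_noise(0), id), 0)
  }
  dffs <- list(mk_dff(gt_live, "live"), mk_dff(gt_dead, "dead"))
  qc <- screen_rois(dffs, pr)
  expect_equal(qc$roi$included, c(TRUE, FALSE))
  expect_equal(qc$roi$reason[2], "no_stim_response")

  # strict > 20 rule at the boundary
  mk_n <- function(n_live) {
    dffs <- c(lapply(seq_len(n_live), function(i) mk_dff(gt_live, paste0("l", i))),
              lapply(1:3, function(i) mk_dff(gt_dead, paste0("d", i))))
    screen_rois(dffs, pr)
  }
  expect_false(mk_n(20)$field_pass)
  expect_true(mk_n(21)$field_pass)
})

test_that("screen is monotone in the noise threshold", {
  set.seed(9)
  f <- simulate_field(n_responsive = 15, n_dead = 10, seed = 17)
  p <- process_field(f, require_pass = FALSE)
  counts <- vapply(c(1, 2, 4, 8), function(k) {
    screen_rois(p$dff_traces, f$protocol, noise_k = k)$n_responsive
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("field averaging masks excluded ROIs", {
  pr <- protocol_pool_1200ap()
  gt <- bouton_ground_truth()
  dffs <- lapply(1:22, function(i) {
    compute_dff(simulate_bouton_trace(gt, pr, quiet_noise(0),
                                      sprintf("r%02d", i)), 0)
  })
  qc <- screen_rois(dffs, pr)
  avg <- field_average(dffs, qc)
  expect_equal(avg$dff, dffs[[1]]$intensity)

  # force one exclusion: average over the remainder only
  qc$roi$included[1] <- FALSE
  dffs_mod <- dffs
  dffs_mod[[1]]$intensity <- dffs_mod[[1]]$intensity * 100
  avg2 <- field_average(dffs_mod, qc)
  expect_equal(avg2$dff, dffs[[2]]$intensity)

  qc$roi$included[] <- FALSE
  qc$n_responsive <- 0; qc$field_pass <- FALSE
  expect_error(field_average(dffs, qc), "excluded")
})

test_that("normalization modes divide by the documented references", {
  pr <- protocol_pool_1200ap()
  t <- pr$frame_times
  # synthetic mean trace: ends stimulation at 0.6, NH4Cl max 1.2
  dff <- ifelse(t < 0, 0, ifelse(t < 120, 0.6 * (t + 1) / 120,
                                 ifelse(t < 140, 0.6, 1.2)))
  tr <- data.frame(time_s = t, dff = dff)
  sp <- normalize_trace(tr, "stim_peak", pr)
  end_stim <- mean(sp$dff[t %in% 115:119])
  expect_equal(end_stim, 1.0, tolerance = 1e-12)
  nh <- normalize_trace(tr, "nh4cl_peak", pr)
  expect_equal(mean(nh$dff[t %in% 115:119]), 0.6 / 1.2 * (118 / 120),
               tolerance = 1e-12)
  # idempotence in the same mode
  expect_equal(normalize_trace(sp, "stim_peak", pr)$dff, sp$dff)
  neg <- data.frame(time_s = t, dff = rep(-1, length(t)))
  expect_error(normalize_trace(neg, "nh4cl_peak", pr), "<= 0")
})

test_that("bleach-free noiseless pipeline reproduces the analytic trace", {
  f <- noiseless_field()
  p <- process_field(f)
  pr <- f$protocol
  nh <- normalize_trace(p$mean_dff, "nh4cl_peak", pr)
  t <- nh$time_s
  stim <- t >= 0 & t < 120
  expect_equal(nh$dff[stim], analytic_c_pool(t[stim]), tolerance = 1e-9)
  # nh4cl-normalized trace stays in [0, 1] under the generative model
  expect_true(all(nh$dff >= -1e-9 & nh$dff <= 1 + 1e-9))
})
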