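test_that("noiseless trace follows the closed-form generative model", {
  # s = 0, q_v = 0, R = 1: stim-window fluorescence is T * (1 - exp(-t/tau))
  gt <- bouton_ground_truth(total_units = 800, surface_frac = 0,
                            recycling_frac = 1, rrp_frac = 0.1,
                            tau_true = 20, vesicular_quench = 0)
  pr <- protocol_pool_1200ap()
  tr <- simulate_bouton_trace(gt, pr, quiet_noise(0))
  stim <- tr$time_s >= 0 & tr$time_s < 120
  expect_equal(tr$intensity[stim],
               800 * (1 - exp(-tr$time_s[stim] / 20)), tolerance = 1e-12)
  expect_equal(tr$intensity[tr$time_s == 20], 800 * (1 - exp(-1)),
               tolerance = 1e-12)
  # NH4Cl dequench reveals the total pool
  expect_equal(tr$intensity[tr$time_s == 150], 800, tolerance = 1e-12)
})

test_that("non-responsive boutons stay flat under stimulation but dequench", {
  gt <- bouton_ground_truth(total_units = 500, surface_frac = 0,
                            vesicular_quench = 0, responsive = FALSE)
  pr <- protocol_pool_1200ap()
  nm <- noise_model(sigma_rel = 0, background_level = 20, bleach_tau = 600)
  tr <- simulate_bouton_trace(gt, pr, nm)
  stim <- tr$time_s >= 0 & tr$time_s < 120
  bleach <- exp(-(tr$time_s - tr$time_s[1]) / 600)
  expect_equal(tr$intensity[stim], (bleach * 20)[stim], tolerance = 1e-12)
  i150 <- which(tr$time_s == 150)
  expect_equal(tr$intensity[i150], bleach[i150] * (20 + 500),
               tolerance = 1e-12)
})

test_that("visibility stays in [0, 1] and is non-decreasing during stimulation", {
  set.seed(11)
  for (proto in list(protocol_pool_1200ap(), protocol_rrp_40ap())) {
    for (i in 1:10) {
      rec <- runif(1, 0.2, 0.9)
      gt <- bouton_ground_truth(
        total_units = runif(1, 500, 2000),
        surface_frac = runif(1, 0, 0.5), recycling_frac = rec,
        rrp_frac = runif(1, 0, rec), tau_true = runif(1, 5, 60))
      tr <- simulate_bouton_trace(gt, proto, quiet_noise(0))
      v <- tr$intensity / gt$total_units
      expect_true(all(v >= -1e-12 & v <= 1 + 1e-12))
      # NH4Cl visibility is the supremum
      nh <- in_window(tr$time_s, proto$windows$nh4cl)
      expect_true(max(v[!nh]) <= min(v[nh]) + 1e-12)
      stim <- tr$time_s >= 0 & tr$time_s < proto$windows$stim[2]
      expect_true(all(diff(tr$intensity[stim]) >= -1e-12))
    }
  }
})

test_that("bouton invariants are enforced", {
  expect_error(bouton_ground_truth(rrp_frac = 0.6, recycling_frac = 0.5),
               "subset")
  expect_error(bouton_ground_truth(tau_true = 0), "tau_true")
  expect_error(bouton_ground_truth(surface_frac = 1.2), "fractions")
  expect_error(simulate_bouton_trace(
    bouton_ground_truth(),
    protocol("p", 0:50, list(baseline = c(0, 5), stim = c(5, 45))),
    quiet_noise()), "NH4Cl")
})

test_that("field simulation keeps the books and is deterministic", {
  f <- simulate_field(n_responsive = 25, n_dead = 5, n_background = 4,
                      seed = 3)
  expect_length(f$traces, 34)
  expect_equal(sum(f$ground_truth$responsive), 25)
  roles <- vapply(f$traces, function(tr) tr$roi_role, character(1))
  expect_equal(sum(roles == "background"), 4)
  expect_error(simulate_field(n_responsive = 0, n_dead = 0,
                              n_background = 0), "at least one ROI")
  expect_error(simulate_field(n_background = 0), "background")

  f2 <- simulate_field(n_responsive = 25, n_dead = 5, n_background = 4,
                       seed = 3)
  tmp1 <- tempfile(fileext = ".csv"); tmp2 <- tempfile(fileext = ".csv")
  write_trace_table(f, tmp1); write_trace_table(f2, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
})

test_that("partitioning plateaus follow the generative model", {
  pr <- protocol_partitioning()
  gt <- bouton_ground_truth(total_units = 1000, surface_frac = 0.3,
                            vesicular_quench = 0)
  nm <- noise_model(sigma_rel = 0, background_level = 0, bleach_tau = Inf,
                    q_mes = 0)
  tr <- simulate_partitioning_trace(gt, pr, nm)
  sal <- mean(tr$intensity[in_window(tr$time_s, pr$windows$saline)])
  mes <- mean(tr$intensity[in_window(tr$time_s, pr$windows$mes)])
  nh <- mean(tr$intensity[in_window(tr$time_s, pr$windows$nh4cl)])
  expect_equal((sal - mes) / (nh - mes), 0.30, tolerance = 1e-12)

  gt_all_surface <- bouton_ground_truth(surface_frac = 1, recycling_frac = 0,
                                        rrp_frac = 0, vesicular_quench = 0)
  tr2 <- simulate_partitioning_trace(gt_all_surface, pr, nm)
  sal2 <- mean(tr2$intensity[in_window(tr2$time_s, pr$windows$saline)])
  nh2 <- mean(tr2$intensity[in_window(tr2$time_s, pr$windows$nh4cl)])
  expect_equal(sal2 / nh2, 1, tolerance = 1e-12)

  bad <- protocol("p", 0:60, list(saline = c(0, 30), nh4cl = c(30, 60)),
                  nh4cl_onset = 30)
  expect_error(simulate_partitioning_trace(gt, bad, nm), "mes")
})

test_that("line profiles have the stated CV behaviour downstream", {
  expect_error(simulate_line_profile(length_px = 100), "60 um")
  flat <- simulate_line_profile(300, n_puncta = 0, noise_sd = 0)
  expect_equal(profile_cv(flat), 0)
  set.seed(5)
  punctate <- simulate_line_profile(300, n_puncta = 10, punctum_amp = 200,
                                    baseline = 50, noise_sd = 0)
  diffuse <- rep(mean(punctate), 300)  # same total, no puncta
  expect_gt(profile_cv(punctate), profile_cv(diffuse))
})

test_that("cohort phenotype links are monotone and validated", {
  vm <- data.frame(variant = paste0("V", 1:6),
                   initial_rate = seq(0.005, 0.03, length.out = 6),
                   tau_s = seq(45, 20, length.out = 6),
                   frac_fused_200AP_pct = seq(12, 35, length.out = 6))
  link <- phenotype_link(
    links = data.frame(measure = "VABS_motor",
                       metric = "frac_fused_200AP_pct",
                       slope = 0.8, intercept = 30),
    noise_sd = 0,
    null_measures = c("VABS_communication", "CVI_total",
                      "movement_disorder_count", "DBC_self_injury"),
    null_base = c(VABS_communication = 60, CVI_total = 20,
                  movement_disorder_count = 2, DBC_self_injury = 4))
  ph <- simulate_cohort_phenotypes(vm, link, seed = 2)
  expect_equal(spearman_r(vm$frac_fused_200AP_pct, ph$VABS_motor), 1)
  expect_true(all(ph$DBC_self_injury >= 0 & ph$DBC_self_injury <= 10))
  expect_true(all(ph$movement_disorder_count >= 0))

  vm_dup <- rbind(vm, vm[1, ])
  expect_error(simulate_cohort_phenotypes(vm_dup, link), "duplicated")
  expect_error(phenotype_link(
    links = data.frame(measure = "CVI_total", metric = "tau_s",
                       slope = 1, intercept = 0),
    null_measures = "CVI_total"), "both linked and null")
})
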