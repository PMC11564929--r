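# shared fixtures: noiseless generative settings and analytic references

quiet_noise <- function(background_level = 0) {
  noise_model(sigma_rel = 0, background_level = background_level,
              bleach_tau = Inf)
}

# field of identical noiseless boutons (enough to pass the > 20 ROI rule)
noiseless_field <- function(gt = bouton_ground_truth(),
                            proto = protocol_pool_1200ap(),
                            n_syn = 22, bg_level = 10,
                            field_id = "f1", variant = "WT") {
  nm_syn <- quiet_noise(0)
  traces <- c(
    lapply(seq_len(n_syn), function(i) {
      simulate_bouton_trace(gt, proto, nm_syn, sprintf("roi_%02d", i))
    }),
    list(simulate_background_trace(proto, quiet_noise(bg_level), "bg_01")))
  field_record(field_id, variant, proto, traces)
}

# cumulative fused fraction of the vesicular pool, recycling-pool protocol
analytic_c_pool <- function(t, R = 0.55, tau = 20) {
  ifelse(t < 0, 0, ifelse(t < 120, R * (1 - exp(-t / tau)),
                          R * (1 - exp(-120 / tau))))
}

# analytic exocytosis metrics for the noiseless pool protocol (frames at
# 1 s; end-of-stim = mean of frames 115..119; NH4Cl-normalized trace = c(t))
analytic_pool_metrics <- function(R = 0.55, tau = 20) {
  cf <- function(t) analytic_c_pool(t, R, tau)
  t5 <- 0:5
  list(
    recycling_pool_pct = 100 * mean(cf(115:119)),
    tau_s = tau,
    initial_rate = unname(stats::coef(stats::lm(cf(t5) ~ t5))[2]),
    frac_fused_200AP_pct = 100 * cf(20))
}
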