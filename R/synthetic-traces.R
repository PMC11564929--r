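#' Generative parameters of one synthetic bouton
#'
#' The latent quantities the pipeline estimates: the total pHluorin
#' fluorescence of the bouton, the fraction resident on the plasma membrane,
#' the recycling fraction of the vesicular pool mobilized by prolonged
#' stimulation, the readily releasable fraction released by a brief
#' high-frequency burst, and the time constant of recycling-pool
#' mobilization. `vesicular_quench` is the residual visibility of pHluorin
#' at vesicular pH (the probe is ~94% quenched inside acidic vesicles).
#'
#' @param total_units total fluorescence of the bouton (a.u.), > 0.
#' @param surface_frac surface (plasma-membrane) fraction in `[0, 1]`.
#' @param recycling_frac recycling fraction of the vesicular pool, `[0, 1]`.
#' @param rrp_frac readily releasable fraction, `<= recycling_frac`.
#' @param tau_true recycling-pool mobilization time constant (s), > 0.
#' @param vesicular_quench residual visible fraction at vesicular pH.
#' @param responsive logical; non-responsive boutons never fuse vesicles
#'   but still dequench under NH4Cl.
#'
#' @return An object of class `bouton_ground_truth`.
#' @export
bouton_ground_truth <- function(total_units = 1000, surface_frac = 0.25,
                                recycling_frac = 0.55, rrp_frac = 0.08,
                                tau_true = 20, vesicular_quench = 0.06,
                                responsive = TRUE) {
  fr <- c(surface_frac, recycling_frac, rrp_frac, vesicular_quench)
  if (any(fr < 0) || any(fr > 1)) stop("all fractions must lie in [0, 1]")
  if (rrp_frac > recycling_frac) {
    stop("rrp_frac must not exceed recycling_frac (the RRP is a subset of the recycling pool)")
  }
  if (!is.finite(total_units) || total_units <= 0) stop("total_units must be > 0")
  if (is.na(tau_true) || tau_true <= 0) stop("tau_true must be > 0")
  structure(
    list(total_units = total_units, surface_frac = surface_frac,
         recycling_frac = recycling_frac, rrp_frac = rrp_frac,
         tau_true = tau_true, vesicular_quench = vesicular_quench,
         responsive = isTRUE(responsive)),
    class = "bouton_ground_truth"
  )
}

#' Acquisition noise and photobleaching model
#'
#' @param sigma_rel Gaussian noise SD as a fraction of the bouton's total
#'   fluorescence (background ROIs scale it by their background level).
#' @param background_level background autofluorescence (a.u.).
#' @param bleach_tau photobleaching time constant (s); `Inf` disables bleach.
#' @param q_mes residual pHluorin visibility in pH 5.5 MES buffer.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_rel = 0.02, background_level = 50,
                        bleach_tau = 600, q_mes = 0.03) {
  if (sigma_rel < 0) stop("sigma_rel must be >= 0")
  if (background_level < 0) stop("background_level must be >= 0")
  if (!(bleach_tau > 0)) stop("bleach_tau must be > 0 (use Inf to disable)")
  structure(
    list(sigma_rel = sigma_rel, background_level = background_level,
         bleach_tau = bleach_tau, q_mes = q_mes),
    class = "noise_model"
  )
}

# Cumulative fused fraction c(t) of the vesicular pool under bafilomycin
# (no reacidification, so c is non-decreasing). Tonic 10 Hz stimulation
# mobilizes the recycling pool as R*(1 - exp(-t/tau)); a 20 Hz burst
# releases the RRP linearly over its duration; the recovery gap holds c
# flat; a subsequent tonic segment resumes first-order kinetics toward R.
cumulative_fusion <- function(times, gt, proto) {
  c_t <- numeric(length(times))
  if (!gt$responsive) return(c_t)
  seg <- proto$stim_segments
  if (nrow(seg) == 0) return(c_t)
  seg <- seg[order(seg$start), , drop = FALSE]
  c0 <- 0
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    sel <- times >= s$start & times < s$end
    rel <- times[sel] - s$start
    val <- switch(s$kind,
      burst = c0 + (gt$rrp_frac - c0) * rel / (s$end - s$start),
      recovery = rep(c0, sum(sel)),
      tonic = gt$recycling_frac -
        (gt$recycling_frac - c0) * exp(-rel / gt$tau_true),
      stop("unknown stimulation segment kind: ", s$kind))
    c_t[sel] <- val
    # carry c to the segment end
    dur <- s$end - s$start
    c0 <- switch(s$kind,
      burst = gt$rrp_frac,
      recovery = c0,
      tonic = gt$recycling_frac -
        (gt$recycling_frac - c0) * exp(-dur / gt$tau_true))
  }
  c_t[times >= seg$end[nrow(seg)]] <- c0
  c_t
}

# Visible fraction V(t) of a bouton's total fluorescence. At bath pH 7.4,
# surface pHluorin is fully visible and vesicular pHluorin contributes its
# fused fraction plus the residual quench of unfused vesicles. NH4Cl
# collapses all pH gradients (V = 1); MES quenches surface pHluorin too
# (V = q_mes).
visibility <- function(times, gt, proto, q_mes) {
  c_t <- cumulative_fusion(times, gt, proto)
  s <- gt$surface_frac
  qv <- gt$vesicular_quench
  v <- s + (1 - s) * (c_t + qv * (1 - c_t))
  if (has_window(proto, "mes")) {
    v[in_window(times, proto$windows$mes)] <- q_mes
  }
  v[in_window(times, proto$windows$nh4cl)] <- 1
  v
}

#' Simulate the fluorescence trace of one bouton
#'
#' Generates `F(t) = bleach(t) * (background + T * V(t)) + eps`, where
#' `bleach(t) = exp(-(t - t_first)/bleach_tau)`, `eps ~ N(0, sigma_rel * T)`
#' and `V(t)` is the visible fraction of the bouton's total fluorescence
#' under the protocol's stimulation and buffer sequence (see
#' [bouton_ground_truth()]).
#'
#' @param gt a [bouton_ground_truth()].
#' @param proto a [protocol()]; must contain an NH4Cl window (otherwise the
#'   total pool is unrecoverable) and, for evoked assays, at least five
#'   baseline frames.
#' @param noise a [noise_model()].
#' @param roi_id ROI identifier.
#'
#' @return A raw [roi_trace()] with role `"synaptic"`.
#' @export
simulate_bouton_trace <- function(gt, proto, noise = noise_model(),
                                  roi_id = "roi_1") {
  stopifnot(inherits(gt, "bouton_ground_truth"), inherits(proto, "protocol"),
            inherits(noise, "noise_model"))
  if (!has_window(proto, "nh4cl")) {
    stop("protocol lacks an NH4Cl window: total pool unrecoverable")
  }
  if (has_window(proto, "baseline") &&
      length(window_idx(proto, "baseline")) < 5) {
    stop("protocol must provide at least 5 baseline frames")
  }
  t <- proto$frame_times
  v <- visibility(t, gt, proto, noise$q_mes)
  bleach <- exp(-(t - t[1]) / noise$bleach_tau)
  f <- bleach * (noise$background_level + gt$total_units * v)
  if (noise$sigma_rel > 0) {
    f <- f + stats::rnorm(length(t), sd = noise$sigma_rel * gt$total_units)
  }
  roi_trace(roi_id, "synaptic", t, f)
}

#' Simulate a background (autofluorescence) ROI
#'
#' Background ROIs carry only the bleaching background level plus noise and
#' share the field's bleach time constant, which is what the
#' background-based bleach correction assumes.
#'
#' @inheritParams simulate_bouton_trace
#' @return A raw [roi_trace()] with role `"background"`.
#' @export
simulate_background_trace <- function(proto, noise = noise_model(),
                                      roi_id = "bg_1") {
  t <- proto$frame_times
  bleach <- exp(-(t - t[1]) / noise$bleach_tau)
  f <- bleach * noise$background_level
  if (noise$sigma_rel > 0) {
    f <- f + stats::rnorm(length(t),
                          sd = noise$sigma_rel * noise$background_level)
  }
  roi_trace(roi_id, "background", t, f)
}

#' Per-bouton parameter ranges for field simulation
#'
#' Boutons within a field draw each generative parameter uniformly from
#' `value * (1 - rel_jitter, 1 + rel_jitter)` (fractions clipped to `[0, 1]`,
#' and the RRP fraction kept below the recycling fraction), emulating
#' bouton-to-bouton heterogeneity around the field's nominal parameters.
#'
#' @inheritParams bouton_ground_truth
#' @param rel_jitter relative half-width of the uniform jitter.
#' @return A list of ranges consumed by [simulate_field()].
#' @export
gt_ranges <- function(total_units = 1000, surface_frac = 0.25,
                      recycling_frac = 0.55, rrp_frac = 0.08, tau = 20,
                      vesicular_quench = 0.06, rel_jitter = 0.1) {
  rng <- function(v) sort(v * c(1 - rel_jitter, 1 + rel_jitter))
  list(total_units = rng(total_units), surface_frac = pmin(rng(surface_frac), 1),
       recycling_frac = pmin(rng(recycling_frac), 1),
       rrp_frac = pmin(rng(rrp_frac), 1), tau = rng(tau),
       vesicular_quench = vesicular_quench)
}

draw_gt <- function(ranges, responsive = TRUE) {
  u <- function(r) if (length(r) == 2) stats::runif(1, r[1], r[2]) else r
  rec <- u(ranges$recycling_frac)
  bouton_ground_truth(
    total_units = u(ranges$total_units),
    surface_frac = u(ranges$surface_frac),
    recycling_frac = rec,
    rrp_frac = min(u(ranges$rrp_frac), rec),
    tau_true = u(ranges$tau),
    vesicular_quench = ranges$vesicular_quench,
    responsive = responsive
  )
}

#' Simulate one field of view
#'
#' Generates a complete field: responsive boutons, non-responsive ("dead")
#' boutons that dequench under NH4Cl but never fuse vesicles, and background
#' autofluorescence ROIs sharing the field's bleach constant. Per-ROI ground
#' truth is retained on the returned record.
#'
#' @param n_responsive,n_dead,n_background ROI counts; at least one
#'   background ROI is required for bleach fitting.
#' @param ranges parameter ranges from [gt_ranges()].
#' @param proto a [protocol()].
#' @param noise a [noise_model()].
#' @param variant,field_id labels carried on the record.
#' @param seed optional integer; when given, the field is reproducible.
#'
#' @return A [field_record()].
#' @export
simulate_field <- function(n_responsive = 25, n_dead = 5, n_background = 4,
                           ranges = gt_ranges(),
                           proto = protocol_pool_1200ap(),
                           noise = noise_model(), variant = "WT",
                           field_id = "field_1", seed = NULL) {
  if (n_responsive + n_dead + n_background == 0) {
    stop("field must contain at least one ROI")
  }
  if (n_background < 1) stop("at least one background ROI is required for bleach fitting")
  if (!is.null(seed)) set.seed(seed)
  traces <- list()
  gt_rows <- list()
  k <- 0
  for (i in seq_len(n_responsive + n_dead)) {
    responsive <- i <= n_responsive
    gt <- draw_gt(ranges, responsive = responsive)
    k <- k + 1
    id <- sprintf("roi_%02d", k)
    traces[[k]] <- simulate_bouton_trace(gt, proto, noise, roi_id = id)
    gt_rows[[k]] <- data.frame(
      roi_id = id, responsive = responsive, total_units = gt$total_units,
      surface_frac = gt$surface_frac, recycling_frac = gt$recycling_frac,
      rrp_frac = gt$rrp_frac, tau_true = gt$tau_true,
      vesicular_quench = gt$vesicular_quench)
  }
  for (j in seq_len(n_background)) {
    k <- k + 1
    traces[[k]] <- simulate_background_trace(
      proto, noise, roi_id = sprintf("bg_%02d", j))
  }
  field_record(field_id, variant, proto, traces,
               ground_truth = do.call(rbind, gt_rows))
}

#' Simulate a membrane-partitioning trace
#'
#' Sequential saline / MES / NH4Cl perfusion of an unstimulated bouton. In
#' the noiseless case the window plateaus follow the generative model:
#' saline `s + (1 - s) q_v` of total, MES `q_mes`, NH4Cl 1.
#'
#' @inheritParams simulate_bouton_trace
#' @return A raw [roi_trace()].
#' @export
simulate_partitioning_trace <- function(gt, proto = protocol_partitioning(),
                                        noise = noise_model(),
                                        roi_id = "roi_1") {
  for (w in c("saline", "mes", "nh4cl")) {
    if (!has_window(proto, w)) {
      stop(sprintf("partitioning protocol lacks a '%s' window", w))
    }
  }
  simulate_bouton_trace(gt, proto, noise, roi_id = roi_id)
}

#' Simulate an axonal line-profile intensity sequence
#'
#' A single-pixel line profile along a neurite: a flat baseline plus
#' Gaussian-shaped puncta plus optional noise. Profiles must correspond to
#' >60 um of neurite at the camera's 0.227 um/px sampling (>= 265 px).
#'
#' @param length_px profile length in pixels (>= 265).
#' @param n_puncta number of puncta placed uniformly at random.
#' @param punctum_amp peak amplitude of each punctum (a.u.).
#' @param baseline diffuse axonal fluorescence (a.u.).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param sigma_px Gaussian width of each punctum (pixels).
#'
#' @return Numeric vector of intensities, one per pixel.
#' @export
simulate_line_profile <- function(length_px = 300, n_puncta = 10,
                                  punctum_amp = 200, baseline = 50,
                                  noise_sd = 0, sigma_px = 3) {
  if (length_px < 265) {
    stop("profile shorter than the 60 um minimum (265 px at 0.227 um/px)")
  }
  x <- seq_len(length_px)
  y <- rep(baseline, length_px)
  if (n_puncta > 0) {
    centers <- stats::runif(n_puncta, 1, length_px)
    for (cc in centers) {
      y <- y + punctum_amp * exp(-(x - cc)^2 / (2 * sigma_px^2))
    }
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length_px, sd = noise_sd)
  y
}
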