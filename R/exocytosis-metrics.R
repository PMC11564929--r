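#' Recycling pool size as a percentage of the total vesicle pool
#'
#' `100 * (end-of-stimulation dF/F0) / (NH4Cl peak dF/F0)`, using the same
#' window operationalizations as [normalize_trace()]: end of stimulation is
#' the mean of the last 5 stimulation-window frames and the NH4Cl peak is
#' the window maximum.
#'
#' @param mean_trace field-mean dF/F0 data frame (`time_s`, `dff`).
#' @param proto the 1200 AP [protocol()].
#'
#' @return Percentage of the total pool mobilized by the stimulus train.
#' @export
recycling_pool_fraction <- function(mean_trace, proto) {
  peak <- nh4cl_peak_value(mean_trace, proto)
  if (peak <= 0) stop(sprintf("NH4Cl peak is %.4g <= 0", peak))
  100 * stim_end_value(mean_trace, proto) / peak
}

#' One-phase exponential fit of cumulative exocytosis
#'
#' Fits `P * (1 - exp(-t / tau))` by nonlinear least squares over the full
#' stimulation window of a stim-peak-normalized trace. The plateau `P` is a
#' free parameter bounded in `(0, 1.5]` (stim-peak normalization pins the
#' endpoint, not the asymptote, at 1; fixing `P = 1` would bias tau downward
#' for non-saturating traces). `tau` is bounded in `(0.1, 10 * window]` and
#' flagged when it lands on a bound.
#'
#' @param norm_trace stim-peak-normalized trace (`time_s`, `dff`).
#' @param proto the field's [protocol()]; the stimulation window must hold
#'   at least 30 frames.
#'
#' @return List with `tau_s`, `plateau`, `rss`, `converged`, `at_bound`.
#' @export
fit_one_phase <- function(norm_trace, proto) {
  i <- which(in_window(norm_trace$time_s, proto$windows$stim))
  if (length(i) < 30) stop("stimulation window must contain >= 30 frames")
  t <- norm_trace$time_s[i]
  y <- norm_trace$dff[i]
  win <- diff(proto$windows$stim)
  lo <- c(P = 1e-6, tau = 0.1)
  hi <- c(P = 1.5, tau = 10 * win)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ P * (1 - exp(-t / tau)),
                      start = list(P = 1, tau = win / 5),
                      lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop(sprintf("one-phase fit failed: %s (rss of start = %.4g)",
                 conditionMessage(fit),
                 sum((y - (1 - exp(-t / (win / 5))))^2)))
  }
  cf <- stats::coef(fit)
  tau <- unname(cf["tau"])
  p_hat <- unname(cf["P"])
  # a parameter pinned to a bound (e.g. by a non-saturating, near-linear
  # trace) means tau is not interpretable as a mobilization time constant
  at_bound <- tau <= lo["tau"] * (1 + 1e-6) ||
    tau >= hi["tau"] * (1 - 1e-6) || p_hat >= hi["P"] * (1 - 1e-6)
  list(tau_s = tau, plateau = unname(cf["P"]),
       rss = sum(stats::resid(fit)^2),
       converged = fit$convInfo$isConv, at_bound = at_bound)
}

#' Initial exocytic rate over the first 5 s of stimulation
#'
#' Least-squares slope of the NH4Cl-peak-normalized trace over
#' `t in [0, 5]` s, where the exocytic rate is largely linear. Units:
#' normalized dF/F0 per second.
#'
#' @param norm_trace NH4Cl-normalized trace (`time_s`, `dff`).
#' @param proto the field's [protocol()].
#'
#' @return Slope in normalized dF/F0 per second.
#' @export
initial_exocytic_rate <- function(norm_trace, proto) {
  sel <- norm_trace$time_s >= 0 & norm_trace$time_s <= 5
  if (sum(sel) < 3) stop("need >= 3 frames in t in [0, 5] s")
  unname(stats::coef(stats::lm(dff ~ time_s, data = norm_trace[sel, ]))[2])
}

#' Percentage of vesicles fused after a given number of action potentials
#'
#' Reads the NH4Cl-normalized trace at the frame nearest
#' `t* = n_ap / stimulation frequency` (200 AP at 10 Hz reads t* = 20 s).
#' Nearest-frame lookup, not interpolation.
#'
#' @param norm_trace NH4Cl-normalized trace (`time_s`, `dff`).
#' @param proto the field's [protocol()]; the tonic frequency defines t*.
#' @param n_ap number of action potentials (>= 0).
#'
#' @return Percent of the total pool fused by `n_ap` action potentials.
#' @export
fraction_fused_at_ap <- function(norm_trace, proto, n_ap) {
  stopifnot(n_ap >= 0)
  seg <- proto$stim_segments
  tonic <- seg[seg$kind == "tonic", , drop = FALSE][1, ]
  t_star <- tonic$start + n_ap / tonic$freq_hz
  w <- proto$windows$stim
  i <- which(in_window(norm_trace$time_s, w))
  dt <- stats::median(diff(norm_trace$time_s[i]))
  if (t_star < w[1] - dt / 2 || t_star > w[2] + dt / 2) {
    stop(sprintf("t* = %.4g s for %d AP lies outside the stimulation window [%g, %g)",
                 t_star, n_ap, w[1], w[2]))
  }
  nearest <- i[which.min(abs(norm_trace$time_s[i] - t_star))]
  100 * norm_trace$dff[nearest]
}

#' Readily releasable pool as a percentage of the total pool
#'
#' Mean NH4Cl-normalized dF/F0 over the 3 s recovery gap following the
#' 40 AP, 20 Hz burst (`t in [2, 5)` s), using the 10 Hz-sampled frames the
#' protocol provides, expressed as a percentage of the total pool revealed
#' by NH4Cl.
#'
#' @param norm_trace NH4Cl-normalized trace (`time_s`, `dff`).
#' @param proto the RRP [protocol()]; must define a `recovery` window.
#'
#' @return RRP size in percent of the total pool.
#' @export
rrp_fraction <- function(norm_trace, proto) {
  if (!has_window(proto, "recovery")) {
    stop("protocol has no burst recovery window; not an RRP protocol")
  }
  sel <- in_window(norm_trace$time_s, proto$windows$recovery)
  if (!any(sel)) stop("no frames in the recovery window")
  100 * mean(norm_trace$dff[sel])
}

#' All exocytosis metrics of one processed field
#'
#' For the 1200 AP protocol: recycling pool (%), one-phase tau (s), initial
#' exocytic rate and % fused by 200 AP. For the RRP protocol: RRP (%).
#'
#' @param processed output of [process_field()].
#' @param n_ap action-potential count for the fused-fraction read-out.
#'
#' @return One-row data frame of metrics plus fit diagnostics as attribute
#'   `fit_diagnostics`.
#' @export
field_metrics <- function(processed, n_ap = 200) {
  proto <- processed$protocol
  tr <- processed$mean_dff
  if (is.null(tr)) stop("field did not pass QC; no mean trace")
  out <- data.frame(field_id = processed$field_id,
                    variant = processed$variant,
                    n_responsive = processed$qc$n_responsive)
  nh <- normalize_trace(tr, "nh4cl_peak", proto)
  if (has_window(proto, "recovery")) {
    out$rrp_pct <- rrp_fraction(nh, proto)
    attr(out, "fit_diagnostics") <- list()
    return(out)
  }
  sp <- normalize_trace(tr, "stim_peak", proto)
  fit <- fit_one_phase(sp, proto)
  out$recycling_pool_pct <- recycling_pool_fraction(tr, proto)
  out$tau_s <- fit$tau_s
  out$initial_rate <- initial_exocytic_rate(nh, proto)
  out$frac_fused_200AP_pct <- fraction_fused_at_ap(nh, proto, n_ap)
  attr(out, "fit_diagnostics") <- list(one_phase = fit)
  out
}

#' Per-variant summary of field-level metrics
#'
#' @param metrics data frame of per-field metrics (rows from
#'   [field_metrics()]).
#' @return Data frame with mean, SEM and n per variant and metric.
#' @export
summarize_metrics <- function(metrics) {
  num <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                 "n_responsive")
  do.call(rbind, lapply(split(metrics, metrics$variant), function(d) {
    row <- data.frame(variant = d$variant[1], n = nrow(d))
    for (m in num) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      row[[paste0(m, "_sem")]] <- stats::sd(d[[m]]) / sqrt(nrow(d))
    }
    row
  }))
}
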