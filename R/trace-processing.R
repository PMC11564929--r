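#' Fit the photobleaching decay of background ROIs
#'
#' Fits a single exponential `a * exp(-b * t)` by nonlinear least squares to
#' the mean background-ROI trace over the experiment prior to NH4Cl
#' superfusion, with `t` measured from the first acquired frame. The decay
#' rate is clipped at zero when the background does not decay.
#'
#' @param background_traces a list of background [roi_trace()] objects (or a
#'   single one).
#' @param nh4cl_onset NH4Cl onset (seconds); only earlier frames are fitted.
#'
#' @return A `bleach_model`: list with `a` (a.u.), `b` (1/s), `fit_window`,
#'   `rss` and `n_frames`.
#' @export
fit_background_bleach <- function(background_traces, nh4cl_onset) {
  if (inherits(background_traces, "roi_trace")) {
    background_traces <- list(background_traces)
  }
  if (length(background_traces) < 1) stop("at least one background ROI required")
  t <- background_traces[[1]]$time_s
  mat <- vapply(background_traces, function(tr) {
    if (!isTRUE(all.equal(tr$time_s, t))) {
      stop("background traces must share one frame schedule")
    }
    tr$intensity
  }, numeric(length(t)))
  y_full <- rowMeans(as.matrix(mat))
  pre <- t < nh4cl_onset
  if (sum(pre) < 10) stop("need >= 10 frames before NH4Cl onset to fit bleach")
  tt <- t[pre] - t[1]
  y <- y_full[pre]
  if (all(y == 0)) stop("background trace is identically zero; cannot fit bleach")

  # log-linear initializer (positive part); slope >= 0 means no decay
  pos <- y > 0
  init <- stats::coef(stats::lm(log(y[pos]) ~ tt[pos]))
  if (!is.finite(init[2]) || init[2] >= -1e-8) {
    a <- mean(y)
    return(structure(list(a = a, b = 0, fit_window = c(t[1], nh4cl_onset),
                          rss = sum((y - a)^2), n_frames = length(y)),
                     class = "bleach_model"))
  }
  start <- list(a = exp(init[[1]]), b = -init[[2]])
  fit <- NULL
  for (attempt in 1:3) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-b * tt), start = start,
                        lower = c(a = 0, b = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
    start <- list(a = max(y), b = start$b * 2)
  }
  if (is.null(fit)) {
    stop(sprintf(
      "bleach fit failed after retries (start a=%.3g b=%.3g, mean y=%.3g)",
      start$a, start$b, mean(y)))
  }
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 fit_window = c(t[1], nh4cl_onset),
                 rss = sum(stats::resid(fit)^2), n_frames = length(y)),
            class = "bleach_model")
}

#' @export
print.bleach_model <- function(x, ...) {
  cat(sprintf("<bleach_model> a = %.4g a.u., b = %.4g /s (tau = %s s), %d frames, rss = %.4g\n",
              x$a, x$b, ifelse(x$b > 0, sprintf("%.4g", 1 / x$b), "Inf"),
              x$n_frames, x$rss))
  invisible(x)
}

#' Correct a trace for photobleaching
#'
#' Ratio correction: each intensity is multiplied by `exp(b * (t - t_first))`
#' so that the first frame is unchanged and the fitted exponential decay is
#' exactly undone.
#'
#' @param trace a raw [roi_trace()].
#' @param model a `bleach_model` from [fit_background_bleach()], fitted on
#'   the same field.
#'
#' @return The corrected trace, flagged `bleach_corrected`.
#' @export
apply_bleach_correction <- function(trace, model) {
  stopifnot(inherits(trace, "roi_trace"), inherits(model, "bleach_model"))
  if (has_flag(trace, "bleach_corrected")) {
    stop("trace is already bleach-corrected")
  }
  trace$intensity <- trace$intensity *
    exp(model$b * (trace$time_s - trace$time_s[1]))
  add_flag(trace, "bleach_corrected")
}

#' Compute dF/F0 relative to the pre-stimulation baseline
#'
#' The baseline `F0` is the mean of the 5 frames immediately preceding
#' stimulation onset; the output is `(F - F0) / F0` per frame (equivalently
#' `F/F0` with the baseline of 1 subtracted).
#'
#' @param trace an intensity [roi_trace()] (bleach-corrected for evoked
#'   assays).
#' @param stim_onset stimulation onset (seconds).
#'
#' @return The trace with `intensity` replaced by dF/F0, flagged `dff`.
#' @export
compute_dff <- function(trace, stim_onset = 0) {
  stopifnot(inherits(trace, "roi_trace"))
  if (has_flag(trace, "dff")) stop("trace is already dF/F0")
  pre <- which(trace$time_s < stim_onset)
  if (length(pre) < 5) stop("need >= 5 frames before stimulation onset")
  f0 <- mean(trace$intensity[utils::tail(pre, 5)])
  if (f0 <= 0) {
    stop(sprintf("baseline F0 = %.4g <= 0 (failed background subtraction?)", f0))
  }
  trace$intensity <- (trace$intensity - f0) / f0
  add_flag(trace, "dff")
}

#' Screen ROIs for stimulation and NH4Cl responsiveness
#'
#' An ROI is responsive when its mean dF/F0 over the stimulation window
#' exceeds `noise_k` baseline SDs *and* its peak dF/F0 in the NH4Cl window
#' exceeds the same threshold (i.e. fluorescence increased from baseline
#' upon both electrical stimulation and NH4Cl superfusion). A field passes
#' only with strictly more than 20 responsive ROIs.
#'
#' @param dff_traces list of synaptic dF/F0 [roi_trace()] objects.
#' @param proto the field's [protocol()].
#' @param noise_k threshold multiplier on the baseline SD (the SD of the
#'   5 baseline frames).
#'
#' @return A `qc_report`: list with per-ROI data frame (`roi_id`,
#'   `included`, `reason`), `n_responsive` and `field_pass`.
#' @export
screen_rois <- function(dff_traces, proto, noise_k = 2) {
  stopifnot(length(dff_traces) > 0)
  stim_i <- window_idx(proto, "stim")
  nh_i <- window_idx(proto, "nh4cl")
  base_i <- window_idx(proto, "baseline")
  rows <- lapply(dff_traces, function(tr) {
    if (!has_flag(tr, "dff")) stop("screen_rois expects dF/F0 traces")
    f <- tr$intensity
    sd_b <- stats::sd(f[utils::tail(base_i, 5)])
    thr <- noise_k * sd_b
    stim_ok <- mean(f[stim_i]) > thr
    nh_ok <- max(f[nh_i]) > thr
    reason <- if (stim_ok && nh_ok) "" else if (!stim_ok) {
      "no_stim_response"
    } else "no_nh4cl_response"
    data.frame(roi_id = tr$roi_id, included = stim_ok && nh_ok,
               reason = reason)
  })
  roi <- do.call(rbind, rows)
  n_resp <- sum(roi$included)
  structure(list(roi = roi, n_responsive = n_resp,
                 field_pass = n_resp > 20, noise_k = noise_k),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d responsive ROIs; field %s (rule: > 20 responsive)\n",
              x$n_responsive, nrow(x$roi),
              ifelse(x$field_pass, "PASS", "FAIL")))
  invisible(x)
}

#' Average dF/F0 over the included ROIs of a field
#'
#' @param dff_traces list of synaptic dF/F0 [roi_trace()] objects.
#' @param qc the field's [screen_rois()] report; the field must pass QC.
#'
#' @return Data frame with `time_s` and `dff` (frame-wise mean over
#'   included ROIs).
#' @export
field_average <- function(dff_traces, qc) {
  stopifnot(inherits(qc, "qc_report"))
  if (!qc$field_pass) {
    stop(sprintf("field excluded: only %d responsive ROIs (> 20 required)",
                 qc$n_responsive))
  }
  keep <- qc$roi$roi_id[qc$roi$included]
  kept <- Filter(function(tr) tr$roi_id %in% keep, dff_traces)
  t <- kept[[1]]$time_s
  mat <- vapply(kept, function(tr) tr$intensity, numeric(length(t)))
  data.frame(time_s = t, dff = rowMeans(as.matrix(mat)))
}

#' Normalize a field-mean dF/F0 trace
#'
#' `stim_peak` mode divides by the fluorescence at the end of stimulation
#' (mean of the last 5 stimulation-window frames, robust to single-frame
#' noise); `nh4cl_peak` mode divides by the maximum dF/F0 within the NH4Cl
#' window (the total-pool reference).
#'
#' @param mean_trace data frame with `time_s`, `dff` from [field_average()].
#' @param mode `"stim_peak"` or `"nh4cl_peak"`.
#' @param proto the field's [protocol()].
#'
#' @return The trace divided by the reference value (which becomes 1).
#' @export
normalize_trace <- function(mean_trace,
                            mode = c("stim_peak", "nh4cl_peak"), proto) {
  mode <- match.arg(mode)
  ref <- if (mode == "stim_peak") {
    stim_end_value(mean_trace, proto)
  } else {
    nh4cl_peak_value(mean_trace, proto)
  }
  if (ref <= 0) stop(sprintf("%s reference is %.4g <= 0", mode, ref))
  out <- mean_trace
  out$dff <- out$dff / ref
  attr(out, "normalization") <- mode
  out
}

# mean dF/F0 of the last 5 frames inside the stimulation window
stim_end_value <- function(mean_trace, proto) {
  i <- which(in_window(mean_trace$time_s, proto$windows$stim))
  if (length(i) == 0) stop("trace has no frames in the stimulation window")
  mean(mean_trace$dff[utils::tail(i, 5)])
}

# maximum dF/F0 inside the NH4Cl window
nh4cl_peak_value <- function(mean_trace, proto) {
  i <- which(in_window(mean_trace$time_s, proto$windows$nh4cl))
  if (length(i) == 0) stop("trace has no frames in the NH4Cl window")
  max(mean_trace$dff[i])
}

#' Process a raw field into a QC-screened mean dF/F0 trace
#'
#' Runs the full per-field pipeline: mean background-ROI subtraction,
#' background-based bleach fitting and correction, per-ROI dF/F0,
#' responsiveness screening, and averaging over included ROIs.
#'
#' @param field a [field_record()] of raw traces.
#' @param noise_k QC threshold multiplier (see [screen_rois()]).
#' @param require_pass error when the field fails QC (default) rather than
#'   returning with `mean_dff = NULL`.
#'
#' @return List with `mean_dff` (data frame `time_s`, `dff`), `qc`,
#'   `bleach`, and the field's `protocol`/labels carried forward.
#' @export
process_field <- function(field, noise_k = 2, require_pass = TRUE) {
  stopifnot(inherits(field, "field_record"))
  proto <- field$protocol
  bg <- field_traces(field, "background")
  if (length(bg) == 0) stop("field has no background ROIs")
  bleach <- fit_background_bleach(bg, proto$nh4cl_onset)
  t <- bg[[1]]$time_s
  bg_mean <- rowMeans(vapply(bg, function(tr) tr$intensity,
                             numeric(length(t))))
  syn <- field_traces(field, "synaptic")
  dff <- lapply(syn, function(tr) {
    tr$intensity <- tr$intensity - bg_mean
    tr <- apply_bleach_correction(tr, bleach)
    compute_dff(tr, stim_onset = proto$windows$baseline[2])
  })
  qc <- screen_rois(dff, proto, noise_k = noise_k)
  mean_dff <- NULL
  if (qc$field_pass) {
    mean_dff <- field_average(dff, qc)
  } else if (require_pass) {
    stop(sprintf("field %s excluded: %d responsive ROIs (> 20 required)",
                 field$field_id, qc$n_responsive))
  }
  list(field_id = field$field_id, variant = field$variant,
       protocol = proto, mean_dff = mean_dff, qc = qc, bleach = bleach,
       dff_traces = dff)
}
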