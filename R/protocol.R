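#' Stimulation and perfusion protocols
#'
#' A protocol bundles the frame-acquisition schedule with the stimulation
#' segments (action-potential count, frequency, time window) and the buffer
#' windows (baseline saline, NH4Cl dequench, MES acid quench) of one assay.
#' All windows are half-open intervals `[start, end)` in seconds; `t = 0` is
#' stimulation onset for evoked assays.
#'
#' @param name protocol identifier.
#' @param frame_times strictly increasing acquisition times (seconds).
#' @param windows named list of `c(start, end)` windows (seconds).
#' @param stim_segments data frame with columns `kind` (`"burst"`,
#'   `"recovery"` or `"tonic"`), `start`, `end`, `freq_hz`, `n_ap`.
#' @param nh4cl_onset onset of NH4Cl superfusion (seconds); bleach fitting
#'   uses only frames before this time.
#'
#' @return An object of class `protocol`.
#' @export
protocol <- function(name, frame_times, windows,
                     stim_segments = empty_stim_segments(),
                     nh4cl_onset = NA_real_) {
  stopifnot(is.numeric(frame_times), all(diff(frame_times) > 0))
  if (!is.list(windows) || is.null(names(windows))) {
    stop("`windows` must be a named list of c(start, end) intervals")
  }
  for (w in windows) {
    if (length(w) != 2 || w[2] <= w[1]) {
      stop("each window must be c(start, end) with end > start")
    }
  }
  structure(
    list(name = name, frame_times = as.numeric(frame_times),
         windows = windows, stim_segments = stim_segments,
         nh4cl_onset = nh4cl_onset),
    class = "protocol"
  )
}

empty_stim_segments <- function() {
  data.frame(kind = character(), start = numeric(), end = numeric(),
             freq_hz = numeric(), n_ap = numeric())
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol>", x$name, "\n")
  cat("  frames:", length(x$frame_times), "spanning",
      sprintf("[%g, %g] s", min(x$frame_times), max(x$frame_times)), "\n")
  for (nm in names(x$windows)) {
    cat(sprintf("  window %-9s [%g, %g) s\n", nm,
                x$windows[[nm]][1], x$windows[[nm]][2]))
  }
  if (nrow(x$stim_segments)) {
    for (i in seq_len(nrow(x$stim_segments))) {
      s <- x$stim_segments[i, ]
      cat(sprintf("  stim %-7s [%g, %g) s, %g Hz, %g AP\n",
                  s$kind, s$start, s$end, s$freq_hz, s$n_ap))
    }
  }
  invisible(x)
}

#' Recycling-pool protocol: 1200 AP at 10 Hz
#'
#' Two minutes of 10 Hz field stimulation (1200 AP) under bafilomycin,
#' followed by NH4Cl superfusion to reveal the total pHluorin pool.
#' Frames every second; five baseline frames at t = -5..-1 s; NH4Cl
#' window at 140-160 s.
#'
#' @return A `protocol`.
#' @export
protocol_pool_1200ap <- function() {
  protocol(
    name = "pool_1200ap",
    frame_times = seq(-5, 159, by = 1),
    windows = list(baseline = c(-5, 0), stim = c(0, 120),
                   nh4cl = c(140, 160)),
    stim_segments = data.frame(
      kind = "tonic", start = 0, end = 120, freq_hz = 10, n_ap = 1200),
    nh4cl_onset = 140
  )
}

#' Readily-releasable-pool protocol: 40 AP at 20 Hz
#'
#' A 2 s, 20 Hz burst (40 AP) releasing the readily releasable pool, a 3 s
#' recovery gap, then continuous 10 Hz stimulation to identify active
#' boutons, and NH4Cl dequench. Frames are acquired at 10 Hz during the
#' 5 s burst-plus-recovery period and at 1 s intervals elsewhere.
#'
#' @return A `protocol`.
#' @export
protocol_rrp_40ap <- function() {
  frames <- c(seq(-5, -1, by = 1), seq(0, 4.9, by = 0.1),
              seq(5, 159, by = 1))
  protocol(
    name = "rrp_40ap",
    frame_times = frames,
    windows = list(baseline = c(-5, 0), burst = c(0, 2), recovery = c(2, 5),
                   stim = c(0, 125), nh4cl = c(140, 160)),
    stim_segments = data.frame(
      kind = c("burst", "recovery", "tonic"),
      start = c(0, 2, 5), end = c(2, 5, 125),
      freq_hz = c(20, 0, 10), n_ap = c(40, 0, 1200)),
    nh4cl_onset = 140
  )
}

#' Membrane-partitioning buffer sequence
#'
#' Sequential perfusion with pH 7.4 saline, pH 5.5 MES (quenching
#' surface-exposed pHluorin) and NH4Cl (revealing the total pool), with no
#' electrical stimulation. Gaps between windows model bath exchange.
#'
#' @return A `protocol`.
#' @export
protocol_partitioning <- function() {
  protocol(
    name = "partitioning",
    frame_times = seq(0, 109, by = 1),
    windows = list(saline = c(0, 30), mes = c(40, 70), nh4cl = c(80, 110)),
    nh4cl_onset = 80
  )
}

#' Look up a shipped protocol preset by name
#'
#' @param preset one of `"pool_1200ap"`, `"rrp_40ap"`, `"partitioning"`.
#' @return A `protocol`.
#' @export
protocol_preset <- function(preset = c("pool_1200ap", "rrp_40ap",
                                       "partitioning")) {
  preset <- match.arg(preset)
  switch(preset,
         pool_1200ap = protocol_pool_1200ap(),
         rrp_40ap = protocol_rrp_40ap(),
         partitioning = protocol_partitioning())
}

# TRUE for times inside the half-open window [start, end)
in_window <- function(times, window) {
  times >= window[1] & times < window[2]
}

# frame indices of a named protocol window; error when absent and required
window_idx <- function(proto, name, required = TRUE) {
  w <- proto$windows[[name]]
  if (is.null(w)) {
    if (required) stop(sprintf("protocol '%s' lacks a '%s' window",
                               proto$name, name))
    return(integer(0))
  }
  which(in_window(proto$frame_times, w))
}

has_window <- function(proto, name) !is.null(proto$windows[[name]])

# frequency (Hz) of the tonic stimulation segment
tonic_frequency <- function(proto) {
  seg <- proto$stim_segments
  tonic <- seg[seg$kind == "tonic", , drop = FALSE]
  if (nrow(tonic) == 0) stop("protocol has no tonic stimulation segment")
  tonic$freq_hz[1]
}
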