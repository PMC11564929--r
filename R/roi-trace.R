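#' One ROI's fluorescence time series
#'
#' @param roi_id identifier.
#' @param roi_role `"synaptic"` or `"background"`.
#' @param time_s strictly increasing frame times (seconds).
#' @param intensity fluorescence per frame (a.u.), finite.
#' @param flags processing-state flags; traces start `"raw"` and acquire
#'   `"bleach_corrected"`, `"dff"`, `"normalized_stim_peak"` or
#'   `"normalized_nh4cl"` as they move through the pipeline.
#'
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(roi_id, roi_role = c("synaptic", "background"),
                      time_s, intensity, flags = "raw") {
  roi_role <- match.arg(roi_role)
  time_s <- as.numeric(time_s)
  intensity <- as.numeric(intensity)
  if (length(time_s) != length(intensity)) {
    stop("time_s and intensity must have equal length")
  }
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (!all(is.finite(intensity))) stop("intensity must be finite")
  structure(
    list(roi_id = roi_id, roi_role = roi_role, time_s = time_s,
         intensity = intensity, flags = flags),
    class = "roi_trace"
  )
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("<roi_trace> %s (%s), %d frames [%g, %g] s, flags: %s\n",
              x$roi_id, x$roi_role, length(x$time_s), min(x$time_s),
              max(x$time_s), paste(x$flags, collapse = ", ")))
  invisible(x)
}

has_flag <- function(trace, flag) flag %in% trace$flags

add_flag <- function(trace, flag) {
  trace$flags <- union(trace$flags, flag)
  trace
}

#' All traces of one field of view
#'
#' A field record holds every ROI trace of a single field of view from an
#' independent coverslip, together with its protocol, variant label and --
#' for synthetic fields -- the generative ground truth per ROI.
#'
#' @param field_id identifier.
#' @param variant construct label (e.g. `"WT"`).
#' @param protocol a [protocol()].
#' @param traces list of [roi_trace()] objects.
#' @param ground_truth optional data frame of per-ROI generative parameters.
#'
#' @return An object of class `field_record`.
#' @export
field_record <- function(field_id, variant, protocol, traces,
                         ground_truth = NULL) {
  if (length(traces) == 0) stop("a field must contain at least one ROI")
  stopifnot(inherits(protocol, "protocol"))
  structure(
    list(field_id = field_id, variant = variant, protocol = protocol,
         traces = traces, ground_truth = ground_truth),
    class = "field_record"
  )
}

#' @export
print.field_record <- function(x, ...) {
  roles <- vapply(x$traces, function(tr) tr$roi_role, character(1))
  cat(sprintf("<field_record> %s (%s): %d synaptic + %d background ROIs, protocol %s\n",
              x$field_id, x$variant, sum(roles == "synaptic"),
              sum(roles == "background"), x$protocol$name))
  invisible(x)
}

field_traces <- function(field, role) {
  Filter(function(tr) tr$roi_role == role, field$traces)
}
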