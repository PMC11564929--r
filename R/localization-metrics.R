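#' Coefficient of variation of one axonal line profile
#'
#' Sample SD divided by mean of the fluorescence along a single-pixel line
#' over a neurite. High CV indicates punctate, synaptically enriched
#' protein; low CV a diffuse axonal distribution.
#'
#' @param profile numeric intensity sequence, >= 265 px (60 um at
#'   0.227 um/px).
#'
#' @return CV (dimensionless).
#' @export
profile_cv <- function(profile) {
  if (length(profile) < 265) {
    stop("profile shorter than the 60 um minimum (265 px at 0.227 um/px)")
  }
  m <- mean(profile)
  if (m <= 0) stop("profile mean must be > 0")
  stats::sd(profile) / m
}

#' Field-level coefficient of variation
#'
#' Arithmetic mean of the per-profile CVs of (at least) five >60 um axonal
#' segments from one field of view.
#'
#' @param profiles list of intensity sequences.
#'
#' @return Field CV, with per-profile CVs as attribute `per_profile`.
#' @export
coefficient_of_variation <- function(profiles) {
  if (!is.list(profiles)) profiles <- list(profiles)
  if (length(profiles) < 5) {
    stop("a field-level CV requires >= 5 axonal profiles")
  }
  cvs <- vapply(profiles, profile_cv, numeric(1))
  structure(mean(cvs), per_profile = cvs)
}

#' Surface/vesicle membrane partitioning of pHluorin fluorescence
#'
#' From the plateau means of the saline, MES and NH4Cl windows:
#' `surface_pct = 100 * (F_saline - F_MES) / (F_NH4Cl - F_MES)` and
#' `vesicular_pct = 100 - surface_pct`. Plateau means use the central 80%
#' of each buffer window to avoid perfusion-transition frames. Negative
#' noise-driven surface estimates are clipped to 0 and flagged.
#'
#' @param trace a raw partitioning [roi_trace()] (or data frame with
#'   `time_s`, `intensity`).
#' @param proto the partitioning [protocol()]; each buffer window must
#'   contain at least 3 frames.
#'
#' @return A `partition_result`: list with `surface_pct`, `vesicular_pct`,
#'   `window_means` and `clipped`.
#' @export
membrane_partition <- function(trace, proto) {
  t <- trace$time_s
  f <- trace$intensity
  plateau <- function(name) {
    w <- proto$windows[[name]]
    if (is.null(w)) stop(sprintf("protocol lacks a '%s' window", name))
    len <- w[2] - w[1]
    core <- c(w[1] + 0.1 * len, w[2] - 0.1 * len)
    sel <- t >= core[1] & t < core[2]
    if (sum(in_window(t, w)) < 3) {
      stop(sprintf("'%s' window has fewer than 3 frames", name))
    }
    mean(f[sel])
  }
  m <- c(saline = plateau("saline"), mes = plateau("mes"),
         nh4cl = plateau("nh4cl"))
  if (m["nh4cl"] <= m["mes"]) {
    stop("NH4Cl plateau does not exceed MES plateau: no dynamic range")
  }
  surface <- 100 * (m["saline"] - m["mes"]) / (m["nh4cl"] - m["mes"])
  clipped <- surface < 0
  surface <- max(unname(surface), 0)
  structure(list(surface_pct = surface, vesicular_pct = 100 - surface,
                 window_means = m, clipped = unname(clipped)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> surface %.1f%% / vesicular %.1f%%%s\n",
              x$surface_pct, x$vesicular_pct,
              if (x$clipped) " (clipped at 0)" else ""))
  invisible(x)
}

#' Expression fold-change over non-transfected cells
#'
#' `(mean(transfected) - mean(background)) /
#'  (mean(untransfected) - mean(background))`: the background-subtracted
#' fluorescence of transfected nerve terminals or somata relative to the
#' endogenous level in non-transfected cells. A fold-change of ~2 mimics
#' heterozygous expression (equal exogenous and endogenous copy number).
#'
#' @param transfected,untransfected,background ROI mean intensities (a.u.),
#'   at least one per class.
#' @param compartment `"terminal"` or `"soma"`.
#'
#' @return An `expression_result`: list with `fold_change`, `compartment`,
#'   `n_rois`.
#' @export
expression_fold_change <- function(transfected, untransfected, background,
                                   compartment = c("terminal", "soma")) {
  compartment <- match.arg(compartment)
  stopifnot(length(transfected) >= 1, length(untransfected) >= 1,
            length(background) >= 1)
  denom <- mean(untransfected) - mean(background)
  if (denom <= 0) {
    stop("untransfected signal does not exceed background; fold-change undefined")
  }
  structure(
    list(fold_change = (mean(transfected) - mean(background)) / denom,
         compartment = compartment,
         n_rois = c(transfected = length(transfected),
                    untransfected = length(untransfected),
                    background = length(background))),
    class = "expression_result"
  )
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("<expression_result> %.2f-fold over endogenous (%s)\n",
              x$fold_change, x$compartment))
  invisible(x)
}
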