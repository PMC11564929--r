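#' Read a long-format ROI trace table
#'
#' Parses a CSV with columns `field_id, roi_id, roi_role, frame_idx,
#' time_s, intensity` into field records. Malformed input (missing columns,
#' duplicated frames, non-monotone time) is reported with the offending
#' location.
#'
#' @param path CSV path.
#' @param proto the [protocol()] the traces were acquired under.
#'
#' @return List of [field_record()]s (canonically sorted by ROI and frame).
#' @export
read_trace_table <- function(path, proto) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("field_id", "roi_id", "roi_role", "frame_idx", "time_s",
            "intensity")
  missing <- setdiff(need, names(dat))
  if (length(missing)) {
    stop("trace table missing column(s): ", paste(missing, collapse = ", "))
  }
  dat$.line <- seq_len(nrow(dat)) + 1L  # header is line 1
  fields <- lapply(split(dat, dat$field_id), function(fd) {
    traces <- lapply(split(fd, fd$roi_id), function(rd) {
      rd <- rd[order(rd$frame_idx), ]
      dup <- duplicated(rd$frame_idx)
      if (any(dup)) {
        stop(sprintf("duplicate frame %d for ROI %s (line %d)",
                     rd$frame_idx[dup][1], rd$roi_id[1],
                     rd$.line[dup][1]))
      }
      if (any(diff(rd$time_s) <= 0)) {
        bad <- which(diff(rd$time_s) <= 0)[1] + 1
        stop(sprintf("non-monotone time for ROI %s (line %d)",
                     rd$roi_id[1], rd$.line[bad]))
      }
      roi_trace(rd$roi_id[1], rd$roi_role[1], rd$time_s, rd$intensity)
    })
    field_record(fd$field_id[1], variant = attr(dat, "variant") %||% "NA",
                 protocol = proto, traces = unname(traces))
  })
  unname(fields)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write field records as a long-format CSV
#'
#' @param fields list of [field_record()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(fields, path) {
  if (inherits(fields, "field_record")) fields <- list(fields)
  rows <- lapply(fields, function(fd) {
    do.call(rbind, lapply(fd$traces, function(tr) {
      data.frame(field_id = fd$field_id, roi_id = tr$roi_id,
                 roi_role = tr$roi_role,
                 frame_idx = seq_along(tr$time_s) - 1L,
                 time_s = tr$time_s, intensity = tr$intensity)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Reported clinical correlation summary
#'
#' Summary-level results of the SYT1 variant case series: Spearman's r and
#' p per (phenotype measure, exocytosis metric) pair, with the reported
#' value `< 0.001` encoded as 0.0009 (any encoding below the first BH
#' threshold yields identical flags). Shipped so the FDR replay runs
#' without any external data.
#'
#' @return Data frame with `measure`, `metric`, `r`, `p`, `reported_p`,
#'   `asterisk`.
#' @export
clinical_correlation_table <- function() {
  utils::read.csv(system.file("extdata", "clinical_correlation_pvalues.csv",
                              package = "vesiclequant"),
                  stringsAsFactors = FALSE)
}

#' Write a pipeline result bundle to disk
#'
#' Emits per-field metrics, per-variant summaries, QC, group comparisons
#' and correlation results as CSV plus a schema-versioned JSON summary.
#'
#' @param bundle output of [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x)) {
      utils::write.csv(as.data.frame(x), file.path(dir, name),
                       row.names = FALSE)
    }
  }
  w(bundle$metrics, "field_metrics.csv")
  w(bundle$summary, "variant_summary.csv")
  w(bundle$qc, "qc_report.csv")
  w(bundle$comparisons, "group_comparisons.csv")
  w(bundle$correlations, "correlations.csv")
  json <- list(schema_version = "1.0", seed = bundle$seed,
               n_fields = if (!is.null(bundle$metrics)) nrow(bundle$metrics) else 0L,
               bh_cutoff = attr(bundle$correlations, "bh_cutoff"),
               flagged_cells = if (!is.null(bundle$correlations)) {
                 d <- bundle$correlations
                 paste(d$measure[d$significant_bh], d$metric[d$significant_bh],
                       sep = ":")
               })
  jsonlite::write_json(json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
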