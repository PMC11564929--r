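#' Configuration of an end-to-end pipeline run
#'
#' @param panel variant ground-truth panel ([variant_panel()]).
#' @param n_fields fields of view per variant and protocol.
#' @param noise a [noise_model()].
#' @param link a [phenotype_link()] for the synthetic cohort.
#' @param noise_k QC threshold multiplier.
#' @param alpha normality-gate level.
#' @param q BH false discovery rate.
#' @param n_perm Monte-Carlo permutation count.
#' @param seed master seed; every stochastic stage derives from it.
#' @param outdir optional output directory for [write_results()].
#' @param stages which stages to run.
#'
#' @return A validated `run_config` list.
#' @export
run_config <- function(panel = variant_panel(), n_fields = 9,
                       noise = noise_model(), link = phenotype_link(),
                       noise_k = 2, alpha = 0.05, q = 0.05, n_perm = 10000,
                       seed = 1, outdir = NULL,
                       stages = c("simulate", "process", "metrics", "stats",
                                  "correlate")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!all(stages %in% c("simulate", "process", "metrics", "stats",
                         "correlate"))) {
    stop("unknown stage name")
  }
  if ("correlate" %in% stages && is.null(link)) {
    stop("correlate stage enabled but no phenotype link configured")
  }
  structure(list(panel = panel, n_fields = n_fields, noise = noise,
                 link = link, noise_k = noise_k, alpha = alpha, q = q,
                 n_perm = n_perm, seed = seed, outdir = outdir,
                 stages = stages),
            class = "run_config")
}

#' Run the full synthetic-experiment pipeline
#'
#' Simulate -> process -> metrics -> group stats -> phenotype correlation,
#' as toggled in the configuration. Errors in any stage halt the run naming
#' the stage and field.
#'
#' @param config a [run_config()].
#'
#' @return Bundle list: `fields`, `metrics`, `summary`, `qc`,
#'   `comparisons`, `correlations`, `phenotypes`, `seed`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  bundle <- list(seed = config$seed)
  if ("simulate" %in% st) {
    bundle$fields <- c(
      simulate_experiment(config$panel, config$n_fields,
                          protocol_pool_1200ap(), config$noise,
                          seed = config$seed),
      simulate_experiment(config$panel, config$n_fields,
                          protocol_rrp_40ap(), config$noise,
                          seed = config$seed + 1))
  }
  if ("process" %in% st || "metrics" %in% st) {
    processed <- lapply(bundle$fields, function(fd) {
      tryCatch(process_field(fd, noise_k = config$noise_k),
               error = function(e) {
                 stop(sprintf("stage process, field %s: %s", fd$field_id,
                              conditionMessage(e)))
               })
    })
    bundle$qc <- do.call(rbind, lapply(processed, function(p) {
      data.frame(field_id = p$field_id, variant = p$variant,
                 n_responsive = p$qc$n_responsive,
                 field_pass = p$qc$field_pass,
                 n_excluded = sum(!p$qc$roi$included))
    }))
    bundle$processed <- processed
  }
  if ("metrics" %in% st) {
    rows <- lapply(bundle$processed, function(p) {
      m <- field_metrics(p)
      attr(m, "fit_diagnostics") <- NULL
      m
    })
    pool <- Filter(function(m) "tau_s" %in% names(m), rows)
    rrp <- Filter(function(m) "rrp_pct" %in% names(m), rows)
    merge_rows <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL
    bundle$metrics_pool <- merge_rows(pool)
    bundle$metrics_rrp <- merge_rows(rrp)
    bundle$metrics <- if (!is.null(bundle$metrics_rrp)) {
      merge(bundle$metrics_pool,
            bundle$metrics_rrp[, c("variant", "field_id", "rrp_pct")],
            by = c("variant", "field_id"), all = TRUE)
    } else bundle$metrics_pool
    bundle$summary <- summarize_metrics(bundle$metrics_pool)
  }
  if ("stats" %in% st) {
    metric_cols <- intersect(c("recycling_pool_pct", "tau_s", "initial_rate",
                               "frac_fused_200AP_pct"),
                             names(bundle$metrics_pool))
    cmps <- lapply(metric_cols, function(mc) {
      d <- bundle$metrics_pool
      gate <- normality_gate(d[[mc]], d$variant, alpha = config$alpha)
      cmp <- compare_to_control(d[[mc]], d$variant, control = "WT",
                                choice = gate$choice)
      data.frame(metric = mc, cmp, test_used = attr(cmp, "test_used"))
    })
    bundle$comparisons <- do.call(rbind, cmps)
  }
  if ("correlate" %in% st) {
    per_variant <- summarize_metrics(bundle$metrics_pool)
    mt <- data.frame(variant = per_variant$variant,
                     initial_rate = per_variant$initial_rate_mean,
                     tau_s = per_variant$tau_s_mean,
                     frac_fused_200AP_pct = per_variant$frac_fused_200AP_pct_mean)
    mt <- mt[mt$variant != "WT", ]  # the cohort holds variant carriers only
    bundle$phenotypes <- simulate_cohort_phenotypes(
      mt, link = config$link, seed = config$seed + 2)
    bundle$correlations <- run_correlation_family(
      mt, bundle$phenotypes, n_perm = config$n_perm,
      seed = config$seed + 3, q = config$q)
  }
  if (!is.null(config$outdir)) write_results(bundle, config$outdir)
  bundle
}
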