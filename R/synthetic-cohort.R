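#' Link between functional deficit and phenotype scores
#'
#' Defines how synthetic phenotype measures are generated from per-variant
#' functional metrics: a linked measure is
#' `slope * metric + intercept + N(0, noise_sd)`; a null measure is its
#' base level plus noise, independent of function. A measure is either
#' linked or null, never both.
#'
#' @param links data frame with columns `measure`, `metric`, `slope`,
#'   `intercept` (score units per metric unit / score units).
#' @param noise_sd score-unit SD of the additive noise.
#' @param null_measures measures generated as pure noise.
#' @param null_base named base levels for the null measures.
#'
#' @return An object of class `phenotype_link`.
#' @export
phenotype_link <- function(
    links = data.frame(
      measure = c("VABS_communication", "VABS_motor"),
      metric = c("frac_fused_200AP_pct", "frac_fused_200AP_pct"),
      slope = c(0.6, 0.8),
      intercept = c(35, 30)),
    noise_sd = 1,
    null_measures = c("CVI_total", "movement_disorder_count",
                      "DBC_self_injury"),
    null_base = c(CVI_total = 20, movement_disorder_count = 2,
                  DBC_self_injury = 4)) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  both <- intersect(links$measure, null_measures)
  if (length(both)) {
    stop("measure(s) both linked and null: ", paste(both, collapse = ", "))
  }
  structure(list(links = links, noise_sd = noise_sd,
                 null_measures = null_measures, null_base = null_base),
            class = "phenotype_link")
}

#' Simulate a variant-level phenotype table
#'
#' One row per variant with adaptive-function scores (VABS communication
#' and motor standard scores), CVI total, movement-disorder count (ordinal,
#' >= 0), DBC self-injury sum (0-10) and age, generated from the variant's
#' functional metrics through a [phenotype_link()].
#'
#' @param variant_metrics data frame with `variant` and the three
#'   functional metrics (`initial_rate`, `tau_s`, `frac_fused_200AP_pct`);
#'   >= 5 variants, no duplicates, no missing metrics.
#' @param link a [phenotype_link()].
#' @param ages ages in years (recycled); drawn from U(3, 20) when `NULL`.
#' @param seed optional seed.
#'
#' @return Data frame: `variant`, the five phenotype measures, `age`,
#'   `n_participants`.
#' @export
simulate_cohort_phenotypes <- function(variant_metrics,
                                       link = phenotype_link(),
                                       ages = NULL, seed = NULL) {
  metric_cols <- c("initial_rate", "tau_s", "frac_fused_200AP_pct")
  if (anyDuplicated(variant_metrics$variant)) {
    stop("duplicated variant labels")
  }
  if (nrow(variant_metrics) < 5) stop("need >= 5 variants")
  if (!all(metric_cols %in% names(variant_metrics)) ||
      anyNA(variant_metrics[, metric_cols])) {
    stop("every variant needs all three functional metrics")
  }
  with_seed(seed, {
    n <- nrow(variant_metrics)
    out <- data.frame(variant = variant_metrics$variant)
    all_measures <- c(link$links$measure, link$null_measures)
    for (ms in all_measures) {
      i <- match(ms, link$links$measure)
      val <- if (!is.na(i)) {
        link$links$slope[i] *
          variant_metrics[[link$links$metric[i]]] +
          link$links$intercept[i] + stats::rnorm(n, sd = link$noise_sd)
      } else {
        link$null_base[[ms]] + stats::rnorm(n, sd = link$noise_sd)
      }
      if (ms == "movement_disorder_count") val <- pmax(round(val), 0)
      if (ms == "DBC_self_injury") val <- pmin(pmax(round(val), 0), 10)
      out[[ms]] <- val
    }
    out$age <- if (is.null(ages)) stats::runif(n, 3, 20) else rep(ages, length.out = n)
    out$n_participants <- 1L
    out
  })
}

#' Graded-deficit panel of variant ground-truth parameters
#'
#' A wild-type condition plus `n_variants` constructs with a graded
#' dominant-negative exocytic deficit: the mobilization time constant
#' lengthens and the recycling and readily releasable fractions shrink
#' monotonically across the panel, emulating the graded impairment spectrum
#' of the assayed missense variants.
#'
#' @param n_variants number of deficit-graded variants besides WT.
#' @param tau_range WT-to-worst time constant (s).
#' @param recycling_range WT-to-worst recycling fraction.
#' @param rrp_range WT-to-worst readily releasable fraction.
#'
#' @return Data frame: `variant`, `tau`, `recycling_frac`, `rrp_frac`.
#' @export
variant_panel <- function(n_variants = 8, tau_range = c(20, 45),
                          recycling_range = c(0.55, 0.35),
                          rrp_range = c(0.08, 0.04)) {
  g <- seq(0, 1, length.out = n_variants + 1)
  data.frame(
    variant = c("WT", sprintf("VAR%02d", seq_len(n_variants))),
    tau = tau_range[1] + g * diff(tau_range),
    recycling_frac = recycling_range[1] + g * diff(recycling_range),
    rrp_frac = rrp_range[1] + g * diff(rrp_range))
}

#' Simulate a complete multi-variant imaging experiment
#'
#' Generates `n_fields` fields of view per panel row under the given
#' protocol, each field drawing bouton parameters around the variant's
#' nominal ground truth.
#'
#' @param panel a [variant_panel()]-style data frame.
#' @param n_fields fields of view (independent coverslips) per variant.
#' @param proto a [protocol()].
#' @param noise a [noise_model()].
#' @param n_responsive,n_dead,n_background per-field ROI counts (the dead
#'   fraction default exercises the QC screen).
#' @param seed integer seed; field seeds are derived deterministically.
#'
#' @return List of [field_record()]s.
#' @export
simulate_experiment <- function(panel = variant_panel(), n_fields = 9,
                                proto = protocol_pool_1200ap(),
                                noise = noise_model(),
                                n_responsive = 25, n_dead = 5,
                                n_background = 4, seed = 1) {
  fields <- list()
  set.seed(seed)
  for (i in seq_len(nrow(panel))) {
    for (f in seq_len(n_fields)) {
      rng <- gt_ranges(tau = panel$tau[i],
                       recycling_frac = panel$recycling_frac[i],
                       rrp_frac = panel$rrp_frac[i])
      fields[[length(fields) + 1]] <- simulate_field(
        n_responsive = n_responsive, n_dead = n_dead,
        n_background = n_background, ranges = rng, proto = proto,
        noise = noise, variant = panel$variant[i],
        field_id = sprintf("%s_f%02d_%s", panel$variant[i], f, proto$name))
    }
  }
  fields
}
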