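# vesiclequant

Quantification of pHluorin-based synaptic vesicle exocytosis assays, from
raw ROI fluorescence traces to genotype–function–phenotype correlation
statistics — with a synthetic-data generator that produces complete
in-silico experiments with known ground truth.

## The problem

pHluorin is a pH-sensitive GFP that is quenched inside acidic synaptic
vesicles and fluoresces on exocytosis. Under bafilomycin A1 (which blocks
vesicle reacidification) the evoked fluorescence rise of a bouton is a
cumulative read-out of vesicle fusion; NH4Cl superfusion collapses the pH
gradient and reveals the total pool, and an acidic MES bath quenches
surface-exposed probe. This package implements the analysis chain used for
such experiments on neurons expressing variants of the calcium sensor
synaptotagmin-1 (SYT1), whose missense variants cause a graded
dominant-negative impairment of evoked release:

1. **Trace processing** — single-exponential photobleach correction fitted
   to background ROIs, ΔF/F₀ against the mean of the 5 pre-stimulation
   frames, strict responsiveness screening (an ROI must respond to both
   stimulation and NH4Cl; a field needs > 20 responsive ROIs), field
   averaging, and normalization to the stimulation end-point or the NH4Cl
   peak.
2. **Exocytosis metrics** per field of view: recycling pool (% of total
   pool), one-phase time constant τ from `P·(1 − e^{−t/τ})` fitted over the
   whole stimulation window, initial exocytic rate (least-squares slope over
   the first 5 s, in normalized (ΔF/F₀)/s), % of vesicles fused by 200 AP,
   and readily releasable pool (% fused by a 40 AP, 20 Hz burst).
3. **Localization metrics** — axonal coefficient of variation (SD/mean over
   ≥ 60 µm line profiles), surface/vesicle membrane partitioning
   `100·(F_saline − F_MES)/(F_NH4Cl − F_MES)`, and expression fold-change
   over non-transfected cells.
4. **Group statistics** — Shapiro–Wilk-gated choice between one-way ANOVA
   with Dunnett's many-to-one comparisons and Kruskal–Wallis with Dunn's
   comparisons, all against the wild-type control, plus per-timepoint
   Dunnett comparison of whole time courses.
5. **Phenotype correlation** — permutation-based Spearman correlations
   (exact enumeration of all n! permutations at the study's cohort size,
   n ≤ 8) between per-variant functional metrics and standardized phenotype
   scores (VABS communication/motor, CVI, movement-disorder count, DBC
   self-injury), age-controlled partial rank correlations for the
   age-sensitive measures, and Benjamini–Hochberg FDR over the whole
   family.

## Worked example

```r
library(vesiclequant)

# one simulated wild-type field: 25 responsive boutons, 5 dead, 4 background
field <- simulate_field(seed = 7)
proc  <- process_field(field)       # bleach-correct, dF/F0, QC, average
proc$qc
#> <qc_report> 25/30 responsive ROIs; field PASS (rule: > 20 responsive)

field_metrics(proc)
#>   field_id variant n_responsive recycling_pool_pct    tau_s initial_rate frac_fused_200AP_pct
#> 1  field_1      WT           25           53.82829 20.43354   0.02242917             34.48137
```

The generative ground truth of this field is a recycling pool of 55% of the
vesicular pool mobilized with τ = 20 s: the pipeline recovers ≈ 53.8%
(the residual gap is the `1 − e^{−120/τ}` saturation of a 2-min train) and
τ ≈ 20.4 s. The correlation stage replays the reported clinical summary
family:

```r
tab <- clinical_correlation_table()
bh_fdr(tab$p, q = 0.05)$n_significant
#> [1] 4
```

— the four flagged cells are VABS motor × all three exocytosis metrics and
VABS communication × % fused by 200 AP.

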