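# compmut

Calling, characterizing and predicting **composite mutations** in tumor
cohorts.

A composite mutation is the co-occurrence of two or more *independent*
driver-level genetic events in the same gene of the same tumor — two
different hotspot substitutions (BRAF V600E + V600M), a hotspot plus a
high-level copy-number event, or, for tumor suppressors, three such
events. Composite mutations flag genes under intense selection and are
a recurrent route to resistance against mutation-specific therapy
(EGFR T790M arising next to L858R is the textbook case). Because they
are often sub-clonal, a biopsy can miss them; this package implements a
pipeline that calls them from gene-level somatic data and predicts
which samples are likely to carry them from the rest of their mutation
profile.

## What it computes

For a cohort of MAF-like mutation records, GISTIC-style discrete CNV
calls (−2…+2), oncogene/tumor-suppressor annotations and a hotspot
catalog:

1. **Composite calling** — driver-level events are hotspot mutations
   and ±2 CNV calls; a gene is composite in a sample iff it carries
   ≥ 2 events (oncogene) or ≥ 3 (tumor suppressor).
2. **Co-mutation statistics** — per tumor type and composite gene *g*,
   each co-gene's 2×2 presence table (composite vs non-composite
   samples) is tested with a two-sided Fisher exact test
   (p = Σ P(tables no more probable than observed), OR = ad/bc),
   selected at raw P < 0.05 and a threshold of 1.04 × the stratum's
   background mutation rate; the composite/non-composite frequency
   correlation ("complementary relationship") and the six-class
   substitution spectrum (A>C, A>T, A>G, C>A, C>G, C>T) are reported.
3. **Chromosysmos** — the fraction of co-mutation events on the
   composite gene's chromosome, versus the flat expectancy of
   1/24 ≈ 4.2% per chromosome, with an empirical p-value from a
   sham-composite-gene randomization null:
   p = (1 + #{null ≥ observed}) / (1 + iterations).
4. **Prediction** — per composite gene, a 100-tree random forest on
   binary co-mutation features and another on genome-normalized
   distances (|Δ concatenated coordinate| / 3×10⁹, absent events at the
   1.0 sentinel), combined as

   score = 0.75 · p_binary + 0.25 · p_distance,

   with the higher weighted class score as the label (ties →
   non-composite), evaluated by confusion matrix, accuracy, balanced
   accuracy, precision, TPR/FPR, ROC and trapezoidal AUC, plus a
   10-step feature-shuffling robustness sweep.
5. **Synthetic cohorts** — `generate_cohort()` plants a 5% composite
   prevalence, co-mutation odds ratios (default 8) and a 35%
   same-chromosome co-mutation placement, with full ground truth, so
   every stage is testable by parameter recovery; `run_pipeline()`
   chains everything and writes reproducible TSV/JSON outputs.

## Worked example

```r
library(compmut)

gen <- generate_cohort(sim_config(seed = 1, n_samples = 2000))
cohort <- gen$cohort
calls <- call_composites(extract_driver_events(cohort), cohort$annotations)

fit <- fit_composite_gene(cohort, calls, "PIK3CA",
                          config = model_config(seed = 7))
fit
#> <composite_gene_fit> PIK3CA: 13 selected co-genes, held-out AUC 0.774

part <- partition_events(cohort, calls)
rt <- randomization_test(calls, part, cohort$annotations,
                         cohort$annotations$gene,
                         n_iterations = 1000, seed = 7)
glance(rt)
#> # A tibble: 1 × 6
#>   observed_fraction null_mean empirical_p n_iterations n_events  seed
#>               <dbl>     <dbl>       <dbl>        <dbl>    <int> <dbl>
#> 1             0.323     0.152      0.0170         1000      835     7
```

Reading: 32.3% of this cohort's co-mutation events fall on the
composite gene's chromosome where sham composite genes capture 15.2% on
average (empirical p = 0.017, 1000 randomizations over 835 events), and
the PIK3CA ensemble separates held-out composite from non-composite
samples with AUC 0.774. At ~1% per-gene prevalence the hard 0.5 label
threshold is conservative (few positive calls); the AUC and the ROC are
the informative summaries. `plot_roc()`, `plot_chromosome_histogram()`,
`plot_complementary()` and `plot_substitution_spectrum()` (or
`autoplot()` on the corresponding objects) draw the standard figures,
and `tidy()`/`glance()` give broom-style tables for every result
object.

## Scope notes

The composite definition operates on gene-level data: cis/trans phase
and clonal structure are not (and cannot be) resolved. Tumor-suppressor
calls require three events as specified — stricter than biallelic
inactivation. The co-mutation selection is per tumor type at raw
P < 0.05 (a BH-corrected variant is available behind a flag), and the
feature selection for the predictor is nested inside the training split
so held-out performance is unbiased; see the methods vignette
(`vignettes/composite-mutation-analysis.Rmd`) for the reasoning behind
every numerical choice.
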