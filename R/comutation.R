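#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided exact test computed by summing hypergeometric probabilities,
#' over all tables with the observed margins, of tables no more probable
#' than the observed one. The odds ratio is the unconditional
#' cross-product ratio `(a*d)/(b*c)`, reported as `Inf` when `b*c == 0`
#' and `a*d > 0` (and `NaN` when both products are zero).
#'
#' Cells follow the co-mutation convention: `a` composite samples with a
#' co-gene event, `b` composite without, `c` non-composite with, `d`
#' non-composite without.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized).
#' @return A tibble with columns `p_value` and `odds_ratio`.
#' @examples
#' fisher_exact(5, 5, 5, 5)   # identical proportions: p = 1
#' @export
fisher_exact <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0)) abort_stat("negative cell count")
  p <- vapply(seq_len(n), function(i) {
    fisher_exact_p(a[i], b[i], c[i], d[i])
  }, numeric(1))
  or <- ifelse(b * c == 0,
               ifelse(a * d == 0, NaN, Inf),
               (a * d) / (b * c))
  tibble(p_value = p, odds_ratio = or)
}

# two-sided exact p for one table; margins fixed at (a+b, c+d) x (a+c, b+d)
fisher_exact_p <- function(a, b, c, d) {
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  n <- row1 + row2
  if (row1 == 0 && row2 == 0) return(1)
  if (row1 == 0 || row2 == 0 || col1 == 0 || col1 == n) {
    # a zero margin admits a single table: no information
    return(1)
  }
  support <- max(0, col1 - row2):min(row1, col1)
  probs <- stats::dhyper(support, col1, n - col1, row1)
  p_obs <- probs[support == a]
  # relative tolerance guards against ties lost to floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Background mutation rate and co-mutation threshold for a stratum
#'
#' The per-gene mutation frequency is the fraction of the stratum's
#' samples with any mutation record in that gene; the background rate is
#' a summary of those frequencies (the median by default, robust to
#' hypermutated outlier genes), and the co-mutation threshold is 1.04
#' times the background rate.
#'
#' @param cohort A [load_cohort()] object.
#' @param tumor_type Stratum label.
#' @param statistic Summary of the per-gene frequency vector: `"median"`
#'   (default) or `"mean"`.
#' @param multiplier Threshold multiplier (default 1.04).
#' @return A list of class `background_rate`: `tumor_type`, `gene_freq`
#'   (tibble of per-gene frequencies over annotated genes),
#'   `background_rate`, `multiplier`, `threshold`.
#' @export
compute_background_rate <- function(cohort, tumor_type,
                                    statistic = c("median", "mean"),
                                    multiplier = 1.04) {
  statistic <- match.arg(statistic)
  ids <- cohort$samples$sample_id[cohort$samples$tumor_type == tumor_type]
  if (length(ids) == 0) {
    abort_stat(sprintf("empty stratum: no samples with tumor type '%s'", tumor_type),
               class = "compmut_empty_stratum")
  }
  mut <- filter(cohort$mutations, .data$sample_id %in% ids)
  per_gene <- mut |>
    distinct(.data$sample_id, .data$gene) |>
    count(.data$gene, name = "n_mutated")
  gene_freq <- cohort$annotations["gene"] |>
    left_join(per_gene, by = "gene") |>
    mutate(frequency = dplyr::coalesce(.data$n_mutated, 0L) / length(ids)) |>
    select("gene", "frequency")
  rate <- switch(statistic,
                 median = stats::median(gene_freq$frequency),
                 mean = mean(gene_freq$frequency))
  structure(list(
    tumor_type = tumor_type, gene_freq = gene_freq,
    background_rate = rate, multiplier = multiplier,
    threshold = multiplier * rate
  ), class = "background_rate")
}

#' Test co-mutated genes for enrichment in composite samples
#'
#' Within one tumor type and for one composite gene, samples are split
#' into composite carriers and non-carriers, and each candidate co-gene
#' (a gene, other than the composite gene, with a driver-level event in
#' at least one composite sample) is tested with [fisher_exact()] on the
#' 2x2 presence table. A co-gene is flagged `significant` at raw
#' p < `p_threshold` (no multiple-testing correction by default; set
#' `adjust = TRUE` for a Benjamini-Hochberg column), and
#' `passes_background_threshold` when its frequency in composite samples
#' is at least 1.04 times the stratum background mutation rate.
#'
#' @param cohort A [load_cohort()] object.
#' @param calls Composite calls from [call_composites()].
#' @param composite_gene Target composite gene symbol.
#' @param tumor_type Stratum label.
#' @param p_threshold Significance threshold on the raw p-value (0.05).
#' @param adjust Add a BH-adjusted `p_adjusted` column and base
#'   `significant` on it (default `FALSE`).
#' @param background Optional precomputed [compute_background_rate()]
#'   result for the stratum.
#' @param sample_ids Optional restriction of the stratum to these
#'   samples (used for selection nested inside a training split).
#' @return A tibble with one row per candidate co-gene: `tumor_type`,
#'   `composite_gene`, `co_gene`, `a`, `b`, `c`, `d`, `p_value`,
#'   `odds_ratio`, `freq_composite`, `freq_noncomposite`,
#'   `passes_background_threshold`, `significant`.
#' @export
test_comutations <- function(cohort, calls, composite_gene, tumor_type,
                             p_threshold = 0.05, adjust = FALSE,
                             background = NULL, sample_ids = NULL) {
  ids <- cohort$samples$sample_id[cohort$samples$tumor_type == tumor_type]
  if (!is.null(sample_ids)) ids <- intersect(ids, sample_ids)
  comp_ids <- unique(calls$sample_id[calls$gene == composite_gene &
                                       calls$sample_id %in% ids])
  if (length(comp_ids) == 0) {
    abort_stat(sprintf(
      "empty stratum: no composite samples for %s in tumor type '%s'",
      composite_gene, tumor_type
    ), class = "compmut_empty_stratum")
  }
  noncomp_ids <- setdiff(ids, comp_ids)
  events <- extract_driver_events(cohort) |>
    filter(.data$sample_id %in% ids, .data$gene != composite_gene) |>
    distinct(.data$sample_id, .data$gene)

  candidates <- unique(events$gene[events$sample_id %in% comp_ids])
  if (length(candidates) == 0) {
    return(tibble(
      tumor_type = character(), composite_gene = character(),
      co_gene = character(), a = integer(), b = integer(), c = integer(),
      d = integer(), p_value = numeric(), odds_ratio = numeric(),
      freq_composite = numeric(), freq_noncomposite = numeric(),
      passes_background_threshold = logical(), significant = logical()
    ))
  }
  tab <- events |>
    filter(.data$gene %in% candidates) |>
    mutate(composite = .data$sample_id %in% comp_ids) |>
    group_by(.data$gene) |>
    summarise(a = sum(.data$composite), c = sum(!.data$composite),
              .groups = "drop") |>
    mutate(b = length(comp_ids) - .data$a,
           d = length(noncomp_ids) - .data$c)

  ft <- fisher_exact(tab$a, tab$b, tab$c, tab$d)
  if (is.null(background)) {
    background <- compute_background_rate(cohort, tumor_type)
  }
  out <- tibble(
    tumor_type = tumor_type, composite_gene = composite_gene,
    co_gene = tab$gene,
    a = as.integer(tab$a), b = as.integer(tab$b),
    c = as.integer(tab$c), d = as.integer(tab$d),
    p_value = ft$p_value, odds_ratio = ft$odds_ratio,
    freq_composite = tab$a / length(comp_ids),
    freq_noncomposite = tab$c / max(length(noncomp_ids), 1L),
    passes_background_threshold = tab$a / length(comp_ids) >= background$threshold
  )
  if (adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < p_threshold
  } else {
    out$significant <- out$p_value < p_threshold
  }
  arrange(out, .data$p_value, .data$co_gene)
}

#' Complementary relationship between composite and non-composite co-mutation frequencies
#'
#' Correlates, over co-genes, the co-mutation frequency observed in
#' composite samples against the frequency of the same genes in
#' non-composite samples (Pearson, two-sided), with the least-squares
#' slope reported alongside.
#'
#' @param results A [test_comutations()] tibble (typically one tumor
#'   type), with `freq_composite` and `freq_noncomposite` columns.
#' @return A one-row tibble of class `complementary_fit`: `n_pairs`,
#'   `pearson_r`, `p_value`, `slope`, `intercept`; the paired
#'   frequencies are kept in the `pairs` attribute for plotting.
#' @export
complementary_relationship <- function(results) {
  x <- results$freq_noncomposite
  y <- results$freq_composite
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    abort_stat("complementary fit needs at least 3 co-genes with defined frequencies",
               class = "compmut_fit_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_stat("zero variance in a frequency vector: correlation undefined",
               class = "compmut_fit_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  out <- tibble(
    n_pairs = length(x),
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1])
  )
  attr(out, "pairs") <- tibble(freq_noncomposite = x, freq_composite = y)
  class(out) <- c("complementary_fit", class(out))
  out
}

#' Substitution spectrum over the six collapsed base-change classes
#'
#' Single-nucleotide substitutions are collapsed into the six classes
#' A>C, A>T, A>G, C>A, C>G, C>T by complementing purine-reference
#' changes (G>A is counted as C>T, T>G as A>C, and so on). Non-SNV
#' records are skipped with a logged count.
#'
#' @param mutations Mutation records with `ref_allele`, `alt_allele`.
#' @return A tibble with one row per class: `class`, `n`, `fraction`
#'   (fractions sum to 1 when any SNV exists); skipped-record count in
#'   the `n_skipped` attribute.
#' @export
substitution_spectrum <- function(mutations) {
  classes <- c("A>C", "A>T", "A>G", "C>A", "C>G", "C>T")
  ref <- toupper(mutations$ref_allele)
  alt <- toupper(mutations$alt_allele)
  is_snv <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  n_skipped <- sum(!is_snv)
  ref <- ref[is_snv]; alt <- alt[is_snv]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("G", "T")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  cls <- paste0(ref, ">", alt)
  counts <- table(factor(cls, levels = classes))
  out <- tibble(
    class = classes,
    n = as.integer(counts),
    fraction = if (sum(counts) > 0) as.numeric(counts) / sum(counts) else rep(0, 6)
  )
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("substitution_spectrum", class(out))
  out
}
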