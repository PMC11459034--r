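#' Fraction of co-mutations on the composite gene's chromosome
#'
#' For each composite call, counts the sample's co-mutation events
#' (driver-level events in non-composite genes) that lie on the same
#' chromosome as the composite gene. Fractions are event-weighted: each
#' co-mutation event counts once per composite call of its sample. Also
#' returns a per-chromosome histogram of co-mutation events split into
#' mutations and CNVs, complete over the layout's chromosomes.
#'
#' @param calls Composite calls from [call_composites()].
#' @param partitions Event partition from [partition_events()].
#' @param annotations Gene annotations (symbol, chromosome).
#' @param layout Optional [genome_layout()] used to complete the
#'   histogram with zero-count chromosomes.
#' @return A list of class `same_chrom_stat`: `per_gene` (tibble of
#'   composite_gene, chromosome, n_events, n_same, fraction),
#'   `pooled_fraction`, `mean_gene_fraction`, `n_events`, `histogram`.
#' @export
same_chromosome_fraction <- function(calls, partitions, annotations,
                                     layout = NULL) {
  comut <- filter(partitions, .data$class == "comutation")
  unknown <- setdiff(unique(c(comut$gene, calls$gene)), annotations$gene)
  if (length(unknown) > 0) {
    abort_validation(sprintf("unannotated gene(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  chrom_of <- function(g) annotations$chromosome[match(g, annotations$gene)]
  comut <- mutate(comut, chromosome = chrom_of(.data$gene))

  totals <- comut |> count(.data$sample_id, name = "n_total")
  per_call <- left_join(calls, totals, by = "sample_id") |>
    mutate(
      chromosome = chrom_of(.data$gene),
      n_total = dplyr::coalesce(.data$n_total, 0L)
    )
  same_counts <- comut |>
    count(.data$sample_id, .data$chromosome, name = "n_same")
  per_call <- per_call |>
    left_join(same_counts, by = c("sample_id", "chromosome")) |>
    mutate(n_same = dplyr::coalesce(.data$n_same, 0L))

  per_gene <- per_call |>
    group_by(.data$gene, .data$chromosome) |>
    summarise(n_events = sum(.data$n_total), n_same = sum(.data$n_same),
              .groups = "drop") |>
    mutate(fraction = ifelse(.data$n_events > 0,
                             .data$n_same / .data$n_events, NA_real_)) |>
    rename(composite_gene = "gene")

  pooled <- if (sum(per_gene$n_events) > 0) {
    sum(per_gene$n_same) / sum(per_gene$n_events)
  } else NA_real_

  comp_chroms <- unique(per_gene$chromosome)
  hist <- comut |>
    mutate(event_type = ifelse(.data$kind == "hotspot_mutation", "mutation", "cnv")) |>
    count(.data$chromosome, .data$event_type) |>
    tidyr::pivot_wider(names_from = "event_type", values_from = "n",
                       values_fill = 0L)
  for (col in c("mutation", "cnv")) {
    if (!col %in% names(hist)) hist[[col]] <- 0L
  }
  if (!is.null(layout)) {
    hist <- tibble(chromosome = layout$chromosome) |>
      left_join(hist, by = "chromosome") |>
      mutate(mutation = dplyr::coalesce(.data$mutation, 0L),
             cnv = dplyr::coalesce(.data$cnv, 0L))
  }
  hist <- mutate(hist, is_composite_chromosome = .data$chromosome %in% comp_chroms)

  structure(list(
    per_gene = per_gene,
    pooled_fraction = pooled,
    mean_gene_fraction = mean(per_gene$fraction, na.rm = TRUE),
    n_events = sum(per_gene$n_events),
    histogram = hist[, c("chromosome", "mutation", "cnv", "is_composite_chromosome")]
  ), class = "same_chrom_stat")
}

#' @export
print.same_chrom_stat <- function(x, ...) {
  cat(sprintf("<same_chrom_stat> pooled fraction %.3f over %d co-mutation events\n",
              x$pooled_fraction, x$n_events))
  print(x$per_gene, n = 10)
  invisible(x)
}

#' Mean per-chromosome share of an event histogram
#'
#' The average, over all chromosomes of the layout, of each chromosome's
#' share of the total event count. With all chromosomes counted
#' (including empty ones) this equals 1 / number of chromosomes — about
#' 4.2% for the 24 nuclear chromosomes — and is the flat-expectancy
#' baseline against which same-chromosome enrichment is judged.
#'
#' @param histogram The `histogram` tibble of [same_chromosome_fraction()]
#'   (columns `mutation` and `cnv`), complete over the layout.
#' @return The mean per-chromosome share (a fraction).
#' @export
chromosome_expectancy <- function(histogram) {
  totals <- histogram$mutation + histogram$cnv
  if (sum(totals) == 0) abort_stat("no events in histogram")
  mean(totals / sum(totals))
}

#' Randomization test for same-chromosome co-mutation enrichment
#'
#' Compares the observed pooled same-chromosome fraction against a null
#' built by repeatedly replacing every true composite gene with a sham
#' gene drawn uniformly (without replacement within an iteration) from a
#' candidate pool of driver genes, and recomputing the pooled fraction.
#' The empirical p-value uses the plus-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_iterations)`, so it is never 0.
#'
#' @inheritParams same_chromosome_fraction
#' @param candidate_genes Driver genes eligible as sham composite genes
#'   (at least 10, and at least as many as there are true composite genes).
#' @param n_iterations Number of randomization iterations (>= 100;
#'   default 1000).
#' @param seed Integer seed (required, for reproducibility).
#' @return A list of class `chromosysmos_test`: `observed_fraction`,
#'   `null_fractions`, `empirical_p`, `n_iterations`, `seed`, `n_events`.
#' @export
randomization_test <- function(calls, partitions, annotations, candidate_genes,
                               n_iterations = 1000, seed) {
  if (missing(seed)) abort_validation("seed is required")
  if (n_iterations < 100) abort_validation("n_iterations must be >= 100")
  if (length(candidate_genes) < 10) {
    abort_validation("need at least 10 candidate genes")
  }
  true_genes <- unique(calls$gene)
  if (length(candidate_genes) < length(true_genes)) {
    abort_validation("fewer candidate genes than composite genes")
  }
  obs <- same_chromosome_fraction(calls, partitions, annotations)
  if (is.na(obs$pooled_fraction)) abort_stat("no co-mutation events")

  comut <- filter(partitions, .data$class == "comutation")
  chrom_of <- function(g) annotations$chromosome[match(g, annotations$gene)]
  chroms <- sort(unique(annotations$chromosome))
  # per-sample x chromosome co-mutation event counts, for fast lookups
  m <- matrix(0L, nrow = length(unique(comut$sample_id)), ncol = length(chroms),
              dimnames = list(sort(unique(comut$sample_id)), chroms))
  tab <- comut |> count(.data$sample_id, chromosome = chrom_of(.data$gene))
  m[cbind(match(tab$sample_id, rownames(m)), match(tab$chromosome, chroms))] <-
    tab$n
  call_rows <- match(calls$sample_id, rownames(m))
  gene_index <- match(calls$gene, true_genes)
  denom <- obs$n_events
  cand_chrom <- chrom_of(candidate_genes)
  if (anyNA(cand_chrom)) abort_validation("unannotated candidate gene")

  set.seed(seed)
  null_fractions <- vapply(seq_len(n_iterations), function(i) {
    sham <- sample(cand_chrom, length(true_genes), replace = FALSE)
    cols <- match(sham[gene_index], chroms)
    keep <- !is.na(call_rows)
    sum(m[cbind(call_rows[keep], cols[keep])]) / denom
  }, numeric(1))

  p <- (1 + sum(null_fractions >= obs$pooled_fraction)) / (1 + n_iterations)
  structure(list(
    observed_fraction = obs$pooled_fraction,
    null_fractions = null_fractions,
    empirical_p = p,
    n_iterations = n_iterations,
    seed = seed,
    n_events = obs$n_events
  ), class = "chromosysmos_test")
}

#' @export
print.chromosysmos_test <- function(x, ...) {
  cat(sprintf(
    "<chromosysmos_test> observed %.3f vs null mean %.3f (n = %d events)\n",
    x$observed_fraction, mean(x$null_fractions), x$n_events
  ))
  cat(sprintf("  empirical p = %.4g (%d iterations, seed %d)\n",
              x$empirical_p, x$n_iterations, x$seed))
  invisible(x)
}
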