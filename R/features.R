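#' Build binary and distance feature matrices for one composite gene
#'
#' The cohort is restricted to tumor types that carry composite calls in
#' the target gene. Each candidate co-gene contributes one binary
#' feature (1 when the sample has a driver-level event in that gene) and
#' one distance feature: the genome-normalized distance between the
#' co-gene and the target gene when the event is present, and the
#' maximal-distance sentinel 1.0 when absent. Features derived from the
#' target gene itself are excluded (leakage guard). Labels mark whether
#' the sample has a composite call in the target gene.
#'
#' @param cohort A [load_cohort()] object.
#' @param calls Composite calls from [call_composites()].
#' @param composite_gene Target gene symbol.
#' @param co_genes Candidate co-genes, typically the significant genes
#'   from [test_comutations()].
#' @param layout Genome layout; defaults to the cohort's.
#' @return A list of class `feature_set`: `sample_id`, `binary` (tibble
#'   of 0/1 columns), `distance` (tibble in `[0, 1]`), `labels` (factor
#'   `composite` / `non_composite`), `composite_gene`, `co_genes`,
#'   `distances` (per-co-gene distance to the target gene).
#' @export
build_feature_matrices <- function(cohort, calls, composite_gene, co_genes,
                                   layout = cohort$layout) {
  co_genes <- unique(co_genes)
  if (composite_gene %in% co_genes) {
    co_genes <- setdiff(co_genes, composite_gene)
  }
  if (length(co_genes) == 0) abort_validation("empty co-gene feature list")
  unknown <- setdiff(co_genes, cohort$annotations$gene)
  if (length(unknown) > 0) {
    abort_validation(sprintf("unannotated co-gene(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  gene_calls <- filter(calls, .data$gene == composite_gene)
  types <- unique(cohort$samples$tumor_type[
    cohort$samples$sample_id %in% gene_calls$sample_id])
  samples <- cohort$samples$sample_id[cohort$samples$tumor_type %in% types]
  if (length(samples) == 0) {
    abort_stat(sprintf("no tumor types bear composites in %s", composite_gene),
               class = "compmut_empty_stratum")
  }

  events <- extract_driver_events(cohort) |>
    filter(.data$sample_id %in% samples, .data$gene %in% co_genes) |>
    distinct(.data$sample_id, .data$gene)
  bin <- matrix(0L, nrow = length(samples), ncol = length(co_genes),
                dimnames = list(samples, co_genes))
  bin[cbind(match(events$sample_id, samples), match(events$gene, co_genes))] <- 1L

  dist_vals <- normalized_distance(co_genes, composite_gene,
                                   cohort$annotations, layout)
  dvec <- dist_vals$normalized_distance
  dist <- matrix(rep(dvec, each = length(samples)),
                 nrow = length(samples), dimnames = list(samples, co_genes))
  dist[bin == 0L] <- 1.0  # absent event: maximally distant sentinel

  labels <- factor(
    ifelse(samples %in% gene_calls$sample_id, "composite", "non_composite"),
    levels = c("non_composite", "composite")
  )
  structure(list(
    sample_id = samples,
    binary = as_tibble(as.data.frame(bin)),
    distance = as_tibble(as.data.frame(dist)),
    labels = labels,
    composite_gene = composite_gene,
    co_genes = co_genes,
    distances = dist_vals
  ), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %d samples x %d co-gene features (%d composite)\n",
              x$composite_gene, length(x$sample_id), length(x$co_genes),
              sum(x$labels == "composite")))
  invisible(x)
}
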