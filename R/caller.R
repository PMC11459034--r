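#' Extract driver-level genetic events from a cohort
#'
#' A driver-level event is either a hotspot mutation (the sample's
#' protein change matches the hotspot catalog for that gene,
#' case-insensitively) or a high-level copy-number call: deep deletion
#' (-2) or high-level amplification (+2). Calls in \{-1, 0, 1\} yield no
#' event. Events are distinct (sample, gene, kind, detail) tuples.
#'
#' @param cohort A validated [load_cohort()] object.
#' @return A tibble with columns `sample_id`, `gene`, `kind`
#'   (`hotspot_mutation`, `deep_deletion`, `high_amplification`) and
#'   `detail` (protein change or CNV call).
#' @export
extract_driver_events <- function(cohort) {
  if (nrow(cohort$hotspots) == 0) abort_validation("hotspot catalog is empty")
  hs <- mutate(cohort$hotspots, key = paste(.data$gene, pchange_key(.data$protein_change)))
  mut <- mutate(cohort$mutations, key = paste(.data$gene, pchange_key(.data$protein_change)))
  hits <- filter(mut, .data$key %in% hs$key)
  ev_mut <- tibble(
    sample_id = hits$sample_id, gene = hits$gene,
    kind = "hotspot_mutation", detail = pchange_key(hits$protein_change)
  )
  cnv <- filter(cohort$cnvs, abs(.data$call) == 2L)
  ev_cnv <- tibble(
    sample_id = cnv$sample_id, gene = cnv$gene,
    kind = ifelse(cnv$call == -2L, "deep_deletion", "high_amplification"),
    detail = as.character(cnv$call)
  )
  distinct(arrange(bind_rows(ev_mut, ev_cnv), .data$sample_id, .data$gene,
                   .data$kind, .data$detail))
}

#' Call composite mutations per sample per gene
#'
#' A gene in a sample is composite-mutated when it carries at least two
#' independent driver-level events if it is an oncogene, or at least
#' three if it is a tumor suppressor. Independent events are distinct
#' (kind, detail) pairs within the gene: for example two different
#' hotspot substitutions, or one hotspot plus a high-level amplification.
#'
#' @param events Driver events from [extract_driver_events()].
#' @param annotations Gene annotations with a `role` column.
#' @return A tibble sorted by (sample, gene) with columns `sample_id`,
#'   `gene`, `role`, `n_events`, `event_detail` (comma-joined
#'   `kind:detail` pairs).
#' @examples
#' ev <- tibble::tibble(sample_id = "s1", gene = "BRAF",
#'                      kind = "hotspot_mutation", detail = c("V600E", "V600M"))
#' ann <- tibble::tibble(gene = "BRAF", role = "oncogene",
#'                       chromosome = "7", start = 1, end = 2)
#' call_composites(ev, ann)
#' @export
call_composites <- function(events, annotations) {
  if (nrow(events) == 0) {
    return(tibble(sample_id = character(), gene = character(),
                  role = character(), n_events = integer(),
                  event_detail = character()))
  }
  unknown <- setdiff(unique(events$gene), annotations$gene)
  if (length(unknown) > 0) {
    abort_validation(sprintf(
      "event gene(s) without annotated role: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  counts <- events |>
    distinct(.data$sample_id, .data$gene, .data$kind, .data$detail) |>
    group_by(.data$sample_id, .data$gene) |>
    summarise(
      n_events = dplyr::n(),
      event_detail = paste(sort(paste0(.data$kind, ":", .data$detail)),
                           collapse = ","),
      .groups = "drop"
    ) |>
    left_join(annotations[, c("gene", "role")], by = "gene")
  threshold <- ifelse(counts$role == "oncogene", 2L, 3L)
  out <- counts[counts$n_events >= threshold,
                c("sample_id", "gene", "role", "n_events", "event_detail")]
  arrange(out, .data$sample_id, .data$gene)
}

#' Partition a composite-bearing sample's events into classes
#'
#' For each sample with at least one composite call, driver-level events
#' in its composite gene(s) are class `composite`; driver-level events in
#' any other gene are class `comutation`; the remaining alterations
#' (non-hotspot mutations and low-level CNV calls -1/+1) are class
#' `background`. Samples without a composite call have no partition
#' entry, since co-mutations are defined only in composite tumors.
#'
#' @param cohort A [load_cohort()] object.
#' @param calls Composite calls from [call_composites()].
#' @return A tibble with columns `sample_id`, `gene`, `class`, `kind`,
#'   `detail`, restricted to composite-bearing samples.
#' @export
partition_events <- function(cohort, calls) {
  empty <- tibble(sample_id = character(), gene = character(),
                  class = character(), kind = character(), detail = character())
  if (nrow(calls) == 0) return(empty)
  events <- extract_driver_events(cohort)
  comp_samples <- unique(calls$sample_id)
  events <- filter(events, .data$sample_id %in% comp_samples)
  key_calls <- paste(calls$sample_id, calls$gene)
  driver <- mutate(events,
                   class = ifelse(paste(.data$sample_id, .data$gene) %in% key_calls,
                                  "composite", "comutation"))
  hs_key <- paste(cohort$hotspots$gene, pchange_key(cohort$hotspots$protein_change))
  bg_mut <- cohort$mutations |>
    filter(.data$sample_id %in% comp_samples,
           !paste(.data$gene, pchange_key(.data$protein_change)) %in% hs_key) |>
    mutate(class = "background", kind = "mutation", detail = .data$protein_change) |>
    select("sample_id", "gene", "class", "kind", "detail")
  bg_cnv <- cohort$cnvs |>
    filter(.data$sample_id %in% comp_samples, abs(.data$call) == 1L) |>
    mutate(class = "background", kind = "cnv", detail = as.character(.data$call)) |>
    select("sample_id", "gene", "class", "kind", "detail")
  out <- bind_rows(
    driver[, c("sample_id", "gene", "class", "kind", "detail")],
    bg_mut, bg_cnv
  )
  arrange(out, .data$sample_id, .data$class, .data$gene, .data$kind, .data$detail)
}

#' Composite-mutation prevalence, overall and per gene by tumor type
#'
#' @param calls Composite calls from [call_composites()].
#' @param cohort The cohort the calls were computed from.
#' @return A list of class `composite_prevalence`: `prevalence` (fraction
#'   of samples with >= 1 composite call), `n_samples`,
#'   `n_composite_samples`, and `by_gene` — a tidy tibble of case counts
#'   per (gene, tumor_type).
#' @export
composite_prevalence <- function(calls, cohort) {
  if (nrow(cohort$samples) == 0) abort_validation("empty cohort")
  n <- nrow(cohort$samples)
  n_comp <- length(unique(calls$sample_id))
  by_gene <- calls |>
    left_join(cohort$samples[, c("sample_id", "tumor_type")], by = "sample_id") |>
    count(.data$gene, .data$tumor_type, name = "n_cases") |>
    arrange(.data$gene, .data$tumor_type)
  structure(list(
    prevalence = n_comp / n,
    n_samples = n,
    n_composite_samples = n_comp,
    by_gene = by_gene
  ), class = "composite_prevalence")
}

#' @export
print.composite_prevalence <- function(x, ...) {
  cat(sprintf("<composite_prevalence> %d / %d samples (%.1f%%)\n",
              x$n_composite_samples, x$n_samples, 100 * x$prevalence))
  print(x$by_gene, n = 10)
  invisible(x)
}
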