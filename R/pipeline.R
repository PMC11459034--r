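#' Run the full composite-mutation analysis pipeline
#'
#' Orchestrates the whole chain on a cohort (or on a freshly generated
#' synthetic cohort): driver-event extraction, composite calling,
#' prevalence, per-gene co-mutation Fisher tests, chromosomal-disruption
#' statistics with the randomization null, per-gene feature matrices,
#' ensemble training and evaluation, and (optionally) the
#' feature-shuffling robustness sweep. Every stage writes a TSV into
#' `out_dir` and the run ends with a JSON manifest holding parameters,
#' seeds, counts and per-stage status. Stages whose stratum is empty are
#' skipped with a logged reason, never a crash; a fixed config and seed
#' yield byte-identical outputs.
#'
#' @param cohort A [load_cohort()] object, or `NULL` to simulate.
#' @param sim A [sim_config()] used when `cohort` is `NULL`.
#' @param genes Composite genes of interest (default BRAF, EGFR, KRAS,
#'   PIK3CA).
#' @param out_dir Output directory.
#' @param seed Master integer seed; per-stage seeds derive from it.
#' @param p_threshold Co-mutation significance threshold (0.05).
#' @param background_multiplier Co-mutation background threshold
#'   multiplier (1.04).
#' @param n_iterations Randomization-test iterations (default 1000).
#' @param model A [model_config()]; its seed is overridden per gene from
#'   the master seed.
#' @param shuffle_fractions Optional shuffle fractions (e.g.
#'   `seq(0.1, 1, 0.1)`); `NULL` (default) skips the robustness sweep.
#' @return Invisibly, a list with `manifest` (also written as
#'   `manifest.json`), `calls`, `prevalence`, `chromosysmos`,
#'   `comutations`, and per-gene `models`.
#' @export
run_pipeline <- function(cohort = NULL, sim = sim_config(),
                         genes = c("BRAF", "EGFR", "KRAS", "PIK3CA"),
                         out_dir, seed = 1, p_threshold = 0.05,
                         background_multiplier = 1.04,
                         n_iterations = 1000,
                         model = model_config(),
                         shuffle_fractions = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  note <- function(stage, status, reason = NULL) {
    stages[[stage]] <<- list(status = status, reason = reason)
  }

  if (is.null(cohort)) {
    sim$seed <- as.integer(seed)
    gen <- generate_cohort(sim)
    cohort <- gen$cohort
    note("simulate", "ok")
  }

  events <- extract_driver_events(cohort)
  calls <- call_composites(events, cohort$annotations)
  readr::write_tsv(calls, file.path(out_dir, "composite_calls.tsv"), progress = FALSE)
  prev <- composite_prevalence(calls, cohort)
  readr::write_tsv(prev$by_gene, file.path(out_dir, "prevalence_by_gene.tsv"),
                   progress = FALSE)
  note("calling", "ok")

  partitions <- partition_events(cohort, calls)
  chrom <- NULL
  rand <- NULL
  if (nrow(calls) == 0) {
    note("chromosysmos", "skipped", "no composite calls in cohort")
  } else if (!any(partitions$class == "comutation")) {
    note("chromosysmos", "skipped", "no co-mutation events")
  } else {
    chrom <- same_chromosome_fraction(calls, partitions, cohort$annotations,
                                      layout = cohort$layout)
    readr::write_tsv(chrom$per_gene, file.path(out_dir, "chromosysmos_per_gene.tsv"),
                     progress = FALSE)
    readr::write_tsv(chrom$histogram, file.path(out_dir, "chromosome_histogram.tsv"),
                     progress = FALSE)
    rand <- randomization_test(calls, partitions, cohort$annotations,
                               candidate_genes = cohort$annotations$gene,
                               n_iterations = n_iterations, seed = seed)
    note("chromosysmos", "ok")
  }

  comut_all <- list()
  models <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    stage <- paste0("gene_", g)
    g_calls <- filter(calls, .data$gene == g)
    if (nrow(g_calls) == 0) {
      note(stage, "skipped", "no composite calls for gene")
      next
    }
    types <- unique(cohort$samples$tumor_type[
      cohort$samples$sample_id %in% g_calls$sample_id])
    res <- purrr::map(types, function(tt) {
      tryCatch(
        test_comutations(cohort, calls, g, tt, p_threshold = p_threshold,
                         background = compute_background_rate(
                           cohort, tt, multiplier = background_multiplier)),
        compmut_empty_stratum = function(e) NULL
      )
    })
    res <- bind_rows(res)
    if (nrow(res) > 0) {
      readr::write_tsv(res, file.path(out_dir, paste0("comutations_", g, ".tsv")),
                       progress = FALSE)
      comut_all[[g]] <- res
    }
    fit <- tryCatch({
      cfg <- model
      cfg$seed <- as.integer(seed + gi)
      gf <- fit_composite_gene(cohort, calls, g, config = cfg,
                               p_threshold = p_threshold,
                               background_multiplier = background_multiplier)
      perf <- gf$performance
      readr::write_tsv(dplyr::bind_cols(perf$confusion, perf$metrics,
                                        tibble(auc = perf$auc)),
                       file.path(out_dir, paste0("performance_", g, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(perf$roc, file.path(out_dir, paste0("roc_", g, ".tsv")),
                       progress = FALSE)
      if (!is.null(shuffle_fractions)) {
        shuf <- shuffle_robustness(gf$features, cfg, fractions = shuffle_fractions)
        readr::write_tsv(shuf, file.path(out_dir, paste0("shuffle_", g, ".tsv")),
                         progress = FALSE)
      }
      note(stage, "ok")
      gf
    },
    compmut_single_class = function(e) {
      note(stage, "skipped", conditionMessage(e)); NULL
    },
    compmut_no_features = function(e) {
      note(stage, "skipped", conditionMessage(e)); NULL
    },
    compmut_validation_error = function(e) {
      note(stage, "skipped", conditionMessage(e)); NULL
    })
    if (!is.null(fit)) models[[g]] <- fit
  }

  manifest <- list(
    package = "compmut",
    version = as.character(utils::packageVersion("compmut")),
    seed = as.integer(seed),
    parameters = list(
      genes = genes, p_threshold = p_threshold,
      background_multiplier = background_multiplier,
      n_iterations = n_iterations,
      n_trees = model$n_trees, train_fraction = model$train_fraction,
      ensemble_weights = as.list(model$weights),
      shuffle_fractions = shuffle_fractions
    ),
    counts = cohort$summary,
    composite = list(
      n_calls = nrow(calls),
      n_composite_samples = prev$n_composite_samples,
      prevalence = prev$prevalence
    ),
    chromosysmos = if (!is.null(rand)) list(
      observed_fraction = rand$observed_fraction,
      empirical_p = rand$empirical_p,
      n_events = rand$n_events
    ),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(manifest = manifest, calls = calls, prevalence = prev,
                 chromosysmos = rand, same_chrom = chrom,
                 comutations = comut_all, models = models))
}
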