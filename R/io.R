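#' Default MAF column dialect (cBioPortal conventions)
#'
#' Maps the internal field names to the column names found in
#' cBioPortal-style MAF exports. Supply a modified copy to [read_maf()]
#' for files with different headers.
#'
#' @return Named character vector: internal field -> file column name.
#' @export
maf_dialect <- function() {
  c(
    sample_id = "Tumor_Sample_Barcode",
    gene = "Hugo_Symbol",
    protein_change = "HGVSp_Short",
    chromosome = "Chromosome",
    position = "Start_Position",
    ref_allele = "Reference_Allele",
    alt_allele = "Tumor_Seq_Allele2"
  )
}

#' Read a MAF-like somatic mutation table
#'
#' Reads a tab-separated mutation table, renames columns according to the
#' dialect, validates positions, and collapses duplicate
#' (sample, gene, protein change) rows to a single record. The number of
#' collapsed rows is stored in the `n_deduplicated` attribute.
#'
#' @param path Path to a TSV file.
#' @param dialect Named character vector mapping internal field names to
#'   file column names; see [maf_dialect()].
#' @return A tibble of mutation records with columns `sample_id`, `gene`,
#'   `protein_change`, `chromosome`, `position`, `ref_allele`, `alt_allele`.
#' @export
read_maf <- function(path, dialect = maf_dialect()) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- dialect[!dialect %in% names(raw)]
  if (length(missing) > 0) {
    abort_format(sprintf(
      "MAF file %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  out <- raw[, unname(dialect)]
  names(out) <- names(dialect)
  pos <- suppressWarnings(as.numeric(out$position))
  bad <- which(is.na(pos) | pos != floor(pos) | pos < 1)
  if (length(bad) > 0) {
    abort_format(sprintf(
      "unparseable position in %s at data row(s): %s",
      path, paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  out$position <- as.integer(pos)
  out$chromosome <- normalize_chromosome(out$chromosome)
  validate_mutations(out)
  n0 <- nrow(out)
  out <- dplyr::distinct(out, .data$sample_id, .data$gene, .data$protein_change,
                         .keep_all = TRUE)
  attr(out, "n_deduplicated") <- n0 - nrow(out)
  out
}

validate_mutations <- function(mut) {
  same <- mut$ref_allele == mut$alt_allele
  if (any(same)) {
    abort_validation(sprintf(
      "%d mutation record(s) have identical ref and alt alleles", sum(same)
    ))
  }
  invisible(mut)
}

#' Read a gene-by-sample discrete copy-number matrix
#'
#' The matrix holds GISTIC-style discrete calls in \{-2, -1, 0, 1, 2\}
#' with genes as rows (first column `gene`) and samples as columns. The
#' result is one record per cell in long form.
#'
#' @param path Path to a TSV file.
#' @param keep_zero Keep call-0 cells (default `TRUE`)? [load_cohort()]
#'   drops zero calls regardless, since a 0 call records no alteration.
#' @return A tibble with columns `sample_id`, `gene`, `call` (integer).
#' @export
read_cnv_matrix <- function(path, keep_zero = TRUE) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"gene" %in% names(raw)) {
    abort_format(sprintf("CNV matrix %s must have a 'gene' first column", path))
  }
  long <- tidyr::pivot_longer(raw, -"gene", names_to = "sample_id",
                              values_to = "call")
  val <- suppressWarnings(as.numeric(long$call))
  bad <- which(is.na(val) | val != floor(val))
  if (length(bad) > 0) {
    abort_format(sprintf(
      "non-integer CNV cell at gene %s, sample %s",
      long$gene[bad[1]], long$sample_id[bad[1]]
    ))
  }
  out_of_range <- which(val < -2 | val > 2)
  if (length(out_of_range) > 0) {
    abort_format(sprintf(
      "CNV call %d out of range [-2, 2] at gene %s, sample %s",
      as.integer(val[out_of_range[1]]), long$gene[out_of_range[1]],
      long$sample_id[out_of_range[1]]
    ))
  }
  long$call <- as.integer(val)
  out <- long[, c("sample_id", "gene", "call")]
  if (!keep_zero) out <- out[out$call != 0L, ]
  if (anyDuplicated(out[, c("sample_id", "gene")])) {
    abort_validation(sprintf("duplicate (sample, gene) CNV calls in %s", path))
  }
  as_tibble(out)
}

#' Read a gene annotation table
#'
#' Columns: `gene` (symbol), `role` (`oncogene` or `tumor_suppressor`),
#' `chromosome`, `start`, `end` (1-based inclusive, GRCh38 convention).
#'
#' @param path Path to a TSV file.
#' @return A tibble of gene annotations.
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), role = readr::col_character(),
    chromosome = readr::col_character(), start = readr::col_double(),
    end = readr::col_double()
  ), progress = FALSE)
  check_columns(out, c("gene", "role", "chromosome", "start", "end"),
                "annotation table")
  out$chromosome <- normalize_chromosome(out$chromosome)
  validate_annotations(out)
}

validate_annotations <- function(ann) {
  bad_role <- !ann$role %in% c("oncogene", "tumor_suppressor")
  if (any(bad_role)) {
    abort_validation(sprintf(
      "invalid role(s): %s (must be oncogene or tumor_suppressor)",
      paste(unique(ann$role[bad_role]), collapse = ", ")
    ))
  }
  if (any(ann$start > ann$end)) abort_validation("annotation with start > end")
  if (anyDuplicated(ann$gene)) abort_validation("duplicate gene annotations")
  as_tibble(ann)
}

#' Read a hotspot catalog of (gene, protein change) pairs
#'
#' @param path Path to a TSV file with columns `gene`, `protein_change`.
#' @return A tibble with the two columns, duplicates removed.
#' @export
read_hotspots <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  out <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(out, c("gene", "protein_change"), "hotspot catalog")
  dplyr::distinct(out[, c("gene", "protein_change")])
}

#' Read a sample metadata table
#'
#' @param path Path to a TSV with columns `sample_id`, `tumor_type` and
#'   optionally `source` (`tissue` or `cell_line`; default `tissue`).
#' @return A tibble of sample metadata.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  out <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(out, c("sample_id", "tumor_type"), "sample table")
  if (!"source" %in% names(out)) out$source <- "tissue"
  out[, c("sample_id", "tumor_type", "source")]
}

#' Read a genome layout TSV of (chromosome, length)
#'
#' @param path Path to a TSV with columns `chromosome`, `length`.
#' @inheritParams genome_layout
#' @return A [genome_layout()].
#' @export
read_genome_layout <- function(path, normalizer = 3e9) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  out <- readr::read_tsv(path, col_types = readr::cols(
    chromosome = readr::col_character(), length = readr::col_double()
  ), progress = FALSE)
  check_columns(out, c("chromosome", "length"), "genome layout")
  genome_layout(out, normalizer = normalizer)
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else as_tibble(x)
}

#' Assemble and validate a cohort
#'
#' Combines mutation, CNV, annotation, hotspot and sample inputs into a
#' validated `cohort` object. Each input may be a data frame or a file
#' path (dispatched to the matching reader). Records in genes absent from
#' the annotation table are dropped with a logged count; zero CNV calls
#' (no alteration) are dropped; duplicate mutation rows are collapsed.
#'
#' @param mutations Mutation records ([read_maf()] output or path).
#' @param cnvs CNV records ([read_cnv_matrix()] output or path).
#' @param annotations Gene annotations ([read_gene_annotations()] or path).
#' @param hotspots Hotspot catalog ([read_hotspots()] or path).
#' @param samples Sample metadata ([read_sample_meta()] or path).
#' @param layout A [genome_layout()]; defaults to [grch38_layout()].
#' @return A `cohort` object: a list of tibbles (`samples`, `mutations`,
#'   `cnvs`, `annotations`, `hotspots`, `layout`) with a `summary`
#'   element of load counts (samples, genes, mutations, cnvs,
#'   dropped_unannotated, deduplicated, dropped_zero_cnv).
#' @export
load_cohort <- function(mutations, cnvs, annotations, hotspots, samples,
                        layout = grch38_layout()) {
  samples <- resolve_input(samples, read_sample_meta)
  annotations <- resolve_input(annotations, read_gene_annotations)
  hotspots <- resolve_input(hotspots, read_hotspots)
  mutations <- resolve_input(mutations, read_maf)
  cnvs <- resolve_input(cnvs, read_cnv_matrix)

  if (nrow(samples) == 0) abort_validation("empty sample set")
  if (anyDuplicated(samples$sample_id)) {
    abort_validation("duplicate sample_id in sample metadata")
  }
  annotations <- validate_annotations(annotations)
  if (!all(annotations$chromosome %in% layout$chromosome)) {
    abort_validation("annotation on chromosome absent from layout (only the 24 nuclear chromosomes are supported)")
  }

  unknown <- setdiff(unique(c(mutations$sample_id, cnvs$sample_id)),
                     samples$sample_id)
  if (length(unknown) > 0) {
    abort_validation(sprintf(
      "records reference unknown sample id(s): %s",
      paste(utils::head(unknown, 5), collapse = ", ")
    ))
  }

  validate_mutations(mutations)
  bad_chrom <- !mutations$chromosome %in% layout$chromosome
  if (any(bad_chrom)) {
    abort_validation(sprintf(
      "mutation(s) on unsupported contig(s): %s",
      paste(unique(mutations$chromosome[bad_chrom]), collapse = ", ")
    ))
  }
  chrom_len <- layout$length[match(mutations$chromosome, layout$chromosome)]
  if (any(mutations$position > chrom_len)) {
    abort_validation("mutation position beyond chromosome length")
  }

  n0 <- nrow(mutations)
  mutations <- dplyr::distinct(mutations, .data$sample_id, .data$gene,
                               .data$protein_change, .keep_all = TRUE)
  n_dedup <- n0 - nrow(mutations)
  attr(mutations, "n_deduplicated") <- NULL

  if (!all(cnvs$call %in% -2:2)) abort_validation("CNV call outside {-2..2}")
  n_zero <- sum(cnvs$call == 0L)
  cnvs <- cnvs[cnvs$call != 0L, ]

  annotated <- annotations$gene
  drop_mut <- !mutations$gene %in% annotated
  drop_cnv <- !cnvs$gene %in% annotated
  n_dropped <- sum(drop_mut) + sum(drop_cnv)
  mutations <- mutations[!drop_mut, ]
  cnvs <- cnvs[!drop_cnv, ]

  out <- list(
    samples = arrange(as_tibble(samples), .data$sample_id),
    mutations = arrange(as_tibble(mutations), .data$sample_id, .data$gene,
                        .data$protein_change),
    cnvs = arrange(as_tibble(cnvs), .data$sample_id, .data$gene),
    annotations = arrange(annotations, .data$gene),
    hotspots = arrange(as_tibble(hotspots), .data$gene, .data$protein_change),
    layout = layout,
    summary = list(
      n_samples = nrow(samples), n_genes = nrow(annotations),
      n_mutations = nrow(mutations), n_cnvs = nrow(cnvs),
      dropped_unannotated = n_dropped, deduplicated = n_dedup,
      dropped_zero_cnv = n_zero
    )
  )
  structure(out, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  s <- x$summary
  cat("<cohort>", s$n_samples, "samples,", s$n_genes, "annotated genes\n")
  cat("  mutations:", s$n_mutations, " CNV alterations:", s$n_cnvs, "\n")
  cat("  tumor types:", paste(sort(unique(x$samples$tumor_type)), collapse = ", "), "\n")
  cat("  dropped unannotated:", s$dropped_unannotated,
      " collapsed duplicates:", s$deduplicated, "\n")
  invisible(x)
}
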