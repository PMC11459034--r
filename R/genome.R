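#' Genome layout: chromosome sizes and concatenated-genome offsets
#'
#' A genome layout holds the ordered chromosome lengths, the cumulative
#' offset of each chromosome in a single concatenated coordinate system,
#' and the normalizing constant used to scale inter-gene distances
#' (3e9 bp by default, the approximate total length of the human genome).
#'
#' @param chromosomes A data frame with columns `chromosome` and `length`
#'   (bp), in the desired karyotype order.
#' @param normalizer Total genome distance used to normalize distances to
#'   `[0, 1]`. Default 3e9.
#' @return A tibble of class `genome_layout` with columns `chromosome`,
#'   `length`, `offset` (0-based start of the chromosome in concatenated
#'   coordinates) and a `normalizer` attribute.
#' @examples
#' toy <- genome_layout(data.frame(chromosome = c("1", "2"), length = c(1e6, 2e6)))
#' attr(toy, "normalizer")
#' @export
genome_layout <- function(chromosomes, normalizer = 3e9) {
  check_columns(chromosomes, c("chromosome", "length"), "genome layout")
  chromosomes <- as_tibble(chromosomes)
  chromosomes$chromosome <- as.character(chromosomes$chromosome)
  if (anyDuplicated(chromosomes$chromosome)) {
    abort_validation("chromosome names must be unique")
  }
  if (any(chromosomes$length <= 0) || any(!is.finite(chromosomes$length))) {
    abort_validation("chromosome lengths must be positive and finite")
  }
  if (!is.numeric(normalizer) || length(normalizer) != 1 || normalizer <= 0) {
    abort_validation("normalizer must be a single positive number")
  }
  out <- chromosomes[, c("chromosome", "length")]
  out$offset <- cumsum(c(0, out$length[-nrow(out)]))
  attr(out, "normalizer") <- normalizer
  class(out) <- c("genome_layout", class(out))
  out
}

#' GRCh38 nuclear chromosome layout
#'
#' The 24 nuclear chromosomes (1-22, X, Y) with GRCh38 lengths, in
#' karyotype order. Mitochondrial and alternative contigs are excluded;
#' records on other contigs are rejected at load time.
#'
#' @inheritParams genome_layout
#' @return A `genome_layout` tibble.
#' @export
grch38_layout <- function(normalizer = 3e9) {
  genome_layout(tibble(
    chromosome = c(as.character(1:22), "X", "Y"),
    length = c(
      248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
      159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
      114364328, 107043718, 101991189, 90338345, 83257441, 80373285,
      58617616, 64444167, 46709983, 50818468, 156040895, 57227415
    )
  ), normalizer = normalizer)
}

# strip a leading "chr" so both "chr7" and "7" resolve
normalize_chromosome <- function(x) sub("^chr", "", as.character(x))

# concatenated-genome coordinate of a gene: chromosome offset + midpoint
gene_concat_coord <- function(genes, annotations, layout) {
  ann <- annotations[match(genes, annotations$gene), ]
  if (anyNA(ann$gene)) {
    abort_validation(sprintf(
      "unannotated gene(s): %s",
      paste(unique(genes[is.na(ann$gene)]), collapse = ", ")
    ))
  }
  off <- layout$offset[match(ann$chromosome, layout$chromosome)]
  if (anyNA(off)) {
    abort_validation("gene annotated on a chromosome absent from the layout")
  }
  off + (ann$start + ann$end) / 2
}

#' Genome-normalized distance between genes
#'
#' Computes the absolute distance between gene midpoints in concatenated
#' genome coordinates (karyotype order), divided by the layout's
#' normalizer (3e9 by default) and clamped to `[0, 1]`. Cross-chromosome
#' distances are defined through the concatenated coordinate system.
#'
#' @param gene_a Character vector of gene symbols (e.g. candidate co-genes).
#' @param gene_b A single gene symbol (e.g. the composite gene); recycled.
#' @param annotations Gene annotation tibble with `gene`, `chromosome`,
#'   `start`, `end`.
#' @param layout A [genome_layout()].
#' @return A tibble with columns `co_gene`, `composite_gene`,
#'   `normalized_distance`.
#' @examples
#' lay <- genome_layout(data.frame(chromosome = c("1", "2", "3"),
#'                                 length = rep(1e9, 3)))
#' ann <- data.frame(gene = c("A", "B"), chromosome = c("1", "2"),
#'                   start = c(50, 50), end = c(150, 150))
#' normalized_distance("A", "B", ann, lay)
#' @export
normalized_distance <- function(gene_a, gene_b, annotations, layout) {
  stopifnot(length(gene_b) == 1)
  ca <- gene_concat_coord(gene_a, annotations, layout)
  cb <- gene_concat_coord(gene_b, annotations, layout)
  d <- pmin(abs(ca - cb) / attr(layout, "normalizer"), 1)
  tibble(co_gene = gene_a, composite_gene = gene_b, normalized_distance = d)
}
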