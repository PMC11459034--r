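#' Configuration for the synthetic tumor cohort generator
#'
#' The generator emulates the statistical structure the analysis
#' assumes: tumor types with different background mutation rates, a
#' planted composite-mutation prevalence (5% of samples by default),
#' planted co-mutation odds ratios in carriers, and planted
#' same-chromosome placement of co-mutations (probability 0.35 by
#' default). Four composite oncogenes are placed at their GRCh38
#' coordinates (BRAF and EGFR on chromosome 7, KRAS on 12, PIK3CA on 3);
#' background panel genes are placed across the genome with probability
#' proportional to chromosome length, with a fixed number forced onto
#' each composite gene's chromosome so that proximal placement always
#' has targets.
#'
#' @param seed Integer seed; every draw of the generator flows from it.
#' @param n_samples Number of samples (default 2000).
#' @param tumor_types Tibble of `name`, `weight` (sampling weights) and
#'   `background_mut_rate` (per-gene passenger-mutation probability).
#' @param n_genes Total panel size including the composite genes.
#' @param tsg_fraction Fraction of background genes annotated as tumor
#'   suppressors.
#' @param composite_genes Composite gene symbols (subset of the four
#'   defaults).
#' @param composite_prevalence Fraction of samples planted as composite
#'   carriers (default 0.05).
#' @param comut_or Named numeric: per co-gene odds ratio of driver-event
#'   presence in carriers versus non-carriers (default: six genes at
#'   odds ratio 8). Use `NULL` for no association channel.
#' @param driver_event_rate Baseline probability that a sample carries a
#'   driver-level event in a given panel gene.
#' @param cnv_driver_prob Probability a planted driver event materializes
#'   as a high-level CNV rather than a hotspot mutation.
#' @param same_chrom_prob Probability a planted proximal co-mutation's
#'   gene lies on the carrier's composite chromosome (default 0.35).
#' @param n_proximal Planted proximal co-mutation events per carrier.
#' @param background_cnv_rate Per-gene probability of a low-level (+/-1)
#'   passenger CNV call.
#' @param substitution_weights Named weights over the six collapsed
#'   substitution classes (C>T-heavy default, the dominant class in
#'   replication-error and mutagen signatures).
#' @param layout A [genome_layout()] (default [grch38_layout()]).
#' @param forced_per_chromosome Background genes forced onto each
#'   composite gene's chromosome (default 6).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_samples = 2000,
                       tumor_types = tibble(
                         name = c("lung", "skin", "breast", "bowel"),
                         weight = c(0.3, 0.2, 0.3, 0.2),
                         background_mut_rate = c(0.10, 0.10, 0.05, 0.05)
                       ),
                       n_genes = 60,
                       tsg_fraction = 0.3,
                       composite_genes = c("BRAF", "EGFR", "KRAS", "PIK3CA"),
                       composite_prevalence = 0.05,
                       comut_or = stats::setNames(rep(8, 6), sprintf("G%02d", 1:6)),
                       driver_event_rate = 0.05,
                       cnv_driver_prob = 0.25,
                       same_chrom_prob = 0.35,
                       n_proximal = 3,
                       background_cnv_rate = 0.02,
                       substitution_weights = c(
                         "C>T" = 0.45, "C>A" = 0.10, "C>G" = 0.08,
                         "A>G" = 0.20, "A>T" = 0.09, "A>C" = 0.08
                       ),
                       layout = grch38_layout(),
                       forced_per_chromosome = 6) {
  probs <- c(composite_prevalence, driver_event_rate, cnv_driver_prob,
             same_chrom_prob, background_cnv_rate, tumor_types$background_mut_rate)
  if (any(probs < 0 | probs > 1)) abort_validation("probabilities must be in [0, 1]")
  if (!is.null(comut_or) && any(comut_or <= 0)) {
    abort_validation("odds ratios must be > 0")
  }
  if (!all(composite_genes %in% c("BRAF", "EGFR", "KRAS", "PIK3CA"))) {
    abort_validation("composite_genes must be a subset of BRAF, EGFR, KRAS, PIK3CA")
  }
  n_bg <- n_genes - length(composite_genes)
  if (!is.null(comut_or) &&
      !all(names(comut_or) %in% sprintf("G%02d", seq_len(n_bg)))) {
    abort_validation("comut_or names a gene absent from the panel")
  }
  structure(list(
    seed = as.integer(seed), n_samples = n_samples, tumor_types = tumor_types,
    n_genes = n_genes, tsg_fraction = tsg_fraction,
    composite_genes = composite_genes,
    composite_prevalence = composite_prevalence, comut_or = comut_or,
    driver_event_rate = driver_event_rate, cnv_driver_prob = cnv_driver_prob,
    same_chrom_prob = same_chrom_prob, n_proximal = n_proximal,
    background_cnv_rate = background_cnv_rate,
    substitution_weights = substitution_weights, layout = layout,
    forced_per_chromosome = forced_per_chromosome, null = FALSE
  ), class = "sim_config")
}

# GRCh38 coordinates of the four composite oncogenes
composite_gene_table <- function() {
  tibble(
    gene = c("BRAF", "EGFR", "KRAS", "PIK3CA"),
    role = "oncogene",
    chromosome = c("7", "7", "12", "3"),
    start = c(140719327, 55019017, 25205246, 179148114),
    end = c(140924929, 55211628, 25250936, 179240093)
  )
}

canonical_hotspots <- function() {
  tibble(
    gene = rep(c("BRAF", "EGFR", "KRAS", "PIK3CA"), each = 4),
    protein_change = c(
      "V600E", "V600M", "K601E", "G469A",
      "T790M", "L858R", "L861Q", "G719S",
      "G12D", "G12V", "G13D", "Q61H",
      "E545K", "H1047R", "E542K", "N345K"
    )
  )
}

# draws the background gene panel; consumes the active RNG stream
generate_panel <- function(config) {
  lay <- config$layout
  comp <- filter(composite_gene_table(), .data$gene %in% config$composite_genes)
  n_bg <- config$n_genes - nrow(comp)
  if (n_bg < 1) abort_validation("panel needs background genes beyond the composite set")
  names_bg <- sprintf("G%02d", seq_len(n_bg))

  forced <- rep(comp$chromosome, each = config$forced_per_chromosome)
  n_forced <- min(length(forced), n_bg)
  chroms <- c(forced[seq_len(n_forced)],
              sample(lay$chromosome, n_bg - n_forced, replace = TRUE,
                     prob = lay$length))
  glen <- round(stats::runif(n_bg, 2e4, 2e5))
  maxpos <- lay$length[match(chroms, lay$chromosome)] - glen - 1
  start <- floor(stats::runif(n_bg, 1, maxpos))
  n_tsg <- round(config$tsg_fraction * n_bg)
  roles <- sample(c(rep("tumor_suppressor", n_tsg),
                    rep("oncogene", n_bg - n_tsg)))
  ann_bg <- tibble(gene = names_bg, role = roles, chromosome = chroms,
                   start = start, end = start + glen)
  annotations <- bind_rows(comp, ann_bg)

  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  hs_bg <- purrr::map_dfr(names_bg, function(g) {
    pos <- sample(50:899, 4)
    tibble(gene = g,
           protein_change = paste0(sample(aa, 4, TRUE), pos, sample(aa, 4, TRUE)))
  })
  hotspots <- bind_rows(
    filter(canonical_hotspots(), .data$gene %in% config$composite_genes),
    hs_bg
  )
  list(annotations = annotations, hotspots = hotspots)
}

# draw ref/alt for one class label, randomly emitting the complemented strand
materialize_substitution <- function(cls, flip) {
  if (length(cls) == 0) {
    return(list(ref = character(0), alt = character(0)))
  }
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- ifelse(flip, comp[ref], ref)
  alt <- ifelse(flip, comp[alt], alt)
  list(ref = unname(ref), alt = unname(alt))
}

#' Generate a synthetic tumor cohort with planted structure
#'
#' Draws samples per tumor type, plants composite carriers at the
#' configured prevalence (two driver events for oncogene carriers, three
#' for tumor-suppressor carriers), plants co-mutation driver events with
#' the configured odds ratios (association channel) and with the
#' configured same-chromosome probability (proximity channel), and adds
#' passenger mutations and low-level CNVs. A non-carrier (sample, gene)
#' pair holds at most one driver-level event, so the recovered
#' composite prevalence equals the planted carrier fraction exactly.
#' Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (a validated [load_cohort()]
#'   object) and `truth` — the planted ground truth: `carriers` (tibble
#'   of sample_id, gene, role, n_events), `driver_events` (tibble of
#'   sample_id, gene, channel, same_chromosome), and the generator
#'   parameters.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- config$layout
  tt <- config$tumor_types
  n <- config$n_samples

  panel <- generate_panel(config)
  ann <- panel$annotations
  hs <- panel$hotspots
  bg_genes <- setdiff(ann$gene, config$composite_genes)
  role_of <- stats::setNames(ann$role, ann$gene)
  chrom_of <- stats::setNames(ann$chromosome, ann$gene)

  samples <- tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    tumor_type = sample(tt$name, n, replace = TRUE, prob = tt$weight),
    source = "tissue"
  )

  ## --- composite carriers -------------------------------------------------
  is_carrier <- stats::runif(n) < config$composite_prevalence
  carrier_idx <- which(is_carrier)
  if (config$composite_prevalence > 0 && length(carrier_idx) == 0) {
    rlang::warn("prevalence x n too small: no composite carriers drawn")
  }
  carrier_gene <- if (length(carrier_idx) > 0) {
    sample(config$composite_genes, length(carrier_idx), replace = TRUE)
  } else character()

  # event ledger: one row per planted driver-level event
  ev_sample <- character(); ev_gene <- character(); ev_kind <- character()
  ev_detail <- character(); ev_channel <- character(); ev_same <- logical()
  add_event <- function(s, g, kind, detail, channel, same = NA) {
    ev_sample[[length(ev_sample) + 1]] <<- s
    ev_gene[[length(ev_gene) + 1]] <<- g
    ev_kind[[length(ev_kind) + 1]] <<- kind
    ev_detail[[length(ev_detail) + 1]] <<- detail
    ev_channel[[length(ev_channel) + 1]] <<- channel
    ev_same[[length(ev_same) + 1]] <<- same
  }

  hs_by_gene <- split(hs$protein_change, hs$gene)
  for (k in seq_along(carrier_idx)) {
    sid <- samples$sample_id[carrier_idx[k]]
    g <- carrier_gene[k]
    n_req <- if (role_of[[g]] == "oncogene") 2L else 3L
    use_cnv <- stats::runif(1) < config$cnv_driver_prob
    n_hot <- if (use_cnv) n_req - 1L else n_req
    picks <- sample(hs_by_gene[[g]], n_hot, replace = FALSE)
    for (p in picks) add_event(sid, g, "hotspot_mutation", p, "composite")
    if (use_cnv) {
      call <- if (role_of[[g]] == "oncogene") "2" else "-2"
      kind <- if (call == "2") "high_amplification" else "deep_deletion"
      add_event(sid, g, kind, call, "composite")
    }
  }

  ## --- association channel (per-gene odds ratios in carriers) -------------
  p0 <- config$driver_event_rate
  o0 <- p0 / (1 - p0)
  has_event <- matrix(FALSE, nrow = n, ncol = length(bg_genes),
                      dimnames = list(samples$sample_id, bg_genes))
  if (p0 > 0) {
    for (g in bg_genes) {
      p_vec <- rep(p0, n)
      or_g <- if (!is.null(config$comut_or) && g %in% names(config$comut_or) &&
                  !config$null) config$comut_or[[g]] else 1
      if (or_g != 1) {
        p_vec[carrier_idx] <- (or_g * o0) / (1 + or_g * o0)
      }
      pres <- stats::runif(n) < p_vec
      idx <- which(pres)
      for (i in idx) {
        sid <- samples$sample_id[i]
        if (stats::runif(1) < config$cnv_driver_prob) {
          call <- if (role_of[[g]] == "oncogene") "2" else "-2"
          kind <- if (call == "2") "high_amplification" else "deep_deletion"
          add_event(sid, g, kind, call, "association")
        } else {
          add_event(sid, g, "hotspot_mutation", sample(hs_by_gene[[g]], 1),
                    "association")
        }
      }
      has_event[idx, g] <- TRUE
    }
  }

  ## --- proximity channel (same-chromosome placement) ----------------------
  ## Under the null the planted extra events go to EVERY sample with uniform
  ## gene placement, so carrier status is independent of co-gene features
  ## (otherwise carrier-specific event burden alone is predictive signal).
  bg_chrom <- chrom_of[bg_genes]
  prox_idx <- if (config$null) seq_len(n) else carrier_idx
  gene_of_idx <- stats::setNames(rep(NA_character_, n), samples$sample_id)
  gene_of_idx[carrier_idx] <- carrier_gene
  for (i in prox_idx) {
    sid <- samples$sample_id[i]
    comp_chrom <- if (is.na(gene_of_idx[i])) NA_character_
                  else chrom_of[[gene_of_idx[i]]]
    for (draw in seq_len(config$n_proximal)) {
      eligible <- bg_genes[!has_event[i, ]]
      if (length(eligible) == 0) break
      if (config$null) {
        pick <- if (length(eligible) == 1) eligible else sample(eligible, 1)
        same <- if (is.na(comp_chrom)) NA else chrom_of[[pick]] == comp_chrom
      } else {
        same <- stats::runif(1) < config$same_chrom_prob
        pool <- if (same) eligible[bg_chrom[eligible] == comp_chrom]
                else eligible[bg_chrom[eligible] != comp_chrom]
        if (length(pool) == 0) next
        pick <- if (length(pool) == 1) pool else sample(pool, 1)
      }
      if (stats::runif(1) < config$cnv_driver_prob) {
        call <- if (role_of[[pick]] == "oncogene") "2" else "-2"
        kind <- if (call == "2") "high_amplification" else "deep_deletion"
        add_event(sid, pick, kind, call, "proximity", same)
      } else {
        add_event(sid, pick, "hotspot_mutation", sample(hs_by_gene[[pick]], 1),
                  "proximity", same)
      }
      has_event[i, pick] <- TRUE
    }
  }

  driver_events <- tibble(sample_id = ev_sample, gene = ev_gene,
                          kind = ev_kind, detail = ev_detail,
                          channel = ev_channel, same_chromosome = ev_same)

  ## --- materialize records ------------------------------------------------
  hot <- filter(driver_events, .data$kind == "hotspot_mutation")
  cls <- sample(names(config$substitution_weights), nrow(hot), replace = TRUE,
                prob = config$substitution_weights)
  flip <- stats::runif(nrow(hot)) < 0.5
  sub <- materialize_substitution(cls, flip)
  gs <- match(hot$gene, ann$gene)
  mut_hot <- tibble(
    sample_id = hot$sample_id, gene = hot$gene, protein_change = hot$detail,
    chromosome = ann$chromosome[gs],
    position = as.integer(floor(stats::runif(nrow(hot), ann$start[gs], ann$end[gs]))),
    ref_allele = sub$ref, alt_allele = sub$alt
  )

  cnv_ev <- filter(driver_events, .data$kind != "hotspot_mutation")
  cnvs <- tibble(sample_id = cnv_ev$sample_id, gene = cnv_ev$gene,
                 call = as.integer(cnv_ev$detail))

  # passenger mutations: protein changes use a frameshift-style suffix so
  # they can never collide with the substitution-style hotspot catalog
  bg_rate <- tt$background_mut_rate[match(samples$tumor_type, tt$name)]
  pm <- which(matrix(stats::runif(n * nrow(ann)), nrow = n) <
                matrix(bg_rate, nrow = n, ncol = nrow(ann)), arr.ind = TRUE)
  if (nrow(pm) > 0) {
    gs <- pm[, 2]
    cls <- sample(names(config$substitution_weights), nrow(pm), replace = TRUE,
                  prob = config$substitution_weights)
    flip <- stats::runif(nrow(pm)) < 0.5
    sub <- materialize_substitution(cls, flip)
    aa <- c("A", "R", "N", "D", "G", "L", "K", "S", "T", "V")
    mut_bg <- tibble(
      sample_id = samples$sample_id[pm[, 1]],
      gene = ann$gene[gs],
      protein_change = paste0(sample(aa, nrow(pm), TRUE),
                              sample(1000:1999, nrow(pm), TRUE), "fs"),
      chromosome = ann$chromosome[gs],
      position = as.integer(floor(stats::runif(nrow(pm), ann$start[gs], ann$end[gs]))),
      ref_allele = sub$ref, alt_allele = sub$alt
    )
  } else {
    mut_bg <- mut_hot[0, ]
  }

  # low-level passenger CNVs, skipping (sample, gene) pairs already called
  pc <- which(matrix(stats::runif(n * nrow(ann)), nrow = n) <
                config$background_cnv_rate, arr.ind = TRUE)
  if (nrow(pc) > 0) {
    cnv_bg <- tibble(
      sample_id = samples$sample_id[pc[, 1]], gene = ann$gene[pc[, 2]],
      call = sample(c(-1L, 1L), nrow(pc), replace = TRUE)
    )
    cnv_bg <- anti_join(cnv_bg, cnvs, by = c("sample_id", "gene"))
    cnvs <- bind_rows(cnvs, cnv_bg)
  }

  cohort <- load_cohort(
    mutations = bind_rows(mut_hot, mut_bg),
    cnvs = cnvs, annotations = ann, hotspots = hs, samples = samples,
    layout = lay
  )
  truth <- list(
    carriers = tibble(
      sample_id = samples$sample_id[carrier_idx], gene = carrier_gene,
      role = unname(role_of[carrier_gene]),
      n_events = ifelse(role_of[carrier_gene] == "oncogene", 2L, 3L)
    ),
    driver_events = driver_events,
    composite_prevalence = config$composite_prevalence,
    comut_or = config$comut_or,
    same_chrom_prob = config$same_chrom_prob,
    null = config$null,
    seed = config$seed
  )
  list(cohort = cohort, truth = truth)
}

#' Generate a matched null cohort (no planted structure)
#'
#' As [generate_cohort()] but with every co-mutation odds ratio forced
#' to 1 and the planted extra events given to every sample with uniform
#' gene placement (approximately chromosome-length-weighted, through the
#' panel's length-proportional placement) instead of carrier-only,
#' composite-chromosome-preferring placement — so carrier status is
#' independent of every non-target feature, including total event
#' burden. Used for type-I-error, null-AUC and super-uniformity checks.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()].
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$null <- TRUE
  generate_cohort(config)
}

#' Write a cohort and its ground truth as a plain-text fixture bundle
#'
#' Emits files readable by the package's readers: `maf.tsv` (cBioPortal
#' column names), `cnv_matrix.tsv` (gene x sample wide, zero-filled),
#' `annotations.tsv`, `hotspots.tsv`, `samples.tsv`, `layout.tsv`, and
#' `truth.json`. Reading the bundle back with [load_cohort()]
#' reproduces the cohort's record set exactly.
#'
#' @param cohort A [load_cohort()] object.
#' @param truth Ground truth from [generate_cohort()] (may be `NULL`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture_bundle <- function(cohort, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    maf = file.path(dir, "maf.tsv"),
    cnv = file.path(dir, "cnv_matrix.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    hotspots = file.path(dir, "hotspots.tsv"),
    samples = file.path(dir, "samples.tsv"),
    layout = file.path(dir, "layout.tsv"),
    truth = file.path(dir, "truth.json")
  )
  maf <- cohort$mutations
  dialect <- maf_dialect()
  names(maf) <- unname(dialect[names(maf)])
  readr::write_tsv(maf, paths[["maf"]], progress = FALSE)

  wide <- cohort$cnvs |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "call",
                       values_fill = 0L) |>
    arrange(.data$gene)
  readr::write_tsv(wide, paths[["cnv"]], progress = FALSE)

  readr::write_tsv(cohort$annotations, paths[["annotations"]], progress = FALSE)
  readr::write_tsv(cohort$hotspots, paths[["hotspots"]], progress = FALSE)
  readr::write_tsv(cohort$samples, paths[["samples"]], progress = FALSE)
  readr::write_tsv(as_tibble(cohort$layout)[, c("chromosome", "length")],
                   paths[["layout"]], progress = FALSE)
  truth_json <- if (is.null(truth)) list() else list(
    n_samples = nrow(cohort$samples),
    n_carriers = nrow(truth$carriers),
    carriers = truth$carriers,
    composite_prevalence = truth$composite_prevalence,
    same_chrom_prob = truth$same_chrom_prob,
    null = truth$null, seed = truth$seed
  )
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}
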