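# Hand-built toy cohort around the canonical worked examples:
# one melanoma sample with BRAF V600E + V600M, one lung sample with
# EGFR T790M + L858R, plus non-composite carriers of single events.
toy_annotations <- function() {
  tibble::tibble(
    gene = c("BRAF", "EGFR", "KRAS", "TP53"),
    role = c("oncogene", "oncogene", "oncogene", "tumor_suppressor"),
    chromosome = c("7", "7", "12", "17"),
    start = c(140719327, 55019017, 25205246, 7668421),
    end = c(140924929, 55211628, 25250936, 7687490)
  )
}

toy_hotspots <- function() {
  tibble::tibble(
    gene = c("BRAF", "BRAF", "EGFR", "EGFR", "KRAS", "TP53", "TP53", "TP53"),
    protein_change = c("V600E", "V600M", "T790M", "L858R", "G12D",
                       "R175H", "R248Q", "R273H")
  )
}

toy_mutation <- function(sample_id, gene, protein_change,
                         chromosome = "7", position = 140753336,
                         ref = "A", alt = "T") {
  tibble::tibble(sample_id = sample_id, gene = gene,
                 protein_change = protein_change, chromosome = chromosome,
                 position = as.integer(position),
                 ref_allele = ref, alt_allele = alt)
}

toy_cohort <- function(extra_mutations = NULL, extra_cnvs = NULL) {
  samples <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4", "s5"),
    tumor_type = c("skin", "lung", "lung", "skin", "lung"),
    source = "tissue"
  )
  mutations <- dplyr::bind_rows(
    toy_mutation("s1", "BRAF", "V600E"),
    toy_mutation("s1", "BRAF", "V600M"),
    toy_mutation("s2", "EGFR", "T790M", position = 55181378),
    toy_mutation("s2", "EGFR", "L858R", position = 55191822),
    toy_mutation("s3", "KRAS", "G12D", chromosome = "12", position = 25245350),
    toy_mutation("s4", "TP53", "R175H", chromosome = "17", position = 7675088),
    extra_mutations
  )
  cnvs <- dplyr::bind_rows(
    tibble::tibble(sample_id = "s5", gene = "KRAS", call = 2L),
    extra_cnvs
  )
  load_cohort(mutations, cnvs, toy_annotations(), toy_hotspots(), samples)
}

# small simulated cohort for module tests
small_sim <- function(seed = 1, n = 400, ...) {
  generate_cohort(sim_config(seed = seed, n_samples = n, ...))
}

# events table with k distinct hotspot events in one gene of one sample
synthetic_events <- function(k, gene = "X1", sample_id = "s") {
  if (k == 0) {
    return(tibble::tibble(sample_id = character(), gene = character(),
                          kind = character(), detail = character()))
  }
  tibble::tibble(sample_id = sample_id, gene = gene,
                 kind = "hotspot_mutation", detail = paste0("V", seq_len(k), "E"))
}

# independent brute-force two-sided Fisher p: enumerate every table with
# the observed margins via binomial-coefficient ratios
fisher_oracle_p <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c; n <- row1 + row2
  if (row1 == 0 || row2 == 0 || col1 == 0 || col1 == n) return(1)
  support <- max(0, col1 - row2):min(row1, col1)
  probs <- choose(row1, support) * choose(row2, col1 - support) / choose(n, col1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# brute-force AUC: concordant-pair counting with half-credit for ties
auc_oracle <- function(truth, score) {
  pos <- which(truth == "composite")
  neg <- which(truth != "composite")
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    }
  }
  total / (length(pos) * length(neg))
}
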