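test_that("fisher_exact matches enumeration on the stated example tables", {
  expect_equal(fisher_exact(5, 5, 5, 5)$p_value, 1.0)
  expect_equal(fisher_exact(3, 1, 1, 5)$p_value, fisher_oracle_p(3, 1, 1, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact(10, 0, 0, 10)$p_value, 2 / choose(20, 10),
               tolerance = 1e-12)
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(1)
  for (i in 1:50) {
    tb <- rpois(4, lambda = sample(c(2, 5, 15), 1))
    if (sum(tb[1:2]) == 0 || sum(tb[3:4]) == 0) next
    mine <- fisher_exact(tb[1], tb[2], tb[3], tb[4])$p_value
    ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("odds ratio follows the cross-product convention with infinities", {
  expect_equal(fisher_exact(3, 1, 1, 5)$odds_ratio, 15)
  expect_equal(fisher_exact(10, 0, 0, 10)$odds_ratio, Inf)
  expect_true(is.nan(fisher_exact(0, 5, 0, 5)$odds_ratio))
  # degenerate zero column margin carries no information
  expect_equal(fisher_exact(0, 5, 0, 5)$p_value, 1.0)
})

test_that("background rate is the median gene frequency times 1.04", {
  samples <- tibble::tibble(sample_id = sprintf("t%02d", 1:10),
                            tumor_type = "lung", source = "tissue")
  ann <- tibble::tibble(gene = c("A1", "B1", "C1"), role = "oncogene",
                        chromosome = "1", start = c(1, 1e6, 2e6),
                        end = c(1e5, 1.1e6, 2.1e6))
  # frequencies 0.1, 0.2, 0.3
  mut <- dplyr::bind_rows(
    toy_mutation("t01", "A1", "X1Y", chromosome = "1", position = 10),
    purrr::map_dfr(1:2, ~toy_mutation(sprintf("t%02d", .x), "B1", "X2Y",
                                      chromosome = "1", position = 1e6 + 5)),
    purrr::map_dfr(1:3, ~toy_mutation(sprintf("t%02d", .x), "C1", "X3Y",
                                      chromosome = "1", position = 2e6 + 5))
  )
  hs <- tibble::tibble(gene = "A1", protein_change = "X1Y")
  co <- load_cohort(mut, tibble::tibble(sample_id = character(),
                                        gene = character(), call = integer()),
                    ann, hs, samples)
  bg <- compute_background_rate(co, "lung")
  expect_equal(bg$background_rate, 0.2)
  expect_equal(bg$threshold, 0.208)
  expect_equal(bg$threshold / bg$background_rate, 1.04)
  expect_error(compute_background_rate(co, "no_such_type"),
               class = "compmut_empty_stratum")
})

test_that("extreme co-gene separation is significant and tables reconstruct", {
  gen <- small_sim(seed = 21, n = 500)
  co <- gen$cohort
  calls <- call_composites(extract_driver_events(co), co$annotations)
  tt <- names(sort(table(co$samples$tumor_type[
    co$samples$sample_id %in% calls$sample_id]), decreasing = TRUE))[1]
  g <- names(sort(table(calls$gene), decreasing = TRUE))[1]
  res <- test_comutations(co, calls, g, tt)
  expect_true(all(res$significant == (res$p_value < 0.05)))
  expect_true(all(res$freq_composite >= 0 & res$freq_composite <= 1))

  # internal consistency: each row's p equals fisher_exact on the
  # independently reconstructed 2x2 table
  ids <- co$samples$sample_id[co$samples$tumor_type == tt]
  comp <- intersect(unique(calls$sample_id[calls$gene == g]), ids)
  ev <- extract_driver_events(co)
  for (i in seq_len(min(nrow(res), 10))) {
    cg <- res$co_gene[i]
    with_ev <- unique(ev$sample_id[ev$gene == cg])
    a <- sum(comp %in% with_ev)
    b <- length(comp) - a
    cc <- sum(setdiff(ids, comp) %in% with_ev)
    d <- length(setdiff(ids, comp)) - cc
    expect_equal(res[i, c("a", "b", "c", "d")],
                 tibble::tibble(a = a, b = b, c = cc, d = d),
                 ignore_attr = TRUE)
    expect_equal(res$p_value[i], fisher_exact(a, b, cc, d)$p_value)
  }
  expect_error(test_comutations(co, calls, g, "no_such_type"),
               class = "compmut_empty_stratum")
})

test_that("a fully separating co-gene is flagged significant", {
  # 10 composite samples all with the co-gene event, 40 non-composite without
  ft <- fisher_exact(10, 0, 0, 40)
  expect_lt(ft$p_value, 0.05)
})

test_that("an odds ratio of 8 is detected in most 30-vs-300 strata", {
  # presence probability 0.1 in non-composite samples; odds scaled by 8
  # in composite samples (8/9 odds -> p = 8/17)
  set.seed(314)
  detected <- replicate(100, {
    a <- stats::rbinom(1, 30, 8 / 17)
    c <- stats::rbinom(1, 300, 0.1)
    fisher_exact(a, 30 - a, c, 300 - c)$p_value < 0.05
  })
  expect_gte(mean(detected), 0.80)
})

test_that("complementary relationship recovers exact and planted correlations", {
  res <- tibble::tibble(freq_noncomposite = c(0.1, 0.2, 0.3, 0.4, 0.5),
                        freq_composite = c(0.1, 0.2, 0.3, 0.4, 0.5))
  fit <- complementary_relationship(res)
  expect_equal(fit$pearson_r, 1.0)
  expect_equal(fit$slope, 1.0)

  # closed-form check on a 5-pair toy vector
  x <- c(0.05, 0.10, 0.20, 0.40, 0.50)
  y <- c(0.12, 0.08, 0.25, 0.30, 0.60)
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  fit2 <- complementary_relationship(
    tibble::tibble(freq_noncomposite = x, freq_composite = y))
  expect_equal(fit2$pearson_r, r_closed, tolerance = 1e-12)

  expect_error(complementary_relationship(
    tibble::tibble(freq_noncomposite = c(0.1, 0.2, 0.3),
                   freq_composite = c(0.2, 0.2, 0.2))),
    "zero variance", class = "compmut_fit_error")
  expect_error(complementary_relationship(
    tibble::tibble(freq_noncomposite = c(0.1, 0.2),
                   freq_composite = c(0.2, 0.3))),
    class = "compmut_fit_error")
})

test_that("complementary relationship recovers a planted correlation", {
  set.seed(42)
  rs <- replicate(100, {
    x <- stats::runif(50, 0, 0.5)
    y <- 0.8 * x + stats::rnorm(50, sd = 0.07)
    complementary_relationship(
      tibble::tibble(freq_noncomposite = x, freq_composite = y))$pearson_r
  })
  planted <- 0.8 * stats::sd(stats::runif(1e5, 0, 0.5)) /
    sqrt((0.8 * stats::sd(stats::runif(1e5, 0, 0.5)))^2 + 0.07^2)
  expect_lt(abs(mean(rs) - planted), 0.05)
})

test_that("substitution spectrum collapses strands and sums to one", {
  m <- toy_mutation("s", "g", "p", ref = "C", alt = "T")
  sp <- substitution_spectrum(m)
  expect_equal(sp$fraction[sp$class == "C>T"], 1.0)

  m2 <- toy_mutation("s", "g", "p", ref = "G", alt = "A")  # complement of C>T
  sp2 <- substitution_spectrum(m2)
  expect_equal(sp2$fraction[sp2$class == "C>T"], 1.0)

  # 10-record toy mix: 3 C>T, 2 G>A (= C>T), 2 T>G (= A>C), 1 A>T, 1 C>G, 1 G>T (= C>A)
  refs <- c("C", "C", "C", "G", "G", "T", "T", "A", "C", "G")
  alts <- c("T", "T", "T", "A", "A", "G", "G", "T", "G", "T")
  m3 <- purrr::map_dfr(seq_along(refs), function(i)
    toy_mutation(paste0("s", i), "g", "p", ref = refs[i], alt = alts[i]))
  sp3 <- substitution_spectrum(m3)
  expect_equal(sp3$fraction[match(c("C>T", "A>C", "A>T", "C>G", "C>A"), sp3$class)],
               c(0.5, 0.2, 0.1, 0.1, 0.1))
  expect_equal(sum(sp3$fraction), 1, tolerance = 1e-12)

  # non-SNV records are skipped with a count
  m4 <- dplyr::bind_rows(m, toy_mutation("s2", "g", "p", ref = "-", alt = "T"))
  sp4 <- substitution_spectrum(m4)
  expect_equal(attr(sp4, "n_skipped"), 1L)
  expect_equal(sum(sp4$fraction), 1, tolerance = 1e-12)
})
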