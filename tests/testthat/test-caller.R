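test_that("driver events cover hotspots and high-level CNVs only", {
  co <- toy_cohort(
    extra_mutations = toy_mutation("s3", "BRAF", "A9X"),  # not in catalog
    extra_cnvs = tibble::tibble(sample_id = "s3", gene = "TP53", call = -1L)
  )
  ev <- extract_driver_events(co)
  expect_false(any(ev$detail == "A9X"))
  expect_false(any(ev$gene == "TP53" & ev$kind != "hotspot_mutation"))
  # s5 has a +2 KRAS call
  expect_true(any(ev$sample_id == "s5" & ev$kind == "high_amplification"))

  co2 <- toy_cohort(extra_cnvs = tibble::tibble(sample_id = "s3",
                                                gene = "EGFR", call = -2L))
  ev2 <- extract_driver_events(co2)
  expect_true(any(ev2$sample_id == "s3" & ev2$gene == "EGFR" &
                    ev2$kind == "deep_deletion"))
})

test_that("worked composite examples are called: BRAF V600E+V600M, EGFR T790M+L858R", {
  co <- toy_cohort()
  calls <- call_composites(extract_driver_events(co), co$annotations)
  expect_true(any(calls$sample_id == "s1" & calls$gene == "BRAF" &
                    calls$n_events == 2))
  expect_true(any(calls$sample_id == "s2" & calls$gene == "EGFR" &
                    calls$n_events == 2))
  # single-event carriers are not composite
  expect_false(any(calls$sample_id %in% c("s3", "s4", "s5")))
})

test_that("composite thresholds are exact over event counts 0..4 for both roles", {
  for (role in c("oncogene", "tumor_suppressor")) {
    need <- if (role == "oncogene") 2L else 3L
    for (k in 0:4) {
      ann <- tibble::tibble(gene = "X1", role = role, chromosome = "1",
                            start = 1, end = 10)
      calls <- call_composites(synthetic_events(k), ann)
      expect_equal(nrow(calls), as.integer(k >= need),
                   info = sprintf("role=%s k=%d", role, k))
    }
  }
})

test_that("a hotspot plus a high-level CNV in one oncogene counts as two events", {
  ev <- dplyr::bind_rows(
    synthetic_events(1),
    tibble::tibble(sample_id = "s", gene = "X1",
                   kind = "high_amplification", detail = "2")
  )
  ann <- tibble::tibble(gene = "X1", role = "oncogene", chromosome = "1",
                        start = 1, end = 10)
  expect_equal(call_composites(ev, ann)$n_events, 2L)
  ann$role <- "tumor_suppressor"
  expect_equal(nrow(call_composites(ev, ann)), 0L)
})

test_that("calling is idempotent and monotone in added events", {
  gen <- small_sim(seed = 5, n = 200)
  co <- gen$cohort
  ev <- extract_driver_events(co)
  calls <- call_composites(ev, co$annotations)
  # idempotence: duplicated event table dedups to the same calls
  expect_equal(call_composites(dplyr::bind_rows(ev, ev), co$annotations), calls)
  # monotonicity: a new distinct event never removes an existing call
  set.seed(7)
  for (i in 1:20) {
    row <- ev[sample(nrow(ev), 1), ]
    extra <- tibble::tibble(sample_id = row$sample_id, gene = row$gene,
                            kind = "hotspot_mutation",
                            detail = paste0("Z", i, "W"))
    calls2 <- call_composites(dplyr::bind_rows(ev, extra), co$annotations)
    expect_true(all(paste(calls$sample_id, calls$gene) %in%
                      paste(calls2$sample_id, calls2$gene)))
  }
})

test_that("event partition classes are disjoint and cover driver events", {
  gen <- small_sim(seed = 11, n = 300)
  co <- gen$cohort
  ev <- extract_driver_events(co)
  calls <- call_composites(ev, co$annotations)
  part <- partition_events(co, calls)
  expect_true(all(part$sample_id %in% calls$sample_id))
  # composite + comutation rows reproduce the samples' driver events
  driver_part <- part[part$class != "background", ]
  ev_comp <- ev[ev$sample_id %in% calls$sample_id, ]
  expect_setequal(paste(driver_part$sample_id, driver_part$gene, driver_part$detail),
                  paste(ev_comp$sample_id, ev_comp$gene, ev_comp$detail))
  # no row is in two classes
  expect_equal(anyDuplicated(part[, c("sample_id", "gene", "kind", "detail")]), 0L)
})

test_that("a composite sample's other driver event is exactly one co-mutation", {
  co <- toy_cohort(extra_cnvs = tibble::tibble(sample_id = "s1",
                                               gene = "KRAS", call = 2L))
  calls <- call_composites(extract_driver_events(co), co$annotations)
  part <- partition_events(co, calls)
  comut <- part[part$class == "comutation" & part$sample_id == "s1", ]
  expect_equal(nrow(comut), 1L)
  expect_equal(comut$gene, "KRAS")
  # non-composite samples have no partition entry
  expect_false(any(part$sample_id == "s3"))
})

test_that("prevalence handles the empty and saturated extremes", {
  co <- toy_cohort()
  calls <- call_composites(extract_driver_events(co), co$annotations)
  prev <- composite_prevalence(calls, co)
  expect_equal(prev$n_composite_samples, 2L)
  expect_equal(prev$prevalence, 2 / 5)
  expect_equal(composite_prevalence(calls[0, ], co)$prevalence, 0)

  gen0 <- generate_cohort(sim_config(seed = 2, n_samples = 100,
                                     composite_prevalence = 0))
  calls0 <- call_composites(extract_driver_events(gen0$cohort),
                            gen0$cohort$annotations)
  expect_equal(nrow(calls0), 0L)
})

test_that("planted prevalence is recovered within the binomial 95% interval", {
  for (pi0 in c(0.02, 0.05, 0.10)) {
    gen <- generate_cohort(sim_config(seed = round(1000 * pi0),
                                      n_samples = 2000,
                                      composite_prevalence = pi0))
    calls <- call_composites(extract_driver_events(gen$cohort),
                             gen$cohort$annotations)
    prev <- composite_prevalence(calls, gen$cohort)
    half <- 1.96 * sqrt(pi0 * (1 - pi0) / 2000)
    expect_gt(prev$prevalence, pi0 - half)
    expect_lt(prev$prevalence, pi0 + half)
    # calls match the planted carriers exactly
    expect_setequal(paste(calls$sample_id, calls$gene),
                    paste(gen$truth$carriers$sample_id, gen$truth$carriers$gene))
  }
})
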