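test_that("degenerate prevalences produce exactly the configured carriers", {
  cfg <- cohort_config(
    n_eec = 10, n_ein = 10,
    prevalence = tibble::tibble(gene = "PTEN", prob_eec = 1, prob_ein = 0),
    hypermutator_fraction = 0, background_mean = 0,
    germline_rate_eec = 0, germline_benign_rate = 0, seed = 3
  )
  co <- generate_cohort(cfg)
  carriers <- unique(co$somatic$sample_id[co$somatic$gene == "PTEN"])
  expect_length(carriers, 10)
  expect_true(all(co$samples$group[match(carriers,
                                         co$samples$sample_id)] == "EEC"))
})

test_that("the generator is a deterministic function of config and seed", {
  cfg <- cohort_config(n_eec = 15, n_ein = 10, seed = 99,
                       cnv_spikes = tibble::tibble(
                         gene = "VEGFB", group = "EEC",
                         carrier_fraction = 0.5, log2_fold = 1
                       ))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$somatic, b$somatic)
  expect_identical(a$germline, b$germline)
  expect_identical(a$regions, b$regions)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(n_eec = 15, n_ein = 10, seed = 100))
  expect_false(identical(a$somatic, c$somatic))
})

test_that("observed prevalence converges to the configured probability", {
  probs <- tibble::tibble(
    gene = c("PTEN", "PIK3CA", "KRAS"),
    prob_eec = c(0.65, 0.40, 0.10),
    prob_ein = c(0.30, 0.40, 0.05)
  )
  n <- 2000
  cfg <- cohort_config(n_eec = n, n_ein = n, prevalence = probs,
                       hypermutator_fraction = 0.02,
                       germline_rate_eec = 0, germline_benign_rate = 0,
                       cnv_genes = character(0), seed = 17)
  co <- generate_cohort(cfg)
  prev <- prevalence_table(co)
  for (i in seq_len(nrow(probs))) {
    row <- prev[prev$gene == probs$gene[i], ]
    for (grp in c("eec", "ein")) {
      p <- probs[[paste0("prob_", grp)]][i]
      obs <- row[[paste0("mutated_", grp)]] / n
      expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
    }
  }
})

test_that("count fixtures reproduce their input tables bit-exactly", {
  counts <- example_gene_counts()
  fx <- fixture_from_counts(counts)
  prev <- prevalence_table(fx)
  for (i in seq_len(nrow(counts))) {
    row <- prev[prev$gene == counts$gene[i], ]
    expect_identical(row$mutated_eec, counts$eec[i])
    expect_identical(row$mutated_ein, counts$ein[i])
  }
  # PTEN 2x2 table [[51, 28], [13, 23]] and PIK3CA overall carrier count
  pten <- prev[prev$gene == "PTEN", ]
  expect_identical(
    c(pten$mutated_eec, pten$n_eec - pten$mutated_eec,
      pten$mutated_ein, pten$n_ein - pten$mutated_ein),
    c(51L, 28L, 13L, 23L)
  )
  expect_identical(prev$mutated_overall[prev$gene == "PIK3CA"], 53L)

  empty <- fixture_from_counts(
    tibble::tibble(gene = "G", eec = 0L, ein = 0L), n_eec = 1, n_ein = 1
  )
  expect_equal(nrow(empty$somatic), 0)

  expect_error(
    fixture_from_counts(tibble::tibble(gene = "G", eec = 3L, ein = 0L),
                        n_eec = 2, n_ein = 2),
    "exceeds group size"
  )
})

test_that("truth-labelled hypermutators carry DDR variants and elevated counts", {
  cfg <- cohort_config(seed = 5, hypermutator_fraction = 0.1)
  co <- generate_cohort(cfg)
  hyp <- co$truth$hypermutators
  expect_gt(length(hyp), 0)
  ddr <- flag_ddr(co$somatic)
  expect_true(all(hyp %in% ddr$sample_id))
  counts <- dplyr::count(co$somatic, sample_id)
  hyp_counts <- counts$n[counts$sample_id %in% hyp]
  other_counts <- counts$n[!counts$sample_id %in% hyp]
  expect_gt(min(hyp_counts), max(other_counts))
})

test_that("CNV spike-ins shift the expected log2 ratio of exactly the chosen regions", {
  reg <- mk_regions(10, tumor = 200, normal = 200)
  expect_identical(spike_cnv(reg, "VEGFB", log2_fold = 0), reg)

  full <- spike_cnv(reg, "VEGFB", log2_fold = 1, affected_fraction = 1)
  lrr <- region_lrr(full)$lrr
  expect_equal(lrr, rep(1, 10), tolerance = 1e-12)

  part <- spike_cnv(reg, "VEGFB", log2_fold = 1, affected_fraction = 0.8)
  expect_equal(sum(part$tumor_depth != reg$tumor_depth), 8)

  expect_error(spike_cnv(reg, "ABSENT", 1), "not present")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_eec = -1), "non-negative")
  expect_error(
    cohort_config(prevalence = tibble::tibble(gene = "G", prob_eec = 1.2,
                                              prob_ein = 0)),
    "probabilities"
  )
  expect_error(cohort_config(mean_tumor_depth = 0), "positive")
  expect_error(
    cohort_config(cnv_spikes = tibble::tibble(
      gene = "NOT_ON_PANEL", group = "EEC",
      carrier_fraction = 0.5, log2_fold = 1
    )),
    "panel"
  )
})
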