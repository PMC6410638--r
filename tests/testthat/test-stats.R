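test_that("Fisher exact p matches enumeration and fisher.test on representative tables", {
  tables <- list(
    c(10, 69, 0, 36),   # sparse: carcinoma-only mutations
    c(3, 76, 6, 30),    # enriched in the precursor group
    c(51, 28, 13, 23),  # balanced margins
    c(0, 10, 0, 10),    # empty column margin
    c(5, 0, 0, 5),      # perfect association
    c(1, 1, 1, 1)
  )
  for (tb in tables) {
    got <- fisher_exact_p(tb[1], tb[2], tb[3], tb[4])
    expect_equal(got, fisher_enum_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    expect_equal(
      got,
      stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
      tolerance = 1e-9
    )
  }
  expect_equal(round(fisher_exact_p(10, 69, 0, 36), 3), 0.030)
  expect_error(fisher_exact_p(-1, 2, 3, 4), "non-negative")
})

test_that("the association test picks Yates chi-square for well-filled tables and Fisher otherwise", {
  pten <- test_association(matrix(c(51, 28, 13, 23), 2, byrow = TRUE))
  expect_equal(pten$test_used, "pearson_yates")
  expect_equal(pten$p_value, yates_oracle(51, 28, 13, 23), tolerance = 1e-12)
  expect_equal(round(pten$p_value, 3), 0.008)

  kdr <- test_association(matrix(c(10, 69, 0, 36), 2, byrow = TRUE))
  expect_equal(kdr$test_used, "fisher_exact")
  expect_equal(round(kdr$p_value, 3), 0.030)

  flat <- test_association(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(flat$p_value, 1)

  degenerate <- test_association(matrix(c(0, 10, 0, 12), 2, byrow = TRUE))
  expect_equal(degenerate$test_used, "fisher_exact")
  expect_equal(degenerate$p_value, 1)

  expect_error(test_association(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("the chi-square statistic and p are invariant to row and column swaps", {
  base <- matrix(c(30, 49, 4, 32), 2, byrow = TRUE)
  ref <- test_association(base)
  for (tab in list(base[2:1, ], base[, 2:1], base[2:1, 2:1], t(base))) {
    got <- test_association(tab)
    expect_equal(got$statistic, ref$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, ref$p_value, tolerance = 1e-12)
  }
})

test_that("prevalence tables count each sample once per gene and conserve margins", {
  fx <- fixture_from_counts(example_gene_counts())
  prev <- prevalence_table(fx, min_mutated = 9)
  expect_equal(round(prev$percentage[prev$gene == "PIK3CA"], 1), 46.1)
  expect_equal(round(prev$percentage[prev$gene == "CTNNB1"], 1), 29.6)
  expect_true(all(prev$mutated_overall ==
                    prev$mutated_eec + prev$mutated_ein))
  expect_true(all(prev$mutated_overall >= 9))
  expect_true(all(diff(prev$mutated_overall) <= 0))

  # duplicated variants in one sample-gene pair do not inflate counts
  dup <- mk_tiny_cohort(mk_variants(c("EEC_001", "EEC_001"), "PTEN"))
  expect_equal(prevalence_table(dup)$mutated_eec, 1L)

  # min_mutated excludes a gene one short of the threshold
  low <- fixture_from_counts(tibble::tibble(gene = "APC", eec = 8L, ein = 0L))
  expect_equal(nrow(prevalence_table(low, min_mutated = 9)), 0)
})

test_that("co-mutation counts carriers of both genes with group shares and a policy test", {
  fx <- fixture_from_counts(example_gene_counts())
  cm <- comutation(fx, "PTEN", "PIK3CA")
  expect_equal(cm$counts$n_comutated, c(24L, 4L))
  expect_equal(round(100 * cm$counts$share, 1), c(30.4, 11.1))
  expect_equal(cm$test$test_used, "pearson_yates")
  expect_equal(round(cm$test$p_value, 3), 0.046)

  self <- comutation(fx, "PTEN", "PTEN")
  prev <- prevalence_table(fx)
  expect_equal(self$counts$n_comutated,
               c(prev$mutated_eec[prev$gene == "PTEN"],
                 prev$mutated_ein[prev$gene == "PTEN"]))

  none <- comutation(fx, "PTEN", "NOT_MUTATED")
  expect_equal(none$counts$n_comutated, c(0L, 0L))
  expect_equal(none$counts$share, c(0, 0))

  td <- tidy(cm)
  expect_equal(td$gene_b, rep("PIK3CA", 2))
})

test_that("the differential screen recovers exactly the significantly enriched genes", {
  fx <- fixture_from_counts(example_gene_counts())
  ds <- differential_screen(fx, min_mutated = 9)
  sig <- sort(ds$gene[ds$significant])
  expect_setequal(sig, c("PTEN", "PIK3R1", "ARID1A", "CTCF", "ARHGAP35",
                         "KDR", "AKT1"))
  expect_false(any(c("NF1", "TP53", "KRAS", "PIK3CA") %in% sig))
  expect_equal(round(ds$p_value[ds$gene == "NF1"], 3), 0.055)
  expect_equal(glance(ds)$n_significant, 7L)

  none <- differential_screen(fx, min_mutated = 9, alpha = 0)
  expect_equal(sum(none$significant), 0)

  single <- differential_screen(
    fixture_from_counts(tibble::tibble(gene = "PTEN", eec = 51L, ein = 13L))
  )
  expect_equal(nrow(single), 1)

  bh <- differential_screen(fx, min_mutated = 9, correction = "BH")
  expect_true(all(bh$p_adjusted >= ds$p_value - 1e-15))
  expect_equal(bh$p_adjusted,
               stats::p.adjust(bh$p_value, method = "BH"))
})

test_that("covariate cross-tabulations keep empty levels and conserve totals", {
  samples <- tibble::tibble(
    sample_id = sprintf("EEC_%03d", 1:6),
    group = "EEC",
    grade = c("G1", "G1", "G2", "G2", "G3", "G3")
  )
  somatic <- mk_variants(sprintf("EEC_%03d", 1:4), "CTNNB1")
  co <- new_cohort(samples, somatic)
  ct <- crosstab(co, "CTNNB1", "grade")
  expect_equal(ct$level, c("G1", "G2", "G3"))
  expect_equal(ct$n_mutated, c(2L, 2L, 0L))  # depleted level retained
  expect_equal(sum(ct$n_mutated), 4)
  expect_equal(ct$n_mutated + ct$n_wildtype, ct$n_total)
})
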