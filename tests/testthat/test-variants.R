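test_that("qualifying-SNV filter applies a strict depth bound and an inclusive VAF floor", {
  v <- mk_variants(
    sample_id = rep("s1", 6), gene = rep("PTEN", 6),
    depth = c(150L, 151L, 500L, 500L, 500L, 149L),
    vaf = c(0.10, 0.03, 0.029, 0.03, 0.50, 0.50),
    variant_type = c("SNV", "SNV", "SNV", "SNV", "deletion", "SNV")
  )
  kept <- filter_qualifying_snvs(v)
  # depth 150 rejected (strict), vaf 0.03 at 151 reads kept (inclusive),
  # sub-floor vaf rejected, indel rejected under snv_only
  expect_equal(kept$depth, c(151L, 500L))
  expect_equal(kept$vaf, c(0.03, 0.03))

  with_indels <- filter_qualifying_snvs(v, filter_policy(snv_only = FALSE))
  expect_true(any(with_indels$variant_type == "deletion"))

  empty <- v[0, ]
  expect_equal(nrow(filter_qualifying_snvs(empty)), 0)
})

test_that("filtering is idempotent and distributes over any partition of the input", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    v <- mk_variants(
      sample_id = sample(c("a", "b"), n, TRUE),
      gene = sample(c("PTEN", "TP53"), n, TRUE),
      depth = sample(c(100L, 150L, 151L, 900L), n, TRUE),
      vaf = sample(c(0.01, 0.03, 0.4), n, TRUE),
      variant_type = sample(c("SNV", "insertion"), n, TRUE)
    )
    once <- filter_qualifying_snvs(v)
    expect_identical(filter_qualifying_snvs(once), once)
    cut <- sample(0:n, 1)
    parts <- dplyr::bind_rows(
      filter_qualifying_snvs(v[seq_len(cut), ]),
      filter_qualifying_snvs(v[setdiff(seq_len(n), seq_len(cut)), ])
    )
    expect_identical(parts, once)
  }
})

test_that("variant validation names the offending field and normalises classes", {
  base <- mk_variants("s1", "PTEN")
  expect_error(validate_variants(dplyr::mutate(base, depth = -1L)), "depth")
  expect_error(validate_variants(dplyr::mutate(base, vaf = 1.2)), "vaf")
  expect_error(validate_variants(dplyr::mutate(base, variant_type = "MNV")),
               "variant_type")
  expect_error(
    validate_variants(dplyr::mutate(base, ref = "A", alt = "AT")),
    "ref/alt"
  )
  expect_error(validate_variants(dplyr::mutate(base, ref = "A", alt = "G,T")),
               "multi-allelic")
  expect_error(validate_variants(base[, c("sample_id", "gene")]), "missing")
  expect_warning(
    out <- validate_variants(dplyr::mutate(base, variant_class = "stopgain")),
    "other"
  )
  expect_equal(out$variant_class, "other")
})

test_that("exon fractions match direct tallies and degrade safely at zero counts", {
  ctnnb1 <- mk_variants(sprintf("s%02d", 1:39), "CTNNB1",
                        exon = c(rep(3L, 31), rep(5L, 5), rep(NA, 3)))
  res <- exon_fraction(ctnnb1, "CTNNB1", 3)
  expect_equal(res$n_in_exon, 31)
  expect_equal(res$n_total, 39)
  expect_equal(res$fraction, 31 / 39)
  expect_equal(round(100 * res$fraction, 1), 79.5)

  arid1a <- mk_variants(sprintf("s%02d", 1:49), "ARID1A",
                        exon = c(rep(20L, 21), rep(1L, 28)))
  expect_equal(round(100 * exon_fraction(arid1a, "ARID1A", 20)$fraction, 1),
               42.9)

  expect_true(is.na(exon_fraction(ctnnb1, "ABSENT", 3)$fraction))
})

test_that("recurrent-variant ranking orders by count with lexicographic ties", {
  kras <- mk_variants(
    sprintf("s%02d", 1:18), "KRAS",
    protein_change = c(rep("p.G12V", 7), rep("p.G12D", 5), rep("p.Q61H", 2),
                       "p.A146T", "p.G13D", "p.K117N", "p.L19F")
  )
  r <- recurrent_variants(kras, "KRAS")
  expect_equal(r$protein_change[1:3], c("p.G12V", "p.G12D", "p.Q61H"))
  expect_equal(r$share[1:3], c(7, 5, 2) / 18)
  expect_equal(round(100 * r$share[1:3], 1), c(38.9, 27.8, 11.1))

  single <- recurrent_variants(mk_variants("s1", "KRAS",
                                           protein_change = "p.G12V"), "KRAS")
  expect_equal(single$share, 1)

  tie <- recurrent_variants(
    mk_variants(c("a", "b"), "G", protein_change = c("p.Z9Z", "p.A1A")), "G"
  )
  expect_equal(tie$protein_change, c("p.A1A", "p.Z9Z"))
})

test_that("variant-class breakdown shares are exact and sum to one", {
  ctcf <- mk_variants(
    sprintf("s%02d", 1:15), "CTCF",
    variant_class = c(rep("frameshift", 5), rep("nonsense", 7),
                      rep("other", 3))
  )
  b <- variant_class_breakdown(ctcf, "CTCF")
  shares <- stats::setNames(b$share, b$variant_class)
  expect_equal(unname(shares["frameshift"]), 5 / 15)
  expect_equal(unname(shares["nonsense"]), 7 / 15)
  expect_equal(round(100 * shares[c("frameshift", "nonsense")], 1),
               c(frameshift = 33.3, nonsense = 46.7))
  expect_equal(sum(b$share), 1, tolerance = 1e-12)

  all_mis <- variant_class_breakdown(mk_variants(c("a", "b"), "G"), "G")
  expect_equal(all_mis$share, 1)
  expect_equal(nrow(variant_class_breakdown(ctcf, "ABSENT")), 0)
})
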