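test_that("region LRR is the log2 depth ratio with degenerate inputs marked not-evaluable", {
  reg <- mk_regions(4, tumor = c(200, 100, 0, 100),
                    normal = c(100, 100, 100, 0))
  out <- region_lrr(reg)
  expect_equal(out$lrr[1], 1)
  expect_equal(out$lrr[2], 0)
  expect_true(is.na(out$lrr[3]))  # zero tumor depth
  expect_true(is.na(out$lrr[4]))  # zero normal depth
  expect_equal(out$evaluable, c(TRUE, TRUE, FALSE, FALSE))

  low_normal <- region_lrr(mk_regions(1, tumor = 100, normal = 19))
  expect_true(is.na(low_normal$lrr))
  expect_false(any(is.infinite(out$lrr), na.rm = TRUE))
})

test_that("region classification uses strict thresholds on both sides", {
  th <- cnv_thresholds()
  expect_equal(classify_region(c(0.40, 0.35, -0.5, -0.60, 0, NA), th),
               c("amp", "neutral", "neutral", "del", "neutral", NA))
  expect_error(cnv_thresholds(amp_lrr = -0.1), "amp_lrr")
  expect_error(cnv_thresholds(majority = 1), "majority")
})

test_that("gene calls follow the strict >70% majority rule over evaluable regions", {
  # 8 of 10 regions amplified -> call; 7 of 10 -> exactly at threshold, none
  amp8 <- mk_regions(10, tumor = c(rep(400, 8), 200, 200), normal = 200)
  call8 <- call_gene_cnv(amp8)
  expect_equal(call8$call, "amplification")
  expect_equal(call8$supporting_fraction, 0.8)

  amp7 <- mk_regions(10, tumor = c(rep(400, 7), rep(200, 3)), normal = 200)
  expect_equal(call_gene_cnv(amp7)$call, "none")

  del10 <- mk_regions(10, tumor = 100, normal = 300)
  expect_equal(call_gene_cnv(del10)$call, "deletion")

  # evaluability: 3 uncovered regions drop out of the denominator
  mixed <- mk_regions(10, tumor = c(rep(400, 8), 200, 200),
                      normal = c(rep(200, 7), 5, 5, 5))
  callm <- call_gene_cnv(mixed)
  expect_equal(callm$n_evaluable, 7)
  expect_equal(callm$call, "amplification")  # 7/7 > 0.7

  none_eval <- call_gene_cnv(mk_regions(3, tumor = 100, normal = 5))
  expect_true(is.na(none_eval$call))
  expect_equal(none_eval$reason, "no evaluable regions")
})

test_that("a null profile yields zero LRR everywhere and no calls", {
  set.seed(41)
  depths <- sample(50:2000, 200, TRUE)
  reg <- purrr::map_dfr(1:5, function(g) {
    r <- mk_regions(40, tumor = depths[(g - 1) * 40 + 1:40],
                    normal = depths[(g - 1) * 40 + 1:40],
                    gene = paste0("G", g))
    r
  })
  out <- region_lrr(reg)
  expect_true(all(out$lrr == 0))
  calls <- call_gene_cnv(reg)
  expect_true(all(calls$call == "none"))
})

test_that("scaling tumor depth by 2^c shifts every evaluable LRR by exactly c", {
  set.seed(43)
  reg <- mk_regions(30, tumor = sample(100:3000, 30), normal = 250)
  for (c_shift in c(-1, 0.5, 2)) {
    scaled <- dplyr::mutate(reg, tumor_depth = tumor_depth * 2^c_shift)
    expect_equal(region_lrr(scaled)$lrr, region_lrr(reg)$lrr + c_shift,
                 tolerance = 1e-12)
  }
})

test_that("spiked genes are recovered in at least 95% of carrier samples", {
  cfg <- cohort_config(
    n_eec = 60, n_ein = 30,
    cnv_spikes = tibble::tibble(gene = "VEGFB", group = "EEC",
                                carrier_fraction = 0.5, log2_fold = 1),
    depth_size = 100, seed = 211
  )
  co <- generate_cohort(cfg)
  carriers <- co$truth$cnv_carriers$sample_id
  expect_gte(length(carriers), 25)
  calls <- call_gene_cnv(co$regions)
  amp <- calls$sample_id[calls$gene == "VEGFB" &
                           calls$call == "amplification"]
  expect_gte(mean(carriers %in% amp), 0.95)
  # and amplification calls stay essentially confined to carriers
  expect_lte(sum(!amp %in% carriers), 1)
})

test_that("cohort CNA summaries count affected samples and group shares correctly", {
  samples <- tibble::tibble(
    sample_id = c(sprintf("EEC_%03d", 1:79), sprintf("EIN_%03d", 1:36)),
    group = rep(c("EEC", "EIN"), c(79, 36))
  )
  mk_call <- function(sample_id, gene, call) {
    tibble::tibble(sample_id = sample_id, gene = gene, call = call,
                   n_regions = 10L, n_evaluable = 10L,
                   n_amp = ifelse(call == "amplification", 10L, 0L),
                   n_del = ifelse(call == "deletion", 10L, 0L),
                   supporting_fraction = 1, reason = NA_character_)
  }
  # VEGFB amplified in 19 EEC + 1 EIN; deletions spread so 48 samples carry >= 1 CNA
  calls <- dplyr::bind_rows(
    mk_call(sprintf("EEC_%03d", 1:19), "VEGFB", "amplification"),
    mk_call("EIN_001", "VEGFB", "amplification"),
    mk_call(sprintf("EEC_%03d", 20:40), "PTEN", "deletion"),
    mk_call(sprintf("EIN_%03d", 2:8), "CTCF", "deletion")
  )
  cs <- cna_summary(calls, samples)
  expect_equal(cs$overall$n_with_cna, 48)
  expect_equal(round(100 * cs$overall$affected_fraction, 1), 41.7)
  vegfb <- cs$per_gene[cs$per_gene$gene == "VEGFB", ]
  expect_equal(vegfb$n_carriers, 20)
  expect_equal(vegfb$carrier_eec_share, 0.95)

  empty <- cna_summary(calls[0, ], samples)
  expect_equal(empty$overall$n_with_cna, 0)
  expect_equal(empty$per_sample$n_cna, rep(0L, 115))

  m <- cnv_matrix(calls)
  expect_equal(m$EEC_001[m$gene == "VEGFB"], "A")
  expect_equal(m$EEC_020[m$gene == "PTEN"], "D")
  expect_equal(m$EEC_020[m$gene == "VEGFB"], ".")
})
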