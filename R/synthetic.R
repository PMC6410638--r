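#' Configuration for the synthetic-cohort generator
#'
#' Describes the statistical structure of a simulated two-group (EEC
#' carcinoma vs EIN precursor-lesion) targeted-panel cohort: group sizes,
#' per-gene mutation prevalences, a hypermutator subpopulation attributable to
#' DNA-damage-repair defects, negative-binomial sequencing-depth noise, a Beta
#' model for alt-allele fractions, optional copy-number spike-ins, and
#' germline pathogenic-carrier rates. Defaults reproduce the scale of a
#' 115-sample endometrial cohort sequenced to ~1690x tumor / ~2389x normal
#' mean depth, with ~4% hypermutators whose mutation counts sit far above the
#' background (means 180 vs 8 per sample).
#'
#' @param n_eec,n_ein Group sizes (default 79 and 36).
#' @param prevalence Tibble `gene`, `prob_eec`, `prob_ein`: per-gene
#'   probability that a sample of each group is mutated. Default derives from
#'   [example_gene_counts()].
#' @param hypermutator_fraction Probability a sample is a hypermutator
#'   (default 5/115).
#' @param background_mean,background_size Negative-binomial mean/size of the
#'   per-sample background mutation count outside the prevalence genes
#'   (defaults 8 and 1.2, giving a 0-50ish range with median ~6).
#' @param hyper_mean,hyper_size Negative-binomial mean/size for hypermutator
#'   mutation counts (defaults 180 and 25, a ~140-280 range).
#' @param mean_tumor_depth,mean_normal_depth,depth_size Negative-binomial
#'   depth model (defaults 1690, 2389, size 50). Variant depths use the mean
#'   of their sample of origin; region-depth pairs are drawn depth-balanced
#'   at the tumor mean for both members, since the pure paired log2 ratio
#'   presumes library-size-matched tumor/normal coverage.
#' @param vaf_mean,vaf_concentration Beta model for alt-allele fractions:
#'   shape1 = mean x concentration, shape2 = (1 - mean) x concentration
#'   (defaults 0.25 and 20).
#' @param cnv_spikes Optional tibble `gene`, `group`, `carrier_fraction`,
#'   `log2_fold`: in each listed group, a `carrier_fraction` share of samples
#'   gets all tumor-depth regions of `gene` multiplied by `2^log2_fold`.
#' @param cnv_genes Genes for which region-depth profiles are emitted
#'   (default: spiked genes, VEGFB, and the first eight panel genes).
#' @param region_width Width in bp of the depth regions tiling each gene's
#'   target (default 100).
#' @param germline_rate_eec,germline_rate_ein Per-sample probability of one
#'   pathogenic/likely-pathogenic germline finding (defaults 10/79 and 0).
#' @param germline_benign_rate Per-sample probability of one VUS/benign
#'   germline record, any group (default 0.1).
#' @param panel Panel tibble (default [default_panel()]).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config including this seed.
#' @return A list with class `cohort_config`.
#' @export
cohort_config <- function(n_eec = 79, n_ein = 36,
                          prevalence = NULL,
                          hypermutator_fraction = 5 / 115,
                          background_mean = 8, background_size = 1.2,
                          hyper_mean = 180, hyper_size = 25,
                          mean_tumor_depth = 1690,
                          mean_normal_depth = 2389,
                          depth_size = 50,
                          vaf_mean = 0.25, vaf_concentration = 20,
                          cnv_spikes = NULL,
                          cnv_genes = NULL,
                          region_width = 100,
                          germline_rate_eec = 10 / 79,
                          germline_rate_ein = 0,
                          germline_benign_rate = 0.1,
                          panel = default_panel(),
                          seed = 1L) {
  if (is.null(prevalence)) {
    cnt <- example_gene_counts()
    prevalence <- tibble::tibble(
      gene = cnt$gene,
      prob_eec = cnt$eec / 79,
      prob_ein = cnt$ein / 36
    )
  }
  prevalence <- tibble::as_tibble(prevalence)
  stopifnot(all(c("gene", "prob_eec", "prob_ein") %in% names(prevalence)))
  probs <- c(prevalence$prob_eec, prevalence$prob_ein,
             hypermutator_fraction, germline_rate_eec, germline_rate_ein,
             germline_benign_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must be in [0, 1]", call. = FALSE)
  }
  if (n_eec < 0 || n_ein < 0 ||
      n_eec != round(n_eec) || n_ein != round(n_ein)) {
    stop("group sizes must be non-negative integers", call. = FALSE)
  }
  if (mean_tumor_depth <= 0 || mean_normal_depth <= 0) {
    stop("mean depths must be positive", call. = FALSE)
  }
  if (!is.null(cnv_spikes)) {
    cnv_spikes <- tibble::as_tibble(cnv_spikes)
    stopifnot(all(c("gene", "group", "carrier_fraction", "log2_fold") %in%
                    names(cnv_spikes)))
    if (any(cnv_spikes$carrier_fraction < 0 |
              cnv_spikes$carrier_fraction > 1)) {
      stop("`carrier_fraction` must be in [0, 1]", call. = FALSE)
    }
    if (!all(cnv_spikes$gene %in% panel$gene)) {
      stop("cnv_spikes reference gene(s) not on the panel", call. = FALSE)
    }
  }
  if (is.null(cnv_genes)) {
    cnv_genes <- unique(c(
      if (!is.null(cnv_spikes)) cnv_spikes$gene, "VEGFB",
      utils::head(panel$gene, 8)
    ))
  }
  cnv_genes <- intersect(cnv_genes, panel$gene)
  structure(
    list(
      n_eec = as.integer(n_eec), n_ein = as.integer(n_ein),
      prevalence = prevalence,
      hypermutator_fraction = hypermutator_fraction,
      background_mean = background_mean, background_size = background_size,
      hyper_mean = hyper_mean, hyper_size = hyper_size,
      mean_tumor_depth = mean_tumor_depth,
      mean_normal_depth = mean_normal_depth,
      depth_size = depth_size,
      vaf_mean = vaf_mean, vaf_concentration = vaf_concentration,
      cnv_spikes = cnv_spikes, cnv_genes = cnv_genes,
      region_width = region_width,
      germline_rate_eec = germline_rate_eec,
      germline_rate_ein = germline_rate_ein,
      germline_benign_rate = germline_benign_rate,
      panel = panel, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# draw variant records for given (sample_id, gene) pairs
simulate_variant_rows <- function(sample_id, gene, cfg, force_class = NULL) {
  n <- length(sample_id)
  if (n == 0) {
    return(validate_variants(tibble::tibble(
      sample_id = character(0), gene = character(0),
      variant_type = character(0), depth = integer(0), vaf = numeric(0)
    )))
  }
  cls_probs <- c(missense = 0.60, nonsense = 0.08, frameshift = 0.14,
                 nonframeshift_indel = 0.04, splice = 0.04,
                 synonymous = 0.08, other = 0.02)
  cls <- if (is.null(force_class)) {
    sample(names(cls_probs), n, replace = TRUE, prob = cls_probs)
  } else {
    rep_len(force_class, n)
  }
  type <- ifelse(cls %in% c("frameshift", "nonframeshift_indel"),
                 sample(c("insertion", "deletion"), n, replace = TRUE),
                 "SNV")
  idx <- match(gene, cfg$panel$gene)
  offset <- floor(stats::runif(n) * cfg$panel$target_bp[idx])
  pos <- cfg$panel$start[idx] + as.integer(offset) + 1L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- bases[(match(ref, bases) + sample.int(3, n, replace = TRUE) - 1L) %%
                 4L + 1L]
  alt <- ifelse(type == "insertion", paste0(ref, "A"), alt)
  ref <- ifelse(type == "deletion", paste0(ref, "A"),
                ifelse(type == "insertion", substr(ref, 1, 1), ref))
  alt <- ifelse(type == "deletion", substr(ref, 1, 1), alt)
  a <- cfg$vaf_mean * cfg$vaf_concentration
  b <- (1 - cfg$vaf_mean) * cfg$vaf_concentration
  tibble::tibble(
    sample_id = sample_id, gene = gene,
    chrom = cfg$panel$chrom[idx], pos = pos, ref = ref, alt = alt,
    variant_type = type, variant_class = cls,
    exon = sample.int(20L, n, replace = TRUE),
    protein_change = sprintf("p.%s%d%s",
                             sample(LETTERS[1:20], n, replace = TRUE),
                             sample.int(900L, n, replace = TRUE),
                             sample(LETTERS[1:20], n, replace = TRUE)),
    depth = as.integer(stats::rnbinom(n, mu = cfg$mean_tumor_depth,
                                      size = cfg$depth_size)),
    vaf = stats::rbeta(n, a, b),
    origin = "somatic", zygosity = NA_character_
  )
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort — sample sheet, somatic variants, germline variants,
#' region-depth profiles with CNV spike-ins — from a [cohort_config()]. The
#' result is a deterministic function of the config (including its seed): the
#' same config yields byte-identical tables. Truth labels (hypermutators, CNV
#' carriers, configured prevalences, germline carriers) are attached for
#' validating downstream callers.
#'
#' Structure: each prevalence gene is mutated per sample by an independent
#' Bernoulli draw at its group's probability, so observed prevalences converge
#' to the configured ones. Background mutations (and hypermutator excess) are
#' placed in panel genes *outside* the prevalence map so they cannot distort
#' those frequencies. Every hypermutator carries at least one variant in a
#' DNA-damage-repair gene, mirroring the repair-defect aetiology of
#' hypermutation.
#'
#' @param config A [cohort_config()].
#' @return A [new_cohort()] bundle with `truth` labels.
#' @examples
#' cfg <- cohort_config(n_eec = 20, n_ein = 10, seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$n_eec + cfg$n_ein
  sample_id <- c(sprintf("EEC_%03d", seq_len(cfg$n_eec)),
                 sprintf("EIN_%03d", seq_len(cfg$n_ein)))
  group <- rep(c("EEC", "EIN"), c(cfg$n_eec, cfg$n_ein))
  grade <- ifelse(group == "EEC",
                  sample(c("G1", "G2", "G3"), n, replace = TRUE,
                         prob = c(40, 24, 15)),
                  "EIN")
  stage <- ifelse(group == "EEC",
                  sample(c("IA", "IB", "II", "III", "IV"), n, replace = TRUE,
                         prob = c(61, 4, 3, 10, 1)),
                  NA_character_)
  samples <- tibble::tibble(sample_id = sample_id, group = group,
                            grade = grade, stage = stage)

  hyper <- stats::runif(n) < cfg$hypermutator_fraction

  # focal genes: Bernoulli mutation status at the configured prevalence
  prev <- cfg$prevalence
  focal <- purrr::pmap_dfr(prev, function(gene, prob_eec, prob_ein, ...) {
    p <- ifelse(group == "EEC", prob_eec, prob_ein)
    hit <- stats::runif(n) < p
    tibble::tibble(sample_id = sample_id[hit], gene = gene)
  })

  # background mutations live outside the prevalence map
  filler <- setdiff(cfg$panel$gene, prev$gene)
  n_bg <- ifelse(hyper,
                 stats::rnbinom(n, mu = cfg$hyper_mean, size = cfg$hyper_size),
                 stats::rnbinom(n, mu = cfg$background_mean,
                                size = cfg$background_size))
  bg <- tibble::tibble(
    sample_id = rep(sample_id, n_bg),
    gene = sample(filler, sum(n_bg), replace = TRUE)
  )

  # every hypermutator gets a DDR-gene variant (repair-defect aetiology)
  ddr_pool <- setdiff(intersect(ddr_gene_set(), cfg$panel$gene), prev$gene)
  if (length(ddr_pool) == 0) ddr_pool <- intersect(ddr_gene_set(),
                                                   cfg$panel$gene)
  forced <- tibble::tibble(
    sample_id = sample_id[hyper],
    gene = sample(ddr_pool, sum(hyper), replace = TRUE)
  )

  pairs <- dplyr::bind_rows(focal, bg, forced)
  somatic <- simulate_variant_rows(pairs$sample_id, pairs$gene, cfg)
  somatic <- dplyr::arrange(somatic, .data$sample_id, .data$gene, .data$pos)

  # region-depth profiles for the CNV genes, with spike-ins
  reg_panel <- cfg$panel[cfg$panel$gene %in% cfg$cnv_genes, , drop = FALSE]
  regions <- NULL
  cnv_truth <- tibble::tibble(gene = character(0), sample_id = character(0),
                              log2_fold = numeric(0))
  if (nrow(reg_panel) > 0 && n > 0) {
    per_gene <- tibble::tibble(
      gene = reg_panel$gene, chrom = reg_panel$chrom,
      gstart = reg_panel$start,
      n_reg = pmax(1L, reg_panel$target_bp %/% as.integer(cfg$region_width))
    )
    grid <- tidyr::uncount(per_gene, weights = .data$n_reg,
                           .id = "region_index")
    grid$start <- grid$gstart + (grid$region_index - 1L) *
      as.integer(cfg$region_width)
    grid$end <- grid$start + as.integer(cfg$region_width)
    regions <- tidyr::crossing(sample_id = sample_id, grid)
    m <- nrow(regions)
    # region pairs are depth-balanced (common expected coverage): the pure
    # paired log2 ratio assumes library-size-matched tumor/normal, and the
    # global mean-depth asymmetry is removed upstream of ratio calling
    regions$tumor_depth <- stats::rnbinom(m, mu = cfg$mean_tumor_depth,
                                          size = cfg$depth_size)
    regions$normal_depth <- stats::rnbinom(m, mu = cfg$mean_tumor_depth,
                                           size = cfg$depth_size)
    if (!is.null(cfg$cnv_spikes)) {
      for (i in seq_len(nrow(cfg$cnv_spikes))) {
        sp <- cfg$cnv_spikes[i, ]
        pool <- sample_id[group == sp$group]
        k <- round(sp$carrier_fraction * length(pool))
        carriers <- sample(pool, k)
        sel <- regions$gene == sp$gene & regions$sample_id %in% carriers
        regions$tumor_depth[sel] <-
          round(regions$tumor_depth[sel] * 2^sp$log2_fold)
        cnv_truth <- dplyr::bind_rows(
          cnv_truth,
          tibble::tibble(gene = sp$gene, sample_id = carriers,
                         log2_fold = sp$log2_fold)
        )
      }
    }
    regions <- tibble::as_tibble(
      regions[, c("sample_id", "gene", "region_index", "chrom",
                  "start", "end", "tumor_depth", "normal_depth")]
    )
    regions <- dplyr::arrange(regions, .data$sample_id, .data$gene,
                              .data$region_index)
  }

  # germline: one pathogenic/likely-pathogenic finding per carrier,
  # plus VUS/benign noise records
  g_rate <- ifelse(group == "EEC", cfg$germline_rate_eec,
                   cfg$germline_rate_ein)
  g_carrier <- stats::runif(n) < g_rate
  g_genes <- c("MLH1", "MSH2", "MUTYH", "GALNT12", "POLE", "MPL", "ATM",
               "ERCC4")
  g_genes <- intersect(g_genes, cfg$panel$gene)
  n_car <- sum(g_carrier)
  noise <- stats::runif(n) < cfg$germline_benign_rate
  n_noise <- sum(noise)
  germline <- tibble::tibble(
    sample_id = c(sample_id[g_carrier], sample_id[noise]),
    gene = c(sample(g_genes, n_car, replace = TRUE),
             sample(cfg$panel$gene, n_noise, replace = TRUE)),
    pathogenicity = c(
      sample(c("pathogenic", "likely_pathogenic"), n_car, replace = TRUE,
             prob = c(0.4, 0.6)),
      sample(c("vus", "benign"), n_noise, replace = TRUE)
    ),
    zygosity = sample(c("het", "hom"), n_car + n_noise, replace = TRUE,
                      prob = c(0.7, 0.3))
  )
  germ_rows <- simulate_variant_rows(germline$sample_id, germline$gene, cfg,
                                     force_class = "missense")
  germ_rows$origin <- "germline"
  germ_rows$depth <- as.integer(stats::rnbinom(nrow(germ_rows),
                                               mu = cfg$mean_normal_depth,
                                               size = cfg$depth_size))
  germ_rows$zygosity <- germline$zygosity
  germ_rows$vaf <- ifelse(germline$zygosity == "hom",
                          pmin(1, 0.9 + stats::runif(nrow(germline)) * 0.1),
                          0.4 + stats::runif(nrow(germline)) * 0.2)
  germ_rows$pathogenicity <- germline$pathogenicity
  germ_rows <- dplyr::arrange(germ_rows, .data$sample_id, .data$gene)

  truth <- list(
    hypermutators = sample_id[hyper],
    cnv_carriers = cnv_truth,
    prevalence = prev,
    germline_carriers = sample_id[g_carrier]
  )
  new_cohort(samples, somatic, germline = germ_rows, regions = regions,
             panel = cfg$panel, truth = truth)
}

#' Deterministic cohort from printed count tables
#'
#' Reconstructs a cohort exactly matching per-gene mutated-sample counts —
#' the inverse of [prevalence_table()]. For each gene, the mutated samples of
#' a group are a contiguous block of the group's samples starting at the
#' gene's offset (wrapping around), so that marginal counts are reproduced
#' bit-exactly and pairwise overlaps (co-mutation counts) can be encoded via
#' the offsets. No randomness is involved.
#'
#' @param gene_counts Tibble `gene`, `eec`, `ein` (mutated samples per group),
#'   optional `offset_eec`, `offset_ein` (default 0).
#' @param n_eec,n_ein Group sizes (defaults 79 and 36).
#' @param panel Optional panel for variant coordinates.
#' @return A [new_cohort()] bundle; every placed variant is a qualifying SNV
#'   (depth 500, VAF 0.25) so QC filters do not disturb the counts.
#' @examples
#' fx <- fixture_from_counts(example_gene_counts())
#' prevalence_table(fx, min_mutated = 9)
#' @export
fixture_from_counts <- function(gene_counts, n_eec = 79, n_ein = 36,
                                panel = default_panel()) {
  gene_counts <- tibble::as_tibble(gene_counts)
  stopifnot(all(c("gene", "eec", "ein") %in% names(gene_counts)))
  if (!"offset_eec" %in% names(gene_counts)) gene_counts$offset_eec <- 0L
  if (!"offset_ein" %in% names(gene_counts)) gene_counts$offset_ein <- 0L
  if (any(gene_counts$eec < 0 | gene_counts$ein < 0)) {
    stop("mutated counts must be non-negative", call. = FALSE)
  }
  if (any(gene_counts$eec > n_eec) || any(gene_counts$ein > n_ein)) {
    stop("mutated count exceeds group size", call. = FALSE)
  }
  ids <- list(EEC = sprintf("EEC_%03d", seq_len(n_eec)),
              EIN = sprintf("EIN_%03d", seq_len(n_ein)))
  samples <- tibble::tibble(
    sample_id = c(ids$EEC, ids$EIN),
    group = rep(c("EEC", "EIN"), c(n_eec, n_ein))
  )
  place <- function(gene, k, offset, grp) {
    pool <- ids[[grp]]
    if (k == 0 || length(pool) == 0) return(NULL)
    idx <- ((offset + seq_len(k) - 1L) %% length(pool)) + 1L
    tibble::tibble(sample_id = pool[idx], gene = gene)
  }
  pairs <- purrr::pmap_dfr(gene_counts,
    function(gene, eec, ein, offset_eec, offset_ein, ...) {
      dplyr::bind_rows(place(gene, eec, offset_eec, "EEC"),
                       place(gene, ein, offset_ein, "EIN"))
    })
  if (!"sample_id" %in% names(pairs)) {
    pairs <- tibble::tibble(sample_id = character(0), gene = character(0))
  }
  pidx <- match(pairs$gene, panel$gene)
  somatic <- tibble::tibble(
    sample_id = pairs$sample_id,
    gene = pairs$gene,
    chrom = if (nrow(pairs) > 0) panel$chrom[pidx] else character(0),
    pos = if (nrow(pairs) > 0) panel$start[pidx] + 1L else integer(0),
    ref = rep("A", nrow(pairs)), alt = rep("G", nrow(pairs)),
    variant_type = rep("SNV", nrow(pairs)),
    variant_class = rep("missense", nrow(pairs)),
    depth = rep(500L, nrow(pairs)), vaf = rep(0.25, nrow(pairs)),
    origin = rep("somatic", nrow(pairs))
  )
  new_cohort(samples, somatic,
             panel = if (all(!is.na(pidx))) panel else NULL)
}

#' Spike a copy-number event into a region-depth profile
#'
#' Multiplies the tumor depth of a fraction of a gene's regions by
#' `2^log2_fold` (per sample, lowest region indices first), leaving all other
#' regions untouched — so the expected log2 ratio of the affected regions
#' shifts by exactly `log2_fold`.
#'
#' @param regions Region-depth tibble (`sample_id`, `gene`, `region_index`,
#'   `tumor_depth`, `normal_depth`, coordinates).
#' @param gene Gene to spike; must exist in `regions`.
#' @param log2_fold Log2 fold change applied to tumor depth.
#' @param affected_fraction Fraction of each sample's regions of the gene to
#'   affect (default 1).
#' @return `regions` with modified tumor depths.
#' @export
spike_cnv <- function(regions, gene, log2_fold, affected_fraction = 1) {
  stopifnot(is.data.frame(regions))
  if (!gene %in% regions$gene) {
    stop("gene not present in region profile: ", gene, call. = FALSE)
  }
  if (affected_fraction < 0 || affected_fraction > 1) {
    stop("`affected_fraction` must be in [0, 1]", call. = FALSE)
  }
  regions <- tibble::as_tibble(regions)
  sel <- regions$gene == gene
  sub <- regions[sel, , drop = FALSE]
  pick <- sub %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::mutate(
      .rank = rank(.data$region_index, ties.method = "first"),
      .hit = .data$.rank <= floor(affected_fraction * dplyr::n() + 1e-9)
    ) %>%
    dplyr::ungroup()
  sub$tumor_depth <- ifelse(pick$.hit,
                            sub$tumor_depth * 2^log2_fold,
                            sub$tumor_depth)
  regions[sel, ] <- sub
  regions
}
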