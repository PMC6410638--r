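#' Copy-number calling thresholds
#'
#' Thresholds for the region-based log2 depth-ratio (LRR) caller. A region is
#' amplified when LRR is strictly above `amp_lrr` and deleted when strictly
#' below `del_lrr`; a gene receives a call only when one type accounts for
#' strictly more than `majority` of its evaluable regions. Regions whose
#' matched-normal depth falls below `min_normal_depth` (or whose tumor depth
#' is zero) are not evaluable and are excluded from both numerator and
#' denominator, which prevents ratio blow-ups at poorly covered targets.
#'
#' The deletion bound defaults to -0.5: the negative mirror of a published
#' formulation whose printed deletion cutoff (+0.5) would classify every
#' neutral region as deleted. Both bounds are configurable.
#'
#' @param amp_lrr Amplification LRR bound, strict (default 0.35).
#' @param del_lrr Deletion LRR bound, strict (default -0.5).
#' @param majority Fraction of evaluable regions one type must exceed for a
#'   gene-level call (default 0.70).
#' @param min_normal_depth Minimum evaluable normal depth (default 20).
#' @return A list with class `cnv_thresholds`.
#' @export
cnv_thresholds <- function(amp_lrr = 0.35, del_lrr = -0.5,
                           majority = 0.70, min_normal_depth = 20) {
  if (!(amp_lrr > 0 && del_lrr < 0)) {
    stop("need `amp_lrr` > 0 > `del_lrr`", call. = FALSE)
  }
  if (!(majority > 0 && majority < 1)) {
    stop("`majority` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(amp_lrr = amp_lrr, del_lrr = del_lrr, majority = majority,
         min_normal_depth = min_normal_depth),
    class = "cnv_thresholds"
  )
}

#' Per-region log2 tumor/normal depth ratio
#'
#' Computes `lrr = log2(tumor_depth / normal_depth)` for each region.
#' Regions with normal depth below the evaluability floor or zero tumor depth
#' are marked not evaluable (`lrr = NA`) rather than producing infinities,
#' and are excluded from gene-level denominators downstream.
#'
#' @param regions Region-depth tibble with `tumor_depth` and `normal_depth`.
#' @param thresholds A [cnv_thresholds()].
#' @return `regions` with `lrr` and `evaluable` columns appended.
#' @export
region_lrr <- function(regions, thresholds = cnv_thresholds()) {
  stopifnot(is.data.frame(regions), inherits(thresholds, "cnv_thresholds"))
  regions <- tibble::as_tibble(regions)
  evaluable <- regions$normal_depth >= thresholds$min_normal_depth &
    regions$tumor_depth > 0
  regions$lrr <- ifelse(evaluable,
                        log2(regions$tumor_depth / regions$normal_depth),
                        NA_real_)
  regions$evaluable <- evaluable
  regions
}

#' Classify regions by LRR
#'
#' Strict thresholding: `"amp"` when `lrr > amp_lrr`, `"del"` when
#' `lrr < del_lrr`, `"neutral"` otherwise; `NA` stays `NA`.
#'
#' @param lrr Numeric vector of log2 depth ratios.
#' @param thresholds A [cnv_thresholds()].
#' @return Character vector in `{"amp", "del", "neutral", NA}`.
#' @export
classify_region <- function(lrr, thresholds = cnv_thresholds()) {
  stopifnot(inherits(thresholds, "cnv_thresholds"))
  dplyr::case_when(
    is.na(lrr) ~ NA_character_,
    lrr > thresholds$amp_lrr ~ "amp",
    lrr < thresholds$del_lrr ~ "del",
    TRUE ~ "neutral"
  )
}

#' Gene-level copy-number calls from region depths
#'
#' The region-majority caller: per sample and gene, each evaluable region is
#' classified amplified/deleted/neutral by its LRR, and the gene is called
#' `amplification` (or `deletion`) when that type accounts for strictly more
#' than the majority fraction of evaluable regions; otherwise `none`. Genes
#' with zero evaluable regions get an `NA` call with a reason.
#'
#' @param regions Region-depth tibble covering one or many samples/genes.
#' @param thresholds A [cnv_thresholds()].
#' @return A tibble, one row per sample x gene: `sample_id`, `gene`, `call`,
#'   `n_regions`, `n_evaluable`, `n_amp`, `n_del`, `supporting_fraction`
#'   (max of the amp/del fractions among evaluable regions), `reason`.
#' @examples
#' reg <- tibble::tibble(
#'   sample_id = "s1", gene = "VEGFB", region_index = 1:10,
#'   chrom = "chr11", start = 0:9 * 100L, end = 1:10 * 100L,
#'   tumor_depth = c(rep(400, 8), 200, 200), normal_depth = 200
#' )
#' call_gene_cnv(reg) # 8/10 regions above the bound: amplification
#' @export
call_gene_cnv <- function(regions, thresholds = cnv_thresholds()) {
  stopifnot(is.data.frame(regions))
  ann <- region_lrr(regions, thresholds)
  ann$state <- classify_region(ann$lrr, thresholds)
  out <- ann %>%
    dplyr::group_by(.data$sample_id, .data$gene) %>%
    dplyr::summarise(
      n_regions = dplyr::n(),
      n_evaluable = sum(.data$evaluable),
      n_amp = sum(.data$state == "amp", na.rm = TRUE),
      n_del = sum(.data$state == "del", na.rm = TRUE),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      supporting_fraction = ifelse(
        .data$n_evaluable > 0,
        pmax(.data$n_amp, .data$n_del) / .data$n_evaluable,
        NA_real_
      ),
      call = dplyr::case_when(
        .data$n_evaluable == 0 ~ NA_character_,
        .data$n_amp / .data$n_evaluable > thresholds$majority ~
          "amplification",
        .data$n_del / .data$n_evaluable > thresholds$majority ~ "deletion",
        TRUE ~ "none"
      ),
      reason = ifelse(.data$n_evaluable == 0, "no evaluable regions",
                      NA_character_)
    )
  dplyr::relocate(out, "sample_id", "gene", "call")
}

#' Cohort copy-number alteration summary
#'
#' Summarises gene-level calls across a cohort: per-sample CNA counts (calls
#' other than `none`), the fraction of samples carrying at least one CNA, and
#' per-gene alteration frequencies with the group breakdown of carriers.
#'
#' @param calls Output of [call_gene_cnv()].
#' @param samples Sample sheet tibble (`sample_id`, `group`); determines the
#'   denominators, including samples without any call row.
#' @return A list of class `cna_summary`: `per_sample` (sample_id, group,
#'   n_cna), `overall` (one row: n_samples, n_with_cna, affected_fraction,
#'   median_cna, min_cna, max_cna), `per_gene` (gene, call type, carriers per
#'   group and group shares).
#' @export
cna_summary <- function(calls, samples) {
  stopifnot(is.data.frame(calls), is.data.frame(samples))
  altered <- calls %>%
    dplyr::filter(!is.na(.data$call), .data$call != "none")
  per_sample <- samples %>%
    dplyr::select("sample_id", "group") %>%
    dplyr::left_join(
      dplyr::count(altered, .data$sample_id, name = "n_cna"),
      by = "sample_id"
    ) %>%
    dplyr::mutate(n_cna = dplyr::coalesce(.data$n_cna, 0L))
  overall <- tibble::tibble(
    n_samples = nrow(per_sample),
    n_with_cna = sum(per_sample$n_cna > 0),
    affected_fraction = ifelse(nrow(per_sample) > 0,
                               sum(per_sample$n_cna > 0) / nrow(per_sample),
                               NA_real_),
    median_cna = ifelse(nrow(per_sample) > 0,
                        stats::median(per_sample$n_cna), NA_real_),
    min_cna = ifelse(nrow(per_sample) > 0, min(per_sample$n_cna), NA_real_),
    max_cna = ifelse(nrow(per_sample) > 0, max(per_sample$n_cna), NA_real_)
  )
  grp_n <- c(EEC = sum(samples$group == "EEC"),
             EIN = sum(samples$group == "EIN"))
  per_gene <- altered %>%
    dplyr::left_join(dplyr::select(samples, "sample_id", "group"),
                     by = "sample_id") %>%
    dplyr::group_by(.data$gene, .data$call) %>%
    dplyr::summarise(
      n_carriers = dplyr::n(),
      n_eec = sum(.data$group == "EEC"),
      n_ein = sum(.data$group == "EIN"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      carrier_eec_share = ifelse(.data$n_carriers > 0,
                                 .data$n_eec / .data$n_carriers, NA_real_),
      freq_overall = .data$n_carriers / nrow(samples)
    ) %>%
    dplyr::arrange(dplyr::desc(.data$n_carriers), .data$gene)
  structure(
    list(per_sample = per_sample, overall = overall, per_gene = per_gene,
         group_sizes = grp_n),
    class = "cna_summary"
  )
}

#' @export
print.cna_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "CNA summary: %d/%d samples affected (%.1f%%), per-sample median %g (range %g-%g)\n",
    o$n_with_cna, o$n_samples, 100 * o$affected_fraction,
    o$median_cna, o$min_cna, o$max_cna
  ))
  if (nrow(x$per_gene) > 0) {
    top <- utils::head(x$per_gene, 5)
    cat("Most frequent alterations:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s %s: %d carriers (%d EEC / %d EIN)\n",
                  top$gene[i], top$call[i], top$n_carriers[i],
                  top$n_eec[i], top$n_ein[i]))
    }
  }
  invisible(x)
}

#' Gene-by-sample CNA matrix
#'
#' Wide matrix of gene-level calls coded `A` (amplification), `D` (deletion)
#' and `.` (none or no call), for export or heatmap plotting.
#'
#' @param calls Output of [call_gene_cnv()].
#' @return A tibble with a `gene` column and one column per sample.
#' @export
cnv_matrix <- function(calls) {
  stopifnot(is.data.frame(calls))
  calls %>%
    dplyr::mutate(code = dplyr::case_when(
      .data$call == "amplification" ~ "A",
      .data$call == "deletion" ~ "D",
      TRUE ~ "."
    )) %>%
    dplyr::select("gene", "sample_id", "code") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "code",
                       values_fill = ".") %>%
    dplyr::arrange(.data$gene)
}
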