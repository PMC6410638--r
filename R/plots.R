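#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a TMB group comparison
#'
#' Box-and-jitter plot of per-sample TMB by group, annotated with the
#' two-sided rank-test p-value.
#'
#' @param object A `tmb_comparison` from [compare_tmb()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tmb_comparison
#' @export
autoplot.tmb_comparison <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$tmb,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = NULL, y = "TMB (mutations / Mb)",
      title = "Tumor mutational burden by group",
      subtitle = sprintf("Mann-Whitney two-sided p = %.3g%s", object$p_value,
                         if (object$exclude_ddr)
                           " (DDR-mutated samples excluded)" else "")
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot a differential mutation-frequency screen
#'
#' Per-gene -log10 p-values, coloured by significance, with the alpha
#' threshold marked.
#'
#' @param object A `diff_screen` from [differential_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diff_screen
#' @export
autoplot.diff_screen <- function(object, ...) {
  alpha <- attr(object, "alpha")
  dat <- tidy(object)
  dat$gene <- factor(dat$gene, levels = rev(dat$gene))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene,
                                    y = -log10(.data$p_adjusted),
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = expression(-log[10] ~ p),
      title = "Differential mutation frequency (EEC vs EIN)"
    ) +
    ggplot2::theme_minimal()
}

#' Oncoprint-style mutation matrix plot
#'
#' Gene-by-sample tile plot of somatic mutation status coloured by variant
#' class, genes ordered by mutation frequency and samples grouped EEC before
#' EIN. When a sample has several variants in one gene the most deleterious
#' class (by a fixed severity order) is shown.
#'
#' @param cohort A [new_cohort()] bundle.
#' @param genes Genes to show; default the `max_genes` most frequently
#'   mutated.
#' @param max_genes Cap on the number of genes shown (default 20).
#' @return A ggplot object.
#' @export
plot_oncoprint <- function(cohort, genes = NULL, max_genes = 20) {
  stopifnot(inherits(cohort, "cohort"))
  severity <- c("frameshift", "nonsense", "splice", "missense",
                "nonframeshift_indel", "synonymous", "other")
  prev <- prevalence_table(cohort)
  if (is.null(genes)) genes <- utils::head(prev$gene, max_genes)
  dat <- cohort$somatic %>%
    dplyr::filter(.data$gene %in% genes) %>%
    dplyr::mutate(
      variant_class = factor(.data$variant_class, levels = severity)
    ) %>%
    dplyr::group_by(.data$sample_id, .data$gene) %>%
    dplyr::summarise(variant_class = sort(.data$variant_class)[1],
                     .groups = "drop")
  sample_order <- cohort$samples %>%
    dplyr::arrange(.data$group, .data$sample_id) %>%
    dplyr::pull(.data$sample_id)
  dat$sample_id <- factor(dat$sample_id, levels = sample_order)
  dat$gene <- factor(dat$gene, levels = rev(intersect(prev$gene, genes)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id, y = .data$gene,
                                    fill = .data$variant_class)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_x_discrete(limits = sample_order, drop = FALSE) +
    ggplot2::labs(x = "sample", y = NULL, fill = "class",
                  title = "Somatic mutation profile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Copy-number alteration matrix plot
#'
#' Gene-by-sample tile plot of gene-level CNV calls (amplification red,
#' deletion blue), restricted to samples carrying at least one alteration.
#'
#' @param calls Output of [call_gene_cnv()].
#' @return A ggplot object.
#' @export
plot_cna_matrix <- function(calls) {
  stopifnot(is.data.frame(calls))
  dat <- calls %>%
    dplyr::filter(!is.na(.data$call), .data$call != "none")
  affected <- unique(dat$sample_id)
  dat <- dat %>% dplyr::filter(.data$sample_id %in% affected)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id, y = .data$gene,
                                    fill = .data$call)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(amplification = "#c0392b",
                                          deletion = "#2e6da4")) +
    ggplot2::labs(x = "sample", y = NULL, fill = NULL,
                  title = "Copy-number alterations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   panel.grid = ggplot2::element_blank())
}
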