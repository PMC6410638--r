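#' Per-sample tumor mutational burden
#'
#' Counts each sample's qualifying somatic SNVs (per the QC policy: depth
#' strictly above the bound, VAF at or above the floor) and converts to
#' mutations per megabase of interrogated territory:
#' `tmb = qualifying_snv_count / panel_mb * extrapolation_factor`. The
#' extrapolation factor rescales panel-level burden toward a whole-exome
#' estimate; the default 1.0 reports panel-level TMB. Samples with no
#' variants are retained with zero burden. Each sample is also flagged
#' `hypermutated` (total somatic mutation count at or above the threshold)
#' and `ddr_mutated` (any somatic variant in a DNA-damage-repair gene).
#'
#' @param cohort A [new_cohort()] bundle.
#' @param panel_mb Megabases of interrogated territory; defaults to the
#'   cohort's panel footprint and must be supplied when the cohort carries no
#'   panel.
#' @param policy A [filter_policy()].
#' @param extrapolation_factor Multiplicative whole-exome extrapolation
#'   (default 1.0).
#' @param ddr_genes DNA-damage-repair gene set (default [ddr_gene_set()]).
#' @param hypermutation_threshold Mutation count at or above which a sample
#'   is hypermutated (default 100, the gap between typical background counts
#'   of 0-48 and repair-defect counts of 141-277).
#' @return A tibble, one row per sample: `sample_id`, `group`,
#'   `qualifying_snv_count`, `mutation_count`, `panel_mb`, `tmb`,
#'   `hypermutated`, `ddr_mutated`.
#' @export
compute_tmb <- function(cohort, panel_mb = NULL,
                        policy = filter_policy(),
                        extrapolation_factor = 1,
                        ddr_genes = ddr_gene_set(),
                        hypermutation_threshold = 100) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(panel_mb)) {
    if (is.null(cohort$panel)) {
      stop("`panel_mb` is required when the cohort has no panel",
           call. = FALSE)
    }
    panel_mb <- panel_size_mb(cohort$panel)
  }
  if (!is.numeric(panel_mb) || panel_mb <= 0) {
    stop("`panel_mb` must be > 0", call. = FALSE)
  }
  qual <- filter_qualifying_snvs(cohort$somatic, policy)
  qual_n <- dplyr::count(qual, .data$sample_id, name = "qualifying_snv_count")
  all_n <- dplyr::count(cohort$somatic, .data$sample_id,
                        name = "mutation_count")
  ddr <- flag_ddr(cohort$somatic, ddr_genes)
  out <- cohort$samples %>%
    dplyr::select("sample_id", "group") %>%
    dplyr::left_join(qual_n, by = "sample_id") %>%
    dplyr::left_join(all_n, by = "sample_id") %>%
    dplyr::left_join(ddr, by = "sample_id") %>%
    dplyr::mutate(
      qualifying_snv_count = dplyr::coalesce(.data$qualifying_snv_count, 0L),
      mutation_count = dplyr::coalesce(.data$mutation_count, 0L),
      ddr_mutated = dplyr::coalesce(.data$ddr_mutated, FALSE),
      panel_mb = panel_mb,
      tmb = .data$qualifying_snv_count / panel_mb * extrapolation_factor,
      hypermutated = classify_hypermutated(.data$mutation_count,
                                           hypermutation_threshold)
    )
  dplyr::relocate(out, "sample_id", "group", "qualifying_snv_count",
                  "mutation_count", "panel_mb", "tmb", "hypermutated",
                  "ddr_mutated")
}

#' Classify hypermutated samples
#'
#' A sample is hypermutated when its somatic mutation count reaches the
#' threshold (inclusive). Accepts a bare numeric vector (optionally named) or
#' a tibble with `sample_id` and `mutation_count` columns.
#'
#' @param counts Numeric vector of per-sample mutation counts, or a tibble.
#' @param threshold Count at or above which a sample is hypermutated
#'   (default 100).
#' @return Logical vector aligned with the input (or the input tibble with a
#'   `hypermutated` column).
#' @export
classify_hypermutated <- function(counts, threshold = 100) {
  if (is.data.frame(counts)) {
    stopifnot("mutation_count" %in% names(counts))
    counts$hypermutated <- counts$mutation_count >= threshold
    return(counts)
  }
  stopifnot(is.numeric(counts), all(counts >= 0, na.rm = TRUE))
  counts >= threshold
}

#' Flag samples with somatic DNA-damage-repair mutations
#'
#' @param variants Somatic variant tibble.
#' @param ddr_genes DDR gene symbols (default [ddr_gene_set()]).
#' @return A tibble `sample_id`, `ddr_mutated` (TRUE), one row per flagged
#'   sample; samples absent from the output carry no DDR variant.
#' @export
flag_ddr <- function(variants, ddr_genes = ddr_gene_set()) {
  stopifnot(is.data.frame(variants), length(ddr_genes) > 0)
  variants %>%
    dplyr::filter(.data$gene %in% ddr_genes) %>%
    dplyr::distinct(.data$sample_id) %>%
    dplyr::mutate(ddr_mutated = TRUE)
}

# Mann-Whitney U two-sided p: exact permutation enumeration when both groups
# are small (handles ties), otherwise normal approximation with tie and
# continuity correction via stats::wilcox.test.
mann_whitney_p <- function(x, y, exact_limit = 8) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0, ny > 0)
  if (nx <= exact_limit && ny <= exact_limit) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(nx)])
    mu <- nx * (nx + ny + 1) / 2
    sums <- utils::combn(r, nx, sum)
    p <- mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
    return(list(p = p, method = "exact_permutation"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  )
  list(p = unname(wt$p.value), method = "normal_approximation")
}

#' Compare TMB between cohort groups
#'
#' Two-group comparison of per-sample TMB (EEC vs EIN) using the
#' Mann-Whitney rank test: exact permutation enumeration when both groups
#' have at most eight samples (valid under ties), otherwise the normal
#' approximation with tie and continuity correction. With
#' `exclude_ddr = TRUE`, samples flagged `ddr_mutated` are removed from both
#' groups first — isolating the burden difference not attributable to
#' DNA-repair-defect hypermutation.
#'
#' @param tmb A tibble from [compute_tmb()].
#' @param exclude_ddr Drop DDR-mutated samples from both groups first.
#' @return An object of class `tmb_comparison`: group medians and sizes, the
#'   two-sided p-value, and the test actually used. Has [tidy()], [glance()]
#'   and [ggplot2::autoplot()] methods.
#' @export
compare_tmb <- function(tmb, exclude_ddr = FALSE) {
  stopifnot(is.data.frame(tmb),
            all(c("sample_id", "group", "tmb") %in% names(tmb)))
  dat <- tmb
  if (exclude_ddr) {
    stopifnot("ddr_mutated" %in% names(dat))
    dat <- dat[!dat$ddr_mutated, , drop = FALSE]
  }
  grp <- split(dat$tmb, factor(dat$group, levels = c("EEC", "EIN")))
  if (any(lengths(grp) == 0)) {
    stop("a group is empty", if (exclude_ddr) " after DDR exclusion",
         call. = FALSE)
  }
  mw <- mann_whitney_p(grp$EEC, grp$EIN)
  structure(
    list(
      medians = tibble::tibble(
        group = c("EEC", "EIN"),
        n = unname(lengths(grp)[c("EEC", "EIN")]),
        median_tmb = unname(
          vapply(grp, stats::median, numeric(1))[c("EEC", "EIN")]
        )
      ),
      p_value = mw$p,
      method = mw$method,
      exclude_ddr = exclude_ddr,
      data = dat
    ),
    class = "tmb_comparison"
  )
}

#' @export
print.tmb_comparison <- function(x, ...) {
  cat("TMB comparison (Mann-Whitney, ", x$method, ")",
      if (x$exclude_ddr) ", DDR-mutated samples excluded", "\n", sep = "")
  for (i in seq_len(nrow(x$medians))) {
    cat(sprintf("  %s: n = %d, median TMB = %.4g\n",
                x$medians$group[i], x$medians$n[i], x$medians$median_tmb[i]))
  }
  cat(sprintf("  two-sided p = %.4g\n", x$p_value))
  invisible(x)
}
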