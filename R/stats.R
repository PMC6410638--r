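#' Vectorized two-sided Fisher exact p for 2x2 tables
#'
#' Conditional-on-margins exact test: with the table `[[a, b], [c, d]]`, the
#' two-sided p-value is the sum of hypergeometric point probabilities of all
#' tables with the same margins whose probability does not exceed that of the
#' observed table (the convention of mainstream statistical software, with a
#' `1 + 1e-7` relative guard against floating-point ties). Vectorized over
#' table rows.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a`,`b` form the first
#'   row, `c`,`d` the second.
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher_exact_p(10, 69, 0, 36) # sparse table, p ~ 0.0295
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  cells <- cbind(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]          # row 1 total
    nn <- c[i] + d[i]         # row 2 total
    k <- a[i] + c[i]          # column 1 total
    if (m + nn == 0) return(1)
    support <- max(0, k - nn):min(k, m)
    dens <- stats::dhyper(support, m, nn, k)
    d_obs <- stats::dhyper(a[i], m, nn, k)
    sum(dens[dens <= d_obs * (1 + 1e-7)])
  }, numeric(1))
}

# expected counts of a 2x2 table under independence
expected_counts <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Association test for a 2x2 table
#'
#' Group-vs-mutation-status frequency comparison with the standard selection
#' policy: Yates continuity-corrected Pearson chi-square when every expected
#' cell count is at least `min_expected` (default 5) and no margin is zero,
#' otherwise the two-sided Fisher exact test. The test actually used is always
#' reported, since sparse tables make the choice consequential.
#'
#' @param tab A 2x2 matrix of counts, rows = groups (EEC, EIN), columns =
#'   (mutated, wild-type). A numeric vector `c(a, b, c, d)` (row-wise) is also
#'   accepted.
#' @param min_expected Expected-count floor for using the chi-square test.
#' @return A one-row tibble: `test_used` (`"pearson_yates"` or
#'   `"fisher_exact"`), `statistic` (NA for Fisher), `p_value`, and the four
#'   cell counts `a`, `b`, `c`, `d`.
#' @examples
#' test_association(matrix(c(51, 28, 13, 23), 2, byrow = TRUE))
#' @export
test_association <- function(tab, min_expected = 5) {
  if (is.numeric(tab) && is.null(dim(tab)) && length(tab) == 4) {
    tab <- matrix(tab, nrow = 2, byrow = TRUE)
  }
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  use_chisq <- !degenerate && all(expected_counts(tab) >= min_expected)
  if (use_chisq) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    test_used <- "pearson_yates"
    statistic <- unname(ct$statistic)
    p <- unname(ct$p.value)
  } else {
    test_used <- "fisher_exact"
    statistic <- NA_real_
    p <- fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  }
  tibble::tibble(
    test_used = test_used, statistic = statistic, p_value = p,
    a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2]
  )
}

#' Per-gene mutation prevalence table
#'
#' One row per gene mutated in at least `min_mutated` samples, with
#' mutated-sample counts per group and overall percentage. A sample counts
#' once per gene regardless of how many variants it carries there. Rows are
#' sorted by descending overall count, ties broken lexicographically.
#'
#' @param cohort A [new_cohort()] bundle.
#' @param min_mutated Minimum overall mutated-sample count for inclusion
#'   (default 1).
#' @return A tibble: `gene`, `mutated_eec`, `n_eec`, `mutated_ein`, `n_ein`,
#'   `mutated_overall`, `n_overall`, `percentage`.
#' @export
prevalence_table <- function(cohort, min_mutated = 1) {
  stopifnot(inherits(cohort, "cohort"))
  sizes <- group_sizes(cohort)
  pairs <- mutated_pairs(cohort) %>%
    dplyr::left_join(dplyr::select(cohort$samples, "sample_id", "group"),
                     by = "sample_id")
  out <- pairs %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      mutated_eec = sum(.data$group == "EEC"),
      mutated_ein = sum(.data$group == "EIN"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      n_eec = unname(sizes["EEC"]), n_ein = unname(sizes["EIN"]),
      mutated_overall = .data$mutated_eec + .data$mutated_ein,
      n_overall = .data$n_eec + .data$n_ein,
      percentage = 100 * .data$mutated_overall / .data$n_overall
    ) %>%
    dplyr::filter(.data$mutated_overall >= min_mutated) %>%
    dplyr::arrange(dplyr::desc(.data$mutated_overall), .data$gene)
  dplyr::relocate(out, "gene", "mutated_eec", "n_eec", "mutated_ein",
                  "n_ein", "mutated_overall", "n_overall", "percentage")
}

#' Co-mutation of a gene pair
#'
#' A sample is co-mutated when it carries at least one somatic variant in
#' each gene. Reports per-group co-mutated counts and shares, and the
#' group-association test of co-mutation status (same selection policy as
#' [test_association()]). With `gene_a == gene_b` the result reduces to the
#' single gene's mutation set.
#'
#' @param cohort A [new_cohort()] bundle.
#' @param gene_a,gene_b Gene symbols.
#' @return An object of class `comutation`: `counts` tibble (per group:
#'   `n_comutated`, `n`, `share`) and `test` (one-row association tibble).
#' @export
comutation <- function(cohort, gene_a, gene_b) {
  stopifnot(inherits(cohort, "cohort"))
  pairs <- mutated_pairs(cohort)
  in_a <- unique(pairs$sample_id[pairs$gene == gene_a])
  in_b <- unique(pairs$sample_id[pairs$gene == gene_b])
  co <- intersect(in_a, in_b)
  sizes <- group_sizes(cohort)
  grp <- cohort$samples$group[match(co, cohort$samples$sample_id)]
  counts <- tibble::tibble(
    group = c("EEC", "EIN"),
    n_comutated = c(sum(grp == "EEC"), sum(grp == "EIN")),
    n = unname(sizes[c("EEC", "EIN")])
  )
  counts$share <- ifelse(counts$n > 0, counts$n_comutated / counts$n, 0)
  tab <- matrix(c(counts$n_comutated[1], counts$n[1] - counts$n_comutated[1],
                  counts$n_comutated[2], counts$n[2] - counts$n_comutated[2]),
                nrow = 2, byrow = TRUE)
  structure(
    list(gene_a = gene_a, gene_b = gene_b, counts = counts,
         test = test_association(tab)),
    class = "comutation"
  )
}

#' @export
print.comutation <- function(x, ...) {
  cat(sprintf("Co-mutation of %s and %s\n", x$gene_a, x$gene_b))
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %s: %d/%d (%.1f%%)\n", x$counts$group[i],
                x$counts$n_comutated[i], x$counts$n[i],
                100 * x$counts$share[i]))
  }
  cat(sprintf("  %s p = %.4g\n", x$test$test_used, x$test$p_value))
  invisible(x)
}

#' Differential mutation-frequency screen
#'
#' Tests every gene of the prevalence table for a frequency difference
#' between the EEC and EIN groups (selection policy of
#' [test_association()]), flagging significance at `alpha` on the raw
#' p-values by default; Benjamini-Hochberg adjustment is available behind
#' `correction = "BH"`.
#'
#' @param cohort A [new_cohort()] bundle.
#' @param min_mutated Minimum overall mutated-sample count for a gene to be
#'   screened (default 1).
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` (default) or `"BH"`.
#' @return A tibble of class `diff_screen`: the prevalence columns plus
#'   `test_used`, `statistic`, `p_value`, `p_adjusted`, `significant`.
#' @export
differential_screen <- function(cohort, min_mutated = 1, alpha = 0.05,
                                correction = c("none", "BH")) {
  correction <- match.arg(correction)
  prev <- prevalence_table(cohort, min_mutated = min_mutated)
  tests <- purrr::pmap_dfr(
    prev[, c("mutated_eec", "n_eec", "mutated_ein", "n_ein")],
    function(mutated_eec, n_eec, mutated_ein, n_ein) {
      test_association(matrix(
        c(mutated_eec, n_eec - mutated_eec,
          mutated_ein, n_ein - mutated_ein), nrow = 2, byrow = TRUE
      ))[, c("test_used", "statistic", "p_value")]
    }
  )
  out <- dplyr::bind_cols(prev, tests)
  out$p_adjusted <- if (correction == "BH") {
    stats::p.adjust(out$p_value, method = "BH")
  } else {
    out$p_value
  }
  out$significant <- out$p_adjusted < alpha
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  class(out) <- c("diff_screen", class(out))
  out
}

#' Cross-tabulate a gene's mutated samples against a clinical covariate
#'
#' Counts mutated and wild-type samples at each level of `grade`, `stage` or
#' `group`. Covariate levels with no mutated samples are retained as zero
#' rows, so depletion (e.g. a gene never mutated in high-grade disease) is
#' visible.
#'
#' @param cohort A [new_cohort()] bundle.
#' @param gene Gene symbol.
#' @param covariate `"grade"`, `"stage"` or `"group"`.
#' @return A tibble: `level`, `n_mutated`, `n_wildtype`, `n_total`.
#' @export
crosstab <- function(cohort, gene, covariate = c("grade", "stage", "group")) {
  covariate <- match.arg(covariate)
  stopifnot(inherits(cohort, "cohort"))
  mut_ids <- unique(cohort$somatic$sample_id[cohort$somatic$gene == gene])
  lv <- cohort$samples[[covariate]]
  levels_all <- sort(unique(lv[!is.na(lv)]))
  mutated <- cohort$samples$sample_id %in% mut_ids
  purrr::map_dfr(levels_all, function(l) {
    in_level <- !is.na(lv) & lv == l
    tibble::tibble(
      level = l,
      n_mutated = sum(in_level & mutated),
      n_wildtype = sum(in_level & !mutated),
      n_total = sum(in_level)
    )
  })
}
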