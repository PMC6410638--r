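#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a TMB group comparison
#'
#' @param x A `tmb_comparison` from [compare_tmb()].
#' @param ... Unused.
#' @return A tibble with one row per group (`group`, `n`, `median_tmb`).
#' @method tidy tmb_comparison
#' @export
tidy.tmb_comparison <- function(x, ...) {
  x$medians
}

#' One-row summary of a TMB group comparison
#'
#' @param x A `tmb_comparison` from [compare_tmb()].
#' @param ... Unused.
#' @return A one-row tibble: group medians and sizes, `p_value`, `method`,
#'   `exclude_ddr`.
#' @method glance tmb_comparison
#' @export
glance.tmb_comparison <- function(x, ...) {
  tibble::tibble(
    median_eec = x$medians$median_tmb[x$medians$group == "EEC"],
    median_ein = x$medians$median_tmb[x$medians$group == "EIN"],
    n_eec = x$medians$n[x$medians$group == "EEC"],
    n_ein = x$medians$n[x$medians$group == "EIN"],
    p_value = x$p_value,
    method = x$method,
    exclude_ddr = x$exclude_ddr
  )
}

#' Tidy a differential mutation-frequency screen
#'
#' @param x A `diff_screen` from [differential_screen()].
#' @param ... Unused.
#' @return The per-gene results as a plain tibble.
#' @method tidy diff_screen
#' @export
tidy.diff_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "diff_screen")
  tibble::as_tibble(out)
}

#' One-row summary of a differential screen
#'
#' @param x A `diff_screen` from [differential_screen()].
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_significant`, `alpha`,
#'   `correction`.
#' @method glance diff_screen
#' @export
glance.diff_screen <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    correction = attr(x, "correction")
  )
}

#' Tidy a co-mutation result
#'
#' @param x A `comutation` from [comutation()].
#' @param ... Unused.
#' @return A tibble with one row per group plus the test columns.
#' @method tidy comutation
#' @export
tidy.comutation <- function(x, ...) {
  dplyr::mutate(
    x$counts,
    gene_a = x$gene_a, gene_b = x$gene_b,
    test_used = x$test$test_used, p_value = x$test$p_value
  )
}
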