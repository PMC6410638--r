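#' Screen germline variants for pathogenic findings
#'
#' Rule-based triage of annotated germline variants: only pathogenic and
#' likely-pathogenic records are retained; each finding is classed as Lynch
#' syndrome (mismatch-repair genes) or non-Lynch by gene set; and findings in
#' recessive predisposition genes are actionable only when biallelic
#' (homozygous) — monoallelic hits are kept as carrier status. Pathogenicity
#' is consumed from the input annotation (ClinVar-style labels), never
#' predicted.
#'
#' @param variants Germline variant tibble with `sample_id`, `gene`,
#'   `zygosity` (`het`/`hom`) and `pathogenicity` (`pathogenic`,
#'   `likely_pathogenic`, `vus`, `benign`; case and spacing are normalised).
#'   A `base_change` or `protein_change` column is carried through if present.
#' @param sets Gene sets from [gene_sets()].
#' @param truncating_upgrade If TRUE, unannotated (`NA` pathogenicity)
#'   truncating variants (nonsense/frameshift/splice) are upgraded to
#'   likely-pathogenic before screening. Off by default.
#' @return A tibble of findings: `sample_id`, `gene`, `base_change`,
#'   `zygosity`, `pathogenicity`, `syndrome_class` (`lynch`/`non_lynch`),
#'   `biallelic_required`, `actionable`.
#' @examples
#' screen_germline(example_germline_variants())
#' @export
screen_germline <- function(variants, sets = gene_sets(),
                            truncating_upgrade = FALSE) {
  stopifnot(is.data.frame(variants))
  variants <- tibble::as_tibble(variants)
  need <- c("sample_id", "gene", "zygosity", "pathogenicity")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) {
    stop("germline table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  path <- tolower(gsub("[ -]", "_", variants$pathogenicity))
  if (isTRUE(truncating_upgrade) && "variant_class" %in% names(variants)) {
    truncating <- variants$variant_class %in%
      c("nonsense", "frameshift", "splice")
    path[is.na(path) & truncating] <- "likely_pathogenic"
  }
  bad <- !is.na(path) & !path %in% pathogenicity_levels
  if (any(bad)) {
    stop("unknown pathogenicity label(s): ",
         paste(unique(variants$pathogenicity[bad]), collapse = ", "),
         call. = FALSE)
  }
  bad_zyg <- !is.na(variants$zygosity) &
    !variants$zygosity %in% c("het", "hom")
  if (any(bad_zyg)) {
    stop("zygosity must be het or hom", call. = FALSE)
  }
  keep <- !is.na(path) & path %in% c("pathogenic", "likely_pathogenic")
  out <- variants[keep, , drop = FALSE]
  path <- path[keep]
  if (!"base_change" %in% names(out)) {
    out$base_change <- if ("protein_change" %in% names(out)) {
      out$protein_change
    } else {
      NA_character_
    }
  }
  tibble::tibble(
    sample_id = out$sample_id,
    gene = out$gene,
    base_change = out$base_change,
    zygosity = out$zygosity,
    pathogenicity = path,
    syndrome_class = ifelse(out$gene %in% sets$lynch, "lynch", "non_lynch"),
    biallelic_required = out$gene %in% sets$recessive,
    actionable = !(out$gene %in% sets$recessive) | out$zygosity == "hom"
  ) %>%
    dplyr::arrange(.data$gene, .data$sample_id)
}

#' Cohort germline carrier rates
#'
#' Patient-level summary of [screen_germline()] findings: the overall
#' pathogenic/likely-pathogenic carrier rate over all patients, the
#' Lynch-gene carrier rate within the carcinoma (EEC) group, and per-gene
#' carrier counts.
#'
#' @param findings Tibble from [screen_germline()].
#' @param cohort A [new_cohort()] bundle (provides the denominators).
#' @return A list of class `germline_summary`: `rates` (one row:
#'   `n_patients`, `n_carriers`, `overall_pct`, `n_eec`, `n_lynch_eec`,
#'   `lynch_eec_pct`), `per_gene` counts, and the findings table sorted by
#'   gene then sample.
#' @export
germline_summary <- function(findings, cohort) {
  stopifnot(is.data.frame(findings), inherits(cohort, "cohort"))
  n_patients <- nrow(cohort$samples)
  sizes <- group_sizes(cohort)
  carriers <- unique(findings$sample_id)
  eec_ids <- cohort$samples$sample_id[cohort$samples$group == "EEC"]
  lynch_eec <- unique(
    findings$sample_id[findings$syndrome_class == "lynch" &
                         findings$sample_id %in% eec_ids]
  )
  rates <- tibble::tibble(
    n_patients = n_patients,
    n_carriers = length(carriers),
    overall_pct = ifelse(n_patients > 0,
                         100 * length(carriers) / n_patients, 0),
    n_eec = unname(sizes["EEC"]),
    n_lynch_eec = length(lynch_eec),
    lynch_eec_pct = ifelse(sizes[["EEC"]] > 0,
                           100 * length(lynch_eec) / sizes[["EEC"]], 0)
  )
  per_gene <- findings %>%
    dplyr::group_by(.data$gene, .data$syndrome_class) %>%
    dplyr::summarise(n_carriers = dplyr::n_distinct(.data$sample_id),
                     n_findings = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$n_carriers), .data$gene)
  listing <- dplyr::arrange(findings, .data$gene, .data$sample_id)
  structure(
    list(rates = rates, per_gene = per_gene, findings = listing),
    class = "germline_summary"
  )
}

#' @export
print.germline_summary <- function(x, ...) {
  r <- x$rates
  cat(sprintf(
    "Germline screen: %d/%d patients carry P/LP findings (%.1f%%)\n",
    r$n_carriers, r$n_patients, r$overall_pct
  ))
  cat(sprintf("  Lynch-gene carriers within EEC: %d/%d (%.1f%%)\n",
              r$n_lynch_eec, r$n_eec, r$lynch_eec_pct))
  invisible(x)
}
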