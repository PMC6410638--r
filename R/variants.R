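#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

variant_types <- c("SNV", "insertion", "deletion")
variant_classes <- c(
  "missense", "nonsense", "frameshift", "nonframeshift_indel",
  "splice", "synonymous", "other"
)
pathogenicity_levels <- c("pathogenic", "likely_pathogenic", "vus", "benign")

variant_columns <- c(
  "sample_id", "gene", "chrom", "pos", "ref", "alt", "variant_type",
  "variant_class", "exon", "protein_change", "depth", "vaf", "origin",
  "zygosity"
)

#' Somatic QC filter policy
#'
#' Thresholds applied to somatic calls before they count toward tumor
#' mutational burden. The depth bound is exclusive (a call at exactly
#' `min_depth_exclusive` reads is rejected) and the allele-fraction bound is
#' inclusive (a call at exactly `min_vaf_inclusive` passes). By default only
#' single-nucleotide variants qualify; set `snv_only = FALSE` to include
#' indels for sensitivity analyses.
#'
#' @param min_depth_exclusive Integer; calls must have depth strictly greater
#'   than this (default 150).
#' @param min_vaf_inclusive Alt-allele fraction floor, inclusive (default
#'   0.03).
#' @param snv_only Logical; restrict qualifying variants to SNVs (default
#'   TRUE).
#' @return A list with class `filter_policy`.
#' @export
filter_policy <- function(min_depth_exclusive = 150,
                          min_vaf_inclusive = 0.03,
                          snv_only = TRUE) {
  if (!is.numeric(min_depth_exclusive) || min_depth_exclusive < 0) {
    stop("`min_depth_exclusive` must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(min_vaf_inclusive) ||
      min_vaf_inclusive < 0 || min_vaf_inclusive > 1) {
    stop("`min_vaf_inclusive` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      min_depth_exclusive = min_depth_exclusive,
      min_vaf_inclusive = min_vaf_inclusive,
      snv_only = isTRUE(snv_only)
    ),
    class = "filter_policy"
  )
}

#' Validate a variant table
#'
#' Checks the columns and value domains of a variant table and normalises it
#' to the package's canonical layout. Missing optional columns (`exon`,
#' `protein_change`, `zygosity`, coordinates) are added as NA. Unknown
#' variant-class strings are mapped to `"other"` with a warning; structural
#' problems (negative depth, VAF outside [0, 1], a variant type inconsistent
#' with the ref/alt allele lengths) are errors naming the offending field and
#' rows.
#'
#' @param variants A data frame with at least `sample_id`, `gene`,
#'   `variant_type`, `depth`, `vaf` columns.
#' @param origin Default origin (`"somatic"` or `"germline"`) for rows
#'   lacking an `origin` column.
#' @return A validated tibble with the canonical column set.
#' @export
validate_variants <- function(variants, origin = "somatic") {
  stopifnot(is.data.frame(variants))
  variants <- tibble::as_tibble(variants)
  required <- c("sample_id", "gene", "variant_type", "depth", "vaf")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0) {
    stop("variant table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(variant_columns, names(variants))) {
    variants[[col]] <- if (col == "origin") {
      origin
    } else if (col %in% c("pos", "exon", "depth")) {
      NA_integer_
    } else if (col == "vaf") {
      NA_real_
    } else {
      NA_character_
    }
  }
  variants <- variants[, c(variant_columns,
                           setdiff(names(variants), variant_columns))]

  bad_rows <- function(cond) which(!is.na(cond) & cond)

  if (length(i <- bad_rows(variants$depth < 0)) > 0) {
    stop("field `depth`: negative values at row(s) ",
         paste(utils::head(i, 5), collapse = ", "), call. = FALSE)
  }
  if (length(i <- bad_rows(variants$vaf < 0 | variants$vaf > 1)) > 0) {
    stop("field `vaf`: values outside [0, 1] at row(s) ",
         paste(utils::head(i, 5), collapse = ", "), call. = FALSE)
  }
  if (length(i <- bad_rows(!variants$variant_type %in% variant_types)) > 0) {
    stop("field `variant_type`: must be one of ",
         paste(variant_types, collapse = "/"), "; bad row(s) ",
         paste(utils::head(i, 5), collapse = ", "), call. = FALSE)
  }
  if (length(i <- bad_rows(!variants$origin %in%
                             c("somatic", "germline"))) > 0) {
    stop("field `origin`: must be somatic or germline; bad row(s) ",
         paste(utils::head(i, 5), collapse = ", "), call. = FALSE)
  }

  # variant_type must be consistent with allele lengths where both are known;
  # multi-allelic alts (comma) must be pre-split to one alt per record
  if (any(grepl(",", variants$alt %||% character(0)), na.rm = TRUE)) {
    stop("field `alt`: multi-allelic records must be split to one alt per row",
         call. = FALSE)
  }
  known <- !is.na(variants$ref) & !is.na(variants$alt)
  if (any(known)) {
    rl <- nchar(variants$ref[known])
    al <- nchar(variants$alt[known])
    ty <- variants$variant_type[known]
    ok <- (ty == "SNV" & rl == al) |
      (ty == "insertion" & al > rl) |
      (ty == "deletion" & rl > al)
    if (any(!ok)) {
      stop("field `variant_type`: inconsistent with ref/alt lengths at row(s) ",
           paste(utils::head(which(known)[!ok], 5), collapse = ", "),
           call. = FALSE)
    }
  }

  unknown_class <- !is.na(variants$variant_class) &
    !variants$variant_class %in% variant_classes
  if (any(unknown_class)) {
    warning("unknown variant_class value(s) mapped to \"other\": ",
            paste(unique(variants$variant_class[unknown_class]),
                  collapse = ", "), call. = FALSE)
    variants$variant_class[unknown_class] <- "other"
  }
  variants
}

#' Filter somatic calls qualifying for TMB
#'
#' Applies the somatic QC policy: keeps SNVs (when `snv_only`) with depth
#' strictly greater than the depth bound and alt-allele fraction at or above
#' the VAF floor. Input row order is preserved; the filter is idempotent.
#'
#' @param variants A variant tibble (see [validate_variants()]).
#' @param policy A [filter_policy()].
#' @return The qualifying subset of `variants`, same columns and order.
#' @examples
#' v <- tibble::tibble(
#'   sample_id = "s1", gene = "PTEN",
#'   variant_type = c("SNV", "SNV", "deletion"),
#'   depth = c(151L, 150L, 900L), vaf = c(0.03, 0.5, 0.4)
#' )
#' filter_qualifying_snvs(v) # keeps only the first row
#' @export
filter_qualifying_snvs <- function(variants, policy = filter_policy()) {
  stopifnot(is.data.frame(variants), inherits(policy, "filter_policy"))
  keep <- variants$depth > policy$min_depth_exclusive &
    variants$vaf >= policy$min_vaf_inclusive
  if (policy$snv_only) {
    keep <- keep & variants$variant_type == "SNV"
  }
  keep[is.na(keep)] <- FALSE
  variants[keep, , drop = FALSE]
}

#' Fraction of a gene's variants falling in one exon
#'
#' Counts variants of `gene` annotated to `exon` against all variants of the
#' gene (variants with unknown exon count toward the denominator only). With
#' no variants for the gene the fraction is NA rather than an error.
#'
#' @param variants A variant tibble.
#' @param gene Gene symbol.
#' @param exon Exon number.
#' @return A one-row tibble: `gene`, `exon`, `n_in_exon`, `n_total`,
#'   `fraction`.
#' @export
exon_fraction <- function(variants, gene, exon) {
  stopifnot(is.data.frame(variants))
  g <- variants[variants$gene == gene, , drop = FALSE]
  n_total <- nrow(g)
  n_in <- sum(!is.na(g$exon) & g$exon == exon)
  tibble::tibble(
    gene = gene, exon = as.integer(exon),
    n_in_exon = n_in, n_total = n_total,
    fraction = if (n_total == 0) NA_real_ else n_in / n_total
  )
}

#' Recurrent protein changes within a gene
#'
#' Tallies a gene's variants by protein change and ranks them by descending
#' count, ties broken lexicographically by protein change. The share is
#' against all counted (protein-change-annotated) variants of the gene.
#'
#' @param variants A variant tibble with `protein_change` populated for the
#'   records to be counted.
#' @param gene Gene symbol.
#' @return A tibble: `protein_change`, `n`, `share`, most recurrent first.
#' @export
recurrent_variants <- function(variants, gene) {
  stopifnot(is.data.frame(variants))
  g <- variants[variants$gene == gene & !is.na(variants$protein_change), ,
                drop = FALSE]
  out <- g %>%
    dplyr::count(.data$protein_change, name = "n") %>%
    dplyr::arrange(dplyr::desc(.data$n), .data$protein_change)
  out$share <- if (nrow(out) == 0) numeric(0) else out$n / sum(out$n)
  tibble::as_tibble(out)
}

#' Breakdown of a gene's variants by functional class
#'
#' @param variants A variant tibble with `variant_class` populated.
#' @param gene Gene symbol.
#' @return A tibble `variant_class`, `n`, `share`; shares sum to 1 over the
#'   observed classes (empty tibble for a gene with no variants).
#' @export
variant_class_breakdown <- function(variants, gene) {
  stopifnot(is.data.frame(variants))
  g <- variants[variants$gene == gene, , drop = FALSE]
  out <- g %>%
    dplyr::count(.data$variant_class, name = "n") %>%
    dplyr::arrange(dplyr::desc(.data$n), .data$variant_class)
  out$share <- if (nrow(out) == 0) numeric(0) else out$n / sum(out$n)
  tibble::as_tibble(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
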