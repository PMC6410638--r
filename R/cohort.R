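#' Assemble a cohort bundle
#'
#' Binds the tables of one cohort — sample sheet, somatic and germline variant
#' tables, region-depth profiles, panel — into a single validated object used
#' by the cohort-level analyses. Referential integrity is enforced: every
#' variant and depth record must reference a sample present in the sample
#' sheet, and group labels must be EEC (carcinoma) or EIN (precursor lesion).
#'
#' @param samples Sample sheet tibble: `sample_id`, `group`, optionally
#'   `grade` and `stage`. Sample ids must be unique.
#' @param somatic Somatic variant tibble (validated via
#'   [validate_variants()]); may be empty.
#' @param germline Optional germline variant tibble.
#' @param regions Optional region-depth tibble: `sample_id`, `gene`,
#'   `region_index`, `chrom`, `start`, `end` (0-based half-open),
#'   `tumor_depth`, `normal_depth`.
#' @param panel Optional panel tibble ([default_panel()] layout).
#' @param truth Optional list of simulation truth labels (see
#'   [generate_cohort()]).
#' @return A list with class `cohort` holding the validated tables.
#' @export
new_cohort <- function(samples, somatic,
                       germline = NULL, regions = NULL,
                       panel = NULL, truth = NULL) {
  stopifnot(is.data.frame(samples))
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("sample sheet needs `sample_id` and `group` columns", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_grp <- setdiff(unique(samples$group), c("EEC", "EIN"))
  if (length(bad_grp) > 0) {
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "),
         " (expected EEC or EIN)", call. = FALSE)
  }
  if (!"grade" %in% names(samples)) samples$grade <- NA_character_
  if (!"stage" %in% names(samples)) samples$stage <- NA_character_

  somatic <- validate_variants(somatic, origin = "somatic")
  check_samples <- function(tbl, what) {
    unknown <- setdiff(unique(tbl$sample_id), samples$sample_id)
    if (length(unknown) > 0) {
      stop(what, " references sample(s) absent from the sample sheet: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  check_samples(somatic, "somatic variant table")

  if (!is.null(germline)) {
    germline <- validate_variants(germline, origin = "germline")
    check_samples(germline, "germline variant table")
  }
  if (!is.null(regions)) {
    regions <- tibble::as_tibble(regions)
    need <- c("sample_id", "gene", "region_index", "start", "end",
              "tumor_depth", "normal_depth")
    miss <- setdiff(need, names(regions))
    if (length(miss) > 0) {
      stop("region-depth table missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (any(regions$start >= regions$end)) {
      stop("region-depth table: `start` must be < `end` (0-based half-open)",
           call. = FALSE)
    }
    if (any(regions$tumor_depth < 0 | regions$normal_depth < 0)) {
      stop("region-depth table: depths must be >= 0", call. = FALSE)
    }
    check_samples(regions, "region-depth table")
  }
  if (!is.null(panel)) {
    panel <- tibble::as_tibble(panel)
    extra <- setdiff(unique(somatic$gene), panel$gene)
    if (length(extra) > 0) {
      stop("somatic variant table contains gene(s) not on the panel: ",
           paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
    }
  }

  structure(
    list(samples = samples, somatic = somatic, germline = germline,
         regions = regions, panel = panel, truth = truth),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  n_grp <- table(factor(x$samples$group, levels = c("EEC", "EIN")))
  cat("<cohort> ", nrow(x$samples), " samples (EEC ", n_grp[["EEC"]],
      ", EIN ", n_grp[["EIN"]], ")\n", sep = "")
  cat("  somatic variants : ", nrow(x$somatic), "\n", sep = "")
  cat("  germline variants: ",
      if (is.null(x$germline)) 0L else nrow(x$germline), "\n", sep = "")
  cat("  depth regions    : ",
      if (is.null(x$regions)) 0L else nrow(x$regions), "\n", sep = "")
  if (!is.null(x$truth)) cat("  truth labels attached\n")
  invisible(x)
}

group_sizes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  c(EEC = sum(cohort$samples$group == "EEC"),
    EIN = sum(cohort$samples$group == "EIN"))
}

# distinct (sample, gene) mutation events, somatic only
mutated_pairs <- function(cohort) {
  dplyr::distinct(cohort$somatic, .data$sample_id, .data$gene)
}
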