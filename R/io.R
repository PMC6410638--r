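tsv_cols <- function(...) readr::cols(...)

read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  if (anyDuplicated(header)) {
    stop("duplicate header column(s) in ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  out <- readr::read_tsv(path, col_types = col_types, na = c(".", "NA", ""),
                         progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("parse error(s) in ", path, " at line(s) ",
         paste(utils::head(unique(probs$row), 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read a sample sheet
#'
#' Tab-separated, headered: `sample_id`, `group` (EEC/EIN), optional `grade`
#' and `stage`. Missing values are encoded `.`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  read_tsv_strict(path, readr::cols(.default = readr::col_character()))
}

#' Read a variant table
#'
#' Tab-separated, headered, one variant per row; columns as in the canonical
#' variant layout (see [validate_variants()]). Multi-allelic records must be
#' pre-split to one alt per row.
#'
#' @param path File path.
#' @param origin Default origin for rows lacking an `origin` column.
#' @return A validated variant tibble.
#' @export
read_variant_table <- function(path, origin = "somatic") {
  raw <- read_tsv_strict(path, readr::cols(
    pos = readr::col_integer(), exon = readr::col_integer(),
    depth = readr::col_integer(), vaf = readr::col_double(),
    .default = readr::col_character()
  ))
  validate_variants(raw, origin = origin)
}

#' Read a region-depth table
#'
#' BED-like, tab-separated, headered: `sample_id`, `gene`, `region_index`,
#' `chrom`, `start`, `end` (0-based half-open), `tumor_depth`,
#' `normal_depth`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_region_depth <- function(path) {
  read_tsv_strict(path, readr::cols(
    region_index = readr::col_integer(), start = readr::col_integer(),
    end = readr::col_integer(), tumor_depth = readr::col_double(),
    normal_depth = readr::col_double(), .default = readr::col_character()
  ))
}

#' Read a panel definition
#'
#' Tab-separated, headered: `gene`, `chrom`, `start`, `end`, `target_bp`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_panel <- function(path) {
  read_tsv_strict(path, readr::cols(
    start = readr::col_integer(), end = readr::col_integer(),
    target_bp = readr::col_integer(), .default = readr::col_character()
  ))
}

#' Read variants from a minimal single-sample VCF
#'
#' Parses a single-sample VCF (via the vcfR package) into the canonical
#' variant layout. Depth and alt-allele fraction are extracted from FORMAT
#' (or INFO) fields named by `mapping`; multi-allelic records are rejected
#' (split them upstream, e.g. `bcftools norm -m-`). Variant type is inferred
#' from allele lengths; functional class is taken from an INFO field when
#' `mapping$class_info` is set, else `NA`.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param sample_id Sample identifier to assign.
#' @param mapping List naming the fields to use: `depth` (default `"DP"`),
#'   `vaf` (default `"AF"`), optional `class_info`.
#' @param origin `"somatic"` or `"germline"`.
#' @return A validated variant tibble.
#' @export
read_vcf_variants <- function(path, sample_id,
                              mapping = list(depth = "DP", vaf = "AF"),
                              origin = "somatic") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- tibble::as_tibble(as.data.frame(fix, stringsAsFactors = FALSE))
  if (any(grepl(",", fix$ALT))) {
    stop("multi-allelic VCF records must be split to one alt per row",
         call. = FALSE)
  }
  get_field <- function(field) {
    gt <- tryCatch(
      vcfR::extract.gt(v, element = field, as.numeric = TRUE)[, 1],
      error = function(e) rep(NA_real_, nrow(fix))
    )
    if (all(is.na(gt))) {
      info <- suppressWarnings(
        as.numeric(vcfR::extract.info(v, element = field))
      )
      if (length(info) == nrow(fix)) gt <- info
    }
    unname(gt)
  }
  depth <- get_field(mapping$depth %||% "DP")
  vaf <- get_field(mapping$vaf %||% "AF")
  rl <- nchar(fix$REF)
  al <- nchar(fix$ALT)
  type <- ifelse(rl == al, "SNV", ifelse(al > rl, "insertion", "deletion"))
  cls <- if (!is.null(mapping$class_info)) {
    as.character(vcfR::extract.info(v, element = mapping$class_info))
  } else {
    NA_character_
  }
  gene <- tryCatch(as.character(vcfR::extract.info(v, element = "GENE")),
                   error = function(e) NA_character_)
  validate_variants(tibble::tibble(
    sample_id = sample_id,
    gene = gene,
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    variant_type = type, variant_class = cls,
    depth = as.integer(round(depth)), vaf = vaf
  ), origin = origin)
}

fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- NA
  out
}

#' Write a table as TSV
#'
#' Tab-separated with header, missing values as `.`, and doubles formatted
#' at six significant digits so repeated runs produce byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  x <- dplyr::mutate(as.data.frame(x),
                     dplyr::across(dplyr::where(is.double), fmt_num))
  readr::write_tsv(x, path, na = ".", progress = FALSE)
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Emits the pipeline's input formats: `samples.tsv`, `somatic.tsv`,
#' `germline.tsv`, `regions.tsv`, `panel.tsv`, and simulation truth labels as
#' `truth.json` when present.
#'
#' @param cohort A [new_cohort()] bundle.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_report_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  write_report_tsv(cohort$somatic, file.path(dir, "somatic.tsv"))
  if (!is.null(cohort$germline)) {
    write_report_tsv(cohort$germline, file.path(dir, "germline.tsv"))
  }
  if (!is.null(cohort$regions)) {
    write_report_tsv(cohort$regions, file.path(dir, "regions.tsv"))
  }
  if (!is.null(cohort$panel)) {
    write_report_tsv(cohort$panel, file.path(dir, "panel.tsv"))
  }
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) with fields: `sample_sheet`, `somatic_variants`, optional
#' `germline_variants`, `region_depth`, `panel` (paths, resolved relative to
#' the config file); optional scalar overrides `min_depth_exclusive`,
#' `min_vaf_inclusive`, `panel_mb`, `extrapolation_factor`,
#' `hypermutation_threshold`, `amp_lrr`, `del_lrr`, `majority`,
#' `min_normal_depth`, `alpha`, `correction`, `min_mutated`, `seed`.
#'
#' @param path Config file path.
#' @return A named list with absolute paths.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  for (key in c("sample_sheet", "somatic_variants", "germline_variants",
                "region_depth", "panel")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  cfg
}

#' Read and cross-validate all pipeline inputs
#'
#' Reads the sample sheet, variant tables, region depths and panel named in a
#' config list and assembles them into a validated cohort bundle; referential
#' integrity failures (unknown samples, off-panel genes, duplicate ids, bad
#' group labels) are reported with the offending identifiers.
#'
#' @param config A list from [read_pipeline_config()] or built inline.
#' @return A [new_cohort()] bundle.
#' @export
read_inputs <- function(config) {
  stopifnot(is.list(config), !is.null(config$sample_sheet),
            !is.null(config$somatic_variants))
  samples <- read_sample_sheet(config$sample_sheet)
  somatic <- read_variant_table(config$somatic_variants, origin = "somatic")
  germline <- if (!is.null(config$germline_variants)) {
    read_variant_table(config$germline_variants, origin = "germline")
  }
  regions <- if (!is.null(config$region_depth)) {
    read_region_depth(config$region_depth)
  }
  panel <- if (!is.null(config$panel)) read_panel(config$panel)
  new_cohort(samples, somatic, germline = germline, regions = regions,
             panel = panel)
}

#' Run the full pipeline
#'
#' Orchestrates every analysis stage on a cohort and writes the report
#' bundle: per-sample TMB (`tmb.tsv`) with the group comparison
#' (`tmb_comparison.json`, computed with and without DDR-mutated samples),
#' gene-level CNV calls (`cnv_calls.tsv`) with the gene-by-sample matrix
#' (`cnv_matrix.tsv`) and cohort CNA summary (`cna_summary.json`), the
#' prevalence/differential-screen report (`gene_screen.tsv`), co-mutation
#' results for the configured pairs (`comutation.tsv`), germline findings
#' (`germline_findings.tsv`) and rates (`germline_rates.json`), and a run
#' manifest (`manifest.json`) recording a config hash, package and R
#' versions, and per-stage record counts. Outputs are deterministic given the
#' inputs.
#'
#' @param cohort A [new_cohort()] bundle, or a config list (then inputs are
#'   read via [read_inputs()]).
#' @param out_dir Output directory.
#' @param policy A [filter_policy()].
#' @param thresholds A [cnv_thresholds()].
#' @param panel_mb Interrogated megabases (default: cohort panel footprint).
#' @param extrapolation_factor Whole-exome extrapolation factor (default 1).
#' @param hypermutation_threshold See [compute_tmb()].
#' @param min_mutated,alpha,correction Screen settings
#'   ([differential_screen()]).
#' @param comutation_pairs Two-column data frame (or list of 2-vectors) of
#'   gene pairs; default PTEN+PIK3CA and PTEN+PIK3R1 when those genes are
#'   present.
#' @param sets Germline [gene_sets()].
#' @return A list of class `pipeline_result` with every stage's in-memory
#'   result and the manifest.
#' @export
run_pipeline <- function(cohort, out_dir,
                         policy = filter_policy(),
                         thresholds = cnv_thresholds(),
                         panel_mb = NULL,
                         extrapolation_factor = 1,
                         hypermutation_threshold = 100,
                         min_mutated = 1, alpha = 0.05,
                         correction = "none",
                         comutation_pairs = NULL,
                         sets = gene_sets()) {
  if (!inherits(cohort, "cohort")) cohort <- read_inputs(cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  tmb <- stage("tmb", compute_tmb(
    cohort, panel_mb = panel_mb, policy = policy,
    extrapolation_factor = extrapolation_factor,
    hypermutation_threshold = hypermutation_threshold
  ))
  write_report_tsv(tmb, file.path(out_dir, "tmb.tsv"))
  cmp_all <- stage("tmb_compare", compare_tmb(tmb, exclude_ddr = FALSE))
  cmp_noddr <- tryCatch(compare_tmb(tmb, exclude_ddr = TRUE),
                        error = function(e) NULL)
  comparison <- list(
    all_samples = c(glance_list(cmp_all)),
    ddr_excluded = if (!is.null(cmp_noddr)) glance_list(cmp_noddr)
  )
  jsonlite::write_json(comparison, file.path(out_dir, "tmb_comparison.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cnv_calls <- NULL
  cna <- NULL
  if (!is.null(cohort$regions) && nrow(cohort$regions) > 0) {
    cnv_calls <- stage("cnv", call_gene_cnv(cohort$regions, thresholds))
    write_report_tsv(cnv_calls, file.path(out_dir, "cnv_calls.tsv"))
    write_report_tsv(cnv_matrix(cnv_calls),
                     file.path(out_dir, "cnv_matrix.tsv"))
    cna <- cna_summary(cnv_calls, cohort$samples)
    jsonlite::write_json(
      list(overall = as.list(cna$overall), per_gene = cna$per_gene),
      file.path(out_dir, "cna_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  screen <- stage("stats", differential_screen(
    cohort, min_mutated = min_mutated, alpha = alpha,
    correction = correction
  ))
  write_report_tsv(screen, file.path(out_dir, "gene_screen.tsv"))

  if (is.null(comutation_pairs)) {
    present <- unique(cohort$somatic$gene)
    cand <- list(c("PTEN", "PIK3CA"), c("PTEN", "PIK3R1"))
    comutation_pairs <- Filter(function(p) all(p %in% present), cand)
  } else if (is.data.frame(comutation_pairs)) {
    comutation_pairs <- apply(comutation_pairs, 1, as.character,
                              simplify = FALSE)
  }
  comut <- purrr::map_dfr(comutation_pairs, function(p) {
    cm <- comutation(cohort, p[1], p[2])
    tibble::tibble(
      gene_a = p[1], gene_b = p[2],
      eec_comutated = cm$counts$n_comutated[1],
      eec_n = cm$counts$n[1],
      ein_comutated = cm$counts$n_comutated[2],
      ein_n = cm$counts$n[2],
      test_used = cm$test$test_used, p_value = cm$test$p_value
    )
  })
  write_report_tsv(comut, file.path(out_dir, "comutation.tsv"))

  germ <- NULL
  if (!is.null(cohort$germline) && nrow(cohort$germline) > 0) {
    findings <- stage("germline", screen_germline(cohort$germline,
                                                  sets = sets))
    germ <- germline_summary(findings, cohort)
    write_report_tsv(germ$findings,
                     file.path(out_dir, "germline_findings.tsv"))
    jsonlite::write_json(as.list(germ$rates),
                         file.path(out_dir, "germline_rates.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "panelcohort",
    package_version = as.character(utils::packageVersion("panelcohort")),
    r_version = R.version.string,
    config_hash = rlang::hash(list(
      policy = unclass(policy), thresholds = unclass(thresholds),
      panel_mb = panel_mb, extrapolation_factor = extrapolation_factor,
      hypermutation_threshold = hypermutation_threshold,
      min_mutated = min_mutated, alpha = alpha, correction = correction
    )),
    n_samples = nrow(cohort$samples),
    n_somatic_variants = nrow(cohort$somatic),
    n_germline_variants = if (is.null(cohort$germline)) 0L
                          else nrow(cohort$germline),
    n_depth_regions = if (is.null(cohort$regions)) 0L
                      else nrow(cohort$regions),
    n_genes_screened = nrow(screen),
    n_cnv_calls = if (is.null(cnv_calls)) 0L else nrow(cnv_calls)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(
    list(tmb = tmb, tmb_comparison = cmp_all,
         tmb_comparison_ddr_excluded = cmp_noddr,
         cnv_calls = cnv_calls, cna_summary = cna,
         screen = screen, comutation = comut,
         germline = germ, manifest = manifest, out_dir = out_dir),
    class = "pipeline_result"
  )
}

glance_list <- function(cmp) {
  list(
    median_eec = cmp$medians$median_tmb[cmp$medians$group == "EEC"],
    median_ein = cmp$medians$median_tmb[cmp$medians$group == "EIN"],
    n_eec = cmp$medians$n[cmp$medians$group == "EEC"],
    n_ein = cmp$medians$n[cmp$medians$group == "EIN"],
    p_value = cmp$p_value, method = cmp$method
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("panelcohort pipeline run -> ", x$out_dir, "\n", sep = "")
  cat("  samples: ", x$manifest$n_samples,
      ", somatic variants: ", x$manifest$n_somatic_variants, "\n", sep = "")
  cat("  genes screened: ", x$manifest$n_genes_screened,
      ", CNV calls: ", x$manifest$n_cnv_calls, "\n", sep = "")
  invisible(x)
}
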