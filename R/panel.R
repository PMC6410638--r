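#' Gene panel bundled with the package
#'
#' A synthetic 363-gene targeted panel laid out deterministically over
#' chr1-chr22. The first entries are recurrently mutated endometrial-cancer
#' genes (PI3K pathway, SWI/SNF, Wnt, DNA-damage-repair, and hereditary-cancer
#' genes); the remainder are numbered filler genes so that the panel footprint
#' is realistic for a capture design of this size (~1.2 Mb of targeted
#' territory). Coordinates are invented and only internally consistent; they
#' exist so that simulated variants and depth regions have well-formed
#' positions, not to match any genome build.
#'
#' @param n_genes Total number of genes on the panel (default 363).
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`, `target_bp`
#'   (targeted bases per gene; `end - start == target_bp`). Coordinates are
#'   0-based half-open, BED convention.
#' @examples
#' panel <- default_panel()
#' panel_size_mb(panel)
#' @export
default_panel <- function(n_genes = 363) {
  named <- c(
    "PTEN", "PIK3CA", "CTNNB1", "PIK3R1", "ARID1A", "KRAS", "CTCF", "FGFR2",
    "ARID5B", "NOTCH1", "ARHGAP35", "KMT2D", "MTOR", "SMC1A", "BRCA2", "KDR",
    "AKT1", "APC", "KMT2B", "ERBB3", "NF1", "TP53", "POLQ",
    "POLE", "MSH2", "MSH6", "MLH1", "MLH3", "PMS1", "PMS2",
    "MUTYH", "GALNT12", "MPL", "ATM", "ERCC4", "VEGFB", "FOXA2", "KMT2C"
  )
  stopifnot(n_genes >= length(named))
  filler <- sprintf("GENE%03d", seq_len(n_genes - length(named)))
  gene <- c(named, filler)
  # deterministic, RNG-free layout: cycle chromosomes, space genes 1 Mb apart
  target_bp <- rep_len(c(2400L, 3000L, 3600L, 4200L), n_genes)
  chrom_idx <- ((seq_len(n_genes) - 1L) %% 22L) + 1L
  rank_on_chrom <- stats::ave(seq_len(n_genes), chrom_idx, FUN = seq_along)
  start <- 1000000L * rank_on_chrom
  tibble::tibble(
    gene = gene,
    chrom = paste0("chr", chrom_idx),
    start = start,
    end = start + target_bp,
    target_bp = target_bp
  )
}

#' Panel footprint in megabases
#'
#' @param panel A panel tibble as returned by [default_panel()] or
#'   [read_panel()].
#' @return Total targeted territory in Mb.
#' @export
panel_size_mb <- function(panel) {
  stopifnot(is.data.frame(panel), "target_bp" %in% names(panel))
  sum(as.numeric(panel$target_bp)) / 1e6
}

#' DNA-damage-repair (DDR) gene set
#'
#' Default set of genes whose somatic mutation is treated as evidence of a
#' disturbed DNA-repair system: the proofreading polymerases POLE and POLQ and
#' the mismatch-repair genes. Samples carrying a somatic variant in any of
#' these are flagged `ddr_mutated` and can be excluded from TMB group
#' comparisons (hypermutation driven by repair defects otherwise dominates the
#' comparison).
#'
#' @return Character vector of gene symbols.
#' @export
ddr_gene_set <- function() {
  c("POLE", "POLQ", "MSH2", "MSH6", "MLH1", "MLH3", "PMS1", "PMS2")
}

#' Germline screening gene sets
#'
#' Gene sets used by [screen_germline()]: the Lynch-syndrome mismatch-repair
#' genes, and genes whose predisposition phenotype is recessive (biallelic
#' hits required; monoallelic pathogenic findings are retained as carrier
#' status but not actionable). MUTYH is the only default recessive gene.
#'
#' @param lynch Character vector of Lynch-syndrome genes.
#' @param recessive Character vector of recessive predisposition genes.
#' @return A list with elements `lynch` and `recessive`.
#' @export
gene_sets <- function(lynch = c("MLH1", "MSH2", "MSH6", "PMS2"),
                      recessive = "MUTYH") {
  lynch <- unique(as.character(lynch))
  if (length(lynch) == 0) {
    stop("`lynch` gene set must be non-empty", call. = FALSE)
  }
  list(lynch = lynch, recessive = unique(as.character(recessive)))
}

#' Example per-gene mutated-sample counts
#'
#' Mutated-sample counts per gene for a 79-carcinoma (EEC) / 36-precursor
#' (EIN) targeted-panel endometrial cohort, restricted to genes mutated in at
#' least nine samples. Intended as input for [fixture_from_counts()]: the
#' resulting deterministic cohort reproduces these marginal counts exactly and
#' exercises the full frequency-testing machinery. Offsets for PTEN and PIK3CA
#' are chosen so the fixture also reproduces the cohort's co-mutation overlap
#' (24 EEC and 4 EIN samples carrying both).
#'
#' @return A tibble with columns `gene`, `eec`, `ein` (mutated samples per
#'   group), `offset_eec`, `offset_ein` (placement offsets, see
#'   [fixture_from_counts()]).
#' @export
example_gene_counts <- function() {
  tbl <- tibble::tribble(
    ~gene,       ~eec, ~ein,
    "PTEN",       51L,  13L,
    "PIK3CA",     37L,  16L,
    "CTNNB1",     22L,  12L,
    "PIK3R1",     30L,   4L,
    "ARID1A",     29L,   4L,
    "KRAS",       12L,   6L,
    "CTCF",       15L,   0L,
    "FGFR2",      12L,   2L,
    "ARID5B",     11L,   2L,
    "NOTCH1",      9L,   3L,
    "ARHGAP35",   12L,   0L,
    "KMT2D",      10L,   2L,
    "MTOR",       10L,   1L,
    "SMC1A",       9L,   1L,
    "BRCA2",       9L,   1L,
    "KDR",        10L,   0L,
    "AKT1",        3L,   6L,
    "APC",         8L,   1L,
    "KMT2B",       7L,   2L,
    "ERBB3",       7L,   2L,
    "NF1",         9L,   0L,
    "TP53",        9L,   0L,
    "POLQ",        8L,   1L
  )
  tbl$offset_eec <- 0L
  tbl$offset_ein <- 0L
  # PTEN occupies EEC samples 1..51; shifting PIK3CA to start at sample 28
  # makes the PTEN&PIK3CA overlap 24 in EEC; likewise 4 in EIN.
  tbl$offset_eec[tbl$gene == "PIK3CA"] <- 27L
  tbl$offset_ein[tbl$gene == "PIK3CA"] <- 9L
  tbl
}

#' Example germline findings table
#'
#' A ten-row germline variant table in the input format of
#' [screen_germline()], modeled on the deleterious germline findings of a
#' 115-patient endometrial cohort (all carriers in the 79-sample carcinoma
#' group; two Lynch-gene carriers; one biallelic and one monoallelic MUTYH
#' carrier). Sample identifiers are synthetic.
#'
#' @return A tibble of germline variant records with `pathogenicity` and
#'   `zygosity` columns.
#' @export
example_germline_variants <- function() {
  tibble::tribble(
    ~sample_id, ~gene,     ~base_change,                   ~zygosity, ~pathogenicity,
    "EEC_005",  "MUTYH",   "c.934-2A>G",                   "hom",     "pathogenic",
    "EEC_012",  "MLH1",    "c.885-1_893delGTTTAGAAAT",     "hom",     "pathogenic",
    "EEC_019",  "MSH2",    "c.C1183T (p.Q395X)",           "hom",     "pathogenic",
    "EEC_023",  "GALNT12", "c.G5A (p.W2X)",                "hom",     "likely_pathogenic",
    "EEC_031",  "POLE",    "c.4430delG (p.S1477Tfs)",      "het",     "likely_pathogenic",
    "EEC_040",  "MPL",     "c.313_316delTTTC (p.F105Rfs)", "het",     "likely_pathogenic",
    "EEC_047",  "ATM",     "c.C8494T (p.R2832C)",          "het",     "likely_pathogenic",
    "EEC_055",  "MUTYH",   "c.G467A (p.W156X)",            "het",     "pathogenic",
    "EEC_062",  "ERCC4",   "c.1536dupA (p.G513Rfs)",       "het",     "likely_pathogenic",
    "EEC_071",  "MPL",     "c.981-1G>C",                   "het",     "pathogenic"
  )
}
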