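# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles (enumeration / closed form), deliberately
# avoiding the package's own code paths.

# two-sided Fisher exact p by explicit hypergeometric enumeration with
# binomial coefficients (same tie convention as mainstream software)
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m + n == 0) return(1)
  sup <- max(0, k - n):min(k, m)
  dens <- choose(m, sup) * choose(n, k - sup) / choose(m + n, k)
  dobs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(dens[dens <= dobs * (1 + 1e-7)])
}

# Yates continuity-corrected chi-square p from the closed 2x2 formula
# N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2)
yates_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- abs(a * d - b * c) - n / 2
  if (num < 0) num <- 0
  stat <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# exact two-sided rank-sum p by enumerating every assignment of the pooled
# observations to the first group
rank_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  mu <- nx * (length(pooled) + 1) / 2
  obs <- sum(r[seq_len(nx)])
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# minimal somatic variant rows with sensible defaults
mk_variants <- function(sample_id, gene, depth = 500L, vaf = 0.25,
                        variant_type = "SNV", variant_class = "missense",
                        exon = NA_integer_, protein_change = NA_character_) {
  tibble::tibble(
    sample_id = sample_id, gene = gene,
    variant_type = variant_type, variant_class = variant_class,
    depth = as.integer(depth), vaf = vaf, exon = as.integer(exon),
    protein_change = protein_change, origin = "somatic"
  )
}

# a flat region-depth profile for one sample and gene
mk_regions <- function(n_regions, tumor, normal, gene = "VEGFB",
                       sample_id = "s1") {
  tibble::tibble(
    sample_id = sample_id, gene = gene,
    region_index = seq_len(n_regions), chrom = "chr11",
    start = (seq_len(n_regions) - 1L) * 100L,
    end = seq_len(n_regions) * 100L,
    tumor_depth = rep_len(tumor, n_regions),
    normal_depth = rep_len(normal, n_regions)
  )
}

# cohort with two samples per group and a fully controlled variant table
mk_tiny_cohort <- function(somatic, n_eec = 2, n_ein = 2, ...) {
  samples <- tibble::tibble(
    sample_id = c(sprintf("EEC_%03d", seq_len(n_eec)),
                  sprintf("EIN_%03d", seq_len(n_ein))),
    group = rep(c("EEC", "EIN"), c(n_eec, n_ein))
  )
  new_cohort(samples, somatic, ...)
}
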