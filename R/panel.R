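#' Variant reference panel
#'
#' Container for a diploid genotype reference panel on a single chromosome:
#' SNP identifiers, 1-based positions (strictly increasing), alleles, a dosage
#' matrix (individuals x SNPs, values in 0/1/2 counting the a1 allele) and the
#' empirical minor allele frequency per SNP.
#'
#' @param snp Character vector of unique SNP identifiers.
#' @param chrom Chromosome label (single value).
#' @param pos Integer 1-based positions, strictly increasing.
#' @param a1,a2 Allele labels; `a1` is the dosage-counted (effect) allele.
#' @param genotypes Numeric matrix, `n_individuals` rows by `length(snp)`
#'   columns, entries in `{0, 1, 2}`.
#' @param block Optional integer LD-block id per SNP (kept by the simulator so
#'   that eQTL cohorts can be drawn from the same LD process).
#' @param sim_freq Optional generating allele frequency per SNP (simulator
#'   bookkeeping).
#'
#' @return An object of class `variant_panel`.
#' @export
variant_panel <- function(snp, chrom, pos, a1, a2, genotypes,
                          block = NULL, sim_freq = NULL) {
  M <- length(snp)
  stopifnot(
    M > 0L, !anyDuplicated(snp),
    length(pos) == M, length(a1) == M, length(a2) == M,
    is.matrix(genotypes), ncol(genotypes) == M, nrow(genotypes) >= 2,
    length(chrom) == 1L
  )
  if (any(diff(pos) <= 0)) stop("positions must be strictly increasing")
  if (!is.null(block)) stopifnot(length(block) == M)
  f <- colMeans(genotypes) / 2
  structure(
    list(
      snp = as.character(snp),
      chrom = as.character(chrom),
      pos = as.integer(pos),
      a1 = as.character(a1),
      a2 = as.character(a2),
      genotypes = genotypes,
      maf = pmin(f, 1 - f),
      n_individuals = nrow(genotypes),
      block = if (!is.null(block)) as.integer(block),
      sim_freq = sim_freq
    ),
    class = "variant_panel"
  )
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("<variant_panel> %d SNPs x %d individuals, chrom %s, pos %d..%d\n",
              length(x$snp), x$n_individuals, x$chrom,
              min(x$pos), max(x$pos)))
  cat(sprintf("  MAF range %.3f..%.3f\n", min(x$maf), max(x$maf)))
  invisible(x)
}

# Subset a panel to a set of SNP column indices (order preserved).
subset_panel <- function(panel, idx) {
  variant_panel(
    snp = panel$snp[idx], chrom = panel$chrom, pos = panel$pos[idx],
    a1 = panel$a1[idx], a2 = panel$a2[idx],
    genotypes = panel$genotypes[, idx, drop = FALSE],
    block = if (!is.null(panel$block)) panel$block[idx],
    sim_freq = if (!is.null(panel$sim_freq)) panel$sim_freq[idx]
  )
}
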