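#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: the LD reference panel
#' (sample size, number of SNPs, AR(1) LD block structure), the two-tissue
#' eQTL catalogs (gene count, probes per gene, cis window, cross-tissue effect
#' correlation rho, cohort sizes), and the GWAS summary-statistic model
#' (sample size N, per-category per-SNP heritability coefficients tau,
#' confounding intercept term a). A fixed `seed` makes every generator output
#' byte-identical across runs.
#'
#' @param n_ref_individuals Diploid individuals in the LD reference panel.
#' @param n_snps Number of SNPs M (before the MAF >= 0.01 filter).
#' @param n_ld_blocks Number of independent LD blocks partitioning the M SNPs.
#' @param within_block_ld Latent AR(1) correlation between adjacent SNPs
#'   within a block, in `[0, 1)`. 0 gives independent SNPs.
#' @param n_genes Number of expressed genes placed along the chromosome.
#' @param probes_per_gene_per_tissue Array probes measuring each gene in each
#'   tissue where it is expressed.
#' @param cis_window_bp Half-width of the cis window around a gene's span
#'   within which SNPs are tested as eQTLs.
#' @param cross_tissue_effect_corr Correlation rho of per-SNP causal effects
#'   on expression across the two tissues, for tissue-shared genes.
#' @param prop_shared_genes Fraction of genes whose effects are shared across
#'   tissues; the remainder are expressed (and have eQTLs) in one tissue only.
#' @param n_causal_per_gene Causal cis-SNPs per gene.
#' @param expr_h2 Heritability of each probe's expression level explained by
#'   its gene's causal SNPs.
#' @param eqtl_sample_sizes Named vector of per-tissue eQTL cohort sizes;
#'   names are the tissue labels (exactly two tissues for catalog generation).
#' @param gwas_n GWAS sample size N.
#' @param tau_true Optional named vector of true per-SNP heritability
#'   coefficients per annotation category, used by [gen_gwas_sumstats()].
#' @param intercept_a Confounding term a; the expected chi-square under the
#'   model is `1 + N*a + N*sum_c tau_c*l(j,c)`.
#' @param seed Integer seed controlling all generator randomness.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_ref_individuals = 500L,
                              n_snps = 3000L,
                              n_ld_blocks = 30L,
                              within_block_ld = 0.98,
                              n_genes = 30L,
                              probes_per_gene_per_tissue = 2L,
                              cis_window_bp = 100000L,
                              cross_tissue_effect_corr = 0.95,
                              prop_shared_genes = 0.5,
                              n_causal_per_gene = 8L,
                              expr_h2 = 0.6,
                              eqtl_sample_sizes = c(blood = 500L, brain = 500L),
                              gwas_n = 50000L,
                              tau_true = NULL,
                              intercept_a = 0,
                              seed = 1L) {
  stopifnot(
    .is_count(n_ref_individuals), n_ref_individuals >= 3,
    .is_count(n_snps),
    .is_count(n_ld_blocks), n_ld_blocks <= n_snps,
    is.numeric(within_block_ld), within_block_ld >= 0, within_block_ld < 1,
    .is_count(n_genes),
    .is_count(probes_per_gene_per_tissue),
    .is_count(cis_window_bp),
    is.numeric(cross_tissue_effect_corr),
    abs(cross_tissue_effect_corr) <= 1,
    is.numeric(prop_shared_genes), prop_shared_genes >= 0, prop_shared_genes <= 1,
    .is_count(n_causal_per_gene),
    is.numeric(expr_h2), expr_h2 > 0, expr_h2 < 1,
    .is_count(gwas_n),
    is.numeric(intercept_a), length(intercept_a) == 1L,
    .is_count(abs(seed) + 1)
  )
  if (is.null(names(eqtl_sample_sizes)) || any(!nzchar(names(eqtl_sample_sizes))))
    stop("eqtl_sample_sizes must be a named vector of per-tissue cohort sizes")
  if (!all(vapply(eqtl_sample_sizes, .is_count, logical(1))))
    stop("eqtl_sample_sizes must be positive integer counts")
  if (!is.null(tau_true) && is.null(names(tau_true)))
    stop("tau_true must be a named vector (one entry per annotation category)")
  structure(
    list(
      n_ref_individuals = as.integer(n_ref_individuals),
      n_snps = as.integer(n_snps),
      n_ld_blocks = as.integer(n_ld_blocks),
      within_block_ld = within_block_ld,
      n_genes = as.integer(n_genes),
      probes_per_gene_per_tissue = as.integer(probes_per_gene_per_tissue),
      cis_window_bp = as.integer(cis_window_bp),
      cross_tissue_effect_corr = cross_tissue_effect_corr,
      prop_shared_genes = prop_shared_genes,
      n_causal_per_gene = as.integer(n_causal_per_gene),
      expr_h2 = expr_h2,
      eqtl_sample_sizes = vapply(eqtl_sample_sizes, as.integer, integer(1)),
      gwas_n = as.integer(gwas_n),
      tau_true = tau_true,
      intercept_a = intercept_a,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  panel: %d individuals, %d SNPs in %d LD blocks (AR rho %.2f)\n",
              x$n_ref_individuals, x$n_snps, x$n_ld_blocks, x$within_block_ld))
  cat(sprintf("  eQTL:  %d genes x %d probes, cohorts [%s], cross-tissue rho %.2f\n",
              x$n_genes, x$probes_per_gene_per_tissue,
              paste(names(x$eqtl_sample_sizes), x$eqtl_sample_sizes,
                    sep = "=", collapse = ", "),
              x$cross_tissue_effect_corr))
  cat(sprintf("  GWAS:  N = %d, intercept a = %g, seed = %d\n",
              x$gwas_n, x$intercept_a, x$seed))
  invisible(x)
}

# Partition M SNPs into B contiguous blocks of near-equal size.
block_sizes <- function(M, B) {
  base <- M %/% B
  sizes <- rep.int(base, B)
  extra <- M - base * B
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes < 1L)) stop("degenerate config: more LD blocks than SNPs")
  sizes
}
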