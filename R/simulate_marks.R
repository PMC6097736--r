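#' Simulate histone-mark intervals and differential-expression ranks
#'
#' Builds (a) a set of genomic intervals (a histone-mark stand-in) covering a
#' controllable fraction of the causal eQTL SNPs in `truth`, and (b) a
#' per-tissue differential-expression ranking of all genes in which a chosen
#' set of genes is placed in the top decile. Intervals are returned as a
#' `GRanges` and written to BED (0-based half-open) by [write_bed()].
#'
#' @param panel The [variant_panel()].
#' @param truth The `ground_truth` from [gen_eqtl_catalogs()].
#' @param overlap_fraction Fraction of causal eQTL SNPs the intervals must
#'   cover, in `[0, 1]`.
#' @param config The [simulation_config()] (seed only).
#' @param interval_halfwidth Half-width in bp of each interval around a
#'   covered SNP (default 25).
#' @param top_genes Optional named list (per tissue) of genes to place in the
#'   top decile; defaults to the tissue's specific genes, padded with shared
#'   genes.
#' @return List with `marks` (GRanges), `de_ranks` (gene, tissue, rank,
#'   decile; rank 1 = most strongly differentially expressed) and
#'   `covered_snps` (the causal SNP ids the intervals were built around).
#' @export
gen_marks_and_de <- function(panel, truth, overlap_fraction, config,
                             interval_halfwidth = 25L, top_genes = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  set.seed(config$seed + 3000L)

  causal <- unique(truth$causal_eqtl_map$snp)
  k <- ceiling(overlap_fraction * length(causal))
  chosen <- if (k > 0) sort(sample(causal, k)) else character()
  if (length(chosen)) {
    cpos <- panel$pos[match(chosen, panel$snp)]
    marks <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = panel$chrom,
      ranges = IRanges::IRanges(
        start = pmax(cpos - interval_halfwidth, 1L),
        end = cpos + interval_halfwidth
      )
    ))
  } else {
    marks <- GenomicRanges::GRanges()
  }

  genes <- c(truth$true_shared_genes, truth$true_specific_genes)
  G <- length(genes)
  d <- ceiling(0.10 * G)
  tissues <- names(config$eqtl_sample_sizes)
  de <- lapply(tissues, function(t) {
    want <- top_genes[[t]] %||%
      names(truth$specific_tissue)[truth$specific_tissue == t]
    want <- intersect(want, genes)
    if (length(want) < d)
      want <- c(want, sample(setdiff(genes, want), d - length(want)))
    want <- want[seq_len(d)]
    rest <- sample(setdiff(genes, want))
    ranked <- c(sample(want), rest)
    rank <- match(genes, ranked)
    # decile cutpoints use the same ceiling convention as the top-decile
    # gene count, so rank <= ceiling(0.1 * G) <=> decile == 1 for any G
    cuts <- ceiling(seq_len(10L) * G / 10)
    decile <- vapply(rank, function(r) which(r <= cuts)[1L], integer(1))
    data.frame(gene = genes, tissue = t, rank = rank, decile = decile)
  })
  de_ranks <- do.call(rbind, de)
  rownames(de_ranks) <- NULL
  list(marks = marks, de_ranks = de_ranks, covered_snps = chosen)
}
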