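#' Annotation matrix
#'
#' Binary SNP-by-category membership matrix aligned to a panel. The `base`
#' category (all panel SNPs) is always present as the first, all-ones column.
#' SNP ids in a category that are absent from the panel are dropped with a
#' message (mirrors restricting analyses to the regression SNP set).
#'
#' @param panel A [variant_panel()].
#' @param categories Named list of character vectors of member SNP ids.
#' @param provenance Optional named character vector of free-text
#'   per-category descriptions.
#' @return An object of class `annotation_matrix`.
#' @export
annotation_matrix <- function(panel, categories = list(), provenance = NULL) {
  stopifnot(inherits(panel, "variant_panel"))
  if (length(categories) && is.null(names(categories)))
    stop("categories must be a named list")
  M <- length(panel$snp)
  mat <- matrix(1L, M, 1L, dimnames = list(NULL, "base"))
  for (nm in names(categories)) {
    ids <- categories[[nm]]
    n_missing <- sum(!(ids %in% panel$snp))
    if (n_missing > 0)
      message("category ", nm, ": dropped ", n_missing,
              " SNP(s) absent from the panel")
    mat <- cbind(mat, as.integer(panel$snp %in% ids))
    colnames(mat)[ncol(mat)] <- nm
  }
  prov <- c(base = "all panel SNPs",
            setNames(
              vapply(names(categories), function(nm)
                provenance[[nm]] %||% nm, character(1)),
              names(categories)
            ))
  structure(
    list(snp = panel$snp, chrom = panel$chrom, pos = panel$pos,
         matrix = mat, provenance = prov),
    class = "annotation_matrix"
  )
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("<annotation_matrix> %d SNPs x %d categories\n",
              nrow(x$matrix), ncol(x$matrix)))
  sz <- colSums(x$matrix)
  for (nm in colnames(x$matrix))
    cat(sprintf("  %-24s %6d SNPs\n", nm, sz[[nm]]))
  invisible(x)
}

#' Per-category SNP counts
#' @param annots An [annotation_matrix()].
#' @return Named integer vector of member counts.
#' @export
category_sizes <- function(annots) colSums(annots$matrix)

#' Select eQTL SNPs per probe under the five inclusion strategies
#'
#' Operates per probe over that probe's significant eQTLs only and returns
#' the union across probes. Strategies: `lead` (smallest p), `median_p` (the
#' SNP whose p is the order-statistic median; the lower of the two middle
#' values for even counts), `mean_p` (the SNP whose p is closest to the
#' arithmetic mean of the probe's significant p-values), `top10` (the ten
#' smallest p; all if fewer than ten), `all_significant` (every flagged SNP).
#' Ties are broken by genomic position (smaller first) when a panel is
#' supplied, otherwise by SNP id.
#'
#' @param catalog An `eqtl_catalog` data frame with significance flags.
#' @param strategy One of `"lead"`, `"median_p"`, `"mean_p"`, `"top10"`,
#'   `"all_significant"`.
#' @param panel Optional [variant_panel()] used for positional tie-breaking.
#' @return Character vector of selected SNP ids.
#' @export
select_eqtl_snps <- function(catalog,
                             strategy = c("lead", "median_p", "mean_p",
                                          "top10", "all_significant"),
                             panel = NULL) {
  strategy <- match.arg(strategy)
  sig <- catalog[catalog$significant %in% TRUE, , drop = FALSE]
  if (!nrow(sig)) return(character())
  tiebreak <- if (!is.null(panel)) {
    panel$pos[match(sig$snp, panel$snp)]
  } else {
    xtfrm(sig$snp)
  }
  key <- paste(sig$tissue, sig$probe, sep = "\r")
  groups <- split(seq_len(nrow(sig)), key)
  picked <- lapply(groups, function(ii) {
    ord <- ii[order(sig$p[ii], tiebreak[ii])]
    switch(strategy,
      lead = ord[1L],
      median_p = ord[ceiling(length(ord) / 2)],
      mean_p = {
        tgt <- mean(sig$p[ii])
        # distances rounded to 12 significant digits so that p-values
        # equidistant at printed precision tie (and break by position)
        d <- signif(abs(sig$p[ii] - tgt), 12)
        ii[order(d, tiebreak[ii])][1L]
      },
      top10 = ord[seq_len(min(10L, length(ord)))],
      all_significant = ii
    )
  })
  unique(sig$snp[unlist(picked, use.names = FALSE)])
}

#' Proximity-window annotations around a SNP set
#'
#' For each window half-width (default 100 and 500 bp), the category of all
#' panel SNPs whose distance to the nearest member SNP is at most the
#' half-width (inclusive), excluding the members themselves. These guard
#' annotations absorb signal that merely sits next to an eQTL.
#'
#' @param snps Character vector of member SNP ids.
#' @param panel A [variant_panel()].
#' @param windows Integer vector of half-widths in bp.
#' @return Named list (`window_100bp`, ...) of SNP id character vectors.
#' @export
window_annotations <- function(snps, panel, windows = c(100L, 500L)) {
  member <- panel$snp %in% snps
  out <- setNames(vector("list", length(windows)),
                  sprintf("window_%dbp", windows))
  if (!any(member)) {
    out[] <- list(character())
    return(out)
  }
  mpos <- sort(panel$pos[member])
  idx <- findInterval(panel$pos, mpos)
  d_left <- ifelse(idx >= 1, panel$pos - mpos[pmax(idx, 1L)], Inf)
  d_right <- ifelse(idx < length(mpos),
                    mpos[pmin(idx + 1L, length(mpos))] - panel$pos, Inf)
  mind <- pmin(d_left, d_right)
  for (k in seq_along(windows)) {
    out[[k]] <- panel$snp[mind <= windows[k] & !member]
  }
  out
}

#' Gene-centric window annotation
#'
#' All panel SNPs within `window_bp` (default 1 Mbp, inclusive) of the span
#' of any listed gene, i.e. positions in `[start - window_bp, end + window_bp]`.
#'
#' @param gene_ids Genes to include.
#' @param gene_coords Data frame with columns gene, chrom, start, end
#'   (1-based inclusive).
#' @param panel A [variant_panel()].
#' @param window_bp Window in bp.
#' @return Character vector of SNP ids.
#' @export
gene_window_annotation <- function(gene_ids, gene_coords, panel,
                                   window_bp = 1e6) {
  if (!length(gene_ids)) return(character())
  miss <- setdiff(gene_ids, gene_coords$gene)
  if (length(miss))
    stop("no coordinates for gene(s): ", paste(miss, collapse = ", "))
  gc <- gene_coords[gene_coords$gene %in% gene_ids &
                      gene_coords$chrom == panel$chrom, , drop = FALSE]
  if (!nrow(gc)) return(character())
  ir <- IRanges::reduce(IRanges::IRanges(
    start = pmax(gc$start - window_bp, 1),
    end = gc$end + window_bp
  ))
  hit <- IRanges::overlapsAny(IRanges::IRanges(panel$pos, width = 1L), ir)
  panel$snp[hit]
}

#' Union of annotation categories
#' @param categories List of SNP id character vectors.
#' @return Character vector: the union.
#' @export
union_annotation <- function(categories) {
  unique(unlist(categories, use.names = FALSE)) %||% character()
}

#' Intersect an eQTL category with genomic intervals
#'
#' Returns the member SNPs whose position falls inside at least one interval.
#' BED semantics are 0-based half-open, so a 1-based SNP position p is covered
#' by `[start, end)` iff `start < p <= end`; interval sets read by
#' [read_bed()] already carry the conversion.
#'
#' @param eqtl_snps Character vector of category member SNP ids.
#' @param intervals A `GRanges`, or a path to a BED file.
#' @param panel A [variant_panel()].
#' @return Character vector of SNP ids in the intersection.
#' @export
intersect_with_intervals <- function(eqtl_snps, intervals, panel) {
  if (is.character(intervals)) intervals <- read_bed(intervals)
  member <- panel$snp %in% eqtl_snps
  if (!any(member) || length(intervals) == 0L) return(character())
  snp_gr <- GenomicRanges::GRanges(
    seqnames = panel$chrom,
    ranges = IRanges::IRanges(panel$pos, width = 1L)
  )
  covered <- IRanges::overlapsAny(snp_gr, intervals)
  panel$snp[member & covered]
}

#' eQTLs of the top-decile differentially expressed genes of a tissue
#'
#' Takes the top `ceiling(0.10 * G)` genes of the tissue's
#' differential-expression ranking and returns the significant eQTL SNPs of
#' those genes from any supplied catalog, regardless of discovery tissue.
#'
#' @param catalogs A single `eqtl_catalog` or a list of them.
#' @param de_ranks Data frame gene/tissue/rank (rank 1 = most DE).
#' @param tissue Tissue label selecting the ranking.
#' @return Character vector of SNP ids.
#' @export
top_decile_de_eqtls <- function(catalogs, de_ranks, tissue) {
  if (is.data.frame(catalogs)) catalogs <- list(catalogs)
  dr <- de_ranks[de_ranks$tissue == tissue, , drop = FALSE]
  if (!nrow(dr)) stop("tissue absent from DE ranks: ", tissue)
  d <- ceiling(0.10 * nrow(dr))
  top <- dr$gene[order(dr$rank)][seq_len(d)]
  hits <- lapply(catalogs, function(ct)
    ct$snp[ct$significant %in% TRUE & ct$gene %in% top])
  unique(unlist(hits, use.names = FALSE)) %||% character()
}
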