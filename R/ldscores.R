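#' Squared correlation between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors of SNPs `j` and `k`.
#' With `adjusted = TRUE` the finite-sample correction
#' `r2 - (1 - r2) / (n - 2)` is applied, which removes the upward bias of the
#' sample r-squared (expected value 1/(n-1) for independent SNPs).
#'
#' @param panel A [variant_panel()].
#' @param j,k SNP column indices.
#' @param adjusted Apply the finite-sample correction?
#' @return A single numeric value.
#' @export
pairwise_r2 <- function(panel, j, k, adjusted = FALSE) {
  g1 <- panel$genotypes[, j]
  g2 <- panel$genotypes[, k]
  if (sd(g1) == 0) stop("monomorphic SNP: ", panel$snp[j])
  if (sd(g2) == 0) stop("monomorphic SNP: ", panel$snp[k])
  r2 <- cor(g1, g2)^2
  if (adjusted) r2 <- r2 - (1 - r2) / (panel$n_individuals - 2)
  r2
}

#' Stratified LD scores
#'
#' For every SNP j and annotation category c, computes
#' `l(j,c) = sum_k a_ck * r2_jk` over all SNPs k within `window_bp` of j
#' (inclusive at both ends; the self-pair with r2 = 1 is included). With
#' `adjusted = TRUE` (the default, standard for regression use) each pairwise
#' r-squared carries the finite-sample correction of [pairwise_r2()];
#' adjusted scores can be slightly negative, unadjusted scores are
#' non-negative and non-decreasing in the window.
#'
#' Computation is chunked: standardized dosages are cross-multiplied against
#' the union window of each chunk of SNPs and out-of-window pairs are masked,
#' so the cost is O(M * window-SNPs * n) rather than O(M^2 * n).
#'
#' @param panel A [variant_panel()].
#' @param annots An [annotation_matrix()] aligned to the panel.
#' @param window_bp Neighbor window in bp (physical distance; default 1 Mbp).
#' @param adjusted Apply the finite-sample r-squared correction?
#' @param chunk_size SNPs per computation chunk.
#' @return An object of class `stratified_ldscores`: snp ids, an M x C score
#'   matrix (one column per category), the window and the adjustment flag.
#' @export
stratified_ld_scores <- function(panel, annots, window_bp = 1e6,
                                 adjusted = TRUE, chunk_size = 256L) {
  stopifnot(inherits(panel, "variant_panel"),
            inherits(annots, "annotation_matrix"))
  if (!is.numeric(window_bp) || window_bp <= 0)
    stop("window_bp must be positive")
  if (!identical(annots$snp, panel$snp))
    stop("annotation matrix is not aligned to the panel")

  Zs <- scale(panel$genotypes)
  mono <- attr(Zs, "scaled:scale") == 0
  if (any(mono)) stop("monomorphic SNP: ",
                      paste(panel$snp[mono], collapse = ", "))
  n <- panel$n_individuals
  M <- length(panel$snp)
  pos <- as.numeric(panel$pos)
  A <- annots$matrix
  storage.mode(A) <- "double"

  lo <- findInterval(pos - window_bp, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + window_bp, pos)

  S <- matrix(0, M, ncol(A), dimnames = list(NULL, colnames(A)))
  starts <- seq.int(1L, M, by = chunk_size)
  for (s in starts) {
    jj <- s:min(s + chunk_size - 1L, M)
    rng <- min(lo[jj]):max(hi[jj])
    R <- crossprod(Zs[, jj, drop = FALSE], Zs[, rng, drop = FALSE]) / (n - 1)
    r2 <- R * R
    if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
    inwin <- outer(lo[jj], rng, "<=") & outer(hi[jj], rng, ">=")
    r2[!inwin] <- 0
    S[jj, ] <- r2 %*% A[rng, , drop = FALSE]
  }
  structure(
    list(snp = panel$snp, scores = S, window_bp = window_bp,
         adjusted = adjusted, n_individuals = n),
    class = "stratified_ldscores"
  )
}

#' @export
print.stratified_ldscores <- function(x, ...) {
  cat(sprintf("<stratified_ldscores> %d SNPs x %d categories, window %g bp, %s\n",
              nrow(x$scores), ncol(x$scores), x$window_bp,
              if (x$adjusted) "adjusted r2" else "raw r2"))
  invisible(x)
}

# Restrict an LD score object to a subset of categories.
subset_ldscores <- function(ldscores, categories) {
  miss <- setdiff(categories, colnames(ldscores$scores))
  if (length(miss)) stop("unknown LD score categories: ",
                         paste(miss, collapse = ", "))
  out <- ldscores
  out$scores <- ldscores$scores[, categories, drop = FALSE]
  out
}

#' Per-category annotation summaries
#'
#' For each annotation category reports the number of member SNPs and the
#' mean and median total (base) LD score and mean MAF over members only —
#' the diagnostics used to compare eQTL annotations against the whole
#' baseline when choosing a SNP-inclusion strategy.
#'
#' @param annots An [annotation_matrix()].
#' @param ldscores Matching [stratified_ld_scores()]; the `base` column
#'   provides the total LD score.
#' @param panel The matching [variant_panel()] (for MAF).
#' @return A data frame: category, n_snps, mean_ld, median_ld, mean_maf.
#'   Empty categories get count 0 and NA statistics.
#' @export
annotation_ld_metrics <- function(annots, ldscores, panel) {
  stopifnot(identical(annots$snp, ldscores$snp),
            identical(annots$snp, panel$snp))
  base_l <- ldscores$scores[, "base"]
  cats <- colnames(annots$matrix)
  rows <- lapply(cats, function(cc) {
    m <- annots$matrix[, cc] == 1
    if (!any(m)) {
      data.frame(category = cc, n_snps = 0L, mean_ld = NA_real_,
                 median_ld = NA_real_, mean_maf = NA_real_)
    } else {
      data.frame(category = cc, n_snps = sum(m), mean_ld = mean(base_l[m]),
                 median_ld = median(base_l[m]), mean_maf = mean(panel$maf[m]))
    }
  })
  do.call(rbind, rows)
}
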