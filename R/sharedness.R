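# single tissue label of a catalog
tissue_of <- function(catalog) {
  t <- unique(catalog$tissue)
  if (length(t) > 1L)
    stop("catalog mixes tissues: ", paste(t, collapse = ", "))
  t
}

#' Broad tissue-sharedness classification
#'
#' Gene-level rule: an eQTL discovered in tissue A is *shared* iff its gene
#' has at least one significant eQTL in the tissue-B catalog, else
#' *specific*; symmetric for tissue B. SNP identity across tissues is
#' irrelevant — the same SNP tagging different genes in the two tissues is
#' tissue-specific in each.
#'
#' @param blood,brain `eqtl_catalog` data frames for the two tissues (any
#'   two tissue labels; names follow the classic blood/brain design).
#' @return A `sharedness_labels` data frame (snp, probe, gene, tissue,
#'   label, definition) with one row per significant eQTL record; labels are
#'   `<tissue>_shared` / `<tissue>_specific`.
#' @export
broad_classify <- function(blood, brain) {
  label_one <- function(cat_a, genes_b, t_a) {
    sig <- cat_a[cat_a$significant %in% TRUE, , drop = FALSE]
    if (!nrow(sig)) return(NULL)
    data.frame(
      snp = sig$snp, probe = sig$probe, gene = sig$gene, tissue = sig$tissue,
      label = ifelse(sig$gene %in% genes_b,
                     paste0(t_a, "_shared"), paste0(t_a, "_specific")),
      definition = "broad"
    )
  }
  t_a <- tissue_of(blood)
  t_b <- tissue_of(brain)
  genes_a <- unique(blood$gene[blood$significant %in% TRUE])
  genes_b <- unique(brain$gene[brain$significant %in% TRUE])
  out <- rbind(label_one(blood, genes_b, t_a), label_one(brain, genes_a, t_b))
  rownames(out) <- NULL
  class(out) <- c("sharedness_labels", "data.frame")
  out
}

#' Pairwise probe-set correlations of eQTL effect sizes
#'
#' For each gene, lists the significant eQTLs of every probe and computes the
#' Pearson correlation of effect sizes over the SNPs significant in *both*
#' probes of a pair. Effect sizes are allele-harmonized first: when a SNP's
#' effect allele differs between the two probes' records, the sign of one
#' beta is flipped if the alleles are swapped, and the SNP is dropped from
#' the overlap (with a logged count) if the allele pairs are irreconcilable.
#' Correlations based on fewer than `missing_floor` overlapping eQTLs are
#' flagged missing.
#'
#' @param blood,brain `eqtl_catalog` data frames.
#' @param within_tissue Also compute within-tissue probe pairs (pair classes
#'   `blood-blood` / `brain-brain` in addition to the cross-tissue class)?
#' @param missing_floor Minimum overlap below which `missing` is set
#'   (default 10).
#' @param effect Correlate raw betas (default) or Z-scores (beta/se).
#' @return Data frame of class `probe_pair_correlations`: gene, probe_a,
#'   probe_b, tissue_a, tissue_b, pair_class, r, n_overlap, missing. The
#'   number of allele-dropped SNPs is in `attr(, "dropped_alleles")`.
#' @export
probe_pair_correlations <- function(blood, brain, within_tissue = FALSE,
                                    missing_floor = 10L,
                                    effect = c("beta", "z")) {
  effect <- match.arg(effect)
  t_a <- tissue_of(blood)
  t_b <- tissue_of(brain)
  prep <- function(cat_t) {
    sig <- cat_t[cat_t$significant %in% TRUE, , drop = FALSE]
    sig$eff <- if (effect == "beta") sig$beta else sig$beta / sig$se
    split(sig, sig$probe)
  }
  pa <- prep(blood)
  pb <- prep(brain)
  probe_gene <- c(
    vapply(pa, function(d) d$gene[1L], character(1)),
    vapply(pb, function(d) d$gene[1L], character(1))
  )
  dropped <- 0L
  rows <- list()

  pair_cor <- function(da, db) {
    ov <- intersect(da$snp, db$snp)
    ia <- match(ov, da$snp)
    ib <- match(ov, db$snp)
    ea <- da$eff[ia]
    eb <- db$eff[ib]
    if (!is.null(da$a1) && !is.null(db$a1)) {
      same <- da$a1[ia] == db$a1[ib] & da$a2[ia] == db$a2[ib]
      swapped <- da$a1[ia] == db$a2[ib] & da$a2[ia] == db$a1[ib]
      eb[swapped] <- -eb[swapped]
      bad <- !(same | swapped)
      if (any(bad)) {
        dropped <<- dropped + sum(bad)
        ea <- ea[!bad]
        eb <- eb[!bad]
      }
    }
    k <- length(ea)
    r <- if (k >= 2 && sd(ea) > 0 && sd(eb) > 0) cor(ea, eb) else NA_real_
    list(r = r, n = k)
  }

  emit <- function(probes_1, probes_2, t1, t2, cls, same_set) {
    for (g in unique(probe_gene)) {
      p1 <- names(probes_1)[vapply(probes_1, function(d) d$gene[1L],
                                   character(1)) == g]
      p2 <- names(probes_2)[vapply(probes_2, function(d) d$gene[1L],
                                   character(1)) == g]
      if (!length(p1) || !length(p2)) next
      for (i in seq_along(p1)) {
        jj <- if (same_set) seq_along(p2)[seq_along(p2) > i] else seq_along(p2)
        for (j in jj) {
          pc <- pair_cor(probes_1[[p1[i]]], probes_2[[p2[j]]])
          rows[[length(rows) + 1L]] <<- data.frame(
            gene = g, probe_a = p1[i], probe_b = p2[j],
            tissue_a = t1, tissue_b = t2, pair_class = cls,
            r = pc$r, n_overlap = pc$n,
            missing = pc$n < missing_floor
          )
        }
      }
    }
  }

  emit(pa, pb, t_a, t_b, "cross", same_set = FALSE)
  if (within_tissue) {
    emit(pa, pa, t_a, t_a, paste(t_a, t_a, sep = "-"), same_set = TRUE)
    emit(pb, pb, t_b, t_b, paste(t_b, t_b, sep = "-"), same_set = TRUE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), probe_a = character(),
               probe_b = character(), tissue_a = character(),
               tissue_b = character(), pair_class = character(),
               r = numeric(), n_overlap = integer(), missing = logical())
  rownames(out) <- NULL
  if (dropped > 0)
    message("dropped ", dropped, " SNP(s) with irreconcilable alleles from probe overlaps")
  attr(out, "dropped_alleles") <- dropped
  class(out) <- c("probe_pair_correlations", "data.frame")
  out
}

#' Per-gene summaries of probe-pair correlations
#'
#' Mean and median correlation and mean overlap per gene within each pair
#' class, excluding missing pairs. Genes whose pairs are all missing are
#' reported with NA statistics.
#'
#' @param pairs Output of [probe_pair_correlations()].
#' @return Data frame: gene, pair_class, n_pairs, mean_r, median_r,
#'   mean_n_overlap.
#' @export
gene_correlation_summary <- function(pairs) {
  key <- interaction(pairs$gene, pairs$pair_class, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(pairs)), key), function(ii) {
    use <- ii[!pairs$missing[ii] & !is.na(pairs$r[ii])]
    data.frame(
      gene = pairs$gene[ii[1L]],
      pair_class = pairs$pair_class[ii[1L]],
      n_pairs = length(use),
      mean_r = if (length(use)) mean(pairs$r[use]) else NA_real_,
      median_r = if (length(use)) median(pairs$r[use]) else NA_real_,
      mean_n_overlap = if (length(use)) mean(pairs$n_overlap[use]) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Narrow tissue-sharedness classification
#'
#' An eQTL record is *shared* iff its probe has at least one cross-tissue
#' probe pair (same gene, other tissue) with `n_overlap >= min_overlap` and
#' correlation strictly above `r_cutoff`; otherwise *specific*. Defaults are
#' the 35-SNP overlap and 0.35 correlation cutoffs; note the classification
#' threshold is distinct from the 10-overlap missingness floor of
#' [probe_pair_correlations()].
#'
#' @param blood,brain `eqtl_catalog` data frames.
#' @param min_overlap Minimum overlapping significant eQTLs (inclusive).
#' @param r_cutoff Correlation cutoff (strict inequality).
#' @param pairs Optional precomputed [probe_pair_correlations()] (cross-tissue
#'   pairs are used).
#' @return A `sharedness_labels` data frame as in [broad_classify()], with
#'   `definition = "narrow"`.
#' @export
narrow_classify <- function(blood, brain, min_overlap = 35L, r_cutoff = 0.35,
                            pairs = NULL) {
  if (is.null(pairs)) pairs <- probe_pair_correlations(blood, brain)
  cross <- pairs[pairs$pair_class == "cross", , drop = FALSE]
  ok <- cross[!is.na(cross$r) & cross$n_overlap >= min_overlap &
                cross$r > r_cutoff, , drop = FALSE]
  shared_a <- unique(ok$probe_a)
  shared_b <- unique(ok$probe_b)
  label_one <- function(cat_t, shared_probes, t) {
    sig <- cat_t[cat_t$significant %in% TRUE, , drop = FALSE]
    if (!nrow(sig)) return(NULL)
    data.frame(
      snp = sig$snp, probe = sig$probe, gene = sig$gene, tissue = sig$tissue,
      label = ifelse(sig$probe %in% shared_probes,
                     paste0(t, "_shared"), paste0(t, "_specific")),
      definition = "narrow"
    )
  }
  out <- rbind(label_one(blood, shared_a, tissue_of(blood)),
               label_one(brain, shared_b, tissue_of(brain)))
  rownames(out) <- NULL
  class(out) <- c("sharedness_labels", "data.frame")
  out
}
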