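# Vectorized per-SNP marginal OLS of one phenotype on each dosage column.
# Returns beta, se, p (two-sided t) for every column with non-zero variance.
marginal_ols <- function(G, y) {
  n <- length(y)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  ok <- sxx > 0
  sxy <- as.vector(crossprod(gc, yc))
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  sse <- pmax(sum(yc^2) - beta * sxy, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  list(beta = beta, se = se, p = pmax(p, 1e-300), ok = ok)
}

#' Generate two-tissue eQTL catalogs with known ground truth
#'
#' Places `n_genes` genes in the panel's LD blocks, designates a fraction of
#' them as tissue-shared (per-causal-SNP effects on expression drawn with
#' correlation `cross_tissue_effect_corr` across the two tissues) and the rest
#' as tissue-specific (expressed, and therefore measured, in only one tissue).
#' For each tissue a fresh cohort of `eqtl_sample_sizes[tissue]` individuals
#' is drawn from the same blockwise LD process as the panel; probe-level
#' expression is the genetic value of the gene's causal SNPs plus Gaussian
#' noise scaled so the causal SNPs explain `expr_h2` of the variance. Every
#' cis SNP (within `cis_window_bp` of the gene span) is tested against every
#' probe by per-SNP OLS; q-values are Benjamini-Hochberg within tissue and
#' rows with q < 0.05 are flagged significant.
#'
#' @param panel A [variant_panel()] from [gen_reference_panel()].
#' @param config The same [simulation_config()].
#' @return A list with `catalogs` (named list of two `eqtl_catalog`
#'   data frames: snp, probe, gene, tissue, a1, a2, beta, se, p, q,
#'   significant), `truth` (a `ground_truth` object with the shared/specific
#'   gene sets and the causal SNP -> (gene, tissue, beta) map) and
#'   `gene_coords` (gene, chrom, start, end; 1-based inclusive).
#' @export
gen_eqtl_catalogs <- function(panel, config) {
  stopifnot(inherits(panel, "variant_panel"),
            inherits(config, "simulation_config"))
  tissues <- names(config$eqtl_sample_sizes)
  if (length(tissues) != 2L)
    stop("catalog generation needs exactly two tissues in eqtl_sample_sizes")
  set.seed(config$seed + 1000L)

  G <- config$n_genes
  rho <- config$cross_tissue_effect_corr
  blocks <- sort(unique(panel$block %||% rep(1L, length(panel$snp))))
  gene_block <- blocks[((seq_len(G) - 1L) %% length(blocks)) + 1L]
  gene_id <- sprintf("gene%03d", seq_len(G))

  # gene spans centered in their block
  coords <- lapply(seq_len(G), function(i) {
    bpos <- panel$pos[panel$block == gene_block[i]]
    ctr <- round(mean(range(bpos)))
    c(start = max(ctr - 5000L, 1L), end = ctr + 5000L)
  })
  gene_coords <- data.frame(
    gene = gene_id, chrom = panel$chrom,
    start = vapply(coords, `[[`, numeric(1), "start"),
    end = vapply(coords, `[[`, numeric(1), "end")
  )

  n_shared <- round(config$prop_shared_genes * G)
  shared_idx <- if (n_shared > 0) sort(sample.int(G, n_shared)) else integer()
  specific_idx <- setdiff(seq_len(G), shared_idx)
  specific_tissue <- setNames(
    tissues[(seq_along(specific_idx) - 1L) %% 2L + 1L],
    gene_id[specific_idx]
  )

  # causal SNPs and effects (standardized-genotype scale)
  sd_b <- sqrt(config$expr_h2 / config$n_causal_per_gene)
  causal <- vector("list", G)
  effects <- vector("list", G)  # list of matrices k x 2 (per tissue)
  for (i in seq_len(G)) {
    lo <- gene_coords$start[i] - config$cis_window_bp
    hi <- gene_coords$end[i] + config$cis_window_bp
    in_cis <- panel$pos >= lo & panel$pos <= hi
    if (!any(in_cis)) stop("gene ", gene_id[i], " has no cis SNPs")
    pool <- which(in_cis & panel$block == gene_block[i])
    if (!length(pool)) pool <- which(in_cis)
    k <- min(config$n_causal_per_gene, length(pool))
    causal[[i]] <- sort(sample(pool, k))
    b1 <- rnorm(k, sd = sd_b)
    b2 <- rho * b1 + sqrt(1 - rho^2) * rnorm(k, sd = sd_b)
    eff <- cbind(b1, b2)
    colnames(eff) <- tissues
    if (i %in% specific_idx) {
      other <- setdiff(tissues, specific_tissue[gene_id[i]])
      eff[, other] <- NA_real_  # not expressed there
    }
    effects[[i]] <- eff
  }

  P <- config$probes_per_gene_per_tissue
  catalogs <- setNames(vector("list", 2L), tissues)
  causal_rows <- list()
  for (t in tissues) {
    nt <- config$eqtl_sample_sizes[[t]]
    Gt <- sim_genotypes(nt, panel$sim_freq %||% panel$maf,
                        panel$block %||% rep(1L, length(panel$snp)),
                        config$within_block_ld)
    rows <- list()
    for (i in seq_len(G)) {
      b <- effects[[i]][, t]
      if (anyNA(b)) next  # gene not expressed in this tissue
      ci <- causal[[i]]
      Zc <- scale(Gt[, ci, drop = FALSE])
      Zc[, attr(Zc, "scaled:scale") == 0] <- 0
      gv <- as.vector(Zc %*% b)
      vg <- var(gv)
      noise_sd <- if (vg > 0)
        sqrt(vg * (1 - config$expr_h2) / config$expr_h2) else 1
      lo <- gene_coords$start[i] - config$cis_window_bp
      hi <- gene_coords$end[i] + config$cis_window_bp
      cis <- which(panel$pos >= lo & panel$pos <= hi)
      for (pp in seq_len(P)) {
        y <- gv + rnorm(nt, sd = noise_sd)
        st <- marginal_ols(Gt[, cis, drop = FALSE], y)
        keep <- st$ok
        rows[[length(rows) + 1L]] <- data.frame(
          snp = panel$snp[cis[keep]],
          probe = sprintf("%s_%s_p%d", gene_id[i], t, pp),
          gene = gene_id[i],
          tissue = t,
          a1 = panel$a1[cis[keep]],
          a2 = panel$a2[cis[keep]],
          beta = st$beta[keep], se = st$se[keep], p = st$p[keep]
        )
      }
      causal_rows[[length(causal_rows) + 1L]] <- data.frame(
        snp = panel$snp[ci], gene = gene_id[i], tissue = t, beta = b
      )
    }
    cat_t <- do.call(rbind, rows)
    cat_t$q <- p.adjust(cat_t$p, method = "BH")
    cat_t$significant <- cat_t$q < 0.05
    rownames(cat_t) <- NULL
    class(cat_t) <- c("eqtl_catalog", "data.frame")
    catalogs[[t]] <- cat_t
  }

  truth <- structure(
    list(
      true_shared_genes = gene_id[shared_idx],
      true_specific_genes = gene_id[specific_idx],
      specific_tissue = specific_tissue,
      causal_eqtl_map = do.call(rbind, causal_rows),
      true_tau = config$tau_true
    ),
    class = "ground_truth"
  )
  list(catalogs = catalogs, truth = truth, gene_coords = gene_coords)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d shared genes, %d specific genes, %d causal eQTL records\n",
              length(x$true_shared_genes), length(x$true_specific_genes),
              nrow(x$causal_eqtl_map)))
  invisible(x)
}
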