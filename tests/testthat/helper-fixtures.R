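# Small builders and independent oracles shared across the suite.

# panel straight from a raw dosage matrix (columns = SNPs)
tiny_panel <- function(genotypes, pos = NULL, snp = NULL) {
  M <- ncol(genotypes)
  variant_panel(
    snp = snp %||% sprintf("s%02d", seq_len(M)),
    chrom = "1",
    pos = pos %||% (seq_len(M) * 1000L),
    a1 = rep("A", M), a2 = rep("G", M),
    genotypes = genotypes
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_genotypes <- function(n, M, seed) {
  set.seed(seed)
  matrix(rbinom(n * M, 2L, runif(M, 0.1, 0.5)[rep(seq_len(M), each = n)]),
         n, M)
}

# minimal eQTL catalog rows with recycling
make_catalog <- function(snp, probe, gene, tissue, p = 1e-6, beta = 0.1,
                         se = 0.02, significant = TRUE,
                         a1 = "A", a2 = "G", q = NULL) {
  d <- data.frame(snp = snp, probe = probe, gene = gene, tissue = tissue,
                  a1 = a1, a2 = a2, beta = beta, se = se, p = p,
                  q = q %||% p, significant = significant)
  class(d) <- c("eqtl_catalog", "data.frame")
  d
}

# O(M^2) brute-force stratified LD scores
oracle_ld_scores <- function(panel, annot, window_bp, adjusted) {
  M <- length(panel$snp)
  out <- matrix(0, M, ncol(annot$matrix),
                dimnames = list(NULL, colnames(annot$matrix)))
  for (j in seq_len(M)) {
    for (k in seq_len(M)) {
      if (abs(panel$pos[k] - panel$pos[j]) <= window_bp) {
        r2 <- cor(panel$genotypes[, j], panel$genotypes[, k])^2
        if (adjusted) r2 <- r2 - (1 - r2) / (panel$n_individuals - 2)
        out[j, ] <- out[j, ] + r2 * annot$matrix[k, ]
      }
    }
  }
  out
}

# textbook Benjamini-Hochberg step-up rejection flags
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= alpha * seq_len(m) / m)
  rej <- rep(FALSE, m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# gene-level accuracy of sharedness labels against ground truth
gene_label_accuracy <- function(labels, truth) {
  genes <- unique(labels$gene)
  pred_shared <- unique(labels$gene[grepl("_shared$", labels$label)])
  mean((genes %in% pred_shared) == (genes %in% truth$true_shared_genes))
}
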