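# Latent-Gaussian AR(1) haplotype process: within each block, adjacent latent
# variables correlate at phi; alleles arise by thresholding at qnorm(freq).
sim_haplotype_latent <- function(n, M, block, phi) {
  eps <- matrix(rnorm(n * M), n, M)
  if (phi <= 0 || M == 1L) return(eps)
  s <- sqrt(1 - phi^2)
  z <- eps
  same_block <- c(FALSE, block[-1L] == block[-M])
  for (j in 2:M) {
    if (same_block[j]) z[, j] <- phi * z[, j - 1L] + s * eps[, j]
  }
  z
}

# Diploid dosages as the sum of two independent haplotypes drawn from the
# same blockwise AR(1) latent process.
sim_genotypes <- function(n, freq, block, phi) {
  M <- length(freq)
  thr <- matrix(qnorm(freq), n, M, byrow = TRUE)
  g <- (sim_haplotype_latent(n, M, block, phi) < thr) +
       (sim_haplotype_latent(n, M, block, phi) < thr)
  storage.mode(g) <- "double"
  g
}

#' Generate a synthetic LD reference panel
#'
#' Simulates a diploid genotype panel on one chromosome with
#' `config$n_ld_blocks` mutually independent LD blocks. Within a block,
#' haplotypes follow a first-order autoregressive latent-allele process with
#' parameter `within_block_ld`, so adjacent SNPs are correlated and LD decays
#' geometrically with SNP distance; across blocks SNPs are independent.
#' Generating allele frequencies are uniform on `[0.05, 0.5]`; SNPs whose
#' empirical MAF falls below 0.01 are removed, and removal of an entire block
#' is an error (it would silently change the LD structure).
#'
#' @param config A [simulation_config()].
#' @return A [variant_panel()] with strictly increasing positions and
#'   empirical MAF >= 0.01 for every retained SNP.
#' @export
gen_reference_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  M <- config$n_snps
  B <- config$n_ld_blocks
  n <- config$n_ref_individuals
  sizes <- block_sizes(M, B)
  block <- rep.int(seq_len(B), sizes)

  freq <- runif(M, 0.05, 0.5)
  gaps <- sample(500:1500, M, replace = TRUE)
  boundary <- c(FALSE, block[-1L] != block[-M])
  gaps[boundary] <- gaps[boundary] + 10000L  # widen inter-block spacing
  pos <- cumsum(as.numeric(gaps))
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, M, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))

  G <- sim_genotypes(n, freq, block, config$within_block_ld)
  f <- colMeans(G) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= 0.01
  if (!any(keep)) stop("MAF filter removed every SNP in LD block(s): ",
                       paste(seq_len(B), collapse = ", "))
  if (!all(keep)) {
    left <- tabulate(block[keep], nbins = B)
    dead <- which(left == 0L)
    if (length(dead))
      stop("MAF filter removed every SNP in LD block(s): ",
           paste(dead, collapse = ", "))
  }
  idx <- which(keep)
  variant_panel(
    snp = sprintf("rs%06d", seq_len(M))[idx],
    chrom = "1",
    pos = pos[idx],
    a1 = a1[idx], a2 = a2[idx],
    genotypes = G[, idx, drop = FALSE],
    block = block[idx],
    sim_freq = freq[idx]
  )
}
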