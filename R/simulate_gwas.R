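#' Simulate GWAS summary statistics under a partitioned polygenic model
#'
#' Draws per-SNP chi-square statistics with mean
#' `E[chi2_j] = 1 + N*a + N * sum_c tau_c * l(j,c)`, i.e. the linear model
#' that stratified LD score regression fits: `l(j,c)` are the stratified LD
#' scores of the supplied annotation categories and `tau_c` the per-SNP
#' heritability coefficients. Each statistic is `m_j * X` with
#' `X ~ chi-square(1)`, so the mean equals the model mean; model means below 1
#' are floored at 1 (a chi-square mean below the null is unphysical) with a
#' warning counting the floored SNPs. Z-scores carry an independent random
#' sign per SNP.
#'
#' @param panel The [variant_panel()] the LD scores were computed on.
#' @param annots The [annotation_matrix()] (alignment check only).
#' @param ldscores [stratified_ld_scores()] for `annots` on `panel`.
#' @param config A [simulation_config()]; supplies defaults for `tau`,
#'   `intercept_a`, `n` and the seed.
#' @param tau Named vector of true tau per category; names must match the LD
#'   score columns.
#' @param intercept_a Confounding term a.
#' @param n GWAS sample size N.
#' @return A `gwas_sumstats` data frame: snp, a1, a2, z, n.
#' @export
gen_gwas_sumstats <- function(panel, annots, ldscores, config,
                              tau = config$tau_true,
                              intercept_a = config$intercept_a,
                              n = config$gwas_n) {
  stopifnot(inherits(ldscores, "stratified_ldscores"))
  if (is.null(tau)) stop("tau_true not set (supply `tau` or config$tau_true)")
  cats <- colnames(ldscores$scores)
  if (!setequal(names(tau), cats))
    stop("names of tau must match LD score categories: ",
         paste(cats, collapse = ", "))
  if (!identical(ldscores$snp, panel$snp))
    stop("ldscores are not aligned to the panel")
  if (!is.null(annots) && !identical(annots$snp, panel$snp))
    stop("annotation matrix is not aligned to the panel")
  set.seed(config$seed + 2000L)

  tau <- tau[cats]
  M <- length(panel$snp)
  mu <- 1 + n * intercept_a + n * as.vector(ldscores$scores %*% tau)
  floored <- mu < 1
  if (any(floored))
    warning(sum(floored), " SNPs had model mean chi-square below 1; floored at 1")
  chi2 <- pmax(mu, 1) * rchisq(M, df = 1)
  z <- sqrt(chi2) * sample(c(-1, 1), M, replace = TRUE)
  out <- data.frame(
    snp = panel$snp, a1 = panel$a1, a2 = panel$a2,
    z = z, n = as.integer(n)
  )
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}
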