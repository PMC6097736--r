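# small panel + LD scores reused across regression tests
sldsr_fixture <- function(seed = 51L, M = 1200L, n_cat_frac = 0.25) {
  cfg <- simulation_config(n_ref_individuals = 120L, n_snps = M,
                           n_ld_blocks = max(M %/% 50L, 1L),
                           within_block_ld = 0.9, gwas_n = 20000L,
                           seed = seed)
  panel <- gen_reference_panel(cfg)
  set.seed(seed + 1L)
  ids <- sample(panel$snp, round(n_cat_frac * length(panel$snp)))
  annot <- annotation_matrix(panel, list(eqtl = ids))
  ld <- stratified_ld_scores(panel, annot, window_bp = 1e6, adjusted = TRUE)
  list(cfg = cfg, panel = panel, annot = annot, ld = ld)
}

noiseless_sumstats <- function(fx, tau, N = 20000L, a = 0) {
  mu <- 1 + N * a + N * as.vector(fx$ld$scores %*% tau)
  d <- data.frame(snp = fx$ld$snp, a1 = "A", a2 = "G", z = sqrt(mu), n = N)
  class(d) <- c("gwas_sumstats", "data.frame")
  d
}

test_that("a noiseless linear system returns the planted tau and intercept", {
  fx <- sldsr_fixture()
  tau <- c(base = 5e-7, eqtl = 1e-7)
  ss <- noiseless_sumstats(fx, tau)
  fit <- sldsr_fit(ss, fx$ld, annot = fx$annot, n_blocks = 50L)
  expect_equal(fit$results$tau, unname(tau), tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)

  # fixed intercept variant recovers tau too
  fit0 <- sldsr_fit(ss, fx$ld, annot = fx$annot, n_blocks = 50L,
                    fit_intercept = FALSE)
  expect_equal(fit0$results$tau, unname(tau), tolerance = 1e-10)
  expect_identical(fit0$intercept, 1)
})

test_that("scale equivariance: kappa * chi2 scales tau and the intercept by kappa", {
  fx <- sldsr_fixture(seed = 52L)
  cfg <- fx$cfg
  ss <- gen_gwas_sumstats(fx$panel, fx$annot, fx$ld, cfg,
                          tau = c(base = 1e-6, eqtl = 4e-6))
  kappa <- 3.7
  ss_k <- ss
  ss_k$z <- ss$z * sqrt(kappa)
  f1 <- sldsr_fit(ss, fx$ld, n_blocks = 40L, weighting = "uniform")
  f2 <- sldsr_fit(ss_k, fx$ld, n_blocks = 40L, weighting = "uniform")
  expect_equal(f2$results$tau, kappa * f1$results$tau, tolerance = 1e-8)
  expect_equal(f2$intercept, kappa * f1$intercept, tolerance = 1e-8)
})

test_that("degenerate designs fail with informative errors", {
  fx <- sldsr_fixture(seed = 53L)
  ss <- noiseless_sumstats(fx, c(base = 1e-6, eqtl = 0))
  # duplicated category -> collinear
  an2 <- fx$annot
  an2$matrix <- cbind(an2$matrix, copy = an2$matrix[, "eqtl"])
  ld2 <- fx$ld
  ld2$scores <- cbind(ld2$scores, copy = ld2$scores[, "eqtl"])
  expect_error(sldsr_fit(ss, ld2, n_blocks = 40L), "collinear")
  # too few SNPs for the requested jackknife
  expect_error(sldsr_fit(ss, fx$ld, n_blocks = 2000L), "n_blocks")
})

test_that("partitioned heritability is consistent and the base enrichment is one", {
  fx <- sldsr_fixture(seed = 54L)
  panel <- fx$panel
  M <- length(panel$snp)
  # disjoint categories covering all SNPs (no explicit base column)
  thirds <- split(panel$snp, rep(1:3, length.out = M))
  annot <- annotation_matrix(panel, setNames(thirds, c("c1", "c2", "c3")))
  an <- annot
  an$matrix <- an$matrix[, c("c1", "c2", "c3")]  # partition only
  ld <- stratified_ld_scores(panel, an, window_bp = 1e6)
  ss <- suppressWarnings(gen_gwas_sumstats(panel, annot, fx$ld, fx$cfg,
                          tau = c(base = 1e-6, eqtl = 3e-6)))
  fit <- sldsr_fit(ss, ld, annot = an, n_blocks = 40L)
  expect_equal(sum(fit$results$h2_annot), fit$h2_total, tolerance = 1e-12)

  # with a base category present its enrichment is exactly one
  fit_b <- sldsr_fit(ss, fx$ld, annot = fx$annot, n_blocks = 40L)
  expect_identical(fit_b$results$enrichment[fit_b$results$category == "base"], 1)
  et <- enrichment_test(fit_b, "base")
  expect_true(is.na(et$p_enrichment))
  expect_match(et$reason, "degenerate")
})

test_that("enrichment test works on both scales with known quantiles", {
  fake <- structure(list(results = data.frame(
    category = c("a", "b", "c"),
    tau = c(1e-6, 1e-6, 1e-6), tau_se = c(1e-6, 1e-6, 1e-6),
    tau_z = c(1, 1, 1),
    enrichment = c(1, 1 + 1.6449, 2), enrichment_se = c(0.5, 1, 1)
  )), class = "sldsr_fit")
  expect_equal(enrichment_test(fake, "a")$p_enrichment, 0.5)
  expect_equal(enrichment_test(fake, "b")$p_enrichment, 0.05, tolerance = 1e-3)
  expect_equal(enrichment_test(fake, "c")$p_enrichment,
               pnorm(1, lower.tail = FALSE))
  expect_equal(enrichment_test(fake, "a")$p_coefficient,
               pnorm(1, lower.tail = FALSE))
  expect_error(enrichment_test(fake, "zzz"), "not in fit")
})

test_that("jackknife SEs agree with closed-form OLS SEs on homoskedastic data", {
  fx <- sldsr_fixture(seed = 55L, M = 1500L)
  N <- 20000L
  X <- cbind(1, N * fx$ld$scores)
  beta_true <- c(1, 1e-6, 4e-6)
  mu <- as.vector(X %*% beta_true)
  ratios <- sapply(1:40, function(i) {
    set.seed(1000L + i)
    y <- mu + rnorm(nrow(X), sd = 1.5)
    ss <- data.frame(snp = fx$ld$snp, a1 = "A", a2 = "G",
                     z = sqrt(pmax(y, 0)), n = N)
    # feed y directly as chi2 via z = sqrt(y); negative draws floored at 0
    ss$z <- sqrt(pmax(y, 1e-12))
    class(ss) <- c("gwas_sumstats", "data.frame")
    fit <- sldsr_fit(ss, fx$ld, n_blocks = 60L, weighting = "uniform")
    yy <- ss$z^2
    ols <- lm(yy ~ X - 1)
    se_ols <- sqrt(diag(vcov(ols)))[-1]
    fit$results$tau_se / se_ols
  })
  expect_true(all(abs(rowMeans(ratios) - 1) < 0.25))
})

test_that("multiple-testing corrections match the step-up arithmetic and an oracle", {
  r <- correct_multiple(c(0.01, 0.02, 0.04), "bh", alpha = 0.05)
  expect_true(all(r$reject))
  r2 <- correct_multiple(0.02, "bonferroni", alpha = 0.05)
  expect_true(r2$reject)
  expect_error(correct_multiple(numeric()), "empty")
  expect_error(correct_multiple(c(0.5, 0)), "\\(0, 1\\]")

  set.seed(61)
  for (i in 1:5) {
    p <- runif(50)^2
    got <- correct_multiple(p, "bh", alpha = 0.05)
    expect_identical(got$reject, oracle_bh(p, 0.05))
    bon <- correct_multiple(p, "bonferroni", alpha = 0.05)
    expect_identical(bon$reject, p <= 0.05 / length(p))
  }
})

test_that("inverse-variance weighted meta-analysis matches closed forms", {
  m1 <- ivw_meta(c(2, 2, 2), c(1, 1, 1))
  expect_equal(m1$pooled_coefficient, 2)
  expect_equal(m1$pooled_se, 1 / sqrt(3), tolerance = 1e-12)

  m2 <- ivw_meta(c(0, 5), c(1, 2))
  expect_equal(m2$pooled_coefficient, 1, tolerance = 1e-12)
  expect_equal(m2$pooled_se, sqrt(1 / (1 + 1 / 4)), tolerance = 1e-12)

  set.seed(62)
  b <- rnorm(6); s <- runif(6, 0.5, 2)
  m3 <- ivw_meta(b, s)
  expect_equal(m3$pooled_coefficient, sum(b / s^2) / sum(1 / s^2))
  expect_lte(m3$pooled_se, min(s))
  expect_error(ivw_meta(c(1, 2), c(1, 0)), "positive")
  expect_error(ivw_meta(1, 1), "length")
})

test_that("the add-one scan flags collinear candidates and recovers planted covariate effects", {
  fx <- sldsr_fixture(seed = 56L, M = 2000L)
  panel <- fx$panel
  set.seed(57)
  k <- 6L
  cand_ids <- lapply(1:k, function(i) sample(panel$snp, 300L))
  names(cand_ids) <- paste0("t", 1:k)
  annot <- annotation_matrix(panel, cand_ids)
  ld <- stratified_ld_scores(panel, annot, window_bp = 1e6)

  # candidate power scales with a planted covariate (per-candidate tau)
  covariate <- setNames(seq(0, 5, length.out = k), names(cand_ids))
  tau <- c(base = 1e-6, 4e-7 * covariate)
  names(tau) <- c("base", names(cand_ids))
  ss <- suppressWarnings(gen_gwas_sumstats(panel, annot, ld, fx$cfg, tau = tau))
  scan <- add_one_scan(ss, ld, candidates = names(cand_ids),
                       n_blocks = 40L, covariate = covariate)
  expect_false(any(scan$table$failed))
  expect_gt(scan$covariate_cor, 0)

  # a candidate duplicating the base column is reported failed, scan continues
  ld_dup <- ld
  ld_dup$scores <- cbind(ld_dup$scores, dup = ld_dup$scores[, "base"])
  scan2 <- add_one_scan(ss, ld_dup, candidates = c("dup", "t1"),
                        n_blocks = 40L)
  expect_true(scan2$table$failed[scan2$table$candidate == "dup"])
  expect_false(scan2$table$failed[scan2$table$candidate == "t1"])

  # null candidates center on zero
  tau0 <- setNames(rep(0, k + 1L), c("base", names(cand_ids)))
  tau0["base"] <- 1e-6
  ss0 <- suppressWarnings(gen_gwas_sumstats(panel, annot, ld, fx$cfg, tau = tau0))
  scan0 <- add_one_scan(ss0, ld, candidates = names(cand_ids),
                        n_blocks = 40L)
  expect_lt(abs(mean(scan0$table$tau_z)), 2)
})
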