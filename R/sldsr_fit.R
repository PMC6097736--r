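# contiguous equal-count jackknife block ids for M SNPs
jackknife_blocks <- function(M, n_blocks) {
  rep.int(seq_len(n_blocks), diff(round(seq(0, M, length.out = n_blocks + 1))))
}

# delete-one-block jackknife SE from a B x P matrix of replicates
jk_se <- function(reps) {
  B <- nrow(reps)
  ctr <- sweep(reps, 2, colMeans(reps))
  sqrt((B - 1) / B * colSums(ctr^2))
}

#' Stratified LD score regression fit
#'
#' Regresses GWAS chi-square statistics on `N * l(j,c)` for every annotation
#' category c (plus a free intercept estimating `1 + N*a`, or an intercept
#' fixed at 1), by weighted least squares. Weights are the product of an
#' LD-overcounting term `1 / max(l_base, 1)` and a heteroskedasticity term
#' `(1 + N * h2bar * l_base / M)^2`, where `h2bar` is a preliminary base-only
#' heritability estimate (one iteration). Uncertainty for tau and every
#' derived quantity comes from a delete-one block jackknife over `n_blocks`
#' contiguous equal-count SNP blocks.
#'
#' Partitioned heritability: per-SNP heritability is `h2_j = sum_c tau_c *
#' a_cj`, `h2_total = sum_j h2_j`, `h2_annot(C) = sum_{j in C} h2_j`, and
#' enrichment is `(h2_annot / h2_total) / (|C| / M)` — 1 for the base
#' category by construction. These require the annotation matrix; without it
#' only tau, its SE/Z and the intercept are reported.
#'
#' @param sumstats A `gwas_sumstats` data frame (snp, a1, a2, z, n).
#' @param ldscores A [stratified_ld_scores()] object.
#' @param annot The matching [annotation_matrix()] (needed for h2 and
#'   enrichment; may be NULL).
#' @param n_blocks Number of jackknife blocks (default 200).
#' @param fit_intercept Fit the intercept freely (default) or fix it at 1.
#' @param weighting `"ldsc"` (default, the two-factor weights above) or
#'   `"uniform"` (OLS; useful for ablation).
#' @return An object of class `sldsr_fit`: `$results` (one row per category
#'   with tau, tau_se, tau_z, p_tau, h2_annot, enrichment, enrichment_se,
#'   enrichment_p, ...), `$intercept`, `$h2_total` and jackknife metadata.
#' @export
sldsr_fit <- function(sumstats, ldscores, annot = NULL, n_blocks = 200L,
                      fit_intercept = TRUE,
                      weighting = c("ldsc", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(ldscores, "stratified_ldscores"))
  m <- match(ldscores$snp, sumstats$snp)
  keep <- which(!is.na(m))
  if (length(keep) < length(ldscores$snp))
    message("dropped ", length(ldscores$snp) - length(keep),
            " SNP(s) absent from the summary statistics")
  ss <- sumstats[m[keep], , drop = FALSE]
  L <- ldscores$scores[keep, , drop = FALSE]
  cats <- colnames(L)
  M <- nrow(L)
  if (M < 2L * n_blocks)
    stop("fewer SNPs (", M, ") than 2 x n_blocks (", 2L * n_blocks, ")")
  A <- NULL
  if (!is.null(annot)) {
    stopifnot(inherits(annot, "annotation_matrix"))
    if (!identical(annot$snp, ldscores$snp))
      stop("annotation matrix is not aligned to the LD scores")
    if (!identical(colnames(annot$matrix), cats))
      stop("annotation categories do not match LD score categories")
    A <- annot$matrix[keep, , drop = FALSE]
    storage.mode(A) <- "double"
  }

  y <- ss$z^2
  N <- ss$n
  X <- L * N
  if (fit_intercept) {
    X <- cbind(`(intercept)` = 1, X)
  } else {
    y <- y - 1
  }

  # collinearity check before fitting
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cc <- abs(suppressWarnings(cor(X)))
    diag(cc) <- 0
    cc[!is.finite(cc)] <- 0  # constant columns have undefined correlation
    worst <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    stop("rank-deficient design: categories '", colnames(X)[worst[1L]],
         "' and '", colnames(X)[worst[2L]], "' are collinear")
  }

  base_col <- if ("base" %in% cats) "base" else cats[1L]
  lbase <- pmax(L[, base_col], 1)
  if (weighting == "ldsc") {
    w0 <- 1 / lbase
    X0 <- cbind(1, N * L[, base_col])
    tau0 <- stats::lm.wfit(x = X0, y = ss$z^2, w = w0)$coefficients[2L]
    h2bar <- min(max(tau0 * M, 0), 1)
    whet <- (1 + N * h2bar * L[, base_col] / M)^2
    w <- 1 / (lbase * whet)
  } else {
    w <- rep(1, M)
  }

  fit <- stats::lm.wfit(x = X, y = y, w = w)
  beta <- fit$coefficients

  # jackknife via per-block normal-equation accumulators
  blk <- jackknife_blocks(M, n_blocks)
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  P <- ncol(X)
  c_blk <- rowsum(Xw * yw, blk)              # B x P
  c_full <- colSums(c_blk)
  A_full <- crossprod(Xw)
  A_blk <- array(0, c(n_blocks, P, P))
  for (p in seq_len(P)) {
    for (q in p:P) {
      s <- rowsum(Xw[, p] * Xw[, q], blk)
      A_blk[, p, q] <- s
      A_blk[, q, p] <- s
    }
  }
  reps <- matrix(NA_real_, n_blocks, P, dimnames = list(NULL, colnames(X)))
  for (b in seq_len(n_blocks)) {
    reps[b, ] <- solve(A_full - A_blk[b, , ], c_full - c_blk[b, ])
  }

  coef_se <- jk_se(reps)
  ti <- if (fit_intercept) match(cats, colnames(X)) else match(cats, colnames(X))
  tau <- beta[cats]
  tau_se <- coef_se[ti]
  tau_z <- tau / tau_se
  intercept <- if (fit_intercept) beta[["(intercept)"]] else 1
  intercept_se <- if (fit_intercept) coef_se[[1L]] else 0

  results <- data.frame(
    category = cats,
    tau = unname(tau),
    tau_se = unname(tau_se),
    tau_z = unname(tau_z),
    p_tau = pnorm(unname(tau_z), lower.tail = FALSE)
  )
  h2_total <- NA_real_
  h2_total_se <- NA_real_
  if (!is.null(A)) {
    sizes <- colSums(A)
    h2_parts <- function(tv) {
      per_snp <- as.vector(A %*% tv)
      annot_part <- as.vector(crossprod(A, per_snp))
      names(annot_part) <- cats
      # identical summation for total and base keeps base enrichment at 1 exactly
      total <- if ("base" %in% cats) annot_part[["base"]] else sum(per_snp)
      c(total, annot_part)
    }
    full <- h2_parts(tau)
    h2_total <- unname(full[1L])
    h2_annot <- unname(full[-1L])
    enr <- (h2_annot / h2_total) / (sizes / M)
    rep_parts <- t(apply(reps[, cats, drop = FALSE], 1L, h2_parts))
    h2t_reps <- rep_parts[, 1L]
    h2a_reps <- rep_parts[, -1L, drop = FALSE]
    enr_reps <- sweep(h2a_reps / h2t_reps, 2L, sizes / M, "/")
    h2_total_se <- jk_se(cbind(h2t_reps))
    results$size <- unname(sizes)
    results$prop_snps <- unname(sizes) / M
    results$h2_annot <- unname(h2_annot)
    results$h2_annot_se <- unname(jk_se(h2a_reps))
    results$prop_h2 <- unname(h2_annot) / h2_total
    results$enrichment <- unname(enr)
    enr_se <- jk_se(enr_reps)
    results$enrichment_se <- unname(enr_se)
    ez <- (results$enrichment - 1) / results$enrichment_se
    results$enrichment_p <- ifelse(
      is.finite(ez) & results$enrichment_se > 0,
      pnorm(ez, lower.tail = FALSE), NA_real_
    )
  }
  rownames(results) <- NULL
  structure(
    list(
      results = results,
      intercept = intercept, intercept_se = intercept_se,
      h2_total = h2_total, h2_total_se = unname(h2_total_se),
      n_snps = M, n_blocks = n_blocks,
      fit_intercept = fit_intercept, weighting = weighting,
      mean_chi2 = mean(ss$z^2),
      tau_jackknife = reps[, cats, drop = FALSE]
    ),
    class = "sldsr_fit"
  )
}

#' @export
print.sldsr_fit <- function(x, ...) {
  cat(sprintf("<sldsr_fit> %d SNPs, %d jackknife blocks, mean chi2 %.3f\n",
              x$n_snps, x$n_blocks, x$mean_chi2))
  cat(sprintf("  intercept %.4f (SE %.4f)",
              x$intercept, x$intercept_se))
  if (is.finite(x$h2_total))
    cat(sprintf(", h2_total %.4f (SE %.4f)", x$h2_total, x$h2_total_se))
  cat("\n")
  print(x$results, digits = 4)
  invisible(x)
}

#' One-tailed enrichment test for a category
#'
#' Tests enrichment > 1 on the enrichment scale,
#' `p = P(Z > (enrichment - 1) / enrichment_se)`, and also reports the
#' coefficient-scale one-tailed p (`tau / tau_se`), since coefficient tables
#' are the customary reporting format.
#'
#' @param result An [sldsr_fit()] object (fitted with an annotation matrix).
#' @param category Category name.
#' @return List: category, enrichment_z, p_enrichment, tau_z, p_coefficient;
#'   `p_enrichment` is NA (with a `reason`) when the jackknife SE is
#'   degenerate, e.g. for the base category.
#' @export
enrichment_test <- function(result, category) {
  stopifnot(inherits(result, "sldsr_fit"))
  row <- result$results[result$results$category == category, , drop = FALSE]
  if (!nrow(row)) stop("category not in fit: ", category)
  if (is.null(row$enrichment))
    stop("fit has no enrichment (no annotation matrix was supplied)")
  out <- list(category = category, tau_z = row$tau_z,
              p_coefficient = pnorm(row$tau_z, lower.tail = FALSE))
  if (!is.finite(row$enrichment_se) || row$enrichment_se <= 0) {
    out$enrichment_z <- NA_real_
    out$p_enrichment <- NA_real_
    out$reason <- "degenerate jackknife SE for enrichment"
  } else {
    out$enrichment_z <- (row$enrichment - 1) / row$enrichment_se
    out$p_enrichment <- pnorm(out$enrichment_z, lower.tail = FALSE)
  }
  out
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up FDR or Bonferroni flags at level `alpha`, with
#' monotone adjusted p-values (via [stats::p.adjust()]).
#'
#' @param pvalues Vector of p-values in `(0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @param alpha Level (default 0.05).
#' @return List: adjusted, reject, method, alpha.
#' @export
correct_multiple <- function(pvalues, method = c("bh", "bonferroni"),
                             alpha = 0.05) {
  method <- match.arg(method)
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  adjusted <- p.adjust(pvalues,
                       method = if (method == "bh") "BH" else "bonferroni")
  list(adjusted = adjusted, reject = adjusted <= alpha,
       method = method, alpha = alpha)
}

#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Pools per-trait estimates as `sum(b_i / se_i^2) / sum(1 / se_i^2)` with
#' `pooled_se = 1 / sqrt(sum(1 / se_i^2))` and a two-tailed normal p-value.
#'
#' @param estimates Numeric vector of per-trait estimates (length >= 2).
#' @param ses Matching standard errors, all positive.
#' @return An `ivw_meta` list: pooled_coefficient, pooled_se, pooled_z,
#'   pooled_p, k_traits.
#' @export
ivw_meta <- function(estimates, ses) {
  if (length(estimates) != length(ses) || length(estimates) < 2L)
    stop("need matching estimate/SE vectors of length >= 2")
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("all SEs must be positive and finite")
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  structure(
    list(pooled_coefficient = pooled, pooled_se = pooled_se,
         pooled_z = z, pooled_p = 2 * pnorm(-abs(z)),
         k_traits = length(estimates)),
    class = "ivw_meta"
  )
}

#' @export
print.ivw_meta <- function(x, ...) {
  cat(sprintf("<ivw_meta> %d traits: pooled %.4g (SE %.4g), z = %.3f, p = %.3g\n",
              x$k_traits, x$pooled_coefficient, x$pooled_se,
              x$pooled_z, x$pooled_p))
  invisible(x)
}

#' Add-one-category scan over candidate annotations
#'
#' Fits one model per candidate category: baseline categories, any shared
#' extra categories (e.g. a union-of-eQTLs annotation and its windows), plus
#' that single candidate. Reports the candidate's tau, SE and Z per model;
#' candidates collinear with the rest of the model are marked failed and the
#' scan continues. When a per-candidate covariate is supplied (e.g. eQTL
#' discovery sample sizes), the Pearson correlation between candidate
#' Z-scores and the covariate is reported.
#'
#' @param sumstats,ldscores,annot As in [sldsr_fit()]; `ldscores`/`annot`
#'   must contain the baseline, shared and candidate categories as columns.
#' @param candidates Character vector of candidate category names.
#' @param shared Character vector of categories present in every model.
#' @param baseline Baseline categories (default: every column that is neither
#'   a candidate nor shared).
#' @param n_blocks,fit_intercept Passed to [sldsr_fit()].
#' @param covariate Optional named numeric vector over candidates.
#' @return List: `table` (candidate, tau, tau_se, tau_z, p_tau, failed,
#'   message), and when a covariate is given, `covariate_cor` and
#'   `covariate_cor_p`.
#' @export
add_one_scan <- function(sumstats, ldscores, candidates,
                         shared = character(), baseline = NULL,
                         annot = NULL, n_blocks = 200L, fit_intercept = TRUE,
                         covariate = NULL) {
  all_cats <- colnames(ldscores$scores)
  baseline <- baseline %||% setdiff(all_cats, c(candidates, shared))
  miss <- setdiff(c(baseline, shared, candidates), all_cats)
  if (length(miss)) stop("categories missing from LD scores: ",
                         paste(miss, collapse = ", "))
  rows <- lapply(candidates, function(cand) {
    cols <- c(baseline, shared, cand)
    sub_ld <- subset_ldscores(ldscores, cols)
    sub_an <- if (!is.null(annot)) {
      an <- annot
      an$matrix <- an$matrix[, cols, drop = FALSE]
      an
    }
    res <- tryCatch(
      sldsr_fit(sumstats, sub_ld, annot = sub_an, n_blocks = n_blocks,
                fit_intercept = fit_intercept),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      data.frame(candidate = cand, tau = NA_real_, tau_se = NA_real_,
                 tau_z = NA_real_, p_tau = NA_real_, failed = TRUE,
                 message = conditionMessage(res))
    } else {
      rr <- res$results[res$results$category == cand, ]
      data.frame(candidate = cand, tau = rr$tau, tau_se = rr$tau_se,
                 tau_z = rr$tau_z, p_tau = rr$p_tau, failed = FALSE,
                 message = "")
    }
  })
  out <- list(table = do.call(rbind, rows))
  if (!is.null(covariate)) {
    tb <- out$table[!out$table$failed, ]
    cv <- covariate[tb$candidate]
    if (sum(is.finite(cv)) >= 3L) {
      ct <- cor.test(tb$tau_z, cv)
      out$covariate_cor <- unname(ct$estimate)
      out$covariate_cor_p <- ct$p.value
    } else {
      out$covariate_cor <- NA_real_
      out$covariate_cor_p <- NA_real_
    }
  }
  out
}
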