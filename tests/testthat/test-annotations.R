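# independent per-probe reimplementation of the five selection strategies
oracle_select <- function(catalog, strategy, panel) {
  sig <- catalog[catalog$significant, ]
  pos <- panel$pos[match(sig$snp, panel$snp)]
  res <- character()
  for (pr in unique(paste(sig$tissue, sig$probe))) {
    rows <- sig[paste(sig$tissue, sig$probe) == pr, ]
    rpos <- pos[paste(sig$tissue, sig$probe) == pr]
    o <- order(rows$p, rpos)
    pick <- switch(strategy,
      lead = o[1],
      median_p = o[ceiling(length(o) / 2)],
      mean_p = {
        target <- mean(rows$p)
        d <- signif(abs(rows$p - target), 12)
        which(d == min(d))[order(rpos[d == min(d)])][1]
      },
      top10 = o[seq_len(min(10, length(o)))],
      all_significant = seq_len(nrow(rows))
    )
    res <- c(res, rows$snp[pick])
  }
  unique(res)
}

test_that("per-probe SNP selection strategies pick the documented SNPs", {
  panel <- tiny_panel(random_genotypes(20L, 6L, seed = 2L))
  ct <- make_catalog(
    snp = panel$snp[1:3], probe = "pr1", gene = "g1", tissue = "blood",
    p = c(1e-8, 1e-5, 1e-3)
  )
  expect_identical(select_eqtl_snps(ct, "lead", panel), panel$snp[1])
  expect_identical(select_eqtl_snps(ct, "median_p", panel), panel$snp[2])
  # mean p = 3.37e-4; 1e-5 is nearer to it than 1e-3
  expect_identical(select_eqtl_snps(ct, "mean_p", panel), panel$snp[2])
  expect_setequal(select_eqtl_snps(ct, "top10", panel), panel$snp[1:3])
  expect_setequal(select_eqtl_snps(ct, "all_significant", panel),
                  panel$snp[1:3])

  # even count: the lower of the two middle order statistics
  ct4 <- make_catalog(snp = panel$snp[1:4], probe = "pr2", gene = "g2",
                      tissue = "blood", p = c(0.04, 0.03, 0.02, 0.01))
  expect_identical(select_eqtl_snps(ct4, "median_p", panel), panel$snp[3])

  # a probe with fewer than ten significant eQTLs contributes all of them
  ct7 <- make_catalog(snp = panel$snp[1:6], probe = "pr3", gene = "g3",
                      tissue = "blood", p = runif(6, 1e-8, 1e-4))
  expect_setequal(select_eqtl_snps(ct7, "top10", panel), panel$snp[1:6])

  # probes with zero significant eQTLs contribute nothing
  ct0 <- make_catalog(snp = panel$snp[5], probe = "pr4", gene = "g4",
                      tissue = "blood", significant = FALSE)
  expect_identical(select_eqtl_snps(ct0, "lead", panel), character())
  expect_error(select_eqtl_snps(ct, "best"), "arg")
})

test_that("selection strategies match the brute-force oracle on random catalogs", {
  set.seed(33)
  panel <- tiny_panel(random_genotypes(20L, 40L, seed = 6L))
  rows <- do.call(rbind, lapply(1:8, function(i) {
    k <- sample(3:15, 1)
    make_catalog(
      snp = sample(panel$snp, k), probe = paste0("pr", i),
      gene = paste0("g", ceiling(i / 2)),
      tissue = sample(c("blood", "brain"), 1),
      p = runif(k, 1e-10, 1e-2),
      significant = runif(k) < 0.8
    )
  }))
  class(rows) <- c("eqtl_catalog", "data.frame")
  for (s in c("lead", "median_p", "mean_p", "top10", "all_significant")) {
    expect_setequal(select_eqtl_snps(rows, s, panel),
                    oracle_select(rows, s, panel))
  }
  # all_significant contains every other strategy's output
  all_sig <- select_eqtl_snps(rows, "all_significant", panel)
  for (s in c("lead", "median_p", "mean_p", "top10"))
    expect_true(all(select_eqtl_snps(rows, s, panel) %in% all_sig))
})

test_that("window annotations use inclusive bp distances and exclude members", {
  panel <- tiny_panel(random_genotypes(20L, 5L, seed = 3L),
                      pos = c(1000L, 1100L, 1101L, 1450L, 1700L))
  w <- window_annotations(panel$snp[1], panel)
  expect_identical(w$window_100bp, panel$snp[2])       # 1100 in, 1101 out
  expect_setequal(w$window_500bp, panel$snp[2:4])      # 1450 in, 1700 out

  w0 <- window_annotations(character(), panel)
  expect_identical(w0$window_100bp, character())
  expect_identical(w0$window_500bp, character())

  # brute-force all-pairs check on a random set
  cfg <- simulation_config(n_ref_individuals = 30L, n_snps = 60L,
                           n_ld_blocks = 6L, seed = 14L)
  rp <- gen_reference_panel(cfg)
  set.seed(15)
  members <- sample(rp$snp, 10L)
  got <- window_annotations(members, rp, windows = c(800L, 5000L))
  mpos <- rp$pos[rp$snp %in% members]
  for (wn in c(800L, 5000L)) {
    want <- rp$snp[
      vapply(rp$pos, function(p) min(abs(p - mpos)), numeric(1)) <= wn &
        !(rp$snp %in% members)
    ]
    expect_setequal(got[[sprintf("window_%dbp", wn)]], want)
  }
})

test_that("gene-window annotation stabs intervals with inclusive boundaries", {
  panel <- tiny_panel(
    random_genotypes(20L, 4L, seed = 4L),
    pos = c(3999999L, 4000000L, 5005000L, 6010001L)
  )
  coords <- data.frame(gene = "gA", chrom = "1",
                       start = 5000000L, end = 5010000L)
  got <- gene_window_annotation("gA", coords, panel, window_bp = 1e6)
  expect_setequal(got, panel$snp[2:3])  # 4000000 in, 3999999 and 6010001 out

  expect_identical(
    gene_window_annotation(character(), coords, panel), character()
  )
  expect_error(gene_window_annotation(c("gA", "gB"), coords, panel), "gB")

  # interval-stab oracle on random genes
  cfg <- simulation_config(n_ref_individuals = 30L, n_snps = 80L,
                           n_ld_blocks = 8L, seed = 16L)
  rp <- gen_reference_panel(cfg)
  set.seed(17)
  rc <- data.frame(
    gene = c("g1", "g2", "g3"), chrom = "1",
    start = sort(sample(rp$pos, 3L))
  )
  rc$end <- rc$start + 4000L
  wbp <- 20000
  got <- gene_window_annotation(rc$gene, rc, rp, window_bp = wbp)
  want <- rp$snp[vapply(rp$pos, function(p)
    any(p >= rc$start - wbp & p <= rc$end + wbp), logical(1))]
  expect_setequal(got, want)
})

test_that("union annotation is a plain set union", {
  expect_length(union_annotation(list(c("a", "b", "c"), c("d", "e", "f", "g"))), 7L)
  expect_setequal(union_annotation(list(c("a", "b"), c("a", "b"))), c("a", "b"))
  expect_setequal(union_annotation(list(c("a"), c("a", "b", "c"))),
                  c("a", "b", "c"))
  expect_identical(union_annotation(list()), character())
})

test_that("BED intersection follows 0-based half-open semantics", {
  panel <- tiny_panel(random_genotypes(10L, 4L, seed = 7L),
                      pos = c(999L, 1000L, 1001L, 2000L))
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t999\t1000", bed)
  got <- intersect_with_intervals(panel$snp, bed, panel)
  expect_identical(got, panel$snp[2])  # covers 1-based position 1000 only

  expect_identical(
    intersect_with_intervals(panel$snp, GenomicRanges::GRanges(), panel),
    character()
  )
  # non-member SNPs are never returned
  expect_identical(
    intersect_with_intervals(panel$snp[1], read_bed(bed), panel), character()
  )

  bad <- tempfile(fileext = ".bed")
  writeLines(c("1\t10\t20", "1\t50"), bad)
  expect_error(read_bed(bad), "line 2")
  bad2 <- tempfile(fileext = ".bed")
  writeLines(c("1\t10\t20", "1\t30\t25"), bad2)
  expect_error(read_bed(bad2), "line 2")

  # per-SNP linear-scan oracle on random intervals
  cfg <- simulation_config(n_ref_individuals = 30L, n_snps = 50L,
                           n_ld_blocks = 5L, seed = 18L)
  rp <- gen_reference_panel(cfg)
  set.seed(19)
  st0 <- sort(sample(max(rp$pos), 6L))
  en0 <- st0 + sample(200:3000, 6L)
  bed3 <- tempfile(fileext = ".bed")
  writeLines(sprintf("1\t%d\t%d", st0, en0), bed3)
  members <- sample(rp$snp, 25L)
  got <- intersect_with_intervals(members, bed3, rp)
  want <- members[vapply(members, function(s) {
    p <- rp$pos[rp$snp == s]
    any(st0 < p & p <= en0)
  }, logical(1))]
  expect_setequal(got, want)
})

test_that("top-decile DE eQTL category filters genes then collects SNPs", {
  de <- data.frame(gene = paste0("g", 1:10), tissue = "brain", rank = 1:10)
  ct1 <- make_catalog(snp = c("s1", "s2"), probe = "p1", gene = "g1",
                      tissue = "blood")
  ct2 <- make_catalog(snp = c("s3"), probe = "p2", gene = "g2",
                      tissue = "brain")
  # G = 10 -> decile holds exactly one gene (g1); discovery tissue irrelevant
  expect_setequal(top_decile_de_eqtls(list(ct1, ct2), de, "brain"),
                  c("s1", "s2"))
  expect_error(top_decile_de_eqtls(list(ct1), de, "muscle"), "muscle")

  # a decile gene with no eQTLs contributes nothing
  de2 <- data.frame(gene = paste0("g", 1:10), tissue = "brain",
                    rank = c(2:10, 1))  # g10 top-ranked, has no eQTLs
  expect_identical(top_decile_de_eqtls(list(ct1, ct2), de2, "brain"),
                   character())

  # set-filter oracle on a random configuration
  set.seed(20)
  genes <- paste0("g", 1:20)
  de3 <- data.frame(gene = genes, tissue = "blood", rank = sample(20))
  ct3 <- make_catalog(
    snp = paste0("s", 1:40), probe = paste0("p", rep(1:8, each = 5)),
    gene = rep(sample(genes, 8), each = 5), tissue = "blood",
    significant = runif(40) < 0.7
  )
  d <- ceiling(0.1 * 20)
  top <- de3$gene[order(de3$rank)][1:d]
  want <- unique(ct3$snp[ct3$significant & ct3$gene %in% top])
  expect_setequal(top_decile_de_eqtls(ct3, de3, "blood"), want)
})

test_that("annotation matrices keep the base category and drop unknown SNPs", {
  panel <- tiny_panel(random_genotypes(10L, 5L, seed = 8L))
  expect_message(
    an <- annotation_matrix(panel, list(c1 = c(panel$snp[1:2], "rs_missing"))),
    "dropped 1"
  )
  expect_identical(unname(an$matrix[, "base"]), rep(1L, 5L))
  expect_identical(sum(an$matrix[, "c1"]), 2L)
  expect_equal(unname(category_sizes(an)), c(5, 2))
})
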