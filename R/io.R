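#' Read a BED interval file
#'
#' Minimal validating BED3+ reader: each data line needs at least chrom,
#' start, end with `0 <= start < end`; a malformed line fails with its line
#' number. `track`/`browser`/comment lines are skipped. Intervals are
#' returned 1-based closed (start0+1 .. end0), so overlap queries against
#' 1-based SNP positions follow the half-open BED convention
#' (`start0 < pos <= end0`).
#'
#' @param path BED file path.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  chrom <- character()
  start0 <- numeric()
  end0 <- numeric()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || grepl("^(track|browser|#)", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) == 1L) f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(f) < 3L)
      stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s || s != round(s) || e != round(e))
      stop("malformed BED line ", i, ": bad interval [", f[2L], ", ", f[3L], ")")
    chrom <- c(chrom, f[1L])
    start0 <- c(start0, s)
    end0 <- c(end0, e)
  }
  if (!length(chrom)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
}

#' Write intervals to BED (0-based half-open)
#' @param gr A `GRanges` (1-based closed, as from [read_bed()]).
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write / read a variant panel
#'
#' The panel is stored as two TSVs: `<prefix>.variants.tsv` (snp, chrom,
#' pos, a1, a2, maf, block) and `<prefix>.genotypes.tsv` (rows = SNPs,
#' columns = individuals, header of individual ids).
#'
#' @param panel A [variant_panel()].
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  vt <- data.frame(
    snp = panel$snp, chrom = panel$chrom, pos = panel$pos,
    a1 = panel$a1, a2 = panel$a2, maf = panel$maf,
    block = panel$block %||% NA_integer_,
    sim_freq = panel$sim_freq %||% NA_real_
  )
  data.table::fwrite(vt, paste0(prefix, ".variants.tsv"), sep = "\t")
  gt <- data.table::as.data.table(t(panel$genotypes))
  data.table::setnames(gt, sprintf("ind%04d", seq_len(panel$n_individuals)))
  data.table::fwrite(gt, paste0(prefix, ".genotypes.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix) {
  vt <- data.table::fread(paste0(prefix, ".variants.tsv"), sep = "\t",
                          data.table = FALSE)
  gt <- as.matrix(data.table::fread(paste0(prefix, ".genotypes.tsv"),
                                    sep = "\t"))
  variant_panel(
    snp = vt$snp, chrom = vt$chrom[1L], pos = vt$pos,
    a1 = vt$a1, a2 = vt$a2, genotypes = t(gt),
    block = if (!all(is.na(vt$block))) vt$block,
    sim_freq = if (!all(is.na(vt$sim_freq))) vt$sim_freq
  )
}

#' Write / read GWAS summary statistics (SNP, A1, A2, Z, N)
#' @param sumstats A `gwas_sumstats` data frame.
#' @param path TSV path.
#' @export
write_sumstats <- function(sumstats, path) {
  data.table::fwrite(
    data.frame(SNP = sumstats$snp, A1 = sumstats$a1, A2 = sumstats$a2,
               Z = sumstats$z, N = sumstats$n),
    path, sep = "\t"
  )
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  names(d) <- tolower(names(d))
  stopifnot(all(c("snp", "z", "n") %in% names(d)))
  out <- data.frame(snp = d$snp, a1 = d$a1 %||% NA_character_,
                    a2 = d$a2 %||% NA_character_, z = d$z, n = d$n)
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

#' Write / read an eQTL catalog TSV
#' @param catalog An `eqtl_catalog` data frame.
#' @param path TSV path.
#' @export
write_catalog <- function(catalog, path) {
  data.table::fwrite(as.data.frame(catalog), path, sep = "\t")
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  class(d) <- c("eqtl_catalog", "data.frame")
  d
}

#' Write LD scores plus the per-category size sidecar
#'
#' Writes `<prefix>.ldscore.tsv` (SNP + one column per category) and
#' `<prefix>.sizes.tsv` (category, n_snps) — the sizes are the enrichment
#' denominators.
#'
#' @param ldscores A [stratified_ld_scores()] object.
#' @param annots The matching [annotation_matrix()] (for the sizes sidecar).
#' @param prefix Output path prefix.
#' @export
write_ldscores <- function(ldscores, annots, prefix) {
  d <- data.frame(SNP = ldscores$snp, ldscores$scores, check.names = FALSE)
  data.table::fwrite(d, paste0(prefix, ".ldscore.tsv"), sep = "\t")
  sz <- category_sizes(annots)
  data.table::fwrite(data.frame(category = names(sz), n_snps = unname(sz)),
                     paste0(prefix, ".sizes.tsv"), sep = "\t")
  invisible(prefix)
}

#' Write / read an annotation matrix (.annot-style TSV)
#'
#' Columns CHR, BP, SNP then one 0/1 column per category.
#'
#' @param annots An [annotation_matrix()].
#' @param path TSV path.
#' @export
write_annot <- function(annots, path) {
  d <- data.frame(CHR = annots$chrom, BP = annots$pos, SNP = annots$snp,
                  annots$matrix, check.names = FALSE)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_annot
#' @export
read_annot <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  mat <- as.matrix(d[, setdiff(names(d), c("CHR", "BP", "SNP")), drop = FALSE])
  storage.mode(mat) <- "integer"
  structure(
    list(snp = d$SNP, chrom = d$CHR[1L], pos = d$BP, matrix = mat,
         provenance = setNames(colnames(mat), colnames(mat))),
    class = "annotation_matrix"
  )
}
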