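# required/known keys of a pipeline config
validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) stop("pipeline config must be a list / YAML mapping")
  known_stages <- c("simulate", "annotate", "ldscore", "gwas", "classify",
                    "regress", "meta")
  stages <- cfg$stages %||% known_stages
  bad <- setdiff(stages, known_stages)
  if (length(bad)) stop("unknown stage(s) in config: ", paste(bad, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set `seed`")
  if (!.is_count(abs(cfg$seed) + 1)) stop("`seed` must be an integer")
  need_before <- list(
    annotate = "simulate", ldscore = "annotate", gwas = "ldscore",
    classify = "simulate", regress = "gwas", meta = "regress"
  )
  for (s in stages) {
    pre <- need_before[[s]]
    if (!is.null(pre) && !(pre %in% stages))
      stop("stage '", s, "' requires stage '", pre, "' in the same run")
  }
  if ("gwas" %in% stages) {
    traits <- cfg$gwas$traits
    if (is.null(traits) || !length(traits) || is.null(names(traits)))
      stop("gwas stage needs a named `gwas: traits:` mapping of tau values")
  }
  stages
}

# md5 digests of a set of files, named by relative file name
file_digests <- function(paths) {
  md5 <- tools::md5sum(paths)
  setNames(unname(md5), basename(paths))
}

#' Run the full eQTL-enrichment pipeline from a declarative config
#'
#' Executes the stage sequence simulate -> annotate -> ldscore -> gwas ->
#' classify -> regress -> meta (any prefix-closed subset selectable via
#' `stages:` in the config) against a single YAML/list configuration, writing
#' every intermediate file under `out_dir` and recording a manifest with the
#' config hash, seed and per-stage file digests. Rerunning with an identical
#' config reproduces identical digests.
#'
#' Config keys (all optional except `seed`; defaults in parentheses):
#' `simulate:` any [simulation_config()] field plus `mark_overlap_fraction`
#' (0.5); `annotate:` `strategy` ("all_significant"), `windows` (100, 500),
#' `gene_window_bp` (1e6), `intersect_marks` (FALSE), `de_tissue` (none),
#' `sharedness` ("none"/"broad"/"narrow" — adds per-tissue specific-eQTL
#' categories for nested specific-vs-all models);
#' `ldscore:` `window_bp` (1e6), `adjusted` (TRUE); `gwas:` `n`, `intercept_a`,
#' `traits:` named mapping trait -> (category: tau) pairs; `classify:`
#' `min_overlap` (35), `r_cutoff` (0.35), `missing_floor` (10); `regress:`
#' `n_blocks` (100), `fit_intercept` (TRUE); `meta:` `category`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @return A `run_manifest` list, invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("sldsr_run_")) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stages <- validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_yaml <- yaml::as.yaml(cfg)
  tmp <- tempfile()
  writeLines(cfg_yaml, tmp)
  manifest <- list(
    tool = paste0("sldsr ", as.character(utils::packageVersion("sldsr"))),
    config_hash = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    stages = list()
  )
  unlink(tmp)

  add_stage <- function(name, files) {
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      name = name, outputs = as.list(file_digests(files))
    )
  }
  pth <- function(...) file.path(out_dir, paste0(...))

  state <- new.env(parent = emptyenv())

  if ("simulate" %in% stages) {
    sim_args <- cfg$simulate %||% list()
    overlap_fraction <- sim_args$mark_overlap_fraction %||% 0.5
    sim_args$mark_overlap_fraction <- NULL
    sc <- do.call(simulation_config, c(sim_args, list(seed = cfg$seed)))
    state$config <- sc
    state$panel <- gen_reference_panel(sc)
    eq <- gen_eqtl_catalogs(state$panel, sc)
    state$catalogs <- eq$catalogs
    state$truth <- eq$truth
    state$gene_coords <- eq$gene_coords
    md <- gen_marks_and_de(state$panel, state$truth, overlap_fraction, sc)
    state$marks <- md$marks
    state$de_ranks <- md$de_ranks

    write_panel(state$panel, pth("panel"))
    files <- c(pth("panel.variants.tsv"), pth("panel.genotypes.tsv"))
    for (t in names(state$catalogs)) {
      f <- pth("catalog_", t, ".tsv")
      write_catalog(state$catalogs[[t]], f)
      files <- c(files, f)
    }
    write_bed(state$marks, pth("marks.bed"))
    data.table::fwrite(state$de_ranks, pth("de_ranks.tsv"), sep = "\t")
    data.table::fwrite(state$gene_coords, pth("gene_coords.tsv"), sep = "\t")
    files <- c(files, pth("marks.bed"), pth("de_ranks.tsv"),
               pth("gene_coords.tsv"))
    add_stage("simulate", files)
  }

  if ("annotate" %in% stages) {
    an_cfg <- cfg$annotate %||% list()
    strategy <- an_cfg$strategy %||% "all_significant"
    windows <- unlist(an_cfg$windows %||% c(100L, 500L))
    gene_window_bp <- an_cfg$gene_window_bp %||% 1e6
    tissues <- names(state$catalogs)
    sel <- lapply(state$catalogs, select_eqtl_snps, strategy = strategy,
                  panel = state$panel)
    cats <- setNames(sel, paste0(tissues, "_eqtl"))
    all_eqtl <- union_annotation(sel)
    win <- window_annotations(all_eqtl, state$panel, windows = windows)
    cats <- c(cats, win)
    genes_used <- unique(unlist(lapply(state$catalogs, function(ct)
      ct$gene[ct$significant %in% TRUE & ct$snp %in% all_eqtl])))
    cats$gene_window <- gene_window_annotation(
      genes_used, state$gene_coords, state$panel, window_bp = gene_window_bp)
    if (isTRUE(an_cfg$intersect_marks))
      cats$eqtl_mark_intersect <- intersect_with_intervals(
        all_eqtl, state$marks, state$panel)
    sharedness <- an_cfg$sharedness %||% "none"
    if (sharedness %in% c("broad", "narrow")) {
      labels <- if (sharedness == "broad") {
        broad_classify(state$catalogs[[1L]], state$catalogs[[2L]])
      } else {
        narrow_classify(state$catalogs[[1L]], state$catalogs[[2L]],
                        min_overlap = an_cfg$min_overlap %||% 35L,
                        r_cutoff = an_cfg$r_cutoff %||% 0.35)
      }
      for (t in tissues) {
        spec_lab <- paste0(t, "_specific")
        cats[[paste0(t, "_specific_eqtl")]] <-
          unique(labels$snp[labels$label == spec_lab])
      }
    }
    if (!is.null(an_cfg$de_tissue))
      cats[[paste0("de_top_decile_", an_cfg$de_tissue)]] <-
        top_decile_de_eqtls(state$catalogs, state$de_ranks, an_cfg$de_tissue)
    empty <- vapply(cats, length, integer(1)) == 0L
    if (any(empty)) {
      message("dropping empty annotation categories: ",
              paste(names(cats)[empty], collapse = ", "))
      cats <- cats[!empty]
    }
    state$annot <- annotation_matrix(state$panel, cats)
    write_annot(state$annot, pth("annot.tsv"))
    add_stage("annotate", pth("annot.tsv"))
  }

  if ("ldscore" %in% stages) {
    ld_cfg <- cfg$ldscore %||% list()
    state$ldscores <- stratified_ld_scores(
      state$panel, state$annot,
      window_bp = ld_cfg$window_bp %||% 1e6,
      adjusted = ld_cfg$adjusted %||% TRUE
    )
    write_ldscores(state$ldscores, state$annot, pth("ld"))
    add_stage("ldscore", c(pth("ld.ldscore.tsv"), pth("ld.sizes.tsv")))
  }

  if ("gwas" %in% stages) {
    gw <- cfg$gwas
    cats <- colnames(state$ldscores$scores)
    state$sumstats <- list()
    files <- character()
    for (trait in names(gw$traits)) {
      tau <- setNames(rep(0, length(cats)), cats)
      spec <- unlist(gw$traits[[trait]])
      bad <- setdiff(names(spec), cats)
      if (length(bad)) stop("trait '", trait, "' names unknown categories: ",
                            paste(bad, collapse = ", "))
      tau[names(spec)] <- spec
      cfg_t <- state$config
      cfg_t$seed <- state$config$seed + match(trait, names(gw$traits))
      ss <- gen_gwas_sumstats(
        state$panel, state$annot, state$ldscores, cfg_t, tau = tau,
        intercept_a = gw$intercept_a %||% 0,
        n = gw$n %||% state$config$gwas_n
      )
      state$sumstats[[trait]] <- ss
      f <- pth("sumstats_", trait, ".tsv")
      write_sumstats(ss, f)
      files <- c(files, f)
    }
    add_stage("gwas", files)
  }

  if ("classify" %in% stages) {
    cl <- cfg$classify %||% list()
    tissues <- names(state$catalogs)
    pairs <- probe_pair_correlations(
      state$catalogs[[1L]], state$catalogs[[2L]], within_tissue = TRUE,
      missing_floor = cl$missing_floor %||% 10L
    )
    broad <- broad_classify(state$catalogs[[1L]], state$catalogs[[2L]])
    narrow <- narrow_classify(
      state$catalogs[[1L]], state$catalogs[[2L]],
      min_overlap = cl$min_overlap %||% 35L,
      r_cutoff = cl$r_cutoff %||% 0.35,
      pairs = pairs
    )
    state$labels <- rbind(broad, narrow)
    state$pairs <- pairs
    data.table::fwrite(state$labels, pth("sharedness_labels.tsv"), sep = "\t")
    data.table::fwrite(pairs, pth("probe_pair_correlations.tsv"), sep = "\t")
    add_stage("classify", c(pth("sharedness_labels.tsv"),
                            pth("probe_pair_correlations.tsv")))
  }

  if ("regress" %in% stages) {
    rg <- cfg$regress %||% list()
    state$fits <- list()
    files <- character()
    for (trait in names(state$sumstats)) {
      fit <- sldsr_fit(
        state$sumstats[[trait]], state$ldscores, annot = state$annot,
        n_blocks = rg$n_blocks %||% 100L,
        fit_intercept = rg$fit_intercept %||% TRUE
      )
      state$fits[[trait]] <- fit
      f <- pth("results_", trait, ".tsv")
      data.table::fwrite(fit$results, f, sep = "\t")
      files <- c(files, f)
    }
    add_stage("regress", files)
  }

  if ("meta" %in% stages) {
    if (length(state$fits) < 2L)
      stop("meta stage needs at least two traits in the gwas config")
    category <- cfg$meta$category %||%
      grep("_eqtl$", state$fits[[1L]]$results$category, value = TRUE)[1L]
    est <- vapply(state$fits, function(f)
      f$results$tau[f$results$category == category], numeric(1))
    ses <- vapply(state$fits, function(f)
      f$results$tau_se[f$results$category == category], numeric(1))
    mm <- ivw_meta(est, ses)
    d <- data.frame(category = category,
                    pooled_coefficient = mm$pooled_coefficient,
                    pooled_se = mm$pooled_se, pooled_z = mm$pooled_z,
                    pooled_p = mm$pooled_p, k_traits = mm$k_traits)
    data.table::fwrite(d, pth("meta.tsv"), sep = "\t")
    state$meta <- mm
    add_stage("meta", pth("meta.tsv"))
  }

  manifest$out_dir <- out_dir
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest)[c("tool", "config_hash", "seed",
                                           "stages")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(manifest, "state") <- state
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, config %s\n", x$seed, x$config_hash))
  for (st in x$stages)
    cat(sprintf("  %-10s %d file(s)\n", st$name, length(st$outputs)))
  invisible(x)
}
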