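# sldsr — stratified LD score regression with tissue-specific eQTL annotations

Expression quantitative trait loci (eQTLs) — SNPs associated with the
expression level of a gene — are a standard bridge between GWAS hits and
biological function, but their effects may be tissue-specific. This package
quantifies, genome-wide, how much cis-eQTLs discovered in one tissue (e.g.
whole blood) versus another (e.g. brain) contribute to the SNP-heritability
of complex traits, and whether *tissue-specific* eQTLs carry signal beyond
eQTLs in general. It is aimed at statistical geneticists who want a fully
self-contained, testable implementation of this analysis: every input a real
study would download (reference genotypes, eQTL catalogs, GWAS summary
statistics, histone-mark intervals, differential-expression rankings) can be
simulated with known ground truth.

## The model

For SNP *j*, annotation categories *c* with binary memberships
*a<sub>cj</sub>*, and stratified LD scores

&nbsp;&nbsp;&nbsp;&nbsp;ℓ(j,c) = Σ<sub>k ∈ c, |pos<sub>k</sub> − pos<sub>j</sub>| ≤ w</sub> r²<sub>jk</sub>,

GWAS test statistics follow, under a polygenic model,

&nbsp;&nbsp;&nbsp;&nbsp;E[χ²<sub>j</sub>] = 1 + N·a + N·Σ<sub>c</sub> τ<sub>c</sub>·ℓ(j,c),

where N is the GWAS sample size, *a* absorbs confounding, and τ<sub>c</sub>
is the per-SNP heritability contributed by category *c*. Weighted
least-squares regression of χ² on the N·ℓ(j,c) partitions SNP-heritability
into h²<sub>annot</sub>(C) = Σ<sub>j∈C</sub> Σ<sub>c</sub> τ<sub>c</sub>
a<sub>cj</sub>; the **enrichment** of a category is its share of h² divided
by its share of SNPs (1 = no enrichment). Uncertainty comes from a
delete-one block jackknife over contiguous SNP blocks; enrichment is tested
one-tailed; cross-trait evidence is pooled by fixed-effects inverse-variance
weighting.

Tissue-sharedness of eQTLs is classified two ways:

* **broad** — an eQTL is shared iff its gene has significant eQTLs in both
  tissues (SNP identity irrelevant);
* **narrow** — an eQTL is shared iff its probe's effect sizes correlate above
  0.35 with a probe of the same gene in the other tissue, over at least 35
  eQTLs significant in both probes (correlations over fewer than 10
  overlapping eQTLs are treated as missing).

## Worked example

Simulate a two-tissue study, build eQTL annotations, compute stratified LD
scores, simulate a GWAS in which blood eQTLs carry extra per-SNP
heritability (τ = 6e-6) and brain eQTLs none, and fit the model:

```r
library(sldsr)

cfg   <- simulation_config(seed = 42)
panel <- gen_reference_panel(cfg)
eq    <- gen_eqtl_catalogs(panel, cfg)

eqtl_snps <- lapply(eq$catalogs, select_eqtl_snps,
                    strategy = "all_significant", panel = panel)
annot <- annotation_matrix(panel, list(blood_eqtl = eqtl_snps$blood,
                                       brain_eqtl = eqtl_snps$brain))
ld    <- stratified_ld_scores(panel, annot, window_bp = 1e6)
ss    <- gen_gwas_sumstats(panel, annot, ld, cfg,
                           tau = c(base = 1e-6, blood_eqtl = 6e-6,
                                   brain_eqtl = 0), n = 50000)
fit   <- sldsr_fit(ss, ld, annot = annot, n_blocks = 100)
fit
#> <sldsr_fit> 3000 SNPs, 100 jackknife blocks, mean chi2 4.447
#>   intercept 0.7108 (SE 0.4978), h2_total 0.0149 (SE 0.0021)
#>     category       tau    tau_se   tau_z     p_tau size prop_snps h2_annot
#> 1       base 8.301e-07 8.440e-07  0.9836 1.627e-01 3000    1.0000 0.014910
#> 2 blood_eqtl 6.017e-06 3.684e-07 16.3302 3.007e-60 1931    0.6437 0.013727
#> 3 brain_eqtl 4.236e-07 3.762e-07  1.1259 1.301e-01 1892    0.6307 0.009556
#>   h2_annot_se prop_h2 enrichment enrichment_se enrichment_p
#> 1    0.002121  1.0000      1.000       0.00000           NA
#> 2    0.001398  0.9207      1.430       0.06412    9.670e-12
#> 3    0.001307  0.6409      1.016       0.02821    2.824e-01
```

The planted blood coefficient is recovered (τ̂ = 6.0e-6, one-tailed
coefficient p ≈ 3e-60; enrichment 1.43 over 64% of SNPs, p ≈ 1e-11), the
null brain category is flat (τ̂ ≈ 4e-7, enrichment p = 0.28), and the base
category's enrichment is 1 by construction. Note that at this desk scale the
eQTL categories cover most of the short chromosome, so enrichments are
numerically modest even for a strong planted signal.

Tissue-sharedness with the narrow definition:

```r
labels <- narrow_classify(eq$catalogs$blood, eq$catalogs$brain)
table(labels$label)
#>   blood_shared blood_specific   brain_shared brain_specific
#>           2407           1304           2458           1256
```

The full workflow (simulate → annotate → ldscore → gwas → classify →
regress → meta) also runs from one YAML config via `run_pipeline()` or the
`inst/cli/eqtl-stratify` script; every stage writes TSV/BED outputs and a
manifest of file digests.

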