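# Example pipeline configuration for `eqtl-stratify run` / run_pipeline().
# Two simulated traits: traitA loads on blood eQTLs, traitB on brain eQTLs.
seed: 1
simulate:
  n_ref_individuals: 300
  n_snps: 1500
  n_ld_blocks: 15
  n_genes: 12
  eqtl_sample_sizes:
    blood: 300
    brain: 300
  mark_overlap_fraction: 0.5
annotate:
  strategy: all_significant
  windows: [100, 500]
  gene_window_bp: 50000
  sharedness: broad
ldscore:
  window_bp: 1000000
  adjusted: true
gwas:
  n: 30000
  traits:
    traitA:
      base: 1.0e-6
      blood_eqtl: 5.0e-6
    traitB:
      base: 1.0e-6
      brain_eqtl: 5.0e-6
classify:
  min_overlap: 35
  r_cutoff: 0.35
  missing_floor: 10
regress:
  n_blocks: 60
meta:
  category: blood_eqtl
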