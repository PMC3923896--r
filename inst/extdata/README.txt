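Reference tables for the ssalar01 Atlantic salmon 132K Axiom array.

ssalar01_qc_ledger.tsv
  Published QC accounting for the array by SNP discovery source (RR-Seq,
  RAD-Seq, RNA-Seq, other): total candidate SNPs tiled, SNPs excluded for
  low-quality clusters, monomorphic SNPs, the high-quality polymorphic set,
  Mendelian-error exclusions, and the final filtered set. The derived rows
  (high_quality_polymorphic, final_filtered) follow from the exclusion rows
  by subtraction; ledger_arithmetic() recomputes them.

ssalar01_chromosome_snps.tsv
  Number of QC-filtered SNPs assigned to each of the 29 Atlantic salmon
  chromosome pairs by sire-based linkage mapping (chromosome and linkage
  group nomenclature of the community map). 40,214 of 43,696
  sire-informative SNPs were assignable (92%).
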