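# dupsnp

SNP array genotyping and linkage grouping for duplicated genomes.

## What this package is for

Atlantic salmon (and salmonids generally) carry the residue of a
whole-genome duplication. That makes two routine tasks hard:

1. **SNP discovery** — fixed differences between paralogous loci (PSVs)
   look exactly like SNPs once reads from both paralogs co-align, so naive
   candidate lists are heavily contaminated.
2. **Array genotyping** — probes hybridise to both paralogs, producing
   multi-site variants (MSVs, bi-locus genotypes AAAA/AAAB/AABB) and
   off-target variants (OTVs, a low-intensity zero-contrast cluster that a
   naive caller miscalls heterozygous).

`dupsnp` implements the full desk-side pipeline used when building and
validating a high-density salmon genotyping array, for researchers who
want to reproduce, stress-test, or adapt that analysis chain:

* **Candidate filtering** — haploid-heterozygote PSV exclusion (a het call
  at genotype quality > 20 in a haploid individual can only be paralogy),
  pooled allele-frequency (≤ 0.1) and depth (≤ 10) thresholds, repeat
  masking (BED, 0-based half-open vs 1-based variant positions),
  per-family Mendelian-error (≥ 2 in any family) and segregation-distortion
  (χ² p < 0.05) filters, transversion + MAF ≥ 0.1 selection for
  transcriptome candidates, and probe-recommendation-based array content
  selection with ordered fill rules.
* **Axiom-style genotype calling** — per-channel quantile normalisation,
  median-polish summarisation of replicate probes, the contrast–size
  transform (contrast = log₂A − log₂B, size = (log₂A + log₂B)/2), an
  exhaustive two-boundary scan to initialise three genotype clusters, a
  Bayesian conjugate-blend update of a 2-D Gaussian mixture prior
  (posterior reusable as a prior), maximum-responsibility calls with a
  0.95 no-call threshold, and an EM-based OTV detector.
* **Six-category SNP QC** (PolyHighRes, MonoHighRes, CallRateBelowThreshold,
  NoMinorHomozygote, OTV, Other), a zero-tolerance pedigree Mendelian
  filter, best-probeset-per-SNP selection, and the standard accounting
  ledger with per-source columns.
* **Chromosome assignment** by sire-based two-point linkage. Male
  salmonids barely recombine, so a sire transmits each chromosome intact;
  a phase-unknown pair LOD
  `Z = log10 L(θ̂)/L(0.5)` with
  `L(θ) = ½[θ^R(1−θ)^(N−R) + (1−θ)^R θ^(N−R)]`
  reaches `(N−1)·log10 2 ≈ 2.71` for a single sire with 10 offspring and
  zero recombinants — which is why the layered "autogroup" ladder
  (LOD 5 → 4 → 3 → 2.5) deliberately ends below the conventional 3.0.
* **Population structure** — genome-wide identity-by-state distance
  (Plink DST convention) and classical multidimensional scaling.
* **Genetic sexing** from Y-specific (sdY) probe intensities by a
  largest-gap split with a relative separation guard.
* **Synthetic data with ground truth** — genomes with paralog pairs,
  structured populations (Balding–Nichols drift), pedigrees with
  sex-specific recombination, candidate tables with PSV/error
  contamination, two-channel intensities with MSV/OTV geometry, and
  bimodal Y-probe signals. Every stage of the pipeline is validated
  against these truth labels.

## Worked example

```r
library(dupsnp)

# the analytic linkage quantity: one sire, 10 offspring, no recombinants
r <- twopoint_lod(R = 0, N = 10)
sprintf("LOD = %.3f at theta = %g", r$lod, r$theta)
#> "LOD = 2.709 at theta = 0"

# a reduced end-to-end run (400 array SNPs from 1,200 candidates)
cfg <- pipeline_config(seed = 1, n_markers = 400, n_candidates = 1200)
res <- run_pipeline(cfg)
res$manifest[, c("stage", "n_in", "n_out")]
#>       stage n_in n_out
#> 1  simulate    0  1200
#> 2    filter 1200   870
#> 3     array  870   400
#> 4      call  400 38400
#> 5        qc  400   341
#> 6       map  160   157
#> 7 popstruct  341    72
#> 8       sex   96    96

res$qc$ledger[, c("row", "Total")]
#>                        row Total
#> 1         total_candidates   400
#> 2     low_quality_clusters    44
#> 3              monomorphic     0
#> 4 high_quality_polymorphic   356
#> 5          mendelian_error    15
#> 6           final_filtered   341
```

Reading the output: 1,200 simulated candidates lose 330 to the PSV,
frequency/depth, repeat, distortion and transversion filters; 400 survive
array content selection and are "tiled". Calling emits 38,400
probeset-by-sample calls (400 × 96 panel samples + 24 pedigree samples).
QC retains 341 SNPs after excluding 44 low-quality-cluster SNPs and 15
with pedigree Mendelian errors — the ledger's bottom row is exactly
`total − low-quality − monomorphic − Mendelian`, the same arithmetic that
yields 135,682 and 132,033 in the shipped reference ledger of the real
132K array (`inst/extdata/ssalar01_qc_ledger.tsv`). Of the retained SNPs,
160 are sire-informative; 157 (98.1%) are assigned to a chromosome with
zero cross-chromosome errors, and the Y-probe sex calls are 100%
concordant with truth on the 63 known-sex samples:

```r
res$sex$concordance
#> $concordance
#> [1] 1
#> $n_known
#> [1] 63
```

## Documentation

The methods vignette (`vignettes/array-genotyping-methods.Rmd`) describes
the models, every tunable threshold with its default and rationale, what
the synthetic generators do and do not emulate, numerical safeguards, and
known limitations.
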