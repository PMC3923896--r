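---
title: "Methods: SNP array genotyping and linkage grouping in a duplicated genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP array genotyping and linkage grouping in a duplicated genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupsnp)
```

## The problem

Salmonids descend from a whole-genome duplication and are still partly
tetraploid in behaviour. For SNP array development this creates two linked
problems. First, during SNP discovery, fixed differences between paralogous
loci (paralogous sequence variants, PSVs) masquerade as SNPs when reads from
both paralogs co-align to one reference location. Second, during array
genotyping, probes can hybridise to both paralogs, producing multi-site
variants (MSVs, with bi-locus genotypes such as AAAA/AAAB/AABB) and
off-target variants (OTVs, where flanking variation suppresses
hybridisation in some samples).

`dupsnp` implements the complete desk-side analysis chain used when
building and validating a high-density Atlantic salmon array: candidate
filtering, Axiom-style intensity clustering, QC classification, sire-based
chromosome assignment, identity-by-state population structure, and Y-probe
sexing, together with a synthetic-data module that generates every input
with known truth so each stage can be tested end-to-end.

## Candidate filtering

Filters partition their input exhaustively, with one machine-readable
removal reason per record:

* **Haploid PSV exclusion.** Reads from a haploid individual sample both
  paralogs' bases at a PSV, so a confident heterozygous call in a haploid
  (genotype quality strictly above 20) is diagnostic of paralogy and the
  candidate is removed. On error-free synthetic data the filter's precision
  and recall against the generator's truth labels are both 1.
* **Frequency/depth.** Pooled allele frequency ≤ 0.1 or read depth ≤ 10
  removes a candidate; both thresholds are inclusive on the removal side
  because that is how they are conventionally stated.
* **Pedigree filters.** Genotypes with quality ≤ 20 are masked, then a
  candidate is removed if any single family shows two or more Mendelian
  errors, or significant segregation distortion (chi-square
  goodness-of-fit without continuity correction, p < 0.05; 1:1 for
  AB × hom crosses, 1:2:1 for AB × AB). The distortion test is only applied
  to informative crosses — expected ratios are undefined otherwise, so
  uninformative crosses pass with p = 1 and a flag.
* **Transcriptome candidates.** Only transversions with predicted minor
  allele frequency ≥ 0.1 are kept (a transversion needs a single Axiom
  probe).
* **Repeat masking.** Mask intervals are 0-based half-open (BED); variant
  positions are 1-based (VCF); the conversion lives inside `mask_repeats()`
  so callers never do coordinate arithmetic.
* **Array content selection.** A candidate enters the base set when at
  least one probe direction is "recommended", or both are "neutral";
  remaining capacity is filled in order by multi-experiment candidates with
  low conversion score, dual-mapping candidates with score strictly over
  0.6, and previously verified candidates with non-zero score, with
  deterministic tie-breaks (descending score, then id). Conversion scoring
  itself is proprietary upstream software; the package accepts any score in
  [0, 1] and the generator draws stand-in scores from a beta distribution.

## Genotype calling

The caller mirrors the Axiom GT stage order. The two channels are
quantile-normalised separately across samples (each sample's sorted vector
is mapped onto the mean sorted vector, ties averaged). Quantile
normalisation assumes the genotype composition averages out across many
probesets; it is appropriate at array scale (hundreds of probesets or more)
and can be disabled (`normalize = FALSE`) for small panels, where it would
distort signal. The two replicate probes per probeset are summarised by
Tukey median polish on the log2 scale (per-sample summary = overall +
column effect, tolerance 1e-6, at most 10 sweeps), then transformed to

* contrast = log2(A) − log2(B)
* size = (log2(A) + log2(B)) / 2.

Log base 2 is the microarray convention; any fixed base only rescales the
space. Under the A-positive convention AA sits at positive contrast.

**Boundary scan.** Initial labels come from an exhaustive scan of all
placements of two ordered vertical boundaries between the sorted contrasts
(degenerate placements give one- and two-cluster labelings). A placement's
score is the sum over non-empty segments of the Gaussian log-likelihood of
the member points (segment mean, prior within-cluster SD) plus the log
prior density of that implied mean under the prior cluster location
(SD `location_sd`, default 1). The scan is fully vectorised with prefix
sums, so the O(n²) enumeration is cheap at n = 96, and the first-maximum
tie-break makes it deterministic and order-independent.

**Bayesian update.** Cluster parameters are updated by a conjugate-style
blend with pseudo-counts: posterior mean `(ν·μ0 + n·x̄)/(ν + n)`, covariance
blended the same way, posterior pseudo-count `ν + n`, weights ∝ `ν + n`.
Empty clusters keep their prior. The exact update used by the commercial
caller is proprietary; the blend is the simplest rule that satisfies the
reuse property — the posterior from one dataset can serve, unchanged, as the
prior for the next, and calling with a reused posterior is identical to
calling with a prior manually set to it. The model JSON flags this rule
explicitly. Default prior geometry: contrast means (+1.5, 0, −1.5),
diagonal covariances (SD 0.3), ν = 1, with the size mean set from the
median observed size; all configurable.

**Calls.** Responsibilities are weighted Gaussian densities normalised over
clusters; the call is the argmax, the confidence the maximum
responsibility, and calls below the threshold (default 0.95, exposed as
configuration — the commercial confidence convention is not public) become
NoCall. MSV probesets get no special caller: their shifted, compressed
three-cluster geometry is absorbed by the adaptive prior update.

**OTV detection.** A fourth component is initialised at contrast 0 and size
`min(cluster size means) − size_offset` (offset default 2 log2 units) and
the four-component mixture is refit by EM (tolerance 1e-8, max 200
iterations). Two numerical safeguards matter here. A variance floor of
0.02 on component eigenvalues prevents the classic EM degeneracy in which
a component collapses onto a single point (with a 1e-4 floor the OTV
component would spike on outliers and relabel samples on perfectly normal
probesets). And the fitted OTV component is accepted only if it keeps the
defining OTV geometry — mean contrast within 0.5 of zero and mean size at
least `size_offset/2` below the lowest genotype cluster; otherwise no
samples are relabelled. With both safeguards, detection on synthetic
probesets with 20–30% OTV samples reaches 100% sensitivity and specificity
in the test suite, and null-geometry probesets are never touched.

## QC classification

Each probeset falls into exactly one of six categories, evaluated in this
order: OTV (any OTV call), call rate below 97%, cluster separation below
the quality floor ("other"), minor allele in fewer than two samples
("monomorphic high resolution"), minor-homozygote cluster absent ("no
minor homozygote"), else "polymorphic high resolution". Only the
polymorphic-high-resolution and no-minor-homozygote categories are retained
downstream, and a final filter drops any SNP with at least one
trio-incompatible genotype in the pedigreed samples (zero tolerance;
missing genotypes never count). The cluster-separation score is the minimum
gap between adjacent cluster contrast means in pooled within-cluster SD
units, with a default floor of 3.0 — no numeric cluster-quality cutoff is
published, so the floor is a package choice exposed as configuration. The
accounting ledger maps the six categories onto the conventional report
rows: low-quality clusters = call-rate + OTV + other; the derived rows
satisfy `final = total − low-quality − monomorphic − Mendelian` per source
column, asserted at construction. When a SNP carries 5′ and 3′ probesets,
exactly one is kept: best category, then call rate, then separation.

## Chromosome assignment

Male salmonids recombine at close to zero over large chromosomal regions,
so a sire transmits each chromosome essentially intact. For markers with
the pattern AB (sire) × AA or BB (dam), the transmitted sire allele is
deduced per offspring by subtracting the dam's obligate contribution. The
phase-unknown two-point likelihood per sire is

L(θ) = ½ [θ^R (1−θ)^(N−R) + (1−θ)^R θ^(N−R)]

with family log-likelihoods summed, and the LOD is log10 L(θ̂)/L(0.5)
maximised over θ ∈ [0, 0.5] (golden-section search, tolerance 1e-6, with
the closed form Z = Σ(N−1)·log10 2, θ̂ = 0 when every family is
recombinant-free up to phase). A single sire with 10 offspring and no
recombinants gives LOD = 9·log10 2 ≈ 2.71 — which is why the final grouping
layer uses a threshold of 2.5 rather than the conventional 3.0. All-pairs
matrices are computed by tabulating the small set of distinct per-family
(R, N) tuples, so a 1,000-marker panel takes under a second.

Grouping follows a four-layer "autogroup" ladder with parameters
(LOD, max θ, min meioses, min link fraction) = (5, 2.0, 4, 0.9),
(4, 1.5, 4, 0.7), (3, 1.0, 4, 0.6), (2.5, 0.5, 4, 0.3). The original
tool's tuple semantics are not publicly documented; this mapping preserves
the printed values and the stringency ordering, and is configurable. Two
of its readings deserve note. The max-θ entries above 0.5 are vacuous
(θ̂ ≤ 0.5 by construction) and are kept only because the values are
printed. And the link fraction is taken over a marker's significant links
*to already-grouped markers*: anchor-seeded groups start with ~3 members,
so a fraction over all links could never reach 0.9 and no group could ever
grow; under the chosen reading groups grow outward from the anchors and the
ladder behaves as described. Markers are evaluated in batch within each
layer (order-independence), ties between groups are deferred, and markers
without qualifying links stay unassigned.

When two anchor chromosomes end up linked (one sire happening to carry
near-identical inheritance patterns on both — as occurs for chromosome
pairs 2/6 and 22/23 in real salmon panels), the conflict is resolved by
finding the family whose own between-anchor LOD stays below threshold and
regrouping the affected markers with that family's LODs alone; if no family
discriminates, the pair is reported as merged rather than silently
assigned.

## Population structure and sexing

Identity-by-state distance is 1 − mean(shared alleles)/2 over SNPs called
in both samples (the Plink DST convention; the tool's exact weighting is
not published, so the definition is recorded in the output metadata).
Missing genotypes are excluded pairwise rather than imputed. Classical MDS
double-centres the squared distances and scales the leading eigenvectors by
√λ; negative eigenvalues are truncated and each dimension's sign is fixed
by its largest-magnitude loading, making the output deterministic. Only
unrelated samples enter by default, matching how such panels are analysed
when family material is present.

Y-probe sexing averages each sample's probe intensities and splits the
sorted means at the largest gap; the upper cluster is male (only males
carry the sdY fragment). A largest-gap split was chosen over 2-means
because it is deterministic and parameter-free, and equivalent on separated
data. If the gap is under 3 pooled within-cluster SDs the data look
unimodal and every call is "unknown" — the guard is relative, so calls are
scale-invariant.

## The synthetic-data module

The generators are first-class, tested code; every output carries truth
labels, and each generator is a pure function of its arguments including
the seed.

* **Genome**: gamma-length contigs; duplicated regions are carved as
  equal-length non-overlapping pairs until a target fraction of sequence is
  paralogous.
* **Panel**: 96 diploid samples by default — 47 farmed Scottish, two farmed
  Norwegian groups of 8, 33 wild — plus one haploid. Per-SNP ancestral
  frequencies are uniform on (0.05, 0.95) and each population drifts under
  a Balding–Nichols beta model with F = (0.06, 0.10, 0.10, 0.18). The
  magnitudes of real wild-population divergence are not published for this
  design; these values were fixed once as plausible for farmed strains
  versus diverse wild fish and produce clearly separable MDS structure.
* **Candidates**: true SNPs draw pooled frequencies from panel genotypes
  and binomial read sampling at Poisson depth (mean 30); PSV sites return
  ~50/50 allele ratios in every individual, including the haploid, because
  both paralogs contribute reads — the mechanism that makes the haploid
  filter work; a small error-site class is monomorphic truth plus miscalls.
  The haploid's genotype and GQ come from a likelihood model over its
  simulated reads.
* **Families**: gene-dropping with founder haplotypes, sire recombination
  as a single per-interval rate (default 0 — the mapping procedure exploits
  only the absence of male recombination, so no positional model is
  needed), dam recombination by Haldane's map function along marker
  positions. Output is Mendelian-consistent by construction.
* **Intensities**: noise is Gaussian in contrast-size space (the space the
  caller clusters in; generator and caller deliberately share the
  convention), two replicates per probeset per sample, MSV probesets
  compress and shift the contrast means toward the fixed paralog's allele,
  OTV probesets draw affected samples at (0, size − 2).
* **Y probes**: 87 probes, male level 2000 versus female 500 with probe
  noise 250 and a per-sample effect of noise/5, giving a between-sex
  separation far above the 6-SD premise used in the validation checks.

What the generators do *not* emulate — and hence what passing tests do not
show — includes read-level artefacts (mapping bias, PCR duplicates), plate
and batch effects on intensities, cryptic relatedness within populations,
non-Gaussian intensity tails, and real MSV allele-dosage mixtures beyond
the shifted-mean approximation. Results on real arrays will be noisier than
the synthetic benchmarks.

## Numerical choices and degenerate inputs

* Boundary-scan ties break on the first maximum in a fixed enumeration
  order; all-identical inputs yield a single cluster labelled by prior
  proximity.
* Covariances are kept positive definite with a 1e-6 diagonal jitter after
  blending; the OTV EM uses the 0.02 eigenvalue floor described above.
* Non-positive signals are floor-clipped to 1e-6 and flagged before the
  log transform.
* Zero-called probesets are classified "other"; populations with no called
  genotypes get NA MAF with a flag; sample pairs sharing no called SNPs get
  NA distance with a warning.
* `twopoint_lod` excludes N = 0 families and errors when nothing remains;
  grouping requires at least `min_meioses` shared meioses per pair.
* All pipeline randomness derives from one master seed through fixed
  integer substreams, so a run is reproducible end to end.

## Problem sizes

The shipped demo scenario (`pipeline_config()`) uses 6,000 candidate
sites, a 2,000-SNP array on 5 chromosomes, 96 unrelated-panel samples plus
two families of 12, and completes in a few minutes on a single core. The
test suite exercises the same stages at smaller sizes (tens of probesets,
1,000-marker linkage panels) chosen to keep each property check fast while
leaving the statistical signal unambiguous.

## Known limitations

* The conjugate-blend update and the autogroup tuple mapping are documented
  stand-ins for proprietary or undocumented algorithms; they preserve the
  published behaviour (adaptivity, reuse-as-prior, stringency ladder) but
  are not bit-compatible with the commercial tools.
* No CEL parsing or image-artefact reduction: the pipeline starts from
  two-channel intensity tables.
* No within-group marker ordering or genetic distances: with ~10 offspring
  per sire there is no power to order markers, only to group them.
* The sexing rule assumes a male-specific fragment; it would need
  recalibration for species with different sex-determination systems.
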