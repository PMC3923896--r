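#' @name variant_filtering
#' @title Candidate-SNP filters for array design in a duplicated genome
#' @description
#' Filters applied to putative SNPs discovered by pooled sequencing before
#' array design. Every filter returns an exhaustive, exclusive partition of
#' its input: `list(kept = ..., removed = ...)` where `removed` carries a
#' single machine-readable `filter_reason` per record.
NULL

partition_result <- function(candidates, remove, reason) {
  removed <- candidates[remove, , drop = FALSE]
  removed$filter_reason <- reason[remove]
  kept <- candidates[!remove, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Remove candidates heterozygous in the haploid sample (putative PSVs)
#'
#' A confidently heterozygous genotype call in a haploid individual cannot be
#' allelic variation; it marks a paralogous sequence variant. Candidates with
#' a haploid `"het"` call at genotype quality above the threshold are
#' removed; missing haploid calls are kept.
#'
#' @param candidates candidate data.frame with columns `haploid_gt`
#'   (`"hom"/"het"/"missing"`) and `haploid_gq`.
#' @param gq_threshold genotype-quality threshold; het calls with
#'   GQ strictly above it are removed (default 20).
#' @return `list(kept, removed)`; removed records have
#'   `filter_reason = "haploid_het_psv"`.
#' @export
filter_haploid_heterozygotes <- function(candidates, gq_threshold = 20) {
  gt <- candidates$haploid_gt
  gq <- candidates$haploid_gq
  remove <- !is.na(gt) & gt == "het" & !is.na(gq) & gq > gq_threshold
  partition_result(candidates, remove,
                   rep("haploid_het_psv", nrow(candidates)))
}

#' Frequency and depth filters for pooled reduced-representation candidates
#'
#' Removes candidates with pooled allele frequency <= `freq_threshold` or
#' read depth <= `depth_threshold` (both thresholds inclusive on the removal
#' side). Candidates missing either value are removed as unscorable.
#'
#' @param candidates data.frame with `pooled_freq` and `depth`.
#' @param freq_threshold removal bound on allele frequency (default 0.1).
#' @param depth_threshold removal bound on read depth (default 10).
#' @return `list(kept, removed)` with reasons `"unscorable"`,
#'   `"low_frequency"` or `"low_depth"`.
#' @export
apply_rr_filters <- function(candidates, freq_threshold = 0.1, depth_threshold = 10) {
  f <- candidates$pooled_freq; d <- candidates$depth
  unscorable <- is.na(f) | is.na(d)
  low_f <- !unscorable & f <= freq_threshold
  low_d <- !unscorable & !low_f & d <= depth_threshold
  reason <- rep(NA_character_, nrow(candidates))
  reason[unscorable] <- "unscorable"
  reason[low_f] <- "low_frequency"
  reason[low_d] <- "low_depth"
  partition_result(candidates, unscorable | low_f | low_d, reason)
}

#' Is a ref/alt substitution a transversion?
#'
#' Transitions are the purine-purine (A/G) and pyrimidine-pyrimidine (C/T)
#' exchanges; every other substitution is a transversion. Transversions are
#' preferred for Axiom probe design because each needs a single probe.
#'
#' @param ref,alt single-nucleotide alleles in `{A,C,G,T}` (vectorised).
#' @return logical vector.
#' @export
is_transversion <- function(ref, alt) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("alleles must be one of A, C, G, T", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  purine <- c("A", "G")
  !( (ref %in% purine) == (alt %in% purine) )
}

#' Transversion and MAF filter for transcriptome-derived candidates
#'
#' Keeps only transversion candidates with predicted minor allele frequency
#' at or above the threshold (inclusive). MAF is derived from the pooled
#' allele frequency as `min(f, 1 - f)`.
#'
#' @param candidates data.frame with `ref`, `alt`, `pooled_freq`.
#' @param maf_threshold retention bound (default 0.1, inclusive).
#' @return `list(kept, removed)` with reasons `"unscorable"`, `"transition"`
#'   or `"low_maf"`.
#' @export
apply_rna_filters <- function(candidates, maf_threshold = 0.1) {
  f <- candidates$pooled_freq
  unscorable <- is.na(f)
  tv <- is_transversion(candidates$ref, candidates$alt)
  maf <- pmin(f, 1 - f)
  reason <- rep(NA_character_, nrow(candidates))
  reason[unscorable] <- "unscorable"
  reason[!unscorable & !tv] <- "transition"
  reason[!unscorable & tv & maf < maf_threshold] <- "low_maf"
  partition_result(candidates, !is.na(reason), reason)
}

## lookup of trio compatibility under bi-allelic autosomal inheritance:
## offspring is possible iff one sire allele + one dam allele can form it
trio_compatible <- local({
  alleles <- list(AA = c(0L, 0L), AB = c(0L, 1L), BB = c(1L, 1L))
  tab <- array(FALSE, c(3, 3, 3), dimnames = list(names(alleles), names(alleles), names(alleles)))
  for (s in names(alleles)) for (d in names(alleles)) for (o in names(alleles)) {
    poss <- FALSE
    for (a in alleles[[s]]) for (b in alleles[[d]])
      if (identical(sort(c(a, b)), sort(alleles[[o]]))) poss <- TRUE
    tab[s, d, o] <- poss
  }
  tab
})

#' Is an offspring genotype Mendelian-inconsistent with its parents?
#'
#' Vectorised trio check under bi-allelic autosomal inheritance. Missing
#' genotypes (`NA`) never count as errors.
#'
#' @param sire,dam,offspring genotype vectors in `{"AA","AB","BB", NA}`.
#' @return logical vector, `TRUE` where transmission is impossible.
#' @export
trio_mendelian_error <- function(sire, dam, offspring) {
  n <- max(length(sire), length(dam), length(offspring))
  sire <- rep_len(sire, n); dam <- rep_len(dam, n); offspring <- rep_len(offspring, n)
  out <- rep(FALSE, n)
  known <- !is.na(sire) & !is.na(dam) & !is.na(offspring)
  out[known] <- !trio_compatible[cbind(sire[known], dam[known], offspring[known])]
  out
}

#' Count Mendelian errors per marker within one family
#'
#' @param genotypes character matrix markers x individuals.
#' @param pedigree a `pedigree`.
#' @param family family id; both parents must be genotyped columns.
#' @return integer vector of error counts, one per marker.
#' @export
count_mendelian_errors <- function(genotypes, pedigree, family) {
  fam <- pedigree[pedigree$family == family & !is.na(pedigree$sire), , drop = FALSE]
  stop_if_not(nrow(fam) > 0, "family has no offspring with recorded parents")
  sire_id <- unique(fam$sire); dam_id <- unique(fam$dam)
  stop_if_not(length(sire_id) == 1 && length(dam_id) == 1,
              "family must have a single sire and dam")
  stop_if_not(all(c(sire_id, dam_id) %in% colnames(genotypes)),
              "both parents must be genotyped")
  err <- integer(nrow(genotypes))
  for (off in fam$id) {
    if (!off %in% colnames(genotypes)) next
    err <- err + trio_mendelian_error(genotypes[, sire_id], genotypes[, dam_id],
                                      genotypes[, off])
  }
  setNames(as.integer(err), rownames(genotypes))
}

#' Chi-square test of segregation distortion within one family
#'
#' For informative crosses, offspring genotype counts are tested against the
#' Mendelian expectation by a chi-square goodness-of-fit with no continuity
#' correction: `AB x AA` expects 1:1 over `{AA, AB}`; `AB x BB` expects 1:1
#' over `{AB, BB}`; `AB x AB` expects 1:2:1 over `{AA, AB, BB}`.
#' Uninformative crosses (no heterozygous parent) return p = 1 and are
#' flagged. Offspring genotypes outside the expected classes (Mendelian
#' errors) and missing genotypes are excluded from the counts.
#'
#' @inheritParams count_mendelian_errors
#' @return data.frame `marker`, `p_value`, `informative`.
#' @export
segregation_distortion_test <- function(genotypes, pedigree, family) {
  fam <- pedigree[pedigree$family == family & !is.na(pedigree$sire), , drop = FALSE]
  stop_if_not(nrow(fam) > 0, "family has no offspring with recorded parents")
  sire_id <- unique(fam$sire); dam_id <- unique(fam$dam)
  offspring <- intersect(fam$id, colnames(genotypes))
  off_g <- genotypes[, offspring, drop = FALSE]
  sire <- genotypes[, sire_id]; dam <- genotypes[, dam_id]
  res <- data.frame(marker = rownames(genotypes),
                    p_value = 1, informative = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genotypes))) {
    s <- sire[i]; d <- dam[i]
    if (is.na(s) || is.na(d)) next
    if (s != "AB" && d != "AB") next   # uninformative
    res$informative[i] <- TRUE
    if (s == "AB" && d == "AB") {
      classes <- c("AA", "AB", "BB"); expected <- c(1, 2, 1) / 4
    } else {
      hom <- if (s == "AB") d else s
      classes <- c(hom, "AB"); expected <- c(0.5, 0.5)
    }
    obs <- table(factor(off_g[i, ], levels = classes))
    n <- sum(obs)
    if (n == 0) next
    e <- expected * n
    chi2 <- sum((as.numeric(obs) - e)^2 / e)
    res$p_value[i] <- pchisq(chi2, df = length(classes) - 1, lower.tail = FALSE)
  }
  res
}

#' Pedigree filters for RAD-derived candidates
#'
#' Removes a candidate if, in any single family, it shows two or more
#' Mendelian errors or significant segregation distortion (chi-square
#' p < `alpha`). Genotypes whose quality is not strictly above `gq_threshold`
#' are masked to missing before counting.
#'
#' @param candidates data.frame with an `id` column matching rows of
#'   `genotypes`.
#' @param genotypes character matrix markers x individuals.
#' @param pedigree a `pedigree`.
#' @param alpha distortion significance level (default 0.05).
#' @param genotype_quality optional numeric matrix matching `genotypes`;
#'   genotypes with quality <= `gq_threshold` are ignored.
#' @param gq_threshold genotype-quality retention bound (default 20,
#'   strictly above retained).
#' @return `list(kept, removed)` with reasons `"mendelian_errors"` or
#'   `"segregation_distortion"`.
#' @export
apply_rad_filters <- function(candidates, genotypes, pedigree, alpha = 0.05,
                              genotype_quality = NULL, gq_threshold = 20) {
  if (!is.null(genotype_quality)) {
    stopifnot(all(dim(genotype_quality) == dim(genotypes)))
    genotypes[!(genotype_quality > gq_threshold)] <- NA
  }
  families <- unique(pedigree$family[!is.na(pedigree$sire)])
  err_any <- rep(FALSE, nrow(genotypes))
  dist_any <- rep(FALSE, nrow(genotypes))
  for (f in families) {
    err <- count_mendelian_errors(genotypes, pedigree, f)
    sg <- segregation_distortion_test(genotypes, pedigree, f)
    err_any <- err_any | err >= 2
    dist_any <- dist_any | (sg$informative & sg$p_value < alpha)
  }
  idx <- match(candidates$id, rownames(genotypes))
  stop_if_not(!anyNA(idx), "every candidate must have genotypes")
  reason <- rep(NA_character_, nrow(candidates))
  reason[err_any[idx]] <- "mendelian_errors"
  reason[is.na(reason) & dist_any[idx]] <- "segregation_distortion"
  partition_result(candidates, !is.na(reason), reason)
}

#' Remove candidates inside repeat-masked intervals
#'
#' Mask intervals are 0-based half-open `[start, end)` (BED convention);
#' candidate positions are 1-based, so a candidate at position p is masked
#' iff `p - 1` falls inside an interval on the same contig. Candidates on
#' contigs absent from the mask are kept with a warning.
#'
#' @param candidates data.frame with `contig`, `position`.
#' @param mask data.frame with `contig`, `start`, `end` (`start < end`).
#' @return `list(kept, removed)` with reason `"repeat_masked"`.
#' @export
mask_repeats <- function(candidates, mask) {
  stop_if_not(all(mask$start < mask$end), "mask intervals must have start < end")
  hit <- rep(FALSE, nrow(candidates))
  unknown <- !(candidates$contig %in% mask$contig)
  if (any(unknown) && nrow(mask) > 0)
    warning(sum(unknown), " candidate(s) on contigs absent from the mask; kept")
  for (ctg in intersect(unique(candidates$contig), unique(mask$contig))) {
    ci <- which(candidates$contig == ctg)
    mi <- mask[mask$contig == ctg, , drop = FALSE]
    ## convert [start,end) 0-based to 1-based closed [start+1, end]
    q <- IRanges::IRanges(start = candidates$position[ci], width = 1L)
    s <- IRanges::IRanges(start = mi$start + 1L, end = mi$end)
    ov <- IRanges::overlapsAny(q, s)
    hit[ci] <- ov
  }
  partition_result(candidates, hit, rep("repeat_masked", nrow(candidates)))
}

#' Select array content from probe recommendations and fill rules
#'
#' Base inclusion follows the probe-direction recommendations: a candidate
#' enters the base set when at least one direction is `"recommended"`, or
#' when both directions are `"neutral"`. Remaining array capacity is filled,
#' in order, by (i) candidates discovered in more than one sequencing
#' experiment with a low conversion score, (ii) candidates mapping to two
#' genome locations with conversion score strictly over 0.6, and (iii)
#' previously verified candidates with a non-zero conversion score. Within
#' each fill class, ties break by descending conversion score then id.
#'
#' @param candidates data.frame with `id`, `conversion_score`, `rec_fwd`,
#'   `rec_rev`, `multi_experiment`, `dual_mapping`, `previously_verified`.
#' @param capacity total array capacity; must be >= base set size.
#' @param low_score_max upper bound defining "low" conversion score for fill
#'   rule (i) (default 0.6).
#' @return data.frame of selected candidates with a `selection_stage` column
#'   (`"base"`, `"fill_multi_experiment"`, `"fill_dual_mapping"`,
#'   `"fill_previously_verified"`).
#' @export
select_array_content <- function(candidates, capacity, low_score_max = 0.6) {
  rec <- function(x) x == "recommended"
  neu <- function(x) x == "neutral"
  base <- rec(candidates$rec_fwd) | rec(candidates$rec_rev) |
    (neu(candidates$rec_fwd) & neu(candidates$rec_rev))
  if (capacity < sum(base))
    stop("capacity (", capacity, ") smaller than base set (", sum(base),
         "); truncation of recommended content is not allowed", call. = FALSE)
  sel <- candidates[base, , drop = FALSE]
  sel$selection_stage <- "base"
  remaining <- capacity - nrow(sel)
  pool <- candidates[!base, , drop = FALSE]
  fill_classes <- list(
    fill_multi_experiment = pool$multi_experiment &
      pool$conversion_score < low_score_max,
    fill_dual_mapping = pool$dual_mapping & pool$conversion_score > 0.6,
    fill_previously_verified = pool$previously_verified & pool$conversion_score > 0)
  for (stage in names(fill_classes)) {
    if (remaining <= 0) break
    elig <- pool[fill_classes[[stage]] & !(pool$id %in% sel$id), , drop = FALSE]
    elig <- elig[order(-elig$conversion_score, elig$id), , drop = FALSE]
    take <- head(elig, remaining)
    if (nrow(take) > 0) {
      take$selection_stage <- stage
      sel <- rbind(sel, take)
      remaining <- capacity - nrow(sel)
    }
  }
  rownames(sel) <- NULL
  sel
}

#' Run the full reduced-representation filter chain with a stage ledger
#'
#' Applies, in order: haploid-heterozygote PSV exclusion, allele
#' frequency/depth thresholds, and repeat masking, recording input/output
#' counts per stage.
#'
#' @param candidates candidate data.frame.
#' @param mask optional repeat mask (see [mask_repeats()]).
#' @param gq_threshold,freq_threshold,depth_threshold stage thresholds.
#' @return list with `kept`, `removed` (all removed records with reasons)
#'   and `ledger` (data.frame `stage`, `n_in`, `n_removed`, `n_out`).
#' @export
rr_filter_chain <- function(candidates, mask = NULL, gq_threshold = 20,
                            freq_threshold = 0.1, depth_threshold = 10) {
  ledger <- data.frame(stage = character(0), n_in = integer(0),
                       n_removed = integer(0), n_out = integer(0))
  removed_all <- list()
  step <- function(name, res, cur) {
    ledger <<- rbind(ledger, data.frame(
      stage = name, n_in = nrow(cur), n_removed = nrow(res$removed),
      n_out = nrow(res$kept)))
    removed_all[[name]] <<- res$removed
    res$kept
  }
  cur <- candidates
  cur <- step("haploid_psv", filter_haploid_heterozygotes(cur, gq_threshold), cur)
  cur <- step("freq_depth", apply_rr_filters(cur, freq_threshold, depth_threshold), cur)
  if (!is.null(mask)) cur <- step("repeat_mask", mask_repeats(cur, mask), cur)
  list(kept = cur, removed = do.call(rbind, c(removed_all, list(make.row.names = FALSE))),
       ledger = ledger)
}
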