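#' @name snp_qc
#' @title Six-category SNP quality classification and accounting
#' @description
#' Every probeset is assigned to exactly one of the six Axiom QC
#' categories: PolyHighRes, MonoHighRes, CallRateBelowThreshold,
#' NoMinorHomozygote, OTV and Other. Only PolyHighRes and NoMinorHomozygote
#' SNPs are retained for downstream analyses; a final pedigree Mendelian
#' filter removes SNPs with any trio-incompatible genotype.
NULL

#' Per-SNP metrics from genotype calls
#'
#' Computes call rate, genotype counts, minor-allele frequency over called
#' samples, the number of samples carrying at least one minor allele, the
#' number of OTV calls and a Fisher-style cluster-separation score (minimum
#' gap between adjacent cluster contrast means divided by the pooled
#' within-cluster contrast SD; `Inf` when fewer than two clusters are
#' observed).
#'
#' @param calls character vector of calls per sample
#'   (`"AA","AB","BB","NoCall","OTV"`).
#' @param contrast optional contrast values per sample (for separation).
#' @return list of metrics.
#' @export
compute_snp_metrics <- function(calls, contrast = NULL) {
  stop_if_not(length(calls) >= 1, "at least one sample required")
  n <- length(calls)
  counts <- table(factor(calls, levels = c("AA", "AB", "BB")))
  n_called <- sum(counts)
  n_otv <- sum(calls == "OTV", na.rm = TRUE)
  call_rate <- n_called / n
  if (n_called == 0) {
    return(list(n = n, n_called = 0, call_rate = 0, counts = counts,
                maf = NA_real_, minor_samples = 0L, n_otv = n_otv,
                separation = NA_real_, minor_hom_observed = NA))
  }
  nB <- counts[["AB"]] + 2 * counts[["BB"]]
  fB <- nB / (2 * n_called)
  maf <- min(fB, 1 - fB)
  minor <- if (fB <= 0.5) "B" else "A"
  minor_samples <- if (minor == "B") counts[["AB"]] + counts[["BB"]]
                   else counts[["AB"]] + counts[["AA"]]
  minor_hom <- if (minor == "B") counts[["BB"]] else counts[["AA"]]
  sep <- Inf
  if (!is.null(contrast)) {
    gt <- calls %in% c("AA", "AB", "BB")
    obs <- split(contrast[gt], calls[gt])
    obs <- obs[vapply(obs, length, 0L) > 0]
    if (length(obs) >= 2) {
      ord <- c("BB", "AB", "AA")
      obs <- obs[order(match(names(obs), ord))]
      m <- vapply(obs, mean, 0)
      ss <- sum(vapply(obs, function(v) sum((v - mean(v))^2), 0))
      pooled <- sqrt(ss / max(1, sum(lengths(obs)) - length(obs)))
      gaps <- abs(diff(m))
      sep <- if (pooled > 0) min(gaps) / pooled else Inf
    }
  }
  list(n = n, n_called = n_called, call_rate = call_rate, counts = counts,
       maf = maf, minor_samples = as.integer(minor_samples), n_otv = n_otv,
       separation = sep, minor_hom_observed = minor_hom > 0)
}

#' Classify a SNP into one of the six QC categories
#'
#' Decision order: OTV flag, call rate below threshold, cluster separation
#' below the quality floor (Other), minor allele observed in fewer than
#' `min_minor_samples` samples (MonoHighRes), minor-homozygote cluster
#' absent (NoMinorHomozygote), else PolyHighRes. Zero called samples always
#' yields Other.
#'
#' @param metrics list from [compute_snp_metrics()].
#' @param call_rate_threshold SNPs with call rate strictly below this are
#'   CallRateBelowThreshold (default 0.97).
#' @param min_minor_samples minimum samples carrying the minor allele for a
#'   polymorphic category (default 2).
#' @param separation_floor minimum cluster-separation score (pooled-SD
#'   units, default 3).
#' @param min_otv_calls OTV category when at least this many samples are
#'   called OTV (default 1).
#' @return category string.
#' @export
classify_snp <- function(metrics, call_rate_threshold = 0.97,
                         min_minor_samples = 2, separation_floor = 3,
                         min_otv_calls = 1) {
  if (metrics$n_called == 0 && metrics$n_otv < min_otv_calls) return("Other")
  if (metrics$n_otv >= min_otv_calls) return("OTV")
  if (metrics$call_rate < call_rate_threshold) return("CallRateBelowThreshold")
  if (!is.infinite(metrics$separation) && metrics$separation < separation_floor)
    return("Other")
  if (metrics$minor_samples < min_minor_samples) return("MonoHighRes")
  if (!isTRUE(metrics$minor_hom_observed)) return("NoMinorHomozygote")
  "PolyHighRes"
}

#' QC categories retained for downstream analyses
#' @return character vector.
#' @export
retained_categories <- function() c("PolyHighRes", "NoMinorHomozygote")

#' Classify every probeset in a call table
#'
#' @param calls data.frame `probeset_id`, `sample_id`, `call`, `confidence`.
#' @param points optional named list of contrast-size data.frames per
#'   probeset (for separation scores).
#' @param ... thresholds passed to [classify_snp()].
#' @return data.frame `probeset_id`, `category`, `call_rate`, `maf`,
#'   `minor_samples`, `separation`, `retained`.
#' @export
classify_probesets <- function(calls, points = NULL, ...) {
  out <- lapply(split(calls, calls$probeset_id), function(d) {
    ctr <- if (!is.null(points)) {
      p <- points[[d$probeset_id[1]]]
      if (!is.null(p)) p$contrast[match(d$sample_id, sort(unique(d$sample_id)))]
    }
    m <- compute_snp_metrics(d$call, ctr)
    data.frame(probeset_id = d$probeset_id[1],
               category = classify_snp(m, ...),
               call_rate = m$call_rate, maf = m$maf,
               minor_samples = m$minor_samples,
               separation = m$separation, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$retained <- res$category %in% retained_categories()
  rownames(res) <- NULL
  res
}

#' Final pedigree Mendelian filter
#'
#' A SNP fails when at least one pedigreed trio shows a Mendelian-impossible
#' genotype (missing genotypes never count). SNPs pass vacuously when no
#' pedigreed samples are genotyped.
#'
#' @param genotypes character matrix markers x samples with values
#'   `"AA"/"AB"/"BB"` or `NA` (NoCall/OTV should be passed as `NA`).
#' @param pedigree a `pedigree`.
#' @return named logical vector, `TRUE` = pass.
#' @export
pedigree_mendelian_filter <- function(genotypes, pedigree) {
  fams <- unique(pedigree$family[!is.na(pedigree$sire)])
  err <- integer(nrow(genotypes))
  for (f in fams) {
    fam <- pedigree[pedigree$family == f & !is.na(pedigree$sire), , drop = FALSE]
    parents <- c(unique(fam$sire), unique(fam$dam))
    if (!all(parents %in% colnames(genotypes))) next
    if (!any(fam$id %in% colnames(genotypes))) next
    err <- err + count_mendelian_errors(genotypes, pedigree, f)
  }
  setNames(err == 0, rownames(genotypes))
}

#' Keep the best probeset per SNP
#'
#' When a SNP is interrogated by independent 5' and 3' probesets, keep
#' exactly one: highest category rank (PolyHighRes > NoMinorHomozygote >
#' MonoHighRes > CallRateBelowThreshold > OTV > Other), then higher call
#' rate, then higher separation score, then probeset id.
#'
#' @param qc data.frame from [classify_probesets()] plus a `snp_id` column.
#' @return subset of `qc`, one row per SNP.
#' @export
choose_best_probeset <- function(qc) {
  stop_if_not("snp_id" %in% names(qc), "qc needs a snp_id column")
  rank_of <- match(qc$category,
                   c("PolyHighRes", "NoMinorHomozygote", "MonoHighRes",
                     "CallRateBelowThreshold", "OTV", "Other"))
  ord <- order(qc$snp_id, rank_of, -qc$call_rate,
               -ifelse(is.finite(qc$separation), qc$separation, .Machine$double.xmax),
               qc$probeset_id)
  s <- qc[ord, , drop = FALSE]
  out <- s[!duplicated(s$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Array QC accounting ledger
#'
#' Builds the stage accounting used to report array performance: per source
#' column, total candidates, low-quality clusters (CallRateBelowThreshold +
#' OTV + Other), monomorphic (MonoHighRes), high-quality polymorphic
#' (PolyHighRes + NoMinorHomozygote), Mendelian errors among the
#' high-quality polymorphic set, and the final filtered count. Internal
#' consistency (`final = total - low_quality - monomorphic - mendelian`) is
#' asserted.
#'
#' @param qc data.frame with columns `source`, `category` and
#'   `mendelian_pass` (logical; only consulted for retained categories).
#' @return data.frame with a `row` column and one column per source plus
#'   `Total`.
#' @export
qc_ledger <- function(qc) {
  stop_if_not(all(c("source", "category", "mendelian_pass") %in% names(qc)),
              "qc needs source, category, mendelian_pass")
  sources <- sort(unique(qc$source))
  lowq_cats <- c("CallRateBelowThreshold", "OTV", "Other")
  count <- function(sel) {
    v <- vapply(sources, function(s) sum(sel & qc$source == s), 0L)
    c(v, Total = sum(sel))
  }
  hq <- qc$category %in% retained_categories()
  rows <- rbind(
    total_candidates = count(rep(TRUE, nrow(qc))),
    low_quality_clusters = count(qc$category %in% lowq_cats),
    monomorphic = count(qc$category == "MonoHighRes"),
    high_quality_polymorphic = count(hq),
    mendelian_error = count(hq & !qc$mendelian_pass),
    final_filtered = count(hq & qc$mendelian_pass))
  ledger <- data.frame(row = rownames(rows), rows, row.names = NULL,
                       check.names = FALSE)
  check <- ledger_arithmetic(rows["total_candidates", ],
                             rows["low_quality_clusters", ],
                             rows["monomorphic", ],
                             rows["mendelian_error", ])
  if (!all(check$final_filtered == rows["final_filtered", ]))
    stop("inconsistent ledger counts", call. = FALSE)
  ledger
}

#' Derived rows of the QC accounting ledger
#'
#' From the exclusion-stage counts, computes the high-quality polymorphic
#' count (`total - low_quality - monomorphic`) and the final filtered count
#' (`high_quality_polymorphic - mendelian`). All arguments vectorise over
#' source columns.
#'
#' @param total,low_quality,monomorphic,mendelian numeric vectors.
#' @return list with `high_quality_polymorphic` and `final_filtered`.
#' @export
ledger_arithmetic <- function(total, low_quality, monomorphic, mendelian) {
  hq <- total - low_quality - monomorphic
  if (any(hq < 0)) stop("inconsistent ledger counts: negative high-quality row",
                        call. = FALSE)
  fin <- hq - mendelian
  if (any(fin < 0)) stop("inconsistent ledger counts: negative final row",
                         call. = FALSE)
  list(high_quality_polymorphic = hq, final_filtered = fin)
}

#' Mean spacing between SNPs over an assembly
#'
#' @param genome_bp total assembly length in bp.
#' @param n_snps number of SNPs.
#' @return mean spacing in bp.
#' @export
snp_spacing <- function(genome_bp, n_snps) {
  stop_if_not(n_snps > 0, "n_snps must be positive")
  genome_bp / n_snps
}
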