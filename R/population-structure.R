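#' @name population_structure
#' @title Per-population allele frequencies, IBS distance and classical MDS
NULL

genotype_dosage <- function(genotypes) {
  d <- matrix(NA_real_, nrow(genotypes), ncol(genotypes),
              dimnames = dimnames(genotypes))
  d[genotypes == "AA"] <- 0
  d[genotypes == "AB"] <- 1
  d[genotypes == "BB"] <- 2
  d
}

#' Per-population minor allele frequencies and segregation flags
#'
#' Computes, per SNP and population, the minor allele frequency over called
#' genotypes of the selected samples, plus flags for segregation at
#' `MAF != 0` and `MAF > maf_threshold`. By convention only unrelated
#' samples should be supplied when family material was genotyped.
#'
#' @param genotypes character matrix markers x samples.
#' @param panel a `population_panel` (or data.frame `sample_id`,
#'   `population`).
#' @param samples sample ids to include (default: all panel samples present
#'   in the genotype matrix).
#' @param maf_threshold segregation threshold (default 0.05).
#' @return list with `maf` (matrix markers x populations; `NA` where a
#'   population has no called genotypes), `segregating` and
#'   `segregating_at_threshold` (logical matrices), `maf_threshold`.
#' @export
population_maf <- function(genotypes, panel, samples = NULL,
                           maf_threshold = 0.05) {
  info <- if (inherits(panel, "population_panel")) panel$samples else panel
  if (is.null(samples))
    samples <- intersect(info$sample_id, colnames(genotypes))
  stop_if_not(length(samples) > 0, "no panel samples in genotype matrix")
  info <- info[match(samples, info$sample_id), , drop = FALSE]
  dos <- genotype_dosage(genotypes[, samples, drop = FALSE])
  pops <- sort(unique(info$population))
  maf <- matrix(NA_real_, nrow(genotypes), length(pops),
                dimnames = list(rownames(genotypes), pops))
  for (p in pops) {
    cols <- samples[info$population == p]
    d <- dos[, cols, drop = FALSE]
    n <- rowSums(!is.na(d))
    f <- rowSums(d, na.rm = TRUE) / (2 * n)
    f[n == 0] <- NA
    maf[, p] <- pmin(f, 1 - f)
  }
  list(maf = maf,
       segregating = !is.na(maf) & maf > 0,
       segregating_at_threshold = !is.na(maf) & maf > maf_threshold,
       maf_threshold = maf_threshold)
}

#' Venn-region counts of SNP sharing between populations
#'
#' Counts SNPs segregating (MAF above the threshold) in each exclusive
#' combination of populations.
#'
#' @param pm result of [population_maf()].
#' @return named integer vector; names are `+`-joined population subsets.
#' @export
venn_counts <- function(pm) {
  seg <- pm$segregating_at_threshold
  pat <- apply(seg, 1, function(r) paste(colnames(seg)[r], collapse = "+"))
  pat[pat == ""] <- "(none)"
  tab <- table(pat)
  setNames(as.integer(tab), names(tab))
}

#' Genome-wide identity-by-state distance matrix
#'
#' For each sample pair, the per-SNP shared-allele count s in {0, 1, 2} is
#' `2 - |dose_i - dose_j|`; similarity is `mean(s) / 2` over SNPs called in
#' both samples, and distance is one minus similarity (the Plink DST
#' convention). Missing genotypes are excluded pairwise; pairs with no
#' overlapping SNPs get `NA` and a warning.
#'
#' @param genotypes character matrix markers x samples.
#' @return list with `dist` (symmetric N x N matrix, zero diagonal) and
#'   `n_shared` (per-pair non-missing SNP counts).
#' @export
ibs_distance <- function(genotypes) {
  dos <- genotype_dosage(genotypes)
  n <- ncol(dos)
  D <- matrix(0, n, n, dimnames = list(colnames(dos), colnames(dos)))
  NS <- matrix(0L, n, n, dimnames = dimnames(D))
  for (i in seq_len(n)) {
    di <- dos[, i]
    for (j in seq_len(n)) {
      if (j < i) next
      ok <- !is.na(di) & !is.na(dos[, j])
      NS[i, j] <- NS[j, i] <- sum(ok)
      if (!any(ok)) {
        D[i, j] <- D[j, i] <- NA
        next
      }
      d <- mean(abs(di[ok] - dos[ok, j])) / 2
      D[i, j] <- D[j, i] <- d
    }
  }
  if (anyNA(D)) warning("some sample pairs share no called SNPs")
  diag(D) <- 0
  list(dist = D, n_shared = NS)
}

#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Double-centres the squared distances, extracts the leading eigenvectors
#' scaled by the square roots of their (positive) eigenvalues, and fixes the
#' sign of each dimension so its largest-magnitude loading is positive. If
#' fewer than `k` positive eigenvalues exist, the configuration is reduced
#' with a warning.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k number of dimensions (default 2).
#' @return list with `points` (n x k matrix, centred) and `eig`
#'   (eigenvalues, non-increasing).
#' @export
classical_mds <- function(D, k = 2) {
  stop_if_not(isTRUE(all.equal(D, t(D), tolerance = 1e-8)),
              "distance matrix must be symmetric")
  stop_if_not(all(abs(diag(D)) < 1e-12), "distance matrix must have zero diagonal")
  fit <- cmdscale(as.dist(D), k = min(k, nrow(D) - 1), eig = TRUE)
  pos <- sum(fit$eig > 1e-9)
  if (pos < k) {
    warning("only ", pos, " positive eigenvalue(s); returning ", pos,
            " dimension(s)")
    k <- pos
  }
  pts <- fit$points[, seq_len(k), drop = FALSE]
  for (d in seq_len(ncol(pts))) {
    m <- which.max(abs(pts[, d]))
    if (pts[m, d] < 0) pts[, d] <- -pts[, d]
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  list(points = pts, eig = sort(fit$eig, decreasing = TRUE))
}
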