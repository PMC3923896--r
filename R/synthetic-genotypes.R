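#' Evenly spaced marker map over a set of chromosomes
#'
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers on each chromosome.
#' @param chromosome_length_mb physical length per chromosome in Mb.
#' @return data.frame `marker`, `chrom`, `pos_mb`.
#' @export
make_marker_map <- function(n_chromosomes = 5, markers_per_chromosome = 200,
                            chromosome_length_mb = 100) {
  do.call(rbind, lapply(seq_len(n_chromosomes), function(c) {
    data.frame(
      marker = sprintf("chr%02d_m%04d", c, seq_len(markers_per_chromosome)),
      chrom = sprintf("chr%02d", c),
      pos_mb = seq(0, chromosome_length_mb, length.out = markers_per_chromosome),
      stringsAsFactors = FALSE)
  }))
}

#' Simulate Mendelian-consistent family genotypes with sex-specific recombination
#'
#' Gene-drops genotypes through a pedigree. Founders receive two haplotypes
#' per chromosome drawn from the given allele frequency. Sire gametes
#' recombine at a single per-interval rate (default 0, emulating the absence
#' of male recombination in salmonids: each offspring inherits one whole sire
#' haplotype per chromosome). Dam gametes recombine between adjacent markers
#' with Haldane probability `0.5 * (1 - exp(-2 * rate * d))` for a gap of
#' `d` Mb. Output is Mendelian-consistent by construction unless a
#' genotyping error rate is set.
#'
#' @param pedigree a `pedigree` (see [make_families()]).
#' @param marker_map data.frame `marker`, `chrom`, `pos_mb`; every marker
#'   must carry a chromosome assignment.
#' @param founder_freq allele-B frequency for founder haplotypes (scalar or
#'   per-marker vector).
#' @param male_recomb per-interval recombination probability in sire meioses.
#' @param female_recomb_per_mb female recombination rate in Morgans per Mb.
#' @param genotyping_error per-genotype probability of being replaced by a
#'   random genotype.
#' @param seed integer seed.
#' @return list with `genotypes` (character matrix markers x individuals,
#'   values `"AA"/"AB"/"BB"`), `truth` (list: `chrom` per marker,
#'   `sire_haplotype` — data.frame of the sire haplotype index transmitted to
#'   each offspring per chromosome — and `founder_haplotypes`).
#' @export
simulate_family_genotypes <- function(pedigree, marker_map,
                                      founder_freq = 0.5,
                                      male_recomb = 0,
                                      female_recomb_per_mb = 0.02,
                                      genotyping_error = 0,
                                      seed = 1L) {
  pedigree <- validate_pedigree(pedigree)
  stop_if_not(all(!is.na(marker_map$chrom)),
              "every marker must be assigned to a chromosome")
  stop_if_not(!anyDuplicated(marker_map$marker), "duplicate marker ids")
  M <- nrow(marker_map)
  freq <- rep_len(founder_freq, M)
  chroms <- split(seq_len(M), marker_map$chrom)
  ## order markers by position within chromosome
  chroms <- lapply(chroms, function(ix) ix[order(marker_map$pos_mb[ix])])

  with_seed(seed, {
    hap <- list()   # id -> matrix M x 2 of alleles (0 = A, 1 = B)
    sire_hap_rows <- list()
    for (i in seq_len(nrow(pedigree))) {
      id <- pedigree$id[i]
      if (is.na(pedigree$sire[i]) && is.na(pedigree$dam[i])) {
        h <- cbind(rbinom(M, 1L, freq), rbinom(M, 1L, freq))
      } else {
        gs <- gamete(hap[[pedigree$sire[i]]], chroms, marker_map,
                     rate_per_interval = male_recomb, haldane = FALSE)
        gd <- gamete(hap[[pedigree$dam[i]]], chroms, marker_map,
                     rate_per_interval = female_recomb_per_mb, haldane = TRUE)
        h <- cbind(gs$alleles, gd$alleles)
        sire_hap_rows[[length(sire_hap_rows) + 1]] <-
          data.frame(id = id, chrom = names(chroms),
                     sire_haplotype = gs$start_hap, stringsAsFactors = FALSE)
      }
      hap[[id]] <- h
    }
    geno <- vapply(pedigree$id, function(id) {
      d <- hap[[id]][, 1] + hap[[id]][, 2]
      c("AA", "AB", "BB")[d + 1L]
    }, character(M))
    rownames(geno) <- marker_map$marker
    if (genotyping_error > 0) {
      flip <- runif(length(geno)) < genotyping_error
      geno[flip] <- sample(c("AA", "AB", "BB"), sum(flip), replace = TRUE)
    }
    list(genotypes = geno,
         truth = list(
           chrom = setNames(marker_map$chrom, marker_map$marker),
           sire_haplotype = if (length(sire_hap_rows) > 0)
             do.call(rbind, sire_hap_rows) else NULL,
           founder_haplotypes = hap[pedigree$id[is.na(pedigree$sire)]]))
  })
}

## one gamete from a parent's 2-haplotype matrix; returns transmitted alleles
## and the haplotype index active at the start of each chromosome
gamete <- function(parent_hap, chroms, marker_map, rate_per_interval, haldane) {
  alleles <- integer(nrow(parent_hap))
  start_hap <- integer(length(chroms))
  for (k in seq_along(chroms)) {
    ix <- chroms[[k]]
    cur <- sample(1:2, 1)
    start_hap[k] <- cur
    if (length(ix) > 1) {
      d <- diff(marker_map$pos_mb[ix])
      p <- if (haldane) 0.5 * (1 - exp(-2 * rate_per_interval * d))
           else rep(rate_per_interval, length(d))
      sw <- runif(length(d)) < p
      state <- cur
      alleles[ix[1]] <- parent_hap[ix[1], state]
      for (j in seq_along(sw)) {
        if (sw[j]) state <- 3L - state
        alleles[ix[j + 1]] <- parent_hap[ix[j + 1], state]
      }
    } else {
      alleles[ix] <- parent_hap[ix, cur]
    }
  }
  list(alleles = alleles, start_hap = start_hap)
}

#' Simulate population-sample genotypes from panel allele frequencies
#'
#' Draws Hardy-Weinberg genotypes for every diploid panel sample at each
#' marker, using the panel's per-population frequencies (recycled over
#' markers from the panel's frequency table rows given by `freq_rows`).
#'
#' @param panel a `population_panel`.
#' @param markers character vector of marker ids.
#' @param freq_rows rows of `panel$pop_freqs` to use (default first
#'   `length(markers)` rows).
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed.
#' @return character matrix markers x samples.
#' @export
simulate_population_genotypes <- function(panel, markers,
                                          freq_rows = seq_along(markers),
                                          missing_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "population_panel"))
  stop_if_not(length(freq_rows) == length(markers),
              "freq_rows must match markers")
  samples <- panel$samples[panel$samples$ploidy == 2, , drop = FALSE]
  popcol <- match(samples$population, colnames(panel$pop_freqs))
  with_seed(seed, {
    M <- length(markers)
    geno <- matrix(NA_character_, M, nrow(samples),
                   dimnames = list(markers, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      pf <- panel$pop_freqs[freq_rows, popcol[j]]
      d <- rbinom(M, 2L, pf)
      geno[, j] <- c("AA", "AB", "BB")[d + 1L]
    }
    if (missing_rate > 0) geno[runif(length(geno)) < missing_rate] <- NA
    geno
  })
}
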