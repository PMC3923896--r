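#' Simulate candidate SNPs with PSV contamination and a haploid diagnostic
#'
#' Generates a candidate-variant table of the kind produced by pooled
#' reduced-representation sequencing of a duplicated genome. Most sites are
#' genuine bi-allelic SNPs whose pooled allele frequency follows the panel's
#' population frequencies; a configurable fraction are paralogous sequence
#' variants (PSVs): fixed differences between duplicated loci whose reads
#' co-align, so every individual — including a haploid — shows both alleles
#' at roughly 50/50. A small fraction of sites are pure sequencing-error
#' artefacts. The haploid sample's genotype call and genotype quality are
#' derived from its simulated reads, making haploid heterozygosity the
#' diagnostic signal for paralogy.
#'
#' @param genome a `genome_model`.
#' @param panel a `population_panel`; PSV sites are preferentially placed in
#'   the genome's duplicated regions.
#' @param n_sites number of candidate sites (must not exceed
#'   `length(panel$ancestral_freqs)`).
#' @param psv_fraction expected fraction of PSV sites, in `[0,1]`.
#' @param depth_mean mean per-site pooled read depth (Poisson, >= 1).
#' @param error_rate per-read base error probability.
#' @param error_site_fraction expected fraction of error-artefact sites
#'   (monomorphic truth, apparent variation from miscalls only).
#' @param seed integer seed.
#' @return list with `candidates` (data.frame: `id`, `contig`, `position`,
#'   `ref`, `alt`, `source`, `pooled_freq`, `depth`, `haploid_gt`
#'   (`"hom"`/`"het"`/`"missing"`), `haploid_gq`, `conversion_score`,
#'   `rec_fwd`, `rec_rev`, `multi_experiment`, `dual_mapping`,
#'   `previously_verified`) and `truth` (data.frame: `id`, `class` in
#'   `{"snp","psv","error"}`, `true_freq`).
#' @export
simulate_candidate_variants <- function(genome, panel, n_sites,
                                        psv_fraction = 0.2,
                                        depth_mean = 30,
                                        error_rate = 0.005,
                                        error_site_fraction = 0.02,
                                        seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(panel, "population_panel"))
  stop_if_not(nrow(panel$samples) > 0, "empty panel")
  stop_if_not(psv_fraction >= 0 && psv_fraction <= 1, "psv_fraction must be in [0,1]")
  stop_if_not(depth_mean >= 1, "depth_mean must be >= 1")
  stop_if_not(n_sites <= length(panel$ancestral_freqs),
              "panel does not carry frequencies for n_sites sites")
  with_seed(seed, {
    cls <- sample(c("psv", "error", "snp"), n_sites, replace = TRUE,
                  prob = c(psv_fraction, error_site_fraction * (1 - psv_fraction),
                           (1 - error_site_fraction) * (1 - psv_fraction)))
    ## site placement: PSVs inside duplicated regions when any exist
    contig <- sample(genome$contigs$contig, n_sites, replace = TRUE,
                     prob = genome$contigs$length)
    clen <- setNames(genome$contigs$length, genome$contigs$contig)
    position <- 1L + as.integer(floor(runif(n_sites) * (clen[contig] - 1)))
    dp <- genome$duplicated_pairs
    if (nrow(dp) > 0) {
      for (i in which(cls == "psv")) {
        j <- sample.int(nrow(dp), 1)
        contig[i] <- dp$contig1[j]
        position[i] <- dp$start1[j] + 1L +
          as.integer(floor(runif(1) * max(1, dp$end1[j] - dp$start1[j])))
      }
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

    samples <- panel$samples
    diploid <- samples$ploidy == 2
    hap_idx <- which(samples$ploidy == 1)[1]  # may be NA
    popcol <- match(samples$population, colnames(panel$pop_freqs))

    depth <- pmax(1L, rpois(n_sites, depth_mean))
    n_dip <- sum(diploid)

    pooled_freq <- numeric(n_sites)
    hap_gt <- rep("missing", n_sites)
    hap_gq <- rep(NA_real_, n_sites)
    true_freq <- numeric(n_sites)

    for (i in seq_len(n_sites)) {
      p <- panel$ancestral_freqs[i]
      if (cls[i] == "snp") {
        ## expected pooled alt dosage across diploid samples
        pf <- panel$pop_freqs[i, popcol[diploid]]
        dos <- rbinom(n_dip, 2L, pf)
        alt_prob <- mean(dos) / 2
        true_freq[i] <- alt_prob
      } else if (cls[i] == "psv") {
        alt_prob <- 0.5    # both paralogs contribute reads; one fixed per allele
        true_freq[i] <- 0.5
      } else {
        alt_prob <- 0      # error site: alt reads arise from miscalls only
        true_freq[i] <- 0
      }
      n_alt <- rbinom(1L, depth[i], alt_prob * (1 - error_rate) +
                        (1 - alt_prob) * error_rate)
      pooled_freq[i] <- n_alt / depth[i]

      if (!is.na(hap_idx)) {
        hd <- max(1L, rpois(1L, depth_mean))
        if (cls[i] == "psv") {
          hp <- 0.5        # haploid reads sample both paralogs' bases
        } else if (cls[i] == "snp") {
          hp <- rbinom(1L, 1L, panel$pop_freqs[i, popcol[hap_idx]])
        } else {
          hp <- 0
        }
        a_alt <- rbinom(1L, hd, hp * (1 - error_rate) + (1 - hp) * error_rate)
        g <- haploid_genotype_call(hd - a_alt, a_alt, error_rate)
        hap_gt[i] <- g$gt
        hap_gq[i] <- g$gq
      }
    }

    conv <- rbeta(n_sites, 5, 2)
    rec_levels <- c("recommended", "neutral", "not recommended")
    rec_of <- function(s) {
      cut_pts <- pmin(pmax(s + rnorm(n_sites, 0, 0.1), 0), 1)
      ifelse(cut_pts > 0.65, rec_levels[1],
             ifelse(cut_pts > 0.4, rec_levels[2], rec_levels[3]))
    }
    cand <- data.frame(
      id = sprintf("snp_%06d", seq_len(n_sites)),
      contig = unname(contig), position = unname(position),
      ref = unname(ref), alt = unname(alt),
      source = sample(c("RR", "RAD", "RNA"), n_sites, replace = TRUE,
                      prob = c(0.35, 0.3, 0.35)),
      pooled_freq = pooled_freq, depth = depth,
      haploid_gt = hap_gt, haploid_gq = hap_gq,
      conversion_score = conv,
      rec_fwd = rec_of(conv), rec_rev = rec_of(conv),
      multi_experiment = runif(n_sites) < 0.05,
      dual_mapping = runif(n_sites) < 0.03,
      previously_verified = runif(n_sites) < 0.02,
      stringsAsFactors = FALSE)
    truth <- data.frame(id = cand$id, class = cls, true_freq = true_freq,
                        stringsAsFactors = FALSE)
    list(candidates = cand, truth = truth)
  })
}

## Genotype call for a haploid sample from (ref, alt) read counts under a
## simple error model: hom-ref, hom-alt, or paralog-mixture ("het", 50/50).
## GQ is the phred-scaled likelihood gap between best and second-best model.
haploid_genotype_call <- function(n_ref, n_alt, error_rate) {
  n <- n_ref + n_alt
  if (n == 0) return(list(gt = "missing", gq = NA_real_))
  e <- max(error_rate, 1e-4)
  ll <- c(hom_ref = n_ref * log10(1 - e) + n_alt * log10(e),
          hom_alt = n_alt * log10(1 - e) + n_ref * log10(e),
          het = n * log10(0.5))
  o <- order(ll, decreasing = TRUE)
  gq <- min(99, 10 * (ll[o[1]] - ll[o[2]]))
  gt <- if (names(ll)[o[1]] == "het") "het" else "hom"
  list(gt = gt, gq = as.numeric(gq))
}
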