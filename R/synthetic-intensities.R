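#' Default two-channel cluster geometry in contrast-size space
#'
#' Genotype clusters live in the (contrast, size) plane where
#' contrast = log2(A) - log2(B) and size = (log2(A) + log2(B)) / 2. Under the
#' A-positive convention AA sits at positive contrast, BB at negative, AB
#' near zero; all three share a common size. MSV probesets (one paralog
#' fixed) have their contrast means compressed and shifted toward the fixed
#' allele; OTV-affected samples collapse to a low-size, zero-contrast
#' cluster.
#'
#' @param delta half-separation of the homozygote contrast means.
#' @param size_mean common size mean (log2 units).
#' @param contrast_sd,size_sd within-cluster standard deviations.
#' @param replicate_sd replicate-probe noise added per tiled copy.
#' @param msv_shift contrast shift applied to MSV probesets.
#' @param otv_size_drop how far (log2 units) the OTV cluster sits below the
#'   genotype clusters.
#' @return list of geometry parameters.
#' @export
default_geometry <- function(delta = 1.5, size_mean = 10,
                             contrast_sd = 0.15, size_sd = 0.15,
                             replicate_sd = 0.08,
                             msv_shift = 0.75, otv_size_drop = 2) {
  list(contrast_means = c(AA = delta, AB = 0, BB = -delta),
       size_mean = size_mean, contrast_sd = contrast_sd, size_sd = size_sd,
       replicate_sd = replicate_sd, msv_shift = msv_shift,
       otv_size_drop = otv_size_drop)
}

#' Simulate two-channel probe intensities from genotypes
#'
#' Emits an Axiom-style intensity table: two replicate probe measurements per
#' probeset per sample (each probe is tiled twice on an array), with Gaussian
#' noise applied in contrast-size space and back-transformed to linear A/B
#' signals. A fraction of probesets are multi-site variants (MSV), whose
#' three bi-locus genotype clusters (AAAA/AAAB/AABB when the second paralog
#' is fixed for A) appear as a compressed, shifted three-cluster pattern. A
#' fraction are OTV probesets: samples carrying a flanking variant
#' hybridise poorly and fall in a low-size, zero-contrast cluster.
#'
#' @param genotypes character matrix probesets x samples (`"AA"/"AB"/"BB"`,
#'   `NA` allowed).
#' @param geometry see [default_geometry()]; the three genotype clusters must
#'   have distinct contrast means.
#' @param msv_fraction expected fraction of MSV probesets.
#' @param otv_fraction expected fraction of OTV probesets.
#' @param otv_sample_rate within an OTV probeset, probability that a sample
#'   is OTV-affected.
#' @param min_separation warn (not error) when cluster contrast means are
#'   closer than this.
#' @param seed integer seed.
#' @return list with `intensities` (data.frame `probeset_id`,
#'   `probe_replicate`, `sample_id`, `signal_A`, `signal_B`) and `truth`
#'   (list: `probeset_class` in `{"plain","msv","otv"}`, `otv_samples`
#'   logical matrix, `genotypes`).
#' @export
simulate_intensities <- function(genotypes, geometry = default_geometry(),
                                 msv_fraction = 0, otv_fraction = 0,
                                 otv_sample_rate = 0.3,
                                 min_separation = 0.5, seed = 1L) {
  cm <- geometry$contrast_means
  stop_if_not(length(unique(cm)) == 3, "geometry must define three distinct contrast means")
  if (min(diff(sort(cm))) < min_separation)
    warning("cluster contrast means closer than min_separation")
  P <- nrow(genotypes); S <- ncol(genotypes)
  with_seed(seed, {
    cls <- sample(c("msv", "otv", "plain"), P, replace = TRUE,
                  prob = c(msv_fraction, otv_fraction,
                           max(0, 1 - msv_fraction - otv_fraction)))
    otv_samples <- matrix(FALSE, P, S, dimnames = dimnames(genotypes))
    rows <- vector("list", P)
    for (i in seq_len(P)) {
      g <- genotypes[i, ]
      mu_c <- cm[g]
      if (cls[i] == "msv") mu_c <- mu_c / 2 + geometry$msv_shift
      mu_s <- rep(geometry$size_mean, S)
      if (cls[i] == "otv") {
        aff <- runif(S) < otv_sample_rate
        otv_samples[i, aff] <- TRUE
        mu_c[aff] <- 0
        mu_s[aff] <- geometry$size_mean - geometry$otv_size_drop
      }
      ctr <- rnorm(S, mu_c, geometry$contrast_sd)
      siz <- rnorm(S, mu_s, geometry$size_sd)
      ctr[is.na(g) & !otv_samples[i, ]] <- rnorm(sum(is.na(g) & !otv_samples[i, ]), 0, 1)
      for (rep_i in 1:2) {
        c_r <- ctr + rnorm(S, 0, geometry$replicate_sd)
        s_r <- siz + rnorm(S, 0, geometry$replicate_sd)
        rows[[i]][[rep_i]] <- data.frame(
          probeset_id = rownames(genotypes)[i] %||% sprintf("ps_%05d", i),
          probe_replicate = rep_i,
          sample_id = colnames(genotypes) %||% sprintf("s%03d", seq_len(S)),
          signal_A = 2^(s_r + c_r / 2),
          signal_B = 2^(s_r - c_r / 2),
          stringsAsFactors = FALSE)
      }
    }
    intens <- do.call(rbind, lapply(rows, function(x) do.call(rbind, x)))
    rownames(intens) <- NULL
    list(intensities = intens,
         truth = list(probeset_class = setNames(cls, rownames(genotypes)),
                      otv_samples = otv_samples,
                      genotypes = genotypes))
  })
}

#' Simulate Y-specific probe intensities bimodal by sex
#'
#' Male samples carry the male-specific sdY fragment and hybridise at a high
#' level on Y-specific probes; females produce background signal only. Each
#' sample gets a random sample-level effect plus per-probe noise, so the
#' per-sample mean intensities form two clusters whose separation is
#' controlled by `male_level - female_level` relative to the noise.
#'
#' @param panel a `population_panel` (its `samples$sex` is the truth), or a
#'   data.frame with columns `sample_id` and `sex`.
#' @param n_probes number of Y probes (default 87, >= 1).
#' @param male_level,female_level mean linear intensities
#'   (`male_level > female_level >= 0`).
#' @param noise_sd per-probe noise standard deviation.
#' @param sample_effect_sd per-sample random shift standard deviation
#'   (defaults to `noise_sd / 5`, so a noise-free run is exactly noise-free).
#' @param seed integer seed.
#' @return list with `intensities` (data.frame `sample_id`, `probe_id`,
#'   `intensity`) and `truth` (data.frame `sample_id`, `sex`).
#' @export
simulate_y_probe_intensities <- function(panel, n_probes = 87,
                                         male_level = 2000, female_level = 500,
                                         noise_sd = 250,
                                         sample_effect_sd = noise_sd / 5,
                                         seed = 1L) {
  stop_if_not(n_probes >= 1, "n_probes must be >= 1")
  stop_if_not(male_level > female_level && female_level >= 0,
              "need male_level > female_level >= 0")
  samples <- if (inherits(panel, "population_panel")) {
    panel$samples[panel$samples$ploidy == 2, , drop = FALSE]
  } else panel
  stop_if_not(all(c("sample_id", "sex") %in% names(samples)),
              "panel must provide sample_id and sex")
  with_seed(seed, {
    n <- nrow(samples)
    level <- ifelse(samples$sex == "male", male_level, female_level)
    eff <- rnorm(n, 0, sample_effect_sd)
    out <- data.frame(
      sample_id = rep(samples$sample_id, each = n_probes),
      probe_id = rep(sprintf("yprobe_%03d", seq_len(n_probes)), times = n),
      intensity = rep(level + eff, each = n_probes) +
        rnorm(n * n_probes, 0, noise_sd),
      stringsAsFactors = FALSE)
    list(intensities = out,
         truth = data.frame(sample_id = samples$sample_id, sex = samples$sex,
                            stringsAsFactors = FALSE))
  })
}
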