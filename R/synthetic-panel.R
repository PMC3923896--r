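#' Construct a structured population panel with known allele frequencies
#'
#' Emulates the validation panel of a salmon SNP array study: several farmed
#' and wild populations genotyped together, optionally including a single
#' haploid individual used for PSV diagnosis. Each SNP gets a common
#' ancestral allele frequency; each population drifts away from it under a
#' beta model (Balding-Nichols style), so downstream MDS can separate the
#' populations.
#'
#' @param populations data.frame with columns `name`, `n` (sample count) and
#'   `divergence` (drift parameter F in (0,1)). Defaults emulate a 96-sample
#'   panel: 47 farmed Scottish, two farmed Norwegian groups of 8, 33 wild.
#' @param n_sites number of SNP sites to carry frequencies for.
#' @param n_haploid number of haploid individuals appended (default 1).
#' @param seed integer seed.
#' @return Object of class `population_panel`: list with `samples`
#'   (data.frame `sample_id`, `population`, `sex`, `ploidy`),
#'   `ancestral_freqs` (length `n_sites`), `divergence` (named numeric) and
#'   `pop_freqs` (matrix sites x populations).
#' @export
make_panel <- function(populations = default_populations(),
                       n_sites = 1000, n_haploid = 1, seed = 1L) {
  stop_if_not(nrow(populations) >= 1, "at least one population required")
  stop_if_not(all(populations$n >= 1), "population sizes must be >= 1")
  stop_if_not(all(populations$divergence > 0 & populations$divergence < 1),
              "divergence must be in (0, 1)")
  with_seed(seed, {
    ids <- character(0); pop <- character(0)
    for (i in seq_len(nrow(populations))) {
      nm <- populations$name[i]
      ids <- c(ids, sprintf("%s_%03d", nm, seq_len(populations$n[i])))
      pop <- c(pop, rep(nm, populations$n[i]))
    }
    sex <- sample(c("male", "female"), length(ids), replace = TRUE)
    ploidy <- rep(2L, length(ids))
    if (n_haploid > 0) {
      ids <- c(ids, sprintf("haploid_%02d", seq_len(n_haploid)))
      pop <- c(pop, rep(populations$name[1], n_haploid))
      sex <- c(sex, rep("female", n_haploid))
      ploidy <- c(ploidy, rep(1L, n_haploid))
    }
    p0 <- runif(n_sites, 0.05, 0.95)
    fr <- matrix(NA_real_, n_sites, nrow(populations),
                 dimnames = list(NULL, populations$name))
    for (i in seq_len(nrow(populations))) {
      F <- populations$divergence[i]
      a <- p0 * (1 - F) / F
      b <- (1 - p0) * (1 - F) / F
      fr[, i] <- rbeta(n_sites, a, b)
    }
    structure(list(
      samples = data.frame(sample_id = ids, population = pop, sex = sex,
                           ploidy = ploidy, stringsAsFactors = FALSE),
      ancestral_freqs = p0,
      divergence = setNames(populations$divergence, populations$name),
      pop_freqs = fr), class = "population_panel")
  })
}

#' Default population design for the synthetic panel
#'
#' 96 diploid samples: one farmed Scottish broodstock group, two farmed
#' Norwegian groups, and a mixed wild group, with drift parameters chosen to
#' give clearly separable but realistic structure.
#' @return data.frame with columns `name`, `n`, `divergence`.
#' @export
default_populations <- function() {
  data.frame(
    name = c("farmed_scottish", "farmed_norwegian_1", "farmed_norwegian_2", "wild"),
    n = c(47L, 8L, 8L, 33L),
    divergence = c(0.06, 0.10, 0.10, 0.18),
    stringsAsFactors = FALSE)
}

#' Build a set of nuclear families for linkage and Mendelian QC
#'
#' Reference-family design: each family has one sire, one dam and a fixed
#' number of offspring, mirroring mapping panels genotyped on arrays.
#'
#' @param n_families number of families.
#' @param n_offspring offspring per family.
#' @return Object of class `pedigree`: data.frame with columns `id`, `sire`,
#'   `dam`, `family`, `sex` (parents have `NA` sire/dam).
#' @export
make_families <- function(n_families = 2, n_offspring = 10) {
  rows <- list()
  for (f in seq_len(n_families)) {
    fam <- sprintf("fam%02d", f)
    rows[[length(rows) + 1]] <- data.frame(
      id = c(sprintf("%s_sire", fam), sprintf("%s_dam", fam),
             sprintf("%s_off%02d", fam, seq_len(n_offspring))),
      sire = c(NA, NA, rep(sprintf("%s_sire", fam), n_offspring)),
      dam = c(NA, NA, rep(sprintf("%s_dam", fam), n_offspring)),
      family = fam,
      sex = c("male", "female",
              rep(c("male", "female"), length.out = n_offspring)),
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  validate_pedigree(ped)
}

#' Validate a pedigree data.frame
#'
#' Checks that referenced sires/dams exist, that no individual is its own
#' ancestor, and that parents precede their offspring (rows are reordered if
#' needed).
#' @param ped data.frame with columns `id`, `sire`, `dam`, `family`, `sex`.
#' @return the pedigree with class `pedigree`.
#' @export
validate_pedigree <- function(ped) {
  stop_if_not(all(c("id", "sire", "dam", "family", "sex") %in% names(ped)),
              "pedigree needs columns id, sire, dam, family, sex")
  stop_if_not(!anyDuplicated(ped$id), "duplicate individual ids in pedigree")
  for (col in c("sire", "dam")) {
    ref <- ped[[col]][!is.na(ped[[col]])]
    bad <- setdiff(ref, ped$id)
    if (length(bad) > 0)
      stop("pedigree references unknown ", col, " id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  ## topological order (parents first); also detects ancestry cycles
  done <- character(0); order <- integer(0); remaining <- seq_len(nrow(ped))
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(i) {
      p <- c(ped$sire[i], ped$dam[i])
      all(is.na(p) | p %in% done)
    }, logical(1))]
    if (length(ready) == 0)
      stop("pedigree contains an ancestry cycle", call. = FALSE)
    order <- c(order, ready)
    done <- c(done, ped$id[ready])
    remaining <- setdiff(remaining, ready)
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}
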