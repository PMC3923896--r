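# shared fixtures built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype matrix for one nuclear family; offspring is a list of
# per-offspring genotype vectors (one element per marker)
family_matrix <- function(sire, dam, offspring, markers = NULL,
                          family = "fam01") {
  g <- cbind(sire, dam)
  for (o in offspring) g <- cbind(g, o)
  colnames(g) <- c(sprintf("%s_sire", family), sprintf("%s_dam", family),
                   sprintf("%s_off%02d", family, seq_along(offspring)))
  rownames(g) <- markers %||% sprintf("m%03d", seq_len(nrow(g)))
  g
}

# pedigree matching family_matrix()
family_pedigree <- function(n_offspring, family = "fam01") {
  p <- make_families(1, n_offspring)
  for (col in c("id", "sire", "dam", "family"))
    p[[col]] <- sub("fam01", family, p[[col]])
  validate_pedigree(p)
}

# brute-force trio-compatibility oracle by gamete enumeration
oracle_trio_possible <- function(s, d, o) {
  al <- list(AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"))
  for (a in al[[s]]) for (b in al[[d]])
    if (paste(sort(c(a, b)), collapse = "") == o) return(TRUE)
  FALSE
}

geno_levels <- c("AA", "AB", "BB")
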