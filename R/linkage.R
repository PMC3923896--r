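#' @name linkage_grouping
#' @title Chromosome assignment by sire-based two-point linkage
#' @description
#' In male salmonids recombination is almost absent over large chromosomal
#' regions, so a sire transmits each chromosome to its offspring as one of
#' two intact haplotypes. Markers heterozygous in a sire (with a homozygous
#' dam, pattern AB x AA/BB) therefore show identical or mirrored
#' transmission patterns whenever they sit on the same chromosome, which a
#' phase-unknown two-point LOD score detects with as few as ten offspring
#' (LOD = (N-1) log10 2 = 2.7 for N = 10 without recombinants). A layered
#' "autogroup" procedure assigns markers to anchor-labelled linkage groups
#' with progressively relaxed stringency.
NULL

#' Identify sire-informative markers and transmitted sire alleles
#'
#' A marker is informative in a family when the sire is AB and the dam is
#' homozygous (AA or BB). The sire allele transmitted to each offspring is
#' deduced by subtracting the dam's obligate contribution: with dam AA,
#' offspring AA received sire-A and AB received sire-B (mirrored for dam
#' BB); genotypes incompatible with the cross (or missing) give `unknown`.
#'
#' @param genotypes character matrix markers x individuals.
#' @param pedigree a `pedigree`.
#' @return object of class `sire_transmission`: list with `informative`
#'   (logical matrix markers x families), `transmission` (list per family of
#'   integer matrices markers x offspring: +1 = sire allele A, -1 = sire
#'   allele B, 0 = unknown), and `markers`.
#' @export
select_sire_informative <- function(genotypes, pedigree) {
  pedigree <- validate_pedigree(pedigree)
  fams <- unique(pedigree$family[!is.na(pedigree$sire)])
  M <- nrow(genotypes)
  informative <- matrix(FALSE, M, length(fams),
                        dimnames = list(rownames(genotypes), fams))
  transmission <- list()
  for (fi in seq_along(fams)) {
    f <- fams[fi]
    fam <- pedigree[pedigree$family == f & !is.na(pedigree$sire), , drop = FALSE]
    sire_id <- unique(fam$sire); dam_id <- unique(fam$dam)
    stop_if_not(all(c(sire_id, dam_id) %in% colnames(genotypes)),
                "parents must be genotyped")
    offs <- intersect(fam$id, colnames(genotypes))
    sire <- genotypes[, sire_id]; dam <- genotypes[, dam_id]
    inf <- !is.na(sire) & sire == "AB" & !is.na(dam) & dam %in% c("AA", "BB")
    informative[, fi] <- inf
    tr <- matrix(0L, M, length(offs),
                 dimnames = list(rownames(genotypes), offs))
    for (o in seq_along(offs)) {
      g <- genotypes[, offs[o]]
      ## dam AA: off AA -> sire A (+1); off AB -> sire B (-1)
      tr[, o] <- ifelse(!inf | is.na(g), 0L,
                 ifelse(dam == "AA",
                        ifelse(g == "AA", 1L, ifelse(g == "AB", -1L, 0L)),
                        ifelse(g == "BB", -1L, ifelse(g == "AB", 1L, 0L))))
    }
    transmission[[f]] <- tr
  }
  structure(list(informative = informative, transmission = transmission,
                 markers = rownames(genotypes)),
            class = "sire_transmission")
}

#' Phase-unknown two-point LOD score
#'
#' Per sire/family the likelihood of a marker pair with R recombinant out of
#' N informative meioses is
#' `L(theta) = 0.5 * (theta^R (1-theta)^(N-R) + (1-theta)^R theta^(N-R))`
#' (sire phase unobserved, both phases a priori equally likely); family
#' log-likelihoods add. The LOD is `Z = log10 L(theta_hat) / L(0.5)`
#' maximised over `theta` in `[0, 0.5]` (golden-section search, tolerance
#' 1e-6, with a closed-form shortcut `Z = sum((N-1) log10 2)`, `theta = 0`
#' when every family is recombinant-free or fully "recombinant" — the two
#' are phase-equivalent).
#'
#' @param R recombinant counts per family (phase-arbitrary).
#' @param N informative meioses per family; families with `N = 0` are
#'   dropped, and all-zero N is an error.
#' @return list with `theta` and `lod`.
#' @export
twopoint_lod <- function(R, N) {
  stopifnot(length(R) == length(N), all(R >= 0), all(R <= N))
  keep <- N > 0
  R <- R[keep]; N <- N[keep]
  if (length(N) == 0) stop("no informative meioses for this pair", call. = FALSE)
  if (all(R == 0 | R == N))
    return(list(theta = 0, lod = sum(pmax(0, (N - 1)) * log10(2))))
  ll <- function(theta) {
    sum(log(0.5 * (theta^R * (1 - theta)^(N - R) +
                   (1 - theta)^R * theta^(N - R))))
  }
  opt <- optimize(ll, c(0, 0.5), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, ll(0)), c(0.5, ll(0.5)))
  cand <- cand[is.finite(cand[, 2]), , drop = FALSE]
  best <- cand[which.max(cand[, 2]), ]
  list(theta = best[1], lod = (best[2] - ll(0.5)) / log(10))
}

#' All-pairs two-point LOD matrices from sire transmissions
#'
#' Computes, for every marker pair, the total informative meioses, the
#' (phase-arbitrary) recombinant count per family, and the combined LOD and
#' recombination estimate. Pair statistics depend only on the small set of
#' distinct (R, N) family tuples, which are tabulated once, so the
#' computation scales to thousands of markers.
#'
#' @param trans a `sire_transmission`.
#' @param families subset of family names to use (default all).
#' @return list with matrices `lod`, `theta`, `n_meioses` (markers x
#'   markers; diagonal zero).
#' @export
lod_matrix <- function(trans, families = names(trans$transmission)) {
  M <- length(trans$markers)
  Ns <- list(); Rs <- list()
  for (f in families) {
    T <- trans$transmission[[f]]
    K <- (T != 0) * 1
    Nf <- K %*% t(K)
    dot <- T %*% t(T)
    same <- (dot + Nf) / 2
    Rf <- Nf - same          # phase-arbitrary; likelihood is symmetric in R, N-R
    Ns[[f]] <- Nf; Rs[[f]] <- Rf
  }
  key <- NULL
  for (f in families) {
    part <- paste(Rs[[f]], Ns[[f]], sep = "/")
    key <- if (is.null(key)) part else paste(key, part, sep = ";")
  }
  ukey <- unique(key)
  lut <- vapply(ukey, function(k) {
    parts <- do.call(rbind, lapply(strsplit(strsplit(k, ";")[[1]], "/"),
                                   as.numeric))
    if (all(parts[, 2] == 0)) return(c(theta = 0.5, lod = 0))
    r <- twopoint_lod(parts[, 1], parts[, 2])
    c(theta = r$theta, lod = r$lod)
  }, c(theta = 0, lod = 0))
  idx <- match(key, ukey)
  theta <- matrix(lut["theta", idx], M, M,
                  dimnames = list(trans$markers, trans$markers))
  lod <- matrix(lut["lod", idx], M, M,
                dimnames = list(trans$markers, trans$markers))
  n_tot <- Reduce(`+`, Ns)
  dimnames(n_tot) <- dimnames(lod)
  diag(lod) <- 0; diag(theta) <- 0
  list(lod = lod, theta = theta, n_meioses = n_tot)
}

#' Default autogroup layer parameters
#'
#' Four layers of decreasing stringency, each a tuple
#' (lod_threshold, max_theta, min_meioses, min_link_fraction). The final
#' layer's LOD threshold of 2.5 deliberately sits below the conventional
#' 3.0 so that markers segregating in a single sire with ten offspring and
#' no recombinants (LOD ~ 2.7) can still be grouped.
#' @return data.frame of layer parameters.
#' @export
default_autogroup_layers <- function() {
  data.frame(lod_threshold = c(5, 4, 3, 2.5),
             max_theta = c(2.0, 1.5, 1.0, 0.5),
             min_meioses = c(4, 4, 4, 4),
             min_link_fraction = c(0.9, 0.7, 0.6, 0.3))
}

#' Layered assignment of markers to anchor-labelled linkage groups
#'
#' Groups are seeded by anchor markers of known chromosome. Layers are
#' processed in order of decreasing stringency; within a layer, markers are
#' evaluated in batch (order-independent): a marker's significant links are
#' the pairs with LOD >= the layer threshold, theta-hat <= max_theta and
#' meioses >= min_meioses; among its significant links to already-grouped
#' markers, it joins the group holding the largest share when that share
#' reaches min_link_fraction. Batches repeat within a layer until no marker
#' moves, so groups grow outward from the anchors. Markers whose best share
#' ties between two groups are left unassigned (deferred to
#' [resolve_anchor_conflicts()]).
#'
#' @param lod result of [lod_matrix()] (list with `lod`, `theta`,
#'   `n_meioses`).
#' @param anchors data.frame `marker`, `chromosome`.
#' @param layers data.frame as [default_autogroup_layers()].
#' @return data.frame `marker`, `chromosome` (NA = unassigned), `layer`,
#'   `n_links`.
#' @export
autogroup_layers <- function(lod, anchors, layers = default_autogroup_layers()) {
  markers <- rownames(lod$lod)
  stop_if_not(all(anchors$marker %in% markers), "anchors missing from LOD matrix")
  assign <- setNames(rep(NA_character_, length(markers)), markers)
  assign[anchors$marker] <- anchors$chromosome
  layer_joined <- setNames(rep(NA_integer_, length(markers)), markers)
  n_links <- setNames(rep(0L, length(markers)), markers)
  for (li in seq_len(nrow(layers))) {
    L <- layers[li, ]
    sig <- lod$lod >= L$lod_threshold & lod$theta <= L$max_theta &
      lod$n_meioses >= L$min_meioses
    diag(sig) <- FALSE
    repeat {
      un <- names(assign)[is.na(assign)]
      if (length(un) == 0) break
      groups <- sort(unique(assign[!is.na(assign)]))
      if (length(groups) == 0) break
      joined <- character(0)
      new_assign <- assign
      for (m in un) {
        links <- sig[m, ] & !is.na(assign)
        tot <- sum(links)
        if (tot == 0) next
        counts <- vapply(groups, function(g)
          sum(links & assign == g, na.rm = TRUE), 0L)
        frac <- counts / tot
        best <- max(frac)
        if (best >= L$min_link_fraction) {
          if (sum(frac == best) > 1) next   # ambiguous between groups: defer
          g <- groups[which.max(frac)]
          new_assign[m] <- g
          layer_joined[m] <- li
          n_links[m] <- counts[which.max(frac)]
          joined <- c(joined, m)
        }
      }
      if (length(joined) == 0) break
      assign <- new_assign
    }
  }
  data.frame(marker = markers, chromosome = unname(assign[markers]),
             layer = unname(layer_joined[markers]),
             n_links = unname(n_links[markers]), stringsAsFactors = FALSE)
}

#' Detect and resolve anchor-chromosome conflicts
#'
#' Two chromosomes conflict when their anchor markers link to each other
#' above the LOD threshold — typically because one sire happens to carry
#' near-identical inheritance patterns on both. For each conflicted pair the
#' discriminating family is the one whose own between-anchor LOD stays below
#' the threshold; members of the two chromosomes are then regrouped using
#' that family's LOD alone (assigned to the chromosome whose anchors they
#' link to best, or unassigned). If no family discriminates, the pair is
#' reported as merged and left untouched.
#'
#' @param assignment data.frame from [autogroup_layers()].
#' @param trans the `sire_transmission` used to build the LOD matrices.
#' @param anchors data.frame `marker`, `chromosome`.
#' @param lod_threshold link threshold (default 2.5).
#' @return list with `assignment` (updated data.frame) and `conflicts`
#'   (data.frame `chrom1`, `chrom2`, `family_used`, `merged`).
#' @export
resolve_anchor_conflicts <- function(assignment, trans, anchors,
                                     lod_threshold = 2.5) {
  fams <- names(trans$transmission)
  fam_lod <- lapply(fams, function(f) lod_matrix(trans, families = f))
  names(fam_lod) <- fams
  all_lod <- lod_matrix(trans)
  chroms <- sort(unique(anchors$chromosome))
  conflicts <- data.frame(chrom1 = character(0), chrom2 = character(0),
                          family_used = character(0), merged = logical(0),
                          stringsAsFactors = FALSE)
  out <- assignment
  for (i in seq_along(chroms)) for (j in seq_along(chroms)) {
    if (j <= i) next
    a1 <- anchors$marker[anchors$chromosome == chroms[i]]
    a2 <- anchors$marker[anchors$chromosome == chroms[j]]
    between <- max(all_lod$lod[a1, a2, drop = FALSE])
    if (between < lod_threshold) next
    ## conflicted pair: find a family whose sire pattern discriminates
    fam_between <- vapply(fams, function(f)
      max(fam_lod[[f]]$lod[a1, a2, drop = FALSE]), 0)
    disc <- fams[fam_between < lod_threshold]
    if (length(disc) == 0) {
      conflicts <- rbind(conflicts, data.frame(
        chrom1 = chroms[i], chrom2 = chroms[j], family_used = NA_character_,
        merged = TRUE, stringsAsFactors = FALSE))
      next
    }
    f <- disc[which.min(fam_between[disc])]
    Lf <- fam_lod[[f]]$lod
    members <- out$marker[!is.na(out$chromosome) &
                            out$chromosome %in% c(chroms[i], chroms[j]) &
                            !(out$marker %in% c(a1, a2))]
    for (m in members) {
      l1 <- max(Lf[m, a1]); l2 <- max(Lf[m, a2])
      new <- if (l1 >= lod_threshold && l1 > l2) chroms[i]
             else if (l2 >= lod_threshold && l2 > l1) chroms[j]
             else NA_character_
      out$chromosome[out$marker == m] <- new
    }
    conflicts <- rbind(conflicts, data.frame(
      chrom1 = chroms[i], chrom2 = chroms[j], family_used = f,
      merged = FALSE, stringsAsFactors = FALSE))
  }
  list(assignment = out, conflicts = conflicts)
}

#' Per-chromosome marker counts from an assignment
#'
#' @param assignment data.frame from [autogroup_layers()].
#' @return data.frame `chromosome`, `n_markers`, plus a `Total` row.
#' @export
chromosome_counts <- function(assignment) {
  tab <- table(assignment$chromosome[!is.na(assignment$chromosome)])
  out <- data.frame(chromosome = names(tab), n_markers = as.integer(tab),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(chromosome = "Total", n_markers = sum(out$n_markers)))
}
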