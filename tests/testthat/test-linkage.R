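test_that("two-point LOD closed forms: single sire, two sires, independence", {
  r <- twopoint_lod(0, 10)
  expect_equal(r$lod, 9 * log10(2), tolerance = 1e-6)   # ~2.709
  expect_equal(r$theta, 0)
  r2 <- twopoint_lod(c(0, 0), c(10, 10))
  expect_equal(r2$lod, 18 * log10(2), tolerance = 1e-6) # ~5.419
  r3 <- twopoint_lod(5, 10)
  expect_equal(r3$lod, 0, tolerance = 1e-6)
  expect_equal(r3$theta, 0.5, tolerance = 1e-3)
  expect_error(twopoint_lod(0, 0), "informative")
})

test_that("LOD maximisation matches a brute-force grid over theta", {
  grid <- seq(0, 0.5, by = 0.001)
  loglik <- function(theta, R, N)
    sum(log(0.5 * (theta^R * (1 - theta)^(N - R) +
                   (1 - theta)^R * theta^(N - R))))
  set.seed(70)
  for (i in 1:100) {
    nf <- sample(1:2, 1)
    N <- sample(4:12, nf, replace = TRUE)
    R <- vapply(N, function(n) sample(0:n, 1), 0L)
    r <- twopoint_lod(R, N)
    gl <- vapply(grid, loglik, 0, R = R, N = N)
    best <- max(gl[is.finite(gl)])
    lod_grid <- (best - loglik(0.5, R, N)) / log(10)
    expect_equal(r$lod, lod_grid, tolerance = 1e-3)
    expect_lt(abs(r$theta - grid[which.max(replace(gl, !is.finite(gl), -Inf))]),
              2e-3)
  }
})

test_that("LOD with zero recombinants strictly increases with meioses", {
  lods <- vapply(2:12, function(n) twopoint_lod(0, n)$lod, 0)
  expect_true(all(diff(lods) > 0))
})

test_that("sire-informative selection deduces transmitted alleles by subtraction", {
  ped <- make_families(1, 3)
  g <- family_matrix(sire = c("AB", "AB", "AA"),
                     dam = c("AA", "AB", "AB"),
                     offspring = list(c("AB", "AA", "AA"),
                                      c("AA", "AB", "AA"),
                                      c("BB", "BB", "AA")))
  tr <- select_sire_informative(g, ped)
  expect_true(tr$informative["m001", "fam01"])
  expect_false(tr$informative["m002", "fam01"])  # dam AB: not informative
  expect_false(tr$informative["m003", "fam01"])  # sire homozygous
  t1 <- tr$transmission$fam01["m001", ]
  expect_equal(unname(t1), c(-1L, 1L, 0L))  # AB -> sire B; AA -> sire A; BB impossible
})

test_that("LOD matrix is symmetric and matches pairwise recomputation", {
  map <- make_marker_map(2, 25, 50)
  ped <- make_families(2, 10)
  fg <- simulate_family_genotypes(ped, map, seed = 71)
  tr <- select_sire_informative(fg$genotypes, ped)
  inf <- rownames(fg$genotypes)[rowSums(tr$informative) > 0]
  tr2 <- select_sire_informative(fg$genotypes[inf, , drop = FALSE], ped)
  lm <- lod_matrix(tr2)
  expect_equal(lm$lod, t(lm$lod))
  expect_equal(lm$theta, t(lm$theta))
  # spot-check five pairs against the scalar implementation
  set.seed(72)
  for (k in 1:5) {
    ij <- sample(length(inf), 2)
    R <- N <- numeric(0)
    for (f in names(tr2$transmission)) {
      a <- tr2$transmission[[f]][ij[1], ]; b <- tr2$transmission[[f]][ij[2], ]
      ok <- a != 0 & b != 0
      N <- c(N, sum(ok)); R <- c(R, sum(ok & a != b))
    }
    if (all(N == 0)) next
    r <- twopoint_lod(R[N > 0], N[N > 0])
    expect_equal(lm$lod[ij[1], ij[2]], r$lod, tolerance = 1e-9)
  }
})

test_that("autogroup assigns >= 90% of informative markers with zero cross-chromosome errors", {
  map <- make_marker_map(5, 200, 100)
  ped <- make_families(2, 10)
  fg <- simulate_family_genotypes(ped, map, male_recomb = 0, seed = 73)
  tr <- select_sire_informative(fg$genotypes, ped)
  inf <- map$marker[rowSums(tr$informative) > 0]
  tr2 <- select_sire_informative(fg$genotypes[inf, , drop = FALSE], ped)
  lm <- lod_matrix(tr2)
  set.seed(74)
  anchors <- do.call(rbind, lapply(
    split(inf, map$chrom[match(inf, map$marker)]),
    function(ms) data.frame(marker = sample(ms, 3))))
  anchors$chromosome <- map$chrom[match(anchors$marker, map$marker)]
  ag <- autogroup_layers(lm, anchors)
  truth <- map$chrom[match(ag$marker, map$marker)]
  assigned <- !is.na(ag$chromosome)
  expect_gte(mean(assigned), 0.9)
  expect_equal(sum(assigned & ag$chromosome != truth), 0)
})

test_that("autogroup is order-independent and leaves linkless markers unassigned", {
  map <- make_marker_map(2, 40, 80)
  ped <- make_families(2, 10)
  fg <- simulate_family_genotypes(ped, map, seed = 75)
  tr <- select_sire_informative(fg$genotypes, ped)
  inf <- map$marker[rowSums(tr$informative) > 0]
  tr2 <- select_sire_informative(fg$genotypes[inf, , drop = FALSE], ped)
  lm <- lod_matrix(tr2)
  set.seed(76)
  anchors <- do.call(rbind, lapply(
    split(inf, map$chrom[match(inf, map$marker)]),
    function(ms) data.frame(marker = sample(ms, 2))))
  anchors$chromosome <- map$chrom[match(anchors$marker, map$marker)]
  ag <- autogroup_layers(lm, anchors)
  # reversed marker order gives identical groups
  rev_ix <- rev(seq_along(inf))
  lm_rev <- list(lod = lm$lod[rev_ix, rev_ix], theta = lm$theta[rev_ix, rev_ix],
                 n_meioses = lm$n_meioses[rev_ix, rev_ix])
  ag_rev <- autogroup_layers(lm_rev, anchors)
  ag_rev <- ag_rev[match(ag$marker, ag_rev$marker), ]
  expect_equal(ag$chromosome, ag_rev$chromosome)
  # an isolated marker stays unassigned
  iso <- matrix(0, 3, 3, dimnames = list(c("a", "b", "x"), c("a", "b", "x")))
  iso["a", "b"] <- iso["b", "a"] <- 10
  lm_iso <- list(lod = iso, theta = iso * 0, n_meioses = iso * 0 + 10)
  ag_iso <- autogroup_layers(lm_iso, data.frame(marker = "a", chromosome = "chr1"))
  expect_true(is.na(ag_iso$chromosome[ag_iso$marker == "x"]))
  expect_equal(ag_iso$chromosome[ag_iso$marker == "b"], "chr1")
})

test_that("anchor conflicts are resolved using the discriminating family only", {
  map <- make_marker_map(2, 50, 100)
  ped <- make_families(2, 10)
  fg <- simulate_family_genotypes(ped, map, male_recomb = 0, seed = 77)
  g <- fg$genotypes
  # make family 1's genotypes identical across the two chromosomes so its
  # sire pattern cannot distinguish them
  f1 <- ped$id[ped$family == "fam01"]
  g[51:100, f1] <- g[1:50, f1]
  tr <- select_sire_informative(g, ped)
  inf <- rownames(g)[rowSums(tr$informative) > 0]
  tr2 <- select_sire_informative(g[inf, , drop = FALSE], ped)
  lm <- lod_matrix(tr2)
  set.seed(78)
  anchors <- do.call(rbind, lapply(
    split(inf, map$chrom[match(inf, map$marker)]),
    function(ms) data.frame(marker = sample(ms, 3))))
  anchors$chromosome <- map$chrom[match(anchors$marker, map$marker)]
  ag <- autogroup_layers(lm, anchors)
  rc <- resolve_anchor_conflicts(ag, tr2, anchors)
  expect_equal(nrow(rc$conflicts), 1)
  expect_equal(rc$conflicts$family_used, "fam02")
  expect_false(rc$conflicts$merged)
  truth <- map$chrom[match(rc$assignment$marker, map$marker)]
  ok <- !is.na(rc$assignment$chromosome)
  expect_true(all(rc$assignment$chromosome[ok] == truth[ok]))
})

test_that("no conflicts leaves groups unchanged; full confounding is flagged as merged", {
  map <- make_marker_map(2, 30, 80)
  ped <- make_families(2, 10)
  fg <- simulate_family_genotypes(ped, map, seed = 79)
  tr <- select_sire_informative(fg$genotypes, ped)
  inf <- rownames(fg$genotypes)[rowSums(tr$informative) > 0]
  tr2 <- select_sire_informative(fg$genotypes[inf, , drop = FALSE], ped)
  lm <- lod_matrix(tr2)
  set.seed(80)
  anchors <- do.call(rbind, lapply(
    split(inf, map$chrom[match(inf, map$marker)]),
    function(ms) data.frame(marker = sample(ms, 2))))
  anchors$chromosome <- map$chrom[match(anchors$marker, map$marker)]
  ag <- autogroup_layers(lm, anchors)
  rc <- resolve_anchor_conflicts(ag, tr2, anchors)
  expect_equal(nrow(rc$conflicts), 0)
  expect_equal(rc$assignment, ag)
  # identical genotypes in both families across chromosomes: merged flag;
  # informativeness and anchors recomputed on the confounded matrix
  g2 <- fg$genotypes
  g2[map$marker[map$chrom == "chr02"], ] <- g2[map$marker[map$chrom == "chr01"], ]
  trm_all <- select_sire_informative(g2, ped)
  infm <- rownames(g2)[rowSums(trm_all$informative) > 0]
  trm <- select_sire_informative(g2[infm, , drop = FALSE], ped)
  set.seed(81)
  anchm <- do.call(rbind, lapply(
    split(infm, map$chrom[match(infm, map$marker)]),
    function(ms) data.frame(marker = sample(ms, 2))))
  anchm$chromosome <- map$chrom[match(anchm$marker, map$marker)]
  agm <- autogroup_layers(lod_matrix(trm), anchm)
  rcm <- resolve_anchor_conflicts(agm, trm, anchm)
  expect_true(any(rcm$conflicts$merged))
})
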