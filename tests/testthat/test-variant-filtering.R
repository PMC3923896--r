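test_that("haploid heterozygote filter honours the GQ threshold", {
  cand <- data.frame(id = c("a", "b", "c", "d"),
                     haploid_gt = c("het", "het", "hom", "missing"),
                     haploid_gq = c(30, 10, 50, NA))
  res <- filter_haploid_heterozygotes(cand)
  expect_equal(res$removed$id, "a")
  expect_setequal(res$kept$id, c("b", "c", "d"))
  expect_equal(res$removed$filter_reason, "haploid_het_psv")
})

test_that("haploid filter recovers the truth PSV set exactly on clean data", {
  g <- make_genome(30, 1e4, 0.3, seed = 20)
  p <- make_panel(n_sites = 600, seed = 20)
  sim <- simulate_candidate_variants(g, p, 600, psv_fraction = 0.2,
                                     depth_mean = 30, error_rate = 0,
                                     error_site_fraction = 0, seed = 21)
  res <- filter_haploid_heterozygotes(sim$candidates)
  truth_psv <- sim$truth$id[sim$truth$class == "psv"]
  expect_setequal(res$removed$id, truth_psv)  # recall and precision both 1
})

test_that("frequency/depth thresholds are inclusive on the removal side", {
  cand <- data.frame(id = c("a", "b", "c", "d"),
                     pooled_freq = c(0.10, 0.25, 0.25, NA),
                     depth = c(50, 11, 10, 30))
  res <- apply_rr_filters(cand)
  expect_setequal(res$removed$id, c("a", "c", "d"))
  expect_equal(res$kept$id, "b")
  expect_equal(res$removed$filter_reason[res$removed$id == "d"], "unscorable")
  expect_equal(res$removed$filter_reason[res$removed$id == "a"], "low_frequency")
})

test_that("transversion test matches transition chemistry and is complement-invariant", {
  expect_false(is_transversion("A", "G"))
  expect_true(is_transversion("A", "C"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- names(comp)
  for (r in bases) for (a in setdiff(bases, r))
    expect_identical(is_transversion(r, a),
                     is_transversion(comp[[r]], comp[[a]]))
  expect_error(is_transversion("N", "A"), "A, C, G, T")
})

test_that("RNA filter keeps transversions with MAF at or above 0.1", {
  cand <- data.frame(id = c("a", "b", "c"),
                     ref = c("C", "A", "A"), alt = c("T", "T", "T"),
                     pooled_freq = c(0.4, 0.1, 0.09))
  res <- apply_rna_filters(cand)
  expect_equal(res$kept$id, "b")
  expect_equal(res$removed$filter_reason,
               c("transition", "low_maf"))
})

test_that("Mendelian-error operator equals the 27-case gamete-enumeration oracle", {
  for (s in geno_levels) for (d in geno_levels) for (o in geno_levels)
    expect_identical(trio_mendelian_error(s, d, o),
                     !oracle_trio_possible(s, d, o),
                     info = paste(s, d, o))
  expect_false(trio_mendelian_error("AA", "AA", NA))
  expect_false(trio_mendelian_error(NA, "AA", "BB"))
})

test_that("Mendelian error counting over a family", {
  g <- family_matrix(sire = c("AA", "AB"), dam = c("AA", "AA"),
                     offspring = list(c("AB", "BB"), c("AA", "AA")))
  ped <- family_pedigree(2)
  err <- count_mendelian_errors(g, ped, "fam01")
  expect_equal(unname(err), c(1L, 1L))  # AAxAA->AB and ABxAA->BB
  expect_error(count_mendelian_errors(g[, 1:2], ped, "fam02"), "family")
})

test_that("segregation distortion chi-square matches closed forms", {
  ped <- family_pedigree(6)
  g <- family_matrix(sire = c("AB", "AB", "AA"), dam = c("AA", "AA", "AA"),
                     offspring = lapply(1:6, function(i)
                       c(if (i <= 3) "AA" else "AB",  # 3:3 balanced
                         "AA",                         # 6:0 distorted
                         "AA")))
  res <- segregation_distortion_test(g, ped, "fam01")
  expect_equal(res$p_value[1], 1)
  expect_true(res$informative[1])
  # 6:0 -> chi2 = 6, p from the chi-square survival function
  expect_equal(res$p_value[2], pchisq(6, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_false(res$informative[3])
  expect_equal(res$p_value[3], 1)
})

test_that("AB x AA with 10:0 offspring gives chi2 = 10, p ~ 0.00157", {
  ped <- family_pedigree(10)
  g <- family_matrix(sire = "AB", dam = "AA",
                     offspring = as.list(rep("AA", 10)))
  res <- segregation_distortion_test(g, ped, "fam01")
  expect_equal(res$p_value, pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(res$p_value, 5), 0.00157)
})

test_that("AB x AB with exact 1:2:1 offspring fits perfectly", {
  ped <- family_pedigree(20)
  g <- family_matrix(sire = "AB", dam = "AB",
                     offspring = as.list(rep(c("AA", "AB", "AB", "BB"), 5)))
  res <- segregation_distortion_test(g, ped, "fam01")
  expect_equal(res$p_value, 1)
})

test_that("RAD filter removes on >= 2 errors in a single family, not spread across families", {
  # 4 families, 2 offspring each; marker m1: one error in each family;
  # marker m2: two errors in family 1 only
  peds <- lapply(1:4, function(i) family_pedigree(2, sprintf("fam%02d", i)))
  ped <- validate_pedigree(do.call(rbind, peds))
  mats <- lapply(1:4, function(i) {
    family_matrix(sire = c("AA", "AA"), dam = c("AA", "AA"),
                  offspring = list(c("AB", if (i == 1) "AB" else "AA"),
                                   c("AA", if (i == 1) "AB" else "AA")),
                  family = sprintf("fam%02d", i))
  })
  g <- do.call(cbind, mats)
  cand <- data.frame(id = c("m001", "m002"))
  res <- apply_rad_filters(cand, g, ped, alpha = 1e-6)
  expect_equal(res$kept$id, "m001")     # 1 error in each family: kept
  expect_equal(res$removed$id, "m002")  # 2 errors in one family: removed
  expect_equal(res$removed$filter_reason, "mendelian_errors")
})

test_that("error-free simulated families lose no candidates to the error clause", {
  map <- make_marker_map(1, 120, 60)
  ped <- make_families(2, 10)
  fg <- simulate_family_genotypes(ped, map, seed = 22)
  cand <- data.frame(id = rownames(fg$genotypes))
  res <- apply_rad_filters(cand, fg$genotypes, ped)
  expect_false(any(res$removed$filter_reason == "mendelian_errors"))
})

test_that("low-quality genotypes are masked before RAD counting", {
  ped <- family_pedigree(2)
  g <- family_matrix(sire = c("AA"), dam = c("AA"),
                     offspring = list("AB", "AB"))
  gq <- matrix(c(99, 99, 10, 10), 1, 4, dimnames = dimnames(g))
  res <- apply_rad_filters(data.frame(id = "m001"), g, ped,
                           genotype_quality = gq)
  expect_equal(res$kept$id, "m001")  # both error genotypes below GQ 20
})

test_that("repeat masking follows the 0-based half-open convention", {
  mask <- data.frame(contig = "c1", start = 100L, end = 200L)
  cand <- data.frame(id = c("a", "b"), contig = "c1", position = c(101L, 100L))
  res <- mask_repeats(cand, mask)
  expect_equal(res$removed$id, "a")
  expect_equal(res$kept$id, "b")
  expect_warning(
    mask_repeats(data.frame(id = "z", contig = "c9", position = 5L), mask),
    "absent from the mask")
})

test_that("repeat masking agrees with a quadratic interval-scan oracle", {
  set.seed(30)
  cand <- data.frame(id = sprintf("s%03d", 1:200),
                     contig = sample(c("c1", "c2", "c3"), 200, TRUE),
                     position = sample(1:1000, 200, TRUE))
  mask <- data.frame(contig = sample(c("c1", "c2", "c3"), 40, TRUE),
                     start = sample(0:900, 40, TRUE))
  mask$end <- mask$start + sample(10:100, 40, TRUE)
  res <- mask_repeats(cand, mask)
  oracle <- vapply(seq_len(nrow(cand)), function(i) {
    p0 <- cand$position[i] - 1
    any(mask$contig == cand$contig[i] & mask$start <= p0 & p0 < mask$end)
  }, logical(1))
  expect_setequal(res$removed$id, cand$id[oracle])
})

test_that("array content selection: base pairing rules and strict fill thresholds", {
  cand <- data.frame(
    id = sprintf("c%02d", 1:6),
    conversion_score = c(0.9, 0.5, 0.3, 0.6, 0.61, 0.2),
    rec_fwd = c("recommended", "neutral", "neutral",
                "not recommended", "not recommended", "not recommended"),
    rec_rev = c("not recommended", "neutral", "not recommended",
                "not recommended", "not recommended", "not recommended"),
    multi_experiment = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    dual_mapping = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    previously_verified = FALSE)
  sel <- select_array_content(cand, capacity = 4)
  base <- sel$id[sel$selection_stage == "base"]
  expect_setequal(base, c("c01", "c02"))     # (rec, not rec) in; (neutral, not rec) out
  # fill: c06 multi-experiment low score; c05 dual-mapping 0.61 (> 0.6);
  # c04 dual-mapping exactly 0.6 is NOT eligible
  expect_setequal(sel$id[sel$selection_stage != "base"], c("c06", "c05"))
  expect_false("c04" %in% sel$id)
  # capacity equal to base set: no fill
  sel2 <- select_array_content(cand, capacity = 2)
  expect_true(all(sel2$selection_stage == "base"))
  expect_error(select_array_content(cand, capacity = 1), "capacity")
})

test_that("partitions are exhaustive and exclusive with one reason per record", {
  g <- make_genome(10, 1e4, 0.2, seed = 31)
  p <- make_panel(n_sites = 200, seed = 31)
  sim <- simulate_candidate_variants(g, p, 200, seed = 32)
  for (res in list(filter_haploid_heterozygotes(sim$candidates),
                   apply_rr_filters(sim$candidates),
                   apply_rna_filters(sim$candidates))) {
    expect_equal(nrow(res$kept) + nrow(res$removed), 200)
    expect_equal(length(intersect(res$kept$id, res$removed$id)), 0)
    if (nrow(res$removed) > 0)
      expect_true(all(!is.na(res$removed$filter_reason)))
  }
  # chain emits a per-stage ledger that reconciles
  chain <- rr_filter_chain(sim$candidates)
  expect_equal(chain$ledger$n_in - chain$ledger$n_removed, chain$ledger$n_out)
  expect_equal(chain$ledger$n_in[-1], chain$ledger$n_out[-nrow(chain$ledger)])
})
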