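test_that("quantile normalization maps samples onto the mean sorted vector", {
  A <- cbind(s1 = c(1, 2, 3), s2 = c(10, 20, 30))
  res <- quantile_normalize_channels(A, A)
  expect_equal(unname(res$A[, 1]), c(5.5, 11, 16.5))
  expect_equal(unname(res$A[, 2]), c(5.5, 11, 16.5))
  # post-condition: sorted columns identical
  set.seed(40)
  M <- matrix(rexp(60, 1 / 100), 20, 3)
  r2 <- quantile_normalize_channels(M, M)$A
  sorted <- apply(r2, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2])
  expect_equal(sorted[, 1], sorted[, 3])
  expect_warning(quantile_normalize_channels(M[, 1, drop = FALSE],
                                             M[, 1, drop = FALSE]),
                 "single sample")
})

# independently coded Tukey median polish (row/column sweeps on the log scale)
oracle_medpolish_summary <- function(mat) {
  z <- log2(mat)
  overall <- 0; re <- rep(0, nrow(z)); ce <- rep(0, ncol(z))
  for (i in 1:50) {
    rm_ <- apply(z, 1, median); z <- sweep(z, 1, rm_); re <- re + rm_
    d <- median(ce); ce <- ce - d; overall <- overall + d
    cm_ <- apply(z, 2, median); z <- sweep(z, 2, cm_); ce <- ce + cm_
    d <- median(re); re <- re - d; overall <- overall + d
    if (max(abs(c(apply(z, 1, median), apply(z, 2, median)))) < 1e-9) break
  }
  2^(overall + ce)
}

test_that("replicate summarisation matches an independent median-polish oracle", {
  m <- rbind(c(2, 8), c(2, 8))     # identical replicates -> that value
  expect_equal(unname(summarize_replicate_probes(m)), c(2, 8))
  set.seed(41)
  r <- matrix(2^(rnorm(40, 10, 1)), 2, 20)
  expect_equal(unname(summarize_replicate_probes(r)),
               unname(oracle_medpolish_summary(r)), tolerance = 1e-6)
})

test_that("contrast-size transform: definition, antisymmetry, clipping", {
  expect_equal(to_contrast_size(4, 4)$contrast, 0)
  cs <- to_contrast_size(4, 1)
  expect_equal(cs$contrast, 2)
  expect_equal(cs$size, 1)
  set.seed(42)
  a <- rexp(100, 1 / 500); b <- rexp(100, 1 / 500)
  fw <- to_contrast_size(a, b); bw <- to_contrast_size(b, a)
  expect_equal(fw$contrast, -bw$contrast)
  expect_equal(fw$size, bw$size)
  cl <- to_contrast_size(c(-1, 2), c(2, 2))
  expect_true(cl$clipped[1]); expect_false(cl$clipped[2])
})

test_that("boundary scan recovers well-separated blobs and handles degenerate inputs", {
  prior <- default_cluster_prior(size_mean = 1)
  set.seed(43)
  x <- c(rnorm(20, -2, 0.1), rnorm(20, 0, 0.1), rnorm(20, 2, 0.1))
  lab <- scan_boundaries(x, prior)
  expect_equal(lab, rep(c("BB", "AB", "AA"), each = 20))
  # 2 points: no AB cluster
  lab2 <- scan_boundaries(c(-2, 2), prior)
  expect_setequal(lab2, c("BB", "AA"))
  # all identical points: single cluster at the closest prior mean
  lab3 <- scan_boundaries(rep(0.01, 5), prior)
  expect_true(all(lab3 == "AB"))
  # order invariance
  perm <- sample(length(x))
  expect_equal(scan_boundaries(x[perm], prior), lab[perm])
})

# naive reference implementation of the boundary-scan objective
oracle_scan <- function(x, prior) {
  n <- length(x); ord <- order(x); xs <- x[ord]
  sdv <- sapply(prior$clusters, function(cl) sqrt(cl$cov[1, 1]))
  mu <- sapply(prior$clusters, function(cl) cl$mean[["contrast"]])
  seg <- function(v, g) {
    if (length(v) == 0) return(0)
    m <- mean(v)
    sum(dnorm(v, m, sdv[g], log = TRUE)) +
      dnorm(m, mu[g], prior$location_sd, log = TRUE)
  }
  best <- -Inf; lab <- NULL
  for (i in 0:n) for (j in i:n) {
    sc <- seg(xs[seq_len(i)], "BB") +
      seg(if (j >= i + 1) xs[(i + 1):j] else numeric(0), "AB") +
      seg(if (j < n) xs[(j + 1):n] else numeric(0), "AA")
    if (sc > best) {
      best <- sc
      l <- rep("AA", n)
      if (i >= 1) l[seq_len(i)] <- "BB"
      if (j >= i + 1) l[(i + 1):j] <- "AB"
      lab <- l
    }
  }
  out <- character(n); out[ord] <- lab; out
}

test_that("vectorised boundary scan equals the brute-force scan", {
  prior <- default_cluster_prior(size_mean = 1)
  set.seed(44)
  for (rep_i in 1:5) {
    x <- rnorm(12, sample(c(-1.5, 0, 1.5), 1), runif(1, 0.2, 1))
    expect_equal(scan_boundaries(x, prior), oracle_scan(x, prior))
  }
})

test_that("posterior update blends prior and data by pseudo-counts", {
  prior <- default_cluster_prior(size_mean = 0, nu = 4)
  pts <- data.frame(contrast = rep(2, 4), size = rep(2, 4))
  post <- posterior_update_clusters(pts, rep("AA", 4), prior)
  # nu = n, prior contrast mean 1.5, sample mean 2 -> 1.75; size 0 vs 2 -> 1
  expect_equal(unname(post$clusters$AA$mean[["contrast"]]), 1.75)
  expect_equal(unname(post$clusters$AA$mean[["size"]]), 1)
  # empty cluster keeps its prior
  expect_equal(post$clusters$AB$mean, prior$clusters$AB$mean)
  expect_equal(post$clusters$AB$nu, prior$clusters$AB$nu)
  # weak-prior limit: posterior mean -> sample mean
  weak <- default_cluster_prior(size_mean = 0, nu = 1e-9)
  postw <- posterior_update_clusters(pts, rep("AA", 4), weak)
  expect_equal(unname(postw$clusters$AA$mean[["contrast"]]), 2, tolerance = 1e-6)
  # weights sum to one
  expect_equal(sum(sapply(post$clusters, `[[`, "weight")), 1)
})

test_that("genotype calls: high confidence at cluster means, no-call at the midpoint", {
  prior <- default_cluster_prior(size_mean = 0, contrast_sd = 0.2, size_sd = 0.2)
  pts <- data.frame(contrast = c(1.5, 0.75), size = c(0, 0))
  cl <- call_genotypes(pts, prior)
  expect_equal(cl$call[1], "AA")
  expect_gt(cl$confidence[1], 0.99)
  expect_equal(cl$call[2], "NoCall")          # equidistant AA/AB
  expect_equal(cl$confidence[2], 0.5, tolerance = 1e-6)
  # responsibilities sum to one
  expect_equal(rowSums(cl[, c("AA", "AB", "BB")]), c(1, 1), tolerance = 1e-12)
})

test_that("end-to-end calling is perfect on a well-separated 96-sample probeset", {
  set.seed(45)
  g <- sample(c("AA", "AB", "BB"), 96, TRUE)
  geno <- matrix(g, 1, 96, dimnames = list("ps1", sprintf("s%03d", 1:96)))
  sim <- simulate_intensities(geno, seed = 46)
  res <- axiom_genotype(sim$intensities, otv = FALSE, normalize = FALSE)
  cm <- calls_to_matrix(res$calls)
  expect_equal(unname(cm["ps1", colnames(geno)]), g)
})

test_that("cluster means are recovered within 0.15 and accuracy is >= 0.99", {
  set.seed(47)
  n_ps <- 25
  geno <- matrix(sample(c("AA", "AB", "BB"), n_ps * 96, TRUE), n_ps, 96,
                 dimnames = list(sprintf("ps%03d", 1:n_ps),
                                 sprintf("s%03d", 1:96)))
  sim <- simulate_intensities(geno, seed = 48)  # separation 10 within-SD
  res <- axiom_genotype(sim$intensities, otv = FALSE, normalize = FALSE)
  cm <- calls_to_matrix(res$calls)
  acc <- mean(cm[rownames(geno), colnames(geno)] == geno, na.rm = TRUE)
  expect_gte(acc, 0.99)
  truth_mu <- c(AA = 1.5, AB = 0, BB = -1.5)
  for (ps in rownames(geno)) {
    m <- res$models[[ps]]
    for (gname in names(truth_mu)) {
      if (sum(geno[ps, ] == gname) < 3) next
      expect_lt(abs(m$clusters[[gname]]$mean[["contrast"]] - truth_mu[[gname]]),
                0.15)
    }
  }
})

test_that("negating all contrasts swaps AA and BB and preserves AB", {
  prior <- default_cluster_prior(size_mean = 0)
  set.seed(49)
  pts <- data.frame(contrast = c(rnorm(10, 1.5, .1), rnorm(10, 0, .1),
                                 rnorm(10, -1.5, .1)),
                    size = rnorm(30, 0, .1))
  lab <- scan_boundaries(pts$contrast, prior)
  post <- posterior_update_clusters(pts, lab, prior)
  cl <- call_genotypes(pts, post)
  neg <- pts; neg$contrast <- -neg$contrast
  lab2 <- scan_boundaries(neg$contrast, prior)
  post2 <- posterior_update_clusters(neg, lab2, prior)
  cl2 <- call_genotypes(neg, post2)
  swap <- c(AA = "BB", AB = "AB", BB = "AA", NoCall = "NoCall")
  expect_equal(unname(swap[cl$call]), cl2$call)
})

test_that("OTV detection: sensitive and specific with a genuine OTV cluster, inert without", {
  set.seed(50)
  n_ps <- 12
  geno <- matrix(sample(c("AA", "AB", "BB"), n_ps * 96, TRUE), n_ps, 96,
                 dimnames = list(sprintf("ps%03d", 1:n_ps),
                                 sprintf("s%03d", 1:96)))
  sim <- simulate_intensities(geno, otv_fraction = 0.5, otv_sample_rate = 0.2,
                              seed = 51)
  res <- axiom_genotype(sim$intensities, otv = FALSE, normalize = FALSE)
  tp <- fp <- fn <- tn <- 0
  null_relabels <- 0; n_null <- 0
  for (ps in rownames(geno)) {
    p <- res$points[[ps]]
    cal0 <- call_genotypes(p, res$models[[ps]])
    ot <- detect_otv(p, res$models[[ps]], cal0)
    expect_true(all(diff(ot$loglik_trace) > -1e-6))  # EM monotone
    tr <- sim$truth$otv_samples[ps, sort(colnames(geno))]
    pred <- ot$calls$call == "OTV"
    if (sim$truth$probeset_class[ps] == "otv") {
      tp <- tp + sum(pred & tr); fn <- fn + sum(!pred & tr)
      fp <- fp + sum(pred & !tr); tn <- tn + sum(!pred & !tr)
    } else {
      n_null <- n_null + 1
      if (any(pred)) null_relabels <- null_relabels + 1
    }
    # no-op contract: rejected/empty OTV component leaves calls unchanged
    if (ot$n_otv == 0) expect_equal(ot$calls$call, cal0$call)
  }
  expect_gte(tp / (tp + fn), 0.95)   # sensitivity
  expect_gte(tn / (tn + fp), 0.95)   # specificity
  expect_equal(null_relabels, 0)     # null geometry: no relabels
})

test_that("a posterior reused as a prior gives identical downstream calls", {
  set.seed(52)
  ptsA <- data.frame(contrast = c(rnorm(30, 1.4, .1), rnorm(30, -0.1, .1),
                                  rnorm(30, -1.6, .1)),
                     size = rnorm(90, 10, .1))
  prior <- default_cluster_prior(size_mean = 10)
  labA <- scan_boundaries(ptsA$contrast, prior)
  postA <- posterior_update_clusters(ptsA, labA, prior)
  ptsB <- data.frame(contrast = rnorm(50, 0.1, 0.8), size = rnorm(50, 10, .2))
  manual <- postA    # a prior manually set to the posterior
  labB1 <- scan_boundaries(ptsB$contrast, postA)
  labB2 <- scan_boundaries(ptsB$contrast, manual)
  expect_identical(labB1, labB2)
  expect_identical(
    call_genotypes(ptsB, posterior_update_clusters(ptsB, labB1, postA)),
    call_genotypes(ptsB, posterior_update_clusters(ptsB, labB2, manual)))
})

test_that("cluster model JSON round-trips the key parameters", {
  prior <- default_cluster_prior()
  f <- tempfile(fileext = ".json")
  write_cluster_model(prior, f)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$clusters$AA$mean$contrast, 1.5)
  expect_match(obj$update_rule, "conjugate")
  unlink(f)
})
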