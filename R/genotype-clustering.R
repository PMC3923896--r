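#' @name genotype_clustering
#' @title Axiom-style two-channel genotype calling
#' @description
#' The calling pipeline mirrors the Axiom GT workflow: quantile
#' normalisation of the two channels separately, median-polish summarisation
#' of replicate probes, transform to contrast-size space
#' (contrast = log2 A - log2 B, size = (log2 A + log2 B)/2), a boundary scan
#' that initialises three genotype clusters, a Bayesian (conjugate-blend)
#' update of a prior two-dimensional Gaussian mixture, posterior genotype
#' calls by maximum responsibility, and an EM step that pulls off-target
#' variant (OTV) samples into a fourth low-size, zero-contrast component.
NULL

#' Quantile-normalise intensity channels across samples
#'
#' Each channel matrix (rows = probes, columns = samples) is normalised so
#' every sample shares the reference distribution (the mean of the sorted
#' sample vectors); ties are averaged. With a single sample the transform is
#' the identity, with a warning.
#'
#' @param A,B numeric matrices, probes x samples, same dimensions.
#' @return `list(A, B)` of normalised matrices.
#' @export
quantile_normalize_channels <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  if (ncol(A) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(list(A = A, B = B))
  }
  list(A = limma::normalizeQuantiles(A, ties = TRUE),
       B = limma::normalizeQuantiles(B, ties = TRUE))
}

#' Summarise replicate probe intensities by median polish
#'
#' Fits Tukey's median polish to the log2 replicate-by-sample matrix and
#' returns the back-transformed per-sample summary (overall effect + column
#' effect). Convergence follows `stats::medpolish` with tolerance `1e-6`
#' and at most 10 sweeps.
#'
#' @param mat numeric matrix, replicates x samples, positive linear signals.
#' @return numeric per-sample summary on the linear scale.
#' @export
summarize_replicate_probes <- function(mat) {
  stopifnot(nrow(mat) >= 1, all(mat > 0))
  if (nrow(mat) == 1) return(drop(mat))
  lg <- log2(mat)
  mp <- stats::medpolish(lg, eps = 1e-6, maxiter = 10L, trace.iter = FALSE)
  2^(mp$overall + mp$col)
}

#' Transform A/B signals to contrast-size coordinates
#'
#' contrast = log2(A) - log2(B); size = (log2(A) + log2(B)) / 2. Log base 2
#' is the microarray convention; any fixed base only rescales the space.
#' Non-positive signals are floor-clipped to `eps` and flagged.
#'
#' @param signal_A,signal_B numeric vectors of linear intensities.
#' @param eps floor for non-positive signals.
#' @return data.frame `contrast`, `size`, `clipped`.
#' @export
to_contrast_size <- function(signal_A, signal_B, eps = 1e-6) {
  clipped <- signal_A <= 0 | signal_B <= 0
  a <- pmax(signal_A, eps); b <- pmax(signal_B, eps)
  data.frame(contrast = log2(a) - log2(b),
             size = (log2(a) + log2(b)) / 2,
             clipped = clipped)
}

#' Construct a prior cluster model
#'
#' Genotype clusters are 2-D Gaussians in contrast-size space with
#' conjugate-style pseudo-count weights. Defaults place the homozygote
#' contrast means at +/- `delta` and the heterozygote at 0 with a common
#' size mean; covariances are diagonal.
#'
#' @param delta prior half-separation of homozygote contrast means.
#' @param size_mean prior size mean (set this near the data's median size).
#' @param contrast_sd,size_sd prior within-cluster standard deviations.
#' @param nu prior pseudo-count per cluster.
#' @param location_sd prior standard deviation of cluster mean locations,
#'   used by the boundary scan's prior density term.
#' @param confidence_threshold no-call bound on posterior responsibility.
#' @return object of class `cluster_model`.
#' @export
default_cluster_prior <- function(delta = 1.5, size_mean = 10,
                                  contrast_sd = 0.3, size_sd = 0.3,
                                  nu = 1, location_sd = 1,
                                  confidence_threshold = 0.95) {
  clusters <- lapply(c(AA = delta, AB = 0, BB = -delta), function(m) {
    list(mean = c(contrast = m, size = size_mean),
         cov = diag(c(contrast_sd^2, size_sd^2)),
         nu = nu, weight = 1 / 3)
  })
  structure(list(clusters = clusters, location_sd = location_sd,
                 confidence_threshold = confidence_threshold),
            class = "cluster_model")
}

#' Initial genotype labelling by exhaustive boundary scan
#'
#' Evaluates every placement of two ordered vertical boundaries between the
#' sorted contrast values (including degenerate placements that yield one or
#' two clusters). Each placement's score is the sum over non-empty clusters
#' of the Gaussian log-likelihood of the member points (cluster mean = the
#' segment sample mean, sd = the prior within-cluster contrast sd) plus the
#' log prior density of that implied mean under the prior cluster location.
#' The highest-scoring placement defines the labels; under the A-positive
#' convention the right segment is AA, the middle AB and the left BB.
#'
#' @param contrast numeric vector of contrast values (>= 1 point).
#' @param prior a `cluster_model`.
#' @return character vector of labels in `{"AA","AB","BB"}`, in input order.
#' @export
scan_boundaries <- function(contrast, prior) {
  stopifnot(length(contrast) >= 1, inherits(prior, "cluster_model"))
  n <- length(contrast)
  ord <- order(contrast)
  x <- contrast[ord]
  cs0 <- c(0, cumsum(x)); cs20 <- c(0, cumsum(x^2))
  sd_g <- vapply(prior$clusters[c("AA", "AB", "BB")],
                 function(cl) sqrt(cl$cov[1, 1]), 0)
  mu_g <- vapply(prior$clusters[c("AA", "AB", "BB")],
                 function(cl) cl$mean[["contrast"]], 0)
  tau <- prior$location_sd
  seg_score_vec <- function(n_g, s, s2, g) {
    m <- s / n_g
    sse <- pmax(0, s2 - n_g * m^2)
    -n_g * log(sd_g[g] * sqrt(2 * pi)) - sse / (2 * sd_g[g]^2) +
      dnorm(m, mu_g[g], tau, log = TRUE)
  }
  ## boundaries after positions i and j (0 <= i <= j <= n):
  ## 1..i -> BB, (i+1)..j -> AB, (j+1)..n -> AA; empty segments score 0
  iv <- 0:n
  bb <- c(0, seg_score_vec(iv[-1], cs0[iv[-1] + 1], cs20[iv[-1] + 1], "BB"))
  ## aa[j+1] = score of segment (j+1)..n
  aa <- numeric(n + 1)
  js <- 0:(n - 1)
  aa[js + 1] <- seg_score_vec(n - js, cs0[n + 1] - cs0[js + 1],
                              cs20[n + 1] - cs20[js + 1], "AA")
  aa[n + 1] <- 0
  I <- matrix(iv, n + 1, n + 1)              # row index = i
  J <- matrix(iv, n + 1, n + 1, byrow = TRUE)  # col index = j
  nM <- J - I
  sM <- matrix(cs0[J + 1] - cs0[I + 1], n + 1)
  s2M <- matrix(cs20[J + 1] - cs20[I + 1], n + 1)
  ab <- matrix(0, n + 1, n + 1)
  pos <- nM > 0
  ab[pos] <- seg_score_vec(nM[pos], sM[pos], s2M[pos], "AB")
  total <- matrix(bb[I + 1], n + 1) + ab + matrix(aa[J + 1], n + 1)
  total[J < I] <- -Inf
  k <- which.max(total)                      # deterministic first-max tie-break
  best_i <- (k - 1) %% (n + 1)
  best_j <- (k - 1) %/% (n + 1)
  lab_sorted <- rep("AA", n)
  if (best_i >= 1) lab_sorted[seq_len(best_i)] <- "BB"
  if (best_j >= best_i + 1) lab_sorted[(best_i + 1):best_j] <- "AB"
  labels <- character(n)
  labels[ord] <- lab_sorted
  labels
}

#' Bayesian update of the cluster model from labelled points
#'
#' Conjugate-blend update per cluster: the posterior mean is the
#' pseudo-count-weighted average of prior mean and sample mean,
#' `(nu * mu0 + n * xbar) / (nu + n)`; the covariance is blended the same
#' way; the posterior pseudo-count becomes `nu + n` (so the posterior can be
#' reused as a prior for future clusterings) and mixture weights are
#' proportional to `nu + n`. Empty clusters keep their prior.
#'
#' @param points data.frame with `contrast`, `size`.
#' @param labels character vector of `"AA"/"AB"/"BB"` labels per point.
#' @param prior a `cluster_model`.
#' @return posterior `cluster_model`.
#' @export
posterior_update_clusters <- function(points, labels, prior) {
  stopifnot(inherits(prior, "cluster_model"), nrow(points) == length(labels))
  X <- cbind(contrast = points$contrast, size = points$size)
  post <- prior
  for (g in intersect(c("AA", "AB", "BB"), names(prior$clusters))) {
    sel <- labels == g
    n_g <- sum(sel)
    cl <- prior$clusters[[g]]
    if (n_g > 0) {
      xb <- colMeans(X[sel, , drop = FALSE])
      S <- if (n_g >= 2) cov(X[sel, , drop = FALSE]) * (n_g - 1) / n_g
           else matrix(0, 2, 2)
      cl$mean <- setNames((cl$nu * cl$mean + n_g * xb) / (cl$nu + n_g),
                          c("contrast", "size"))
      cl$cov <- (cl$nu * cl$cov + n_g * S) / (cl$nu + n_g)
      cl$cov <- cl$cov + diag(1e-6, 2)   # keep positive definite
      cl$nu <- cl$nu + n_g
    }
    post$clusters[[g]] <- cl
  }
  tot <- sum(vapply(post$clusters, `[[`, 0, "nu"))
  for (g in names(post$clusters)) post$clusters[[g]]$weight <-
    post$clusters[[g]]$nu / tot
  post
}

## log density of 2-D Gaussian, vectorised over rows of X
dmvnorm2_log <- function(X, mu, sigma) {
  R <- chol(sigma)
  z <- forwardsolve(t(R), t(X) - mu)
  -log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

#' Posterior genotype calls from a cluster model
#'
#' Each point's responsibility for a cluster is its weighted Gaussian
#' density normalised over active clusters; the call is the argmax and the
#' confidence is the maximum responsibility. Calls below the confidence
#' threshold become `"NoCall"`.
#'
#' @param points data.frame with `contrast`, `size`.
#' @param model a fitted `cluster_model`.
#' @param confidence_threshold no-call bound (default from the model).
#' @return data.frame `call`, `confidence`, plus one responsibility column
#'   per cluster.
#' @export
call_genotypes <- function(points, model,
                           confidence_threshold = model$confidence_threshold) {
  X <- cbind(points$contrast, points$size)
  gs <- names(model$clusters)
  ll <- vapply(gs, function(g) {
    cl <- model$clusters[[g]]
    log(cl$weight) + dmvnorm2_log(X, cl$mean, cl$cov)
  }, numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X), dimnames = list(NULL, gs))
  mx <- apply(ll, 1, max)
  resp <- exp(ll - mx)
  resp <- resp / rowSums(resp)
  call <- gs[max.col(resp, ties.method = "first")]
  conf <- apply(resp, 1, max)
  call[conf < confidence_threshold] <- "NoCall"
  out <- data.frame(call = call, confidence = conf, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(resp))
}

#' Detect off-target-variant samples by EM
#'
#' Augments the posterior three-cluster mixture with a fourth OTV component
#' initialised at contrast 0 and size equal to the lowest cluster size mean
#' minus `size_offset`, then runs EM on all four components until the
#' log-likelihood change falls below `tol` (or `max_iter` iterations).
#' Samples whose maximal responsibility lands on the OTV component are
#' relabelled `"OTV"`; all other calls are kept as given. The fitted OTV
#' component is accepted only when it retains the defining OTV geometry —
#' mean contrast within `max_otv_contrast` of zero and mean size at least
#' `size_offset / 2` below the lowest genotype cluster; otherwise (e.g. when
#' EM drifts the component into the tail of a genuine genotype cluster) no
#' samples are relabelled. The variance floor keeps components from
#' collapsing onto single points.
#'
#' @param points data.frame with `contrast`, `size`.
#' @param model posterior `cluster_model` from
#'   [posterior_update_clusters()].
#' @param calls data.frame from [call_genotypes()].
#' @param size_offset how far below the genotype clusters the OTV component
#'   starts.
#' @param otv_weight initial OTV mixing weight.
#' @param tol,max_iter EM convergence controls.
#' @param var_floor lower bound applied to component variances.
#' @param max_otv_contrast acceptance bound on the fitted OTV contrast mean.
#' @return list with `calls` (updated data.frame), `n_otv`,
#'   `loglik_trace` (non-decreasing), `accepted`, and `otv_model`.
#' @export
detect_otv <- function(points, model, calls, size_offset = 2,
                       otv_weight = 0.1, tol = 1e-8, max_iter = 200,
                       var_floor = 0.02, max_otv_contrast = 0.5) {
  X <- cbind(points$contrast, points$size)
  n <- nrow(X)
  gs <- names(model$clusters)
  mus <- lapply(model$clusters, `[[`, "mean")
  covs <- lapply(model$clusters, `[[`, "cov")
  ws <- vapply(model$clusters, `[[`, 0, "weight") * (1 - otv_weight)
  min_size <- min(vapply(mus, `[[`, 0, "size"))
  mus$OTV <- c(contrast = 0, size = min_size - size_offset)
  covs$OTV <- diag(c(0.25, 0.25))
  ws <- c(ws, OTV = otv_weight)
  comps <- c(gs, "OTV")
  loglik_trace <- numeric(0)
  floor_cov <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$values <- pmax(e$values, var_floor)
    e$vectors %*% diag(e$values) %*% t(e$vectors)
  }
  for (it in seq_len(max_iter)) {
    ll <- vapply(comps, function(g)
      log(ws[[g]]) + dmvnorm2_log(X, mus[[g]], covs[[g]]), numeric(n))
    ll <- matrix(ll, nrow = n, dimnames = list(NULL, comps))
    mx <- apply(ll, 1, max)
    lse <- mx + log(rowSums(exp(ll - mx)))
    loglik_trace <- c(loglik_trace, sum(lse))
    if (it > 1 && abs(loglik_trace[it] - loglik_trace[it - 1]) < tol) break
    resp <- exp(ll - lse)
    nk <- colSums(resp)
    for (g in comps) {
      if (nk[g] < 1e-8) next
      mu <- colSums(resp[, g] * X) / nk[g]
      D <- t(X) - mu
      S <- (D %*% (resp[, g] * t(D))) / nk[g]
      mus[[g]] <- setNames(mu, c("contrast", "size"))
      covs[[g]] <- floor_cov(S)
    }
    ws <- nk / n
  }
  ll <- vapply(comps, function(g)
    log(ws[[g]]) + dmvnorm2_log(X, mus[[g]], covs[[g]]), numeric(n))
  ll <- matrix(ll, nrow = n, dimnames = list(NULL, comps))
  otv <- comps[max.col(ll, ties.method = "first")] == "OTV"
  gsize <- vapply(mus[gs], `[[`, 0, "size")
  accepted <- abs(mus$OTV[["contrast"]]) <= max_otv_contrast &&
    mus$OTV[["size"]] <= min(gsize) - size_offset / 2
  if (!accepted) otv[] <- FALSE
  out <- calls
  out$call[otv] <- "OTV"
  list(calls = out, n_otv = sum(otv), loglik_trace = loglik_trace,
       accepted = accepted,
       otv_model = list(means = mus, covs = covs, weights = ws))
}

#' Full genotype-calling pipeline over an intensity table
#'
#' Runs the calling stages in order: per-channel quantile normalisation
#' across samples, median-polish summarisation of the two replicate probes,
#' contrast-size transform, boundary-scan initialisation, Bayesian posterior
#' update, genotype calls, and (optionally) OTV detection — one probeset at
#' a time with a shared prior. If no prior is supplied, the default prior is
#' used with its size mean set to the median observed size.
#'
#' @param intensities data.frame `probeset_id`, `probe_replicate`,
#'   `sample_id`, `signal_A`, `signal_B`.
#' @param prior optional `cluster_model`.
#' @param confidence_threshold no-call bound.
#' @param otv run OTV detection per probeset (default TRUE).
#' @param normalize quantile-normalise channels first (default TRUE).
#' @return list with `calls` (data.frame `probeset_id`, `sample_id`, `call`,
#'   `confidence`), `models` (posterior `cluster_model` per probeset),
#'   `points` (contrast-size data.frame per probeset) and `prior`.
#' @export
axiom_genotype <- function(intensities, prior = NULL,
                           confidence_threshold = 0.95, otv = TRUE,
                           normalize = TRUE) {
  req <- c("probeset_id", "probe_replicate", "sample_id", "signal_A", "signal_B")
  stop_if_not(all(req %in% names(intensities)), "malformed intensity table")
  key <- interaction(intensities$probeset_id, intensities$probe_replicate, drop = TRUE)
  samples <- sort(unique(intensities$sample_id))
  rows <- sort(unique(key))
  A <- matrix(NA_real_, length(rows), length(samples),
              dimnames = list(as.character(rows), samples))
  B <- A
  A[cbind(match(key, rows), match(intensities$sample_id, samples))] <- intensities$signal_A
  B[cbind(match(key, rows), match(intensities$sample_id, samples))] <- intensities$signal_B
  stop_if_not(!anyNA(A) && !anyNA(B), "intensity table has missing probeset/sample cells")
  if (normalize && length(samples) >= 2) {
    nrm <- quantile_normalize_channels(A, B)
    A <- nrm$A; B <- nrm$B
  }
  ps_of_row <- sub("\\.[0-9]+$", "", rownames(A))
  probesets <- unique(ps_of_row)
  ## summarize replicates, then transform
  pts <- list()
  for (ps in probesets) {
    ri <- which(ps_of_row == ps)
    a <- summarize_replicate_probes(A[ri, , drop = FALSE])
    b <- summarize_replicate_probes(B[ri, , drop = FALSE])
    pts[[ps]] <- to_contrast_size(a, b)
  }
  if (is.null(prior)) {
    med_size <- median(unlist(lapply(pts, `[[`, "size")))
    prior <- default_cluster_prior(size_mean = med_size,
                                   confidence_threshold = confidence_threshold)
  }
  calls_list <- vector("list", length(probesets))
  models <- list()
  for (k in seq_along(probesets)) {
    ps <- probesets[k]
    p <- pts[[ps]]
    labels <- scan_boundaries(p$contrast, prior)
    post <- posterior_update_clusters(p, labels, prior)
    cl <- call_genotypes(p, post, confidence_threshold)
    if (otv) cl <- detect_otv(p, post, cl)$calls
    calls_list[[k]] <- data.frame(probeset_id = ps, sample_id = samples,
                                  call = cl$call, confidence = cl$confidence,
                                  stringsAsFactors = FALSE)
    models[[ps]] <- post
  }
  calls <- do.call(rbind, calls_list)
  rownames(calls) <- NULL
  list(calls = calls, models = models, points = pts, prior = prior)
}

#' Serialise a cluster model to JSON
#'
#' The JSON records per-cluster mean, covariance, weight and pseudo-count,
#' and flags that the posterior update is a conjugate-blend stand-in rather
#' than the proprietary BRLMM-P update.
#' @param model a `cluster_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  obj <- list(
    update_rule = "conjugate-blend (pseudo-count weighted); stand-in for proprietary BRLMM-P posterior update",
    location_sd = model$location_sd,
    confidence_threshold = model$confidence_threshold,
    clusters = lapply(model$clusters, function(cl)
      list(mean = as.list(cl$mean), cov = cl$cov, weight = cl$weight, nu = cl$nu)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
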