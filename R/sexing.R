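#' @name sexing
#' @title Genetic sex inference from Y-specific probe intensities
#' @description
#' Males carry the sdY master sex-determining fragment, so Y-specific probes
#' hybridise strongly in males and give background signal in females. The
#' per-sample mean probe intensity is therefore bimodal by sex and a simple
#' largest-gap split calls sex deterministically.
NULL

#' Call genetic sex from Y-probe intensities
#'
#' Averages each sample's probe intensities, splits the sorted means at the
#' largest gap into two clusters, and calls the upper cluster male (the sdY
#' fragment is male-specific). If the gap is smaller than `min_gap` times
#' the pooled within-cluster standard deviation — i.e. the means look
#' unimodal — every call is `"unknown"`. A single sample, or all-equal
#' means, also yields `"unknown"`. Because the guard is relative, calls are
#' invariant to rescaling all intensities by a positive constant.
#'
#' @param y data.frame `sample_id`, `probe_id`, `intensity` (>= 1 probe).
#' @param min_gap required gap between clusters, in units of the pooled
#'   within-cluster SD (default 3).
#' @return data.frame `sample_id`, `mean_intensity`, `call` in
#'   `{"male","female","unknown"}`.
#' @export
call_sex_from_y_probes <- function(y, min_gap = 3) {
  stop_if_not(all(c("sample_id", "intensity") %in% names(y)),
              "y needs sample_id and intensity columns")
  means <- tapply(y$intensity, y$sample_id, mean)
  out <- data.frame(sample_id = names(means),
                    mean_intensity = as.numeric(means),
                    call = "unknown", stringsAsFactors = FALSE)
  n <- nrow(out)
  if (n < 2) return(out)
  ord <- order(out$mean_intensity)
  v <- out$mean_intensity[ord]
  gaps <- diff(v)
  if (max(gaps) <= 0) return(out)      # all means equal: no gap
  cut <- which.max(gaps)
  lower <- v[seq_len(cut)]; upper <- v[(cut + 1):n]
  ss <- sum((lower - mean(lower))^2) + sum((upper - mean(upper))^2)
  dfree <- n - 2
  pooled_sd <- if (dfree > 0) sqrt(ss / dfree) else 0
  gap <- max(gaps)
  if (pooled_sd > 0 && gap < min_gap * pooled_sd) return(out)
  call_sorted <- rep(c("female", "male"), c(cut, n - cut))
  out$call[ord] <- call_sorted
  out
}

#' Concordance of sex calls with known phenotypic sex
#'
#' Fraction of known-sex samples whose genetic call matches; `"unknown"`
#' calls count as discordant. Returns `NA` (with a warning) when no known
#' labels overlap the calls.
#'
#' @param calls data.frame from [call_sex_from_y_probes()].
#' @param known data.frame `sample_id`, `sex` in `{"male","female"}`.
#' @return list with `concordance` (proportion) and `n_known`.
#' @export
sex_concordance <- function(calls, known) {
  m <- merge(calls, known, by = "sample_id")
  if (nrow(m) == 0) {
    warning("no known-sex samples among the calls; concordance undefined")
    return(list(concordance = NA_real_, n_known = 0L))
  }
  list(concordance = mean(m$call == m$sex), n_known = nrow(m))
}
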