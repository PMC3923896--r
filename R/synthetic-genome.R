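#' Generate a fragmented genome model with paralogous region pairs
#'
#' Builds a contig-level genome emulating a draft salmonid assembly: many
#' contigs with gamma-distributed lengths, a configurable fraction of which
#' lies inside duplicated (paralogous) region pairs left over from the
#' salmonid whole-genome duplication. Paralogy is represented as pairs of
#' equal-length, non-overlapping regions; candidate variants simulated inside
#' these regions behave as PSVs.
#'
#' @param n_contigs number of contigs (>= 1).
#' @param mean_length mean contig length in bp (> 0).
#' @param duplicated_fraction target fraction of total sequence inside
#'   duplicated region pairs, in `[0, 1]`.
#' @param seed integer seed; identical seeds give identical models.
#' @return An object of class `genome_model`: list with `contigs`
#'   (data.frame `contig`, `length`), `duplicated_pairs` (data.frame with
#'   0-based half-open regions `contig1`, `start1`, `end1`, `contig2`,
#'   `start2`, `end2`) and `seed`.
#' @examples
#' g <- make_genome(50, 1e4, duplicated_fraction = 0.3, seed = 1)
#' realized_duplicated_fraction(g)
#' @export
make_genome <- function(n_contigs, mean_length, duplicated_fraction = 0, seed = 1L) {
  stop_if_not(n_contigs >= 1, "n_contigs must be >= 1")
  stop_if_not(mean_length > 0, "mean_length must be positive")
  stop_if_not(duplicated_fraction >= 0 && duplicated_fraction <= 1,
              "duplicated_fraction must be in [0, 1]")
  with_seed(seed, {
    lens <- pmax(200L, as.integer(round(rgamma(n_contigs, shape = 5, rate = 5 / mean_length))))
    contigs <- data.frame(contig = sprintf("contig_%04d", seq_len(n_contigs)),
                          length = lens, stringsAsFactors = FALSE)
    total <- sum(as.double(lens))
    need <- round(duplicated_fraction * total)
    slices <- list()
    if (need > 0) {
      block <- max(1, ceiling(mean_length / 4))
      ## carve non-overlapping slices greedily from contigs in random order
      for (ci in sample.int(n_contigs)) {
        if (need <= 0) break
        pos <- 0L
        avail <- lens[ci]
        while (avail > 0 && need > 0) {
          s <- min(block, avail, need)
          slices[[length(slices) + 1L]] <-
            c(ci = ci, start = pos, end = pos + s)
          pos <- pos + s
          avail <- avail - s
          need <- need - s
        }
      }
    }
    pairs <- data.frame(contig1 = character(0), start1 = integer(0), end1 = integer(0),
                        contig2 = character(0), start2 = integer(0), end2 = integer(0),
                        stringsAsFactors = FALSE)
    if (length(slices) > 0) {
      if (length(slices) %% 2 == 1) {
        ## split the last slice so every region has a partner
        last <- slices[[length(slices)]]
        w <- last["end"] - last["start"]
        if (w >= 2) {
          h <- floor(w / 2)
          slices[[length(slices)]] <- c(last["ci"], last["start"], last["start"] + h)
          names(slices[[length(slices)]]) <- c("ci", "start", "end")
          slices[[length(slices) + 1L]] <- c(ci = unname(last["ci"]),
                                             start = unname(last["start"] + h),
                                             end = unname(last["end"]))
        } else {
          slices[[length(slices)]] <- NULL
        }
      }
      if (length(slices) >= 2) {
        odd <- seq(1, length(slices) - 1, by = 2)
        pairs <- data.frame(
          contig1 = contigs$contig[vapply(slices[odd], `[[`, 0, "ci")],
          start1  = vapply(slices[odd], `[[`, 0, "start"),
          end1    = vapply(slices[odd], `[[`, 0, "end"),
          contig2 = contigs$contig[vapply(slices[odd + 1], `[[`, 0, "ci")],
          start2  = vapply(slices[odd + 1], `[[`, 0, "start"),
          end2    = vapply(slices[odd + 1], `[[`, 0, "end"),
          stringsAsFactors = FALSE)
      }
    }
    structure(list(contigs = contigs, duplicated_pairs = pairs, seed = as.integer(seed)),
              class = "genome_model")
  })
}

#' Realized duplicated fraction of a genome model
#'
#' Fraction of total assembly length that lies inside either side of a
#' duplicated region pair.
#' @param genome a `genome_model`.
#' @return numeric in `[0, 1]`.
#' @export
realized_duplicated_fraction <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  p <- genome$duplicated_pairs
  if (nrow(p) == 0) return(0)
  dup <- sum(as.double(p$end1 - p$start1)) + sum(as.double(p$end2 - p$start2))
  dup / sum(as.double(genome$contigs$length))
}

## TRUE where (contig, 1-based position) falls in a duplicated region
in_duplicated_region <- function(genome, contig, position) {
  p <- genome$duplicated_pairs
  if (nrow(p) == 0) return(rep(FALSE, length(contig)))
  pos0 <- position - 1L
  hit <- rep(FALSE, length(contig))
  for (i in seq_len(nrow(p))) {
    hit <- hit |
      (contig == p$contig1[i] & pos0 >= p$start1[i] & pos0 < p$end1[i]) |
      (contig == p$contig2[i] & pos0 >= p$start2[i] & pos0 < p$end2[i])
  }
  hit
}
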