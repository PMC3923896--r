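#' Pipeline configuration
#'
#' Collects every stage threshold and simulation parameter in one validated,
#' serialisable object. Defaults reproduce the demo scenario: a fragmented
#' genome with 25% duplicated sequence, a 96-sample genotyping panel (72
#' unrelated fish from four populations plus two reference families of 2
#' parents and 10 offspring), 2,000 array SNPs on 5 chromosomes, and the
#' standard thresholds (haploid GQ 20; pooled frequency 0.1; depth 10;
#' distortion alpha 0.05; call rate 0.97; two minor-allele samples; MAF
#' 0.05; call confidence 0.95; four autogroup layers ending at LOD 2.5).
#'
#' @param seed master seed; all stage randomness derives from it.
#' @param n_markers SNPs placed on the simulated array.
#' @param n_candidates candidate sites simulated upstream of filtering.
#' @param n_chromosomes,n_families,n_offspring mapping-panel design.
#' @param psv_fraction,depth_mean,error_rate candidate simulation controls.
#' @param msv_fraction,otv_fraction intensity simulation controls.
#' @param gq_threshold,freq_threshold,depth_threshold,alpha filtering
#'   thresholds.
#' @param call_rate_threshold,min_minor_samples,separation_floor QC
#'   thresholds.
#' @param maf_threshold,confidence_threshold analysis thresholds.
#' @param layers autogroup layers (see [default_autogroup_layers()]).
#' @param anchors_per_chromosome sire-informative anchor markers per
#'   chromosome.
#' @param n_known_sex samples with known phenotypic sex for the concordance
#'   report.
#' @param stages named logical vector of stage toggles.
#' @param out_dir optional directory for stage outputs (TSV/VCF/JSON).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_markers = 2000L, n_candidates = 3L * n_markers,
                            n_chromosomes = 5L, n_families = 2L,
                            n_offspring = 10L,
                            psv_fraction = 0.2, depth_mean = 30,
                            error_rate = 0.002,
                            msv_fraction = 0.05, otv_fraction = 0.05,
                            gq_threshold = 20, freq_threshold = 0.1,
                            depth_threshold = 10, alpha = 0.05,
                            call_rate_threshold = 0.97,
                            min_minor_samples = 2L, separation_floor = 3,
                            maf_threshold = 0.05,
                            confidence_threshold = 0.95,
                            layers = default_autogroup_layers(),
                            anchors_per_chromosome = 3L,
                            n_known_sex = 63L,
                            stages = c(simulate = TRUE, filter = TRUE,
                                       call = TRUE, qc = TRUE, map = TRUE,
                                       popstruct = TRUE, sex = TRUE),
                            out_dir = NULL) {
  cfg <- as.list(environment())
  stop_if_not(freq_threshold >= 0 && freq_threshold <= 1, "freq_threshold in [0,1]")
  stop_if_not(alpha > 0 && alpha < 1, "alpha in (0,1)")
  stop_if_not(call_rate_threshold > 0 && call_rate_threshold <= 1,
              "call_rate_threshold in (0,1]")
  stop_if_not(confidence_threshold > 0 && confidence_threshold < 1,
              "confidence_threshold in (0,1)")
  stop_if_not(n_candidates >= n_markers, "need n_candidates >= n_markers")
  structure(cfg, class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration (YAML)
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `path` (write) / `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$layers <- as.list(config$layers)
  obj$stages <- as.list(config$stages)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$layers <- as.data.frame(obj$layers)
  obj$stages <- unlist(obj$stages)
  do.call(pipeline_config, obj)
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in order — simulate, filter, call, qc, map,
#' popstruct, sex — skipping disabled ones, with all randomness derived
#' from the config seed through named substreams, and returns every stage
#' output together with a run manifest of input/output record counts.
#'
#' @param config a `pipeline_config`.
#' @return list with one element per executed stage plus `manifest`
#'   (data.frame `stage`, `n_in`, `n_out`, `seconds`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  manifest <- data.frame(stage = character(0), n_in = integer(0),
                         n_out = integer(0), seconds = numeric(0))
  note <- function(stage, n_in, n_out, t0) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, n_in = n_in, n_out = n_out,
      seconds = round(as.numeric(Sys.time()) - t0, 2)))
  }
  on <- function(s) isTRUE(config$stages[[s]])
  sseed <- function(k) substream_seed(config$seed, k)

  ## ---- simulate --------------------------------------------------------
  stop_if_not(on("simulate"), "pipeline requires the simulate stage")
  t0 <- as.numeric(Sys.time())
  genome <- make_genome(n_contigs = 400, mean_length = 1e4,
                        duplicated_fraction = 0.25, seed = sseed(1))
  panel <- make_panel(populations = data.frame(
    name = c("farmed_scottish", "farmed_norwegian_1",
             "farmed_norwegian_2", "wild"),
    n = c(23L, 8L, 8L, 33L),
    divergence = c(0.06, 0.10, 0.10, 0.18)),
    n_sites = config$n_candidates, n_haploid = 1, seed = sseed(2))
  sim <- simulate_candidate_variants(
    genome, panel, n_sites = config$n_candidates,
    psv_fraction = config$psv_fraction, depth_mean = config$depth_mean,
    error_rate = config$error_rate, seed = sseed(3))
  mask <- with_seed(sseed(4), {
    ctg <- sample(genome$contigs$contig, 80)
    len <- genome$contigs$length[match(ctg, genome$contigs$contig)]
    st <- as.integer(floor(runif(80) * pmax(1, len - 500)))
    data.frame(contig = ctg, start = st, end = pmin(st + 500L, len))
  })
  res$simulate <- list(genome = genome, panel = panel,
                       candidates = sim$candidates, truth = sim$truth,
                       mask = mask)
  note("simulate", 0L, nrow(sim$candidates), t0)

  ## ---- filter ----------------------------------------------------------
  cand <- sim$candidates
  if (on("filter")) {
    t0 <- as.numeric(Sys.time())
    n_in <- nrow(cand)
    parts <- split(cand, cand$source)
    rr <- rr_filter_chain(parts$RR, mask = mask,
                          gq_threshold = config$gq_threshold,
                          freq_threshold = config$freq_threshold,
                          depth_threshold = config$depth_threshold)
    rna <- apply_rna_filters(parts$RNA, maf_threshold = config$freq_threshold)
    ## RAD candidates: pedigree-based filters on family genotypes simulated
    ## at the RAD markers (no chromosome structure needed for filtering)
    ped_rad <- make_families(config$n_families, config$n_offspring)
    rad_map <- data.frame(marker = parts$RAD$id, chrom = "radchr",
                          pos_mb = seq_len(nrow(parts$RAD)) * 50)
    rad_sim <- simulate_family_genotypes(
      ped_rad, rad_map, founder_freq = pmin(0.95, pmax(0.05, parts$RAD$pooled_freq)),
      female_recomb_per_mb = 0.05, seed = sseed(5))
    rad <- apply_rad_filters(parts$RAD, rad_sim$genotypes, ped_rad,
                             alpha = config$alpha)
    kept <- rbind(rr$kept, rad$kept, rna$kept)
    removed <- rbind(rr$removed, rad$removed, rna$removed)
    res$filter <- list(kept = kept, removed = removed, rr_ledger = rr$ledger)
    note("filter", n_in, nrow(kept), t0)
    cand <- kept
  }

  ## ---- array content + genotypes + intensities -------------------------
  t0 <- as.numeric(Sys.time())
  capacity <- min(config$n_markers, nrow(cand))
  sel <- select_array_content(cand, capacity = max(capacity,
    sum(cand$rec_fwd == "recommended" | cand$rec_rev == "recommended" |
          (cand$rec_fwd == "neutral" & cand$rec_rev == "neutral"))))
  sel <- sel[order(sel$selection_stage != "base", -sel$conversion_score,
                   sel$id), , drop = FALSE]
  sel <- head(sel, capacity)
  markers <- sel$id
  marker_map <- data.frame(
    marker = markers,
    chrom = sprintf("chr%02d", rep_len(seq_len(config$n_chromosomes),
                                       length(markers))),
    pos_mb = as.numeric(ave(seq_along(markers),
                            rep_len(seq_len(config$n_chromosomes),
                                    length(markers)), FUN = seq_along)))
  ped <- make_families(config$n_families, config$n_offspring)
  famg <- simulate_family_genotypes(ped, marker_map, founder_freq = 0.5,
                                    male_recomb = 0,
                                    female_recomb_per_mb = 0.02,
                                    seed = sseed(6))
  popg <- simulate_population_genotypes(
    panel, markers, freq_rows = match(markers, sim$candidates$id),
    seed = sseed(7))
  geno <- cbind(famg$genotypes[markers, , drop = FALSE], popg)
  intens <- simulate_intensities(geno, msv_fraction = config$msv_fraction,
                                 otv_fraction = config$otv_fraction,
                                 seed = sseed(8))
  res$array <- list(selected = sel, marker_map = marker_map, pedigree = ped,
                    genotypes = geno, truth = intens$truth,
                    family_truth = famg$truth)
  note("array", nrow(cand), length(markers), t0)

  ## ---- call ------------------------------------------------------------
  if (on("call")) {
    t0 <- as.numeric(Sys.time())
    called <- axiom_genotype(intens$intensities,
                             confidence_threshold = config$confidence_threshold,
                             otv = TRUE)
    res$call <- called
    note("call", length(markers), nrow(called$calls), t0)
  } else {
    ## calling disabled: consume the simulated genotypes directly
    called <- list(calls = data.frame(
      probeset_id = rep(rownames(geno), ncol(geno)),
      sample_id = rep(colnames(geno), each = nrow(geno)),
      call = as.vector(geno), confidence = 1), points = NULL)
  }

  ## call matrix (markers x samples) with NoCall/OTV as NA
  cm <- calls_to_matrix(called$calls)

  ## ---- qc --------------------------------------------------------------
  if (on("qc")) {
    t0 <- as.numeric(Sys.time())
    qc <- classify_probesets(called$calls, points = called$points,
                             call_rate_threshold = config$call_rate_threshold,
                             min_minor_samples = config$min_minor_samples,
                             separation_floor = config$separation_floor)
    mend <- pedigree_mendelian_filter(cm, ped)
    qc$mendelian_pass <- mend[qc$probeset_id]
    qc$source <- sel$source[match(qc$probeset_id, sel$id)]
    res$qc <- list(table = qc, ledger = qc_ledger(qc))
    retained <- qc$probeset_id[qc$retained & qc$mendelian_pass]
    note("qc", length(markers), length(retained), t0)
  } else {
    retained <- rownames(cm)
  }

  ## ---- map -------------------------------------------------------------
  if (on("map")) {
    t0 <- as.numeric(Sys.time())
    gmap <- cm[retained, , drop = FALSE]
    trans <- select_sire_informative(gmap, ped)
    inf <- rownames(gmap)[rowSums(trans$informative) > 0]
    trans_inf <- select_sire_informative(gmap[inf, , drop = FALSE], ped)
    lm <- lod_matrix(trans_inf)
    anchors <- with_seed(sseed(9), {
      do.call(rbind, lapply(split(inf, marker_map$chrom[match(inf, marker_map$marker)]),
        function(ms) data.frame(
          marker = sample(ms, min(config$anchors_per_chromosome, length(ms))),
          stringsAsFactors = FALSE)))
    })
    anchors$chromosome <- marker_map$chrom[match(anchors$marker, marker_map$marker)]
    ag <- autogroup_layers(lm, anchors, layers = config$layers)
    rc <- resolve_anchor_conflicts(ag, trans_inf, anchors)
    res$map <- list(informative = inf, assignment = rc$assignment,
                    conflicts = rc$conflicts, anchors = anchors,
                    counts = chromosome_counts(rc$assignment))
    note("map", length(inf), sum(!is.na(rc$assignment$chromosome)), t0)
  }

  ## ---- popstruct -------------------------------------------------------
  if (on("popstruct")) {
    t0 <- as.numeric(Sys.time())
    unrelated <- intersect(colnames(cm), panel$samples$sample_id)
    gk <- cm[retained, unrelated, drop = FALSE]
    pm <- population_maf(gk, panel, maf_threshold = config$maf_threshold)
    ib <- ibs_distance(gk)
    md <- classical_mds(ib$dist, k = 2)
    res$popstruct <- list(maf = pm, venn = venn_counts(pm), ibs = ib, mds = md)
    note("popstruct", length(retained), nrow(md$points), t0)
  }

  ## ---- sex -------------------------------------------------------------
  if (on("sex")) {
    t0 <- as.numeric(Sys.time())
    sex_samples <- rbind(
      panel$samples[panel$samples$ploidy == 2, c("sample_id", "sex")],
      data.frame(sample_id = ped$id, sex = ped$sex))
    ysim <- simulate_y_probe_intensities(sex_samples, seed = sseed(10))
    calls <- call_sex_from_y_probes(ysim$intensities)
    known <- with_seed(sseed(11), {
      ks <- sample(ysim$truth$sample_id,
                   min(config$n_known_sex, nrow(ysim$truth)))
      ysim$truth[ysim$truth$sample_id %in% ks, , drop = FALSE]
    })
    conc <- sex_concordance(calls, known)
    res$sex <- list(calls = calls, truth = ysim$truth, known = known,
                    concordance = conc)
    note("sex", nrow(sex_samples), nrow(calls), t0)
  }

  res$manifest <- manifest
  res$config <- config
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' Convert a long call table to a markers-by-samples genotype matrix
#'
#' `NoCall` and `OTV` become `NA`.
#' @param calls data.frame `probeset_id`, `sample_id`, `call`.
#' @return character matrix.
#' @export
calls_to_matrix <- function(calls) {
  ms <- unique(calls$probeset_id); ss <- sort(unique(calls$sample_id))
  m <- matrix(NA_character_, length(ms), length(ss),
              dimnames = list(ms, ss))
  v <- calls$call
  v[!(v %in% c("AA", "AB", "BB"))] <- NA
  m[cbind(match(calls$probeset_id, ms), match(calls$sample_id, ss))] <- v
  m
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_minimal_vcf(res$simulate$candidates, p("candidates.vcf"))
  write_tsv(res$simulate$truth, p("candidate_truth.tsv"))
  if (!is.null(res$filter)) write_tsv(res$filter$kept, p("filtered_candidates.tsv"))
  write_ped(res$array$pedigree, p("pedigree.ped"))
  if (!is.null(res$call)) write_tsv(res$call$calls, p("genotype_calls.tsv"))
  if (!is.null(res$qc)) {
    write_tsv(res$qc$table, p("snp_qc.tsv"))
    write_tsv(res$qc$ledger, p("qc_ledger.tsv"))
  }
  if (!is.null(res$map)) write_tsv(res$map$assignment, p("chromosome_assignment.tsv"))
  if (!is.null(res$popstruct)) {
    write_tsv(as.data.frame(res$popstruct$ibs$dist), p("ibs_distance.tsv"))
    write_tsv(as.data.frame(res$popstruct$mds$points), p("mds_coordinates.tsv"))
    jsonlite::write_json(as.list(res$popstruct$venn), p("venn_counts.json"),
                         auto_unbox = TRUE)
  }
  if (!is.null(res$sex)) write_tsv(res$sex$calls, p("sex_calls.tsv"))
  write_tsv(res$manifest, p("manifest.tsv"))
  invisible(out_dir)
}
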