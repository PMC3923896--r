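#' @name io
#' @title Readers and writers for the pipeline's standard formats
#' @description
#' Minimal, validated text I/O: VCF (CHROM POS ID REF ALT QUAL FILTER INFO
#' with DP and AF), 6-column PED pedigrees, BED repeat masks (0-based
#' half-open), and TSV intensity tables. Malformed lines are reported with
#' their line numbers.
NULL

#' Write candidates as a minimal VCF
#'
#' @param candidates data.frame with `contig`, `position`, `id`, `ref`,
#'   `alt`, and optionally `depth` (INFO DP) and `pooled_freq` (INFO AF).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_minimal_vcf <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pooled read depth\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Pooled alternate allele frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  dp <- if (is.null(candidates$depth)) rep(".", nrow(candidates))
        else paste0("DP=", candidates$depth)
  af <- if (is.null(candidates$pooled_freq)) ""
        else paste0(";AF=", signif(candidates$pooled_freq, 6))
  info <- paste0(dp, af)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                     candidates$contig, candidates$position, candidates$id,
                     candidates$ref, candidates$alt, info), con)
  invisible(path)
}

#' Read a minimal VCF into a candidate table
#'
#' @param path VCF file (plain text).
#' @return data.frame `contig`, `position`, `id`, `ref`, `alt`, `depth`,
#'   `pooled_freq` (NA where the INFO field is absent).
#' @export
read_minimal_vcf <- function(path) {
  lines <- readLines(path)
  body_ix <- which(!startsWith(lines, "#"))
  if (length(body_ix) == 0)
    return(data.frame(contig = character(0), position = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), depth = integer(0),
                      pooled_freq = numeric(0)))
  fields <- strsplit(lines[body_ix], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8)
  if (length(bad) > 0)
    stop("malformed VCF line(s): ", paste(body_ix[bad], collapse = ", "),
         call. = FALSE)
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos) || any(pos < 1))
    stop("invalid POS at line(s): ",
         paste(body_ix[is.na(pos) | pos < 1], collapse = ", "), call. = FALSE)
  ok_allele <- function(x) grepl("^[ACGT]+$", x)
  if (!all(ok_allele(m[, 4]) & ok_allele(m[, 5])))
    stop("invalid REF/ALT allele at line(s): ",
         paste(body_ix[!(ok_allele(m[, 4]) & ok_allele(m[, 5]))],
               collapse = ", "), call. = FALSE)
  get_info <- function(info, tag) {
    v <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(^|;)", tag, "="), info)
    out[hit] <- sub(paste0(".*", tag, "="), "", v)
    out
  }
  data.frame(contig = m[, 1], position = pos, id = m[, 3],
             ref = m[, 4], alt = m[, 5],
             depth = suppressWarnings(as.integer(get_info(m[, 8], "DP"))),
             pooled_freq = suppressWarnings(as.numeric(get_info(m[, 8], "AF"))),
             stringsAsFactors = FALSE)
}

#' Write a pedigree as 6-column PED-like text
#'
#' Columns: family, id, sire, dam, sex (1 = male, 2 = female, 0 = unknown),
#' phenotype (always 0 here). Missing parents are written as 0.
#' @param pedigree a `pedigree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ped <- function(pedigree, path) {
  sex_code <- ifelse(pedigree$sex == "male", 1L,
                     ifelse(pedigree$sex == "female", 2L, 0L))
  df <- data.frame(pedigree$family, pedigree$id,
                   ifelse(is.na(pedigree$sire), "0", pedigree$sire),
                   ifelse(is.na(pedigree$dam), "0", pedigree$dam),
                   sex_code, 0L)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column PED-like pedigree
#'
#' Referenced parent ids must exist in the file; violations name the
#' offending individual.
#' @param path PED file.
#' @return a validated `pedigree`.
#' @export
read_ped <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   colClasses = "character", col.names =
                     c("family", "id", "sire", "dam", "sex", "phenotype"))
  for (i in seq_len(nrow(df))) {
    for (col in c("sire", "dam")) {
      p <- df[[col]][i]
      if (p != "0" && !(p %in% df$id))
        stop("individual '", df$id[i], "' references unknown ", col, " '",
             p, "'", call. = FALSE)
    }
  }
  ped <- data.frame(
    id = df$id,
    sire = ifelse(df$sire == "0", NA_character_, df$sire),
    dam = ifelse(df$dam == "0", NA_character_, df$dam),
    family = df$family,
    sex = c("0" = "unknown", "1" = "male", "2" = "female")[df$sex],
    stringsAsFactors = FALSE)
  validate_pedigree(ped)
}

#' Read a BED repeat mask (0-based, half-open)
#'
#' Intervals with `start >= end` (including empty intervals) are rejected
#' with their line numbers; intervals are sorted per contig.
#' @param path BED file (first three columns used).
#' @return data.frame `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t")[, 1:3]
  names(df) <- c("contig", "start", "end")
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0)
    stop("invalid BED interval(s) (need start < end) at line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write/read TSV tables (intensities, calls, truth sidecars)
#' @param x data.frame.
#' @param path file path.
#' @return `path` (write) or data.frame (read).
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
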