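# Readers and writers for the standard interchange formats: VCFv4.2 with
# haploid GT (read through vcfR), BED (0-based half-open, converted to the
# package's 1-based inclusive intervals at the boundary), per-sample depth
# TSV, mating-outcome CSV and strain/group tables.

#' Write a variant matrix as a haploid VCFv4.2 file
#'
#' @param vm A \code{variant_matrix}.
#' @param file Output path (plain-text VCF).
#' @return \code{file}, invisibly.
#' @export
write_vcf <- function(vm, file) {
  stopifnot(inherits(vm, "variant_matrix"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hetrv",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (!is.null(vm$chrom_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(vm$chrom_lengths),
                       as.integer(vm$chrom_lengths)), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vm$samples), collapse = "\t"), con)
  gt <- vm$geno
  gt_chr <- matrix(".", nrow(gt), ncol(gt))
  gt_chr[!is.na(gt)] <- as.character(gt[!is.na(gt)])
  body <- paste(vm$chrom, vm$pos, ".", vm$ref, vm$alt, ".", "PASS", ".",
                "GT", sep = "\t")
  if (nrow(gt)) {
    body <- paste(body, apply(gt_chr, 1, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(file)
}

#' Read a haploid multi-sample VCF into a variant matrix
#'
#' Parses with \code{vcfR}, keeps biallelic SNPs only and interprets the
#' GT field as haploid 0/1 calls ("." = missing). Contig lengths are taken
#' from the header when present.
#'
#' @param file Path to a VCF (optionally gzipped).
#' @return A \code{variant_matrix}.
#' @export
read_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  fix <- fix[biallelic, , drop = FALSE]
  gt <- gt[biallelic, , drop = FALSE]
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
  geno[gt == "0"] <- 0L
  geno[gt == "1"] <- 1L
  chrom_lengths <- NULL
  meta <- v@meta
  contig <- meta[grepl("^##contig=", meta)]
  if (length(contig)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                            contig)))
    if (!anyNA(lens)) chrom_lengths <- stats::setNames(lens, ids)
  }
  variant_matrix(fix[, "CHROM"], as.integer(fix[, "POS"]), geno,
                 samples = colnames(gt), ref = fix[, "REF"],
                 alt = fix[, "ALT"], chrom_lengths = chrom_lengths)
}

#' Write intervals as a BED file (0-based, half-open)
#'
#' @param intervals Data frame with chrom, start, end in the package's
#'   1-based inclusive convention.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_bed <- function(intervals, file) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  utils::write.table(
    data.frame(intervals$chrom, intervals$start - 1L, intervals$end),
    file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param file Path to a BED file (0-based half-open).
#' @return Data frame with chrom, start, end (1-based inclusive).
#' @export
read_bed <- function(file) {
  info <- file.info(file)
  if (!is.na(info$size) && info$size == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  bed <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]])
}

#' Write per-sample coverage as a long TSV (chrom, pos, sample, depth)
#'
#' @param coverage A \code{coverage_track}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_coverage_tsv <- function(coverage, file) {
  rows <- lapply(names(coverage), function(ch) {
    m <- coverage[[ch]]
    data.frame(chrom = ch, pos = rep(seq_len(nrow(m)), ncol(m)),
               sample = rep(colnames(m), each = nrow(m)),
               depth = as.vector(m))
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a long-format coverage TSV back into a coverage track
#'
#' @param file Path to a TSV with columns chrom, pos, sample, depth.
#' @return A \code{coverage_track}.
#' @export
read_coverage_tsv <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- list()
  for (ch in unique(d$chrom)) {
    dd <- d[d$chrom == ch, ]
    samples <- unique(dd$sample)
    L <- max(dd$pos)
    m <- matrix(NA_integer_, L, length(samples),
                dimnames = list(NULL, samples))
    for (s in samples) {
      ds <- dd[dd$sample == s, ]
      m[ds$pos, s] <- ds$depth
    }
    out[[ch]] <- m
  }
  structure(out, class = "coverage_track")
}

#' Write / read a mating-outcome matrix as CSV
#'
#' Strain IDs form the header row and first column; cells hold codes 1-6 or
#' are empty for unscored crosses.
#'
#' @param m Integer matrix of mating codes.
#' @param file Path.
#' @return \code{file} (write) or the integer matrix (read).
#' @export
write_mating_csv <- function(m, file) {
  utils::write.csv(m, file, na = "")
  invisible(file)
}

#' @rdname write_mating_csv
#' @export
read_mating_csv <- function(file) {
  d <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "integer"
  m
}

#' Write a window-statistics table as TSV (missing values as "NA")
#'
#' @param stats Data frame from \code{\link{window_stats}}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_windows_tsv <- function(stats, file) {
  utils::write.table(stats, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(file)
}
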