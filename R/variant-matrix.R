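#' Haploid biallelic variant matrix
#'
#' Container for a multi-sample set of biallelic SNPs with haploid calls.
#' Genotypes are stored as an integer matrix with sites in rows and samples
#' in columns; 0 = reference allele, 1 = alternate allele, NA = missing call.
#' Positions are 1-based and strictly increasing within each chromosome.
#'
#' @param chrom Character vector of chromosome names, one per site.
#' @param pos Integer vector of 1-based positions, one per site.
#' @param geno Integer matrix (sites x samples) of 0/1/NA haploid calls.
#' @param samples Character vector of sample names (defaults to the column
#'   names of \code{geno}).
#' @param ref,alt Optional reference/alternate allele characters per site.
#' @param chrom_lengths Optional named vector of chromosome lengths in bp.
#' @return An object of class \code{variant_matrix}.
#' @export
variant_matrix <- function(chrom, pos, geno, samples = colnames(geno),
                           ref = NULL, alt = NULL, chrom_lengths = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- nrow(geno)
  if (length(chrom) != n_sites || length(pos) != n_sites) {
    hetrv_stop("'chrom' and 'pos' must have one entry per row of 'geno'")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    hetrv_stop("genotype calls must be 0, 1 or NA (biallelic haploid)")
  }
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(geno)))
  colnames(geno) <- samples
  ord <- order(match(chrom, unique(chrom)), pos)
  chrom <- as.character(chrom)[ord]
  pos <- as.integer(pos)[ord]
  geno <- geno[ord, , drop = FALSE]
  if (!is.null(ref)) ref <- ref[ord]
  if (!is.null(alt)) alt <- alt[ord]
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (anyDuplicated(p)) hetrv_stop("duplicated positions on ", ch)
  }
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("T", n_sites)
  if (!is.null(chrom_lengths)) {
    for (ch in unique(chrom)) {
      if (!ch %in% names(chrom_lengths)) {
        hetrv_stop("no length given for chromosome ", ch)
      }
      if (any(pos[chrom == ch] > chrom_lengths[[ch]])) {
        hetrv_stop("positions beyond the stated length of ", ch)
      }
    }
  }
  structure(
    list(chrom = chrom, pos = pos, ref = ref, alt = alt, geno = geno,
         samples = samples, chrom_lengths = chrom_lengths),
    class = "variant_matrix"
  )
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat("variant_matrix:", nrow(x$geno), "biallelic sites x",
      ncol(x$geno), "haploid samples\n")
  tab <- table(x$chrom)
  cat("  sites per chromosome:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.variant_matrix <- function(x) dim(x$geno)

#' Subset a variant matrix by chromosome and/or site filter
#'
#' @param vm A \code{variant_matrix}.
#' @param chrom Optional chromosome name(s) to retain.
#' @param sites Optional logical or integer index over sites.
#' @return A \code{variant_matrix} restricted to the selected sites.
#' @export
subset_sites <- function(vm, chrom = NULL, sites = NULL) {
  keep <- rep(TRUE, nrow(vm$geno))
  if (!is.null(chrom)) keep <- keep & vm$chrom %in% chrom
  if (!is.null(sites)) {
    sel <- rep(FALSE, nrow(vm$geno))
    sel[sites] <- TRUE
    keep <- keep & sel
  }
  variant_matrix(vm$chrom[keep], vm$pos[keep],
                 vm$geno[keep, , drop = FALSE], samples = vm$samples,
                 ref = vm$ref[keep], alt = vm$alt[keep],
                 chrom_lengths = vm$chrom_lengths)
}
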