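# Strain-level genotype utilities: WD40 repeat counts from amplicon sizes,
# het-r allele classification, two-locus association, the substrate
# contingency test, allele-frequency trajectories through time, and the
# recombination arithmetic used in positional cloning.

#' WD40 repeat count from amplicon size
#'
#' One WD40 repeat corresponds to a PCR product of about 126 bp, so the
#' repeat count is the amplicon size divided by 126, rounded to the nearest
#' integer. Exact half-integers are rounded down with a warning (the call
#' should be confirmed by sequencing).
#'
#' @param amplicon_bp Amplicon size(s) in bp (> 0).
#' @param bp_per_repeat Size of one repeat unit (default 126 bp).
#' @return Integer repeat count(s).
#' @examples
#' wd40_repeat_count(1386) # 11 repeats
#' @export
wd40_repeat_count <- function(amplicon_bp, bp_per_repeat = 126) {
  if (any(!is.finite(amplicon_bp)) || any(amplicon_bp <= 0)) {
    hetrv_stop("'amplicon_bp' must be positive")
  }
  x <- amplicon_bp / bp_per_repeat
  frac <- x - floor(x)
  if (any(abs(frac - 0.5) < 1e-9)) {
    warning("amplicon size exactly between two repeat counts; rounding down")
  }
  as.integer(floor(x + 0.5 - 1e-9))
}

#' Classify a het-r allele from its WD40 repeat structure
#'
#' The functional allele R has exactly 11 WD40 repeats in a specific
#' reference order; any other repeat count, or 11 repeats in a different
#' order, is the non-functional allele r. If the repeat order has not been
#' determined, a count of 11 yields a provisional R call flagged for
#' sequencing.
#'
#' @param repeat_count Integer repeat count(s).
#' @param order_matches Logical: does the repeat order match the reference
#'   R arrangement? NA = order unknown.
#' @return Data frame with columns allele ("R" or "r") and provisional
#'   (TRUE when the call rests on the count alone).
#' @export
classify_het_r <- function(repeat_count, order_matches = NA) {
  n <- length(repeat_count)
  order_matches <- rep_len(order_matches, n)
  allele <- ifelse(repeat_count == 11 &
                     (is.na(order_matches) | order_matches), "R", "r")
  provisional <- repeat_count == 11 & is.na(order_matches)
  data.frame(allele = allele, provisional = provisional,
             stringsAsFactors = FALSE)
}

#' Two-locus association (r2) from a strain genotype table
#'
#' Computes the squared allele-frequency correlation between two biallelic
#' loci across the strains genotyped at both, together with the 2x2
#' haplotype count table. Delegates the r2 computation to
#' \code{\link{r2_pair}} on allele-indicator vectors.
#'
#' @param records Data frame of strain records.
#' @param locus_a,locus_b Column names of the two loci (e.g. "het_r",
#'   "het_v"); values "unknown" or NA are treated as missing.
#' @return List with \code{r2}, \code{counts} (2x2 haplotype table) and
#'   \code{n} (strains with both calls).
#' @examples
#' tab <- data.frame(het_r = c("r", "R", "r"), het_v = c("V", "V1", "V1"))
#' two_locus_r2(tab, "het_r", "het_v")
#' @export
two_locus_r2 <- function(records, locus_a = "het_r", locus_b = "het_v") {
  a <- as.character(records[[locus_a]])
  b <- as.character(records[[locus_b]])
  a[a == "unknown"] <- NA; b[b == "unknown"] <- NA
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  ua <- sort(unique(a)); ub <- sort(unique(b))
  if (length(ua) != 2) hetrv_stop("locus '", locus_a,
                                  "' is not biallelic among scored strains")
  if (length(ub) != 2) hetrv_stop("locus '", locus_b,
                                  "' is not biallelic among scored strains")
  xa <- as.integer(a == ua[2]); xb <- as.integer(b == ub[2])
  list(r2 = r2_pair(xa, xb),
       counts = table(factor(a, ua), factor(b, ub)),
       n = length(a))
}

#' Contingency test of group abundance by substrate
#'
#' Pearson chi-squared test on the 2x2 table of reproductive-isolation
#' group versus substrate. Continuity correction is off by default.
#'
#' @param records Data frame with a group column and a substrate column, or
#'   NULL if \code{table2x2} is given directly.
#' @param group_col,substrate_col Column names (defaults "group",
#'   "substrate").
#' @param substrates The two substrate categories to test (others dropped).
#' @param yates Apply the Yates continuity correction (default FALSE).
#' @param table2x2 Optional 2x2 count table, overriding \code{records}.
#' @return List with \code{statistic}, \code{df}, \code{p_value} and
#'   \code{table}.
#' @export
substrate_test <- function(records = NULL, group_col = "group",
                           substrate_col = "substrate",
                           substrates = c("horse", "rabbit"),
                           yates = FALSE, table2x2 = NULL) {
  if (is.null(table2x2)) {
    keep <- records[[substrate_col]] %in% substrates
    tab <- table(records[[group_col]][keep],
                 records[[substrate_col]][keep])
  } else {
    tab <- as.table(as.matrix(table2x2))
  }
  if (!all(dim(tab) == c(2, 2))) hetrv_stop("need a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    hetrv_stop("zero margin in the contingency table; merge categories")
  }
  ct <- stats::chisq.test(tab, correct = yates)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}

#' Per-year allele frequencies at a locus
#'
#' @param records Strain table with a year column and the locus column;
#'   "unknown"/NA genotypes are dropped.
#' @param locus Column name of the locus.
#' @param min_per_year Minimum genotyped strains for a year to be reported
#'   (default 6, i.e. years with more than five samples).
#' @return Data frame with year, allele, n_year and frequency; frequencies
#'   sum to 1 within each reported year.
#' @export
allele_trajectories <- function(records, locus = "het_v", min_per_year = 6L) {
  g <- as.character(records[[locus]])
  g[g == "unknown"] <- NA
  ok <- !is.na(g) & !is.na(records$year)
  d <- data.frame(year = records$year[ok], allele = g[ok])
  counts <- as.data.frame(table(d$year, d$allele),
                          stringsAsFactors = FALSE)
  names(counts) <- c("year", "allele", "n")
  counts$year <- as.integer(counts$year)
  totals <- tapply(counts$n, counts$year, sum)
  counts$n_year <- as.integer(totals[as.character(counts$year)])
  counts <- counts[counts$n_year >= min_per_year, , drop = FALSE]
  counts$frequency <- counts$n / counts$n_year
  out <- counts[order(counts$year, counts$allele),
                c("year", "allele", "n_year", "frequency")]
  rownames(out) <- NULL
  out
}

#' Recombination-distance report for a positional-cloning cross
#'
#' Converts observed recombinant counts between two markers into the
#' recombination percentage and the physical distance corresponding to 1%
#' recombination. Full precision is kept internally; the print method
#' reports at 1 decimal, matching the usual reporting convention.
#'
#' @param total Total progeny scored (> 0).
#' @param recombinants Number of recombinant progeny (0 <= r <= total).
#' @param physical_bp Physical distance between the markers in bp (> 0).
#' @return Object of class \code{map_distance}: \code{percent}
#'   (recombination %), \code{kb_per_pct} (kb per 1% recombination; NA when
#'   no recombinants were seen), plus the inputs.
#' @examples
#' map_distance_report(103, 11, 244000)
#' @export
map_distance_report <- function(total, recombinants, physical_bp) {
  total <- check_count(total, "total")
  if (recombinants < 0 || recombinants > total) {
    hetrv_stop("'recombinants' must lie in [0, total]")
  }
  if (physical_bp <= 0) hetrv_stop("'physical_bp' must be > 0")
  percent <- 100 * recombinants / total
  kb_per_pct <- if (percent > 0) physical_bp / percent / 1000 else NA_real_
  structure(list(percent = percent, kb_per_pct = kb_per_pct,
                 total = total, recombinants = recombinants,
                 physical_bp = physical_bp),
            class = "map_distance")
}

#' @export
print.map_distance <- function(x, ...) {
  cat(sprintf("%d of %d progeny recombinant: %.1f%% recombination\n",
              x$recombinants, x$total, x$percent))
  if (is.na(x$kb_per_pct)) {
    cat("  no recombinants observed; kb per 1% recombination undefined\n")
  } else {
    cat(sprintf("  %.0f kb physical distance: %.1f kb per 1%% recombination\n",
                x$physical_bp / 1000, x$kb_per_pct))
  }
  invisible(x)
}
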