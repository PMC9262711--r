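# Linkage disequilibrium: pairwise r2 on haploid calls, chromosome-wise
# decay fitting under the recombination-drift equilibrium expectation,
# distance-binned summaries, thinned LD matrices and locus-vs-genome scans.

#' Squared allele-frequency correlation between two sites
#'
#' Computes haplotype-based r2 = D^2 / (pA qA pB qB) with D = pAB - pA pB on
#' the pairwise-complete haploid calls; for phased haploid data this equals
#' the squared Pearson correlation of the two 0/1 site vectors.
#'
#' @param x,y Numeric/integer 0/1 vectors of haploid calls (NA = missing).
#' @return r2 in [0, 1], or NA (with a message) if fewer than two complete
#'   pairs remain or either site is monomorphic in the overlap.
#' @examples
#' r2_pair(c(1, 1, 0, 0), c(1, 1, 0, 0)) # 1: perfect association
#' @export
r2_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) {
    message("r2_pair: fewer than two complete pairs; returning NA")
    return(NA_real_)
  }
  pA <- mean(x); pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    message("r2_pair: monomorphic site in the pairwise-complete overlap")
    return(NA_real_)
  }
  D <- mean(x == 1 & y == 1) - pA * pB
  # clamp floating-point spill just outside [0, 1]
  min(max(D^2 / (pA * (1 - pA) * pB * (1 - pB)), 0), 1)
}

#' Sample within-window site pairs for LD-decay estimation
#'
#' For each chromosome, draws \code{windows_per_chrom} windows of
#' \code{window_len} bp uniformly at random (overlaps permitted; duplicate
#' site pairs are de-duplicated), removes singleton sites and computes r2
#' for every remaining within-window pair.
#'
#' @param vm A \code{variant_matrix} with \code{chrom_lengths}.
#' @param windows_per_chrom Number of windows per chromosome (default 30).
#' @param window_len Window length in bp (default 50000).
#' @param drop_singletons Remove sites whose minor allele is carried by a
#'   single sample (default TRUE).
#' @param seed Optional seed.
#' @return Data frame of LD records: chrom, pos1, pos2, dist, r2
#'   (pos1 < pos2). Chromosomes shorter than \code{window_len} are skipped
#'   with a warning.
#' @export
sample_decay_pairs <- function(vm, windows_per_chrom = 30L,
                               window_len = 50000L, drop_singletons = TRUE,
                               seed = NULL) {
  stopifnot(inherits(vm, "variant_matrix"))
  if (is.null(vm$chrom_lengths)) hetrv_stop("'vm' must carry chrom_lengths")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (ch in names(vm$chrom_lengths)) {
    L <- vm$chrom_lengths[[ch]]
    if (L < window_len) {
      warning("chromosome ", ch, " shorter than window_len; skipped")
      next
    }
    on_ch <- which(vm$chrom == ch)
    pos <- vm$pos[on_ch]
    geno <- vm$geno[on_ch, , drop = FALSE]
    if (drop_singletons && length(on_ch)) {
      cnt <- rowSums(geno == 1L, na.rm = TRUE)
      n_i <- rowSums(!is.na(geno))
      keep <- pmin(cnt, n_i - cnt) >= 2
      pos <- pos[keep]; geno <- geno[keep, , drop = FALSE]
    }
    if (length(pos) < 2) next
    starts <- sample.int(L - window_len + 1L, windows_per_chrom,
                         replace = TRUE)
    seen <- character(0)
    for (s in starts) {
      idx <- which(pos >= s & pos <= s + window_len - 1L)
      if (length(idx) < 2) next
      prs <- utils::combn(idx, 2)
      for (cidx in seq_len(ncol(prs))) {
        i <- prs[1, cidx]; j <- prs[2, cidx]
        key <- paste(pos[i], pos[j])
        if (key %in% seen) next
        seen <- c(seen, key)
        r2 <- suppressMessages(r2_pair(geno[i, ], geno[j, ]))
        if (is.na(r2)) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, pos1 = pos[i], pos2 = pos[j],
          dist = pos[j] - pos[i], r2 = r2)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), pos1 = integer(0),
                      pos2 = integer(0), dist = integer(0), r2 = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Equilibrium expectation of r2 under recombination and drift
#'
#' The expected r2 between two sites separated by scaled recombination
#' distance C = rho * d (with rho = 4 Ne c the population recombination
#' rate per bp and d the distance in bp), for a sample of n sequences,
#' under a recombination-drift equilibrium model with low mutation:
#' \deqn{E[r^2] = \frac{10 + C}{(2 + C)(11 + C)}
#'   \left[1 + \frac{(3 + C)(12 + 12C + C^2)}{n (2 + C)(11 + C)}\right]}
#' At C = 0 and large n this tends to 10/22; as C grows it tends to 1/n.
#'
#' @param C Scaled recombination distance(s), >= 0.
#' @param n Sample size (number of sequences).
#' @return Expected r2 value(s).
#' @export
expected_r2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD-decay curve and estimate the population recombination rate
#'
#' Least-squares fit of \code{\link{expected_r2}} to observed distance-r2
#' records, over the single parameter rho (per bp). The sum of squares is
#' first profiled on a log-spaced grid (multi-start) and then refined by
#' golden-section search around the best grid point.
#'
#' @param records Data frame with columns dist and r2 (as produced by
#'   \code{\link{sample_decay_pairs}}); at least 10 records with positive
#'   distances.
#' @param n Number of sequences behind the r2 values.
#' @param rho_range Log10 search range for rho per bp.
#' @return Object of class \code{ld_decay_fit}: \code{rho} (per bp),
#'   \code{n}, \code{ss} (residual sum of squares), \code{converged},
#'   \code{d02} (distance in bp where the fitted expectation crosses 0.2,
#'   or NA if it never does), \code{n_records}.
#' @export
fit_decay <- function(records, n, rho_range = c(-8, 0)) {
  records <- records[!is.na(records$r2) & records$dist > 0, , drop = FALSE]
  if (nrow(records) < 10) hetrv_stop("need >= 10 records with positive distance")
  d <- records$dist; r2 <- records$r2
  ssfun <- function(log10rho) {
    sum((r2 - expected_r2((10^log10rho) * d, n))^2)
  }
  grid <- seq(rho_range[1], rho_range[2], length.out = 121)
  ss_grid <- vapply(grid, ssfun, numeric(1))
  best <- which.min(ss_grid)
  lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(ssfun, c(lo, hi), tol = 1e-12)
  rho <- 10^opt$minimum
  converged <- best > 1 && best < length(grid)
  d02 <- NA_real_
  f02 <- function(dd) expected_r2(rho * dd, n) - 0.2
  if (f02(1e-9) > 0 && f02(1e12) < 0) {
    d02 <- stats::uniroot(f02, c(1e-9, 1e12), tol = 1e-9)$root
  }
  structure(list(rho = rho, n = n, ss = opt$objective, converged = converged,
                 d02 = d02, n_records = nrow(records)),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat("LD decay fit (recombination-drift equilibrium expectation)\n")
  cat(sprintf("  rho = %.4g per bp (n = %d sequences, %d pairs, SS = %.4g)\n",
              x$rho, x$n, x$n_records, x$ss))
  if (!is.na(x$d02)) {
    cat(sprintf("  fitted E[r2] crosses 0.2 at %.1f bp\n", x$d02))
  }
  if (!x$converged) cat("  WARNING: estimate at the search boundary\n")
  invisible(x)
}

#' @export
coef.ld_decay_fit <- function(object, ...) c(rho = object$rho)

#' @export
predict.ld_decay_fit <- function(object, dist, ...) {
  expected_r2(object$rho * dist, object$n)
}

#' Mean r2 in distance bins
#'
#' @param records LD record data frame (columns dist, r2).
#' @param bin_width Bin width in bp (right-open bins from 0).
#' @return Data frame with bin_start, bin_end, n_pairs, mean_r2 (NA for
#'   empty bins).
#' @export
binned_ld <- function(records, bin_width = 1000L) {
  if (bin_width <= 0) hetrv_stop("'bin_width' must be > 0")
  if (!nrow(records)) hetrv_stop("no LD records")
  bin <- floor(records$dist / bin_width)
  n_bins <- max(bin) + 1L
  out <- data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_width,
                    bin_end = seq_len(n_bins) * bin_width,
                    n_pairs = 0L, mean_r2 = NA_real_)
  agg <- tapply(records$r2, bin, mean, na.rm = TRUE)
  cnt <- tapply(records$r2, bin, function(v) sum(!is.na(v)))
  idx <- as.integer(names(agg)) + 1L
  out$mean_r2[idx] <- as.numeric(agg)
  out$n_pairs[idx] <- as.integer(cnt)
  out
}

#' Thinned pairwise r2 matrix
#'
#' Filters sites by minor allele frequency, greedily thins so no two kept
#' sites lie within \code{min_spacing} bp of each other (keep the first
#' site, drop any site closer than the spacing to the last kept one), and
#' computes the full pairwise r2 matrix among the kept sites, suitable for
#' LD heatmaps within or between chromosome segments.
#'
#' @param vm A \code{variant_matrix}.
#' @param maf_min Minimum minor allele frequency (default 0.02).
#' @param min_spacing Minimum spacing between kept sites in bp.
#' @param chrom Optional chromosome restriction.
#' @return List with \code{sites} (data frame chrom, pos) and \code{r2}
#'   (symmetric matrix with unit diagonal). Both empty if no site passes.
#' @export
thin_and_matrix <- function(vm, maf_min = 0.02, min_spacing = 1000L,
                            chrom = NULL) {
  stopifnot(inherits(vm, "variant_matrix"))
  keep <- rep(TRUE, nrow(vm$geno))
  if (!is.null(chrom)) keep <- keep & vm$chrom %in% chrom
  maf <- site_maf(vm$geno)
  keep <- keep & !is.na(maf) & maf >= maf_min & maf > 0
  idx <- which(keep)
  kept <- integer(0)
  for (ch in unique(vm$chrom[idx])) {
    ich <- idx[vm$chrom[idx] == ch]
    ich <- ich[order(vm$pos[ich])]
    last <- -Inf
    for (i in ich) {
      if (vm$pos[i] - last >= min_spacing || !is.finite(last)) {
        kept <- c(kept, i)
        last <- vm$pos[i]
      }
    }
  }
  if (!length(kept)) {
    return(list(sites = data.frame(chrom = character(0), pos = integer(0)),
                r2 = matrix(numeric(0), 0, 0)))
  }
  g <- vm$geno[kept, , drop = FALSE]
  k <- length(kept)
  m <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- suppressMessages(r2_pair(g[i, ], g[j, ]))
    }
  }
  list(sites = data.frame(chrom = vm$chrom[kept], pos = vm$pos[kept]),
       r2 = m)
}

#' LD of a focal locus against every SNP
#'
#' Computes r2 between a focal genotype vector (for example the het-v allele
#' indicator) and every SNP passing the MAF filter, plus a genome-wide
#' distribution summary so named comparisons can be situated within it.
#'
#' @param vm A \code{variant_matrix}.
#' @param focal Named 0/1 vector aligned to the samples of \code{vm}.
#' @param maf_min Minimum minor allele frequency for scanned SNPs.
#' @return List with \code{records} (chrom, pos, r2 per site) and
#'   \code{summary} (mean, median and upper quantiles of the r2
#'   distribution).
#' @export
locus_ld_scan <- function(vm, focal, maf_min = 0.02) {
  stopifnot(inherits(vm, "variant_matrix"))
  if (!is.null(names(focal))) focal <- focal[vm$samples]
  if (length(focal) != length(vm$samples)) {
    hetrv_stop("'focal' must align with the samples of 'vm'")
  }
  fo <- focal[!is.na(focal)]
  if (length(unique(fo)) < 2) hetrv_stop("focal locus is monomorphic")
  maf <- site_maf(vm$geno)
  idx <- which(!is.na(maf) & maf >= maf_min & maf > 0)
  r2 <- vapply(idx, function(i)
    suppressMessages(r2_pair(vm$geno[i, ], focal)), numeric(1))
  records <- data.frame(chrom = vm$chrom[idx], pos = vm$pos[idx], r2 = r2)
  vals <- r2[!is.na(r2)]
  list(records = records,
       summary = c(n = length(vals), mean = mean(vals),
                   median = stats::median(vals),
                   q95 = unname(stats::quantile(vals, 0.95)),
                   max = max(vals)))
}
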