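# Sliding-window diversity and differentiation scan with callability
# masking. Standard VCFs only list variable sites, so sites with unreliable
# coverage must be flagged explicitly and removed from the window length
# (the "effective length" L_eff) before per-bp statistics are computed;
# otherwise missing data deflates the estimates.

#' Coverage-quantile callability mask
#'
#' Flags, per sample, sites whose depth lies strictly below that sample's
#' low quantile or strictly above its high quantile of the genome-wide depth
#' distribution ("bad" coverage); the mask is the set of sites that are bad
#' in every sample AND overlap the repeat annotation. Masked sites are
#' treated as missing data and excluded from the effective window length.
#' Quantiles use the empirical type-7 rule with strict inequalities, so
#' constant coverage masks nothing.
#'
#' @param coverage A \code{coverage_track}: list of positions x samples depth
#'   matrices, one per chromosome.
#' @param repeats Data frame of repeat intervals with columns chrom, start,
#'   end (1-based inclusive). May have zero rows.
#' @param low_q,high_q Quantile thresholds, defaults 0.25 and 0.985.
#' @return A \code{callability_mask}: data frame of masked intervals (chrom,
#'   start, end, 1-based inclusive) with the per-chromosome masked-position
#'   sets stored in the \code{"positions"} attribute.
#' @export
mask_sites <- function(coverage, repeats, low_q = 0.25, high_q = 0.985) {
  if (!length(coverage)) hetrv_stop("empty coverage")
  if (low_q <= 0 || low_q >= 1 || high_q <= 0 || high_q >= 1) {
    hetrv_stop("quantiles must lie strictly inside (0, 1)")
  }
  samples <- colnames(coverage[[1]])
  n_samp <- ncol(coverage[[1]])
  # per-sample genome-wide depth quantiles
  lo <- hi <- numeric(n_samp)
  for (s in seq_len(n_samp)) {
    depths <- unlist(lapply(coverage, function(m) m[, s]), use.names = FALSE)
    qs <- stats::quantile(depths, c(low_q, high_q), type = 7, names = FALSE)
    lo[s] <- qs[1]; hi[s] <- qs[2]
  }
  masked_pos <- list()
  rows <- list()
  for (ch in names(coverage)) {
    m <- coverage[[ch]]
    bad_all <- rep(TRUE, nrow(m))
    for (s in seq_len(n_samp)) {
      bad_all <- bad_all & (m[, s] < lo[s] | m[, s] > hi[s])
    }
    rep_ch <- repeats[repeats$chrom == ch, , drop = FALSE]
    in_rep <- rep(FALSE, nrow(m))
    for (i in seq_len(nrow(rep_ch))) {
      in_rep[rep_ch$start[i]:min(rep_ch$end[i], nrow(m))] <- TRUE
    }
    pos <- which(bad_all & in_rep)
    masked_pos[[ch]] <- pos
    if (length(pos)) {
      runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
      rows[[ch]] <- data.frame(chrom = ch,
                               start = vapply(runs, min, numeric(1)),
                               end = vapply(runs, max, numeric(1)),
                               row.names = NULL)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  rownames(out) <- NULL
  structure(out, positions = masked_pos, class = c("callability_mask",
                                                   "data.frame"))
}

#' Build a callability mask directly from intervals
#'
#' @param intervals Data frame with columns chrom, start, end (1-based
#'   inclusive) of positions to mask.
#' @return A \code{callability_mask}.
#' @export
callability_mask <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start > intervals$end)) {
    hetrv_stop("invalid mask intervals")
  }
  pos <- lapply(split(intervals, intervals$chrom), function(d) {
    sort(unique(unlist(mapply(seq, d$start, d$end, SIMPLIFY = FALSE))))
  })
  structure(as.data.frame(intervals), positions = pos,
            class = c("callability_mask", "data.frame"))
}

# internal: masked positions on one chromosome (integer vector)
mask_positions <- function(mask, chrom) {
  if (is.null(mask)) return(integer(0))
  p <- attr(mask, "positions")[[chrom]]
  if (is.null(p)) integer(0) else p
}

# internal: per-site summaries used by every window statistic
site_summaries <- function(geno) {
  n_i <- rowSums(!is.na(geno))
  j_i <- rowSums(geno == 1L, na.rm = TRUE)
  list(n = n_i, j = j_i)
}

# Tajima (1989) normalising constants for sample size n
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# internal: window grid tiling a chromosome from position 1
window_grid <- function(chrom_len, window, step) {
  starts <- seq(1L, max(1L, chrom_len), by = step)
  starts <- starts[starts <= chrom_len]
  ends <- pmin(starts + window - 1L, chrom_len)
  data.frame(start = starts, end = ends)
}

#' Sliding-window diversity and differentiation statistics
#'
#' Computes, in windows tiling each chromosome, the per-site pairwise
#' nucleotide diversity pi, Watterson's theta, Tajima's D and, when group
#' labels are supplied, Hudson's Fst (window-level ratio of averages,
#' 1 - sum(Hw)/sum(Hb)) and the absolute divergence Dxy. Masked positions
#' are excluded from the effective window length L_eff and variant sites
#' falling on them are ignored; windows with L_eff below
#' \code{min_eff} are reported as NA throughout.
#'
#' Definitions (per window, usable sites only): pi = sum over sites of
#' 2 j (n - j) / (n (n - 1)) divided by L_eff, with j the alternate-allele
#' count among the n non-missing calls at the site; thetaW = sum over
#' segregating sites of 1 / a_n (per-site sample size) divided by L_eff;
#' Tajima's D uses only sites with complete calls, so that its mean pairwise
#' difference, segregating-site count and variance constants refer to one
#' common sample size; Dxy = sum of p1 (1 - p2) + p2 (1 - p1) over usable
#' sites with at least two calls per group, divided by L_eff.
#'
#' @param vm A \code{variant_matrix} carrying \code{chrom_lengths}.
#' @param mask Optional \code{callability_mask}.
#' @param window,step Window length and step in bp (defaults 10000 and 1000).
#' @param min_eff Minimum effective length in bp (default 5000); shorter
#'   windows are set to missing.
#' @param groups Optional named vector of two group labels per sample (for
#'   Fst/Dxy).
#' @param n_perm Number of label permutations for the per-window Fst null
#'   (0 = skip). Permutations are shared across windows within an iteration
#'   and drawn without replacement at the observed group sizes.
#' @param seed Seed for the permutations.
#' @return Data frame with one row per window: chrom, start, end, l_eff,
#'   n_sites, pi, theta_w, tajima_d and, with groups, fst, dxy, p_perm.
#' @export
window_stats <- function(vm, mask = NULL, window = 10000L, step = 1000L,
                         min_eff = 5000L, groups = NULL, n_perm = 0L,
                         seed = NULL) {
  stopifnot(inherits(vm, "variant_matrix"))
  if (is.null(vm$chrom_lengths)) {
    hetrv_stop("'vm' must carry chrom_lengths to define the window grid")
  }
  if (step > window) hetrv_stop("'step' must be <= 'window'")
  if (min_eff > window) hetrv_stop("'min_eff' must be <= 'window'")
  if (n_perm < 0) hetrv_stop("'n_perm' must be >= 0")
  g_idx <- NULL
  if (!is.null(groups)) {
    groups <- groups[vm$samples]
    if (anyNA(groups)) hetrv_stop("groups must cover every sample")
    lv <- unique(groups)
    if (length(lv) != 2) hetrv_stop("exactly two groups are required")
    g_idx <- list(which(groups == lv[1]), which(groups == lv[2]))
    if (any(lengths(g_idx) < 2)) hetrv_stop("each group needs >= 2 samples")
  }
  perms <- NULL
  if (!is.null(g_idx) && n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    n_samp <- length(vm$samples)
    n1 <- length(g_idx[[1]])
    perms <- replicate(n_perm, sample.int(n_samp, n1), simplify = FALSE)
  }

  res <- list()
  for (ch in names(vm$chrom_lengths)) {
    L <- vm$chrom_lengths[[ch]]
    grid <- window_grid(L, window, step)
    on_ch <- vm$chrom == ch
    pos <- vm$pos[on_ch]
    geno <- vm$geno[on_ch, , drop = FALSE]
    mpos <- mask_positions(mask, ch)
    usable_site <- !(pos %in% mpos)

    ss <- site_summaries(geno)
    pi_site <- ifelse(ss$n >= 2, 2 * ss$j * (ss$n - ss$j) /
                        (ss$n * (ss$n - 1)), NA_real_)
    seg <- ss$j > 0 & ss$j < ss$n & ss$n >= 2
    theta_site <- ifelse(seg, 1 / vapply(ss$n, function(nn)
      if (nn >= 2) watterson_a(nn) else NA_real_, numeric(1)), 0)
    complete <- ss$n == ncol(geno)

    fst_parts <- NULL
    if (!is.null(g_idx)) {
      fst_parts <- fst_site_components(geno, g_idx[[1]], g_idx[[2]])
    }

    df <- grid
    df$chrom <- ch
    df$l_eff <- NA_real_; df$n_sites <- NA_integer_
    df$pi <- df$theta_w <- df$tajima_d <- NA_real_
    if (!is.null(g_idx)) df$fst <- df$dxy <- NA_real_
    if (!is.null(perms)) df$p_perm <- NA_real_
    obs_fst <- rep(NA_real_, nrow(grid))
    win_sites <- vector("list", nrow(grid))

    for (wi in seq_len(nrow(grid))) {
      s <- grid$start[wi]; e <- grid$end[wi]
      wlen <- e - s + 1L
      masked_bp <- if (length(mpos)) sum(mpos >= s & mpos <= e) else 0L
      l_eff <- wlen - masked_bp
      df$l_eff[wi] <- l_eff
      if (l_eff < min_eff) next
      in_w <- which(pos >= s & pos <= e & usable_site)
      win_sites[[wi]] <- in_w
      df$n_sites[wi] <- length(in_w)
      df$pi[wi] <- sum(pi_site[in_w], na.rm = TRUE) / l_eff
      df$theta_w[wi] <- sum(theta_site[in_w], na.rm = TRUE) / l_eff
      # Tajima's D on complete-call sites in the window; undefined below
      # n = 4 (the variance constants vanish identically at n = 3)
      cw <- in_w[complete[in_w]]
      S <- sum(seg[cw])
      if (S >= 1 && ncol(geno) >= 4) {
        tc <- tajima_constants(ncol(geno))
        pi_tot <- sum(pi_site[cw])
        df$tajima_d[wi] <- (pi_tot - S / tc$a1) /
          sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
      }
      if (!is.null(g_idx) && length(in_w)) {
        ok <- in_w[fst_parts$ok[in_w]]
        hb_sum <- sum(fst_parts$hb[ok])
        hw_sum <- sum(fst_parts$hw[ok])
        df$dxy[wi] <- hb_sum / l_eff
        if (hb_sum > 0) {
          df$fst[wi] <- 1 - hw_sum / hb_sum
          obs_fst[wi] <- df$fst[wi]
        }
      }
    }

    if (!is.null(perms)) {
      exceed <- rep(0L, nrow(grid))
      n_samp <- length(vm$samples)
      for (pm in perms) {
        parts <- fst_site_components(geno, pm, setdiff(seq_len(n_samp), pm))
        for (wi in seq_len(nrow(grid))) {
          if (is.na(obs_fst[wi])) next
          in_w <- win_sites[[wi]]
          ok <- in_w[parts$ok[in_w]]
          hb <- sum(parts$hb[ok]); hw <- sum(parts$hw[ok])
          if (hb > 0 && (1 - hw / hb) >= obs_fst[wi]) {
            exceed[wi] <- exceed[wi] + 1L
          }
        }
      }
      df$p_perm <- ifelse(is.na(obs_fst), NA_real_,
                          (1 + exceed) / (n_perm + 1))
    }
    cols <- c("chrom", "start", "end", "l_eff", "n_sites", "pi", "theta_w",
              "tajima_d",
              if (!is.null(g_idx)) c("fst", "dxy"),
              if (!is.null(perms)) "p_perm")
    res[[ch]] <- df[cols]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# internal: per-site Hudson components. hw = mean within-group unbiased
# heterozygosity, hb = between-group heterozygosity; ok = both groups have
# >= 2 non-missing calls.
fst_site_components <- function(geno, idx1, idx2) {
  g1 <- geno[, idx1, drop = FALSE]; g2 <- geno[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(g1)); j1 <- rowSums(g1 == 1L, na.rm = TRUE)
  n2 <- rowSums(!is.na(g2)); j2 <- rowSums(g2 == 1L, na.rm = TRUE)
  ok <- n1 >= 2 & n2 >= 2
  p1 <- ifelse(n1 > 0, j1 / n1, NA_real_)
  p2 <- ifelse(n2 > 0, j2 / n2, NA_real_)
  hw1 <- ifelse(n1 >= 2, 2 * j1 * (n1 - j1) / (n1 * (n1 - 1)), NA_real_)
  hw2 <- ifelse(n2 >= 2, 2 * j2 * (n2 - j2) / (n2 * (n2 - 1)), NA_real_)
  list(hw = (hw1 + hw2) / 2, hb = p1 * (1 - p2) + p2 * (1 - p1), ok = ok)
}

#' Principal component analysis of SNP genotypes
#'
#' Filters to biallelic sites with minor allele frequency at or above
#' \code{maf_min} (and, by default, no missing calls), centres the 0/1
#' sample x site matrix column-wise and eigendecomposes it. Centring only
#' (no unit-variance scaling) is the default; set \code{scale = TRUE} for
#' the standardised variant.
#'
#' @param vm A \code{variant_matrix}.
#' @param maf_min Minimum minor allele frequency (default 0.01; sites below
#'   it are filtered out).
#' @param require_complete Drop sites with any missing call (default TRUE).
#' @param chrom Optional chromosome(s) to restrict to (genome-wide
#'   otherwise).
#' @param scale Standardise sites to unit variance (default FALSE).
#' @return Object of class \code{snp_pca}: \code{scores} (samples x PCs),
#'   \code{varfrac} (fraction of variance per PC), \code{n_sites}.
#' @export
pca_snps <- function(vm, maf_min = 0.01, require_complete = TRUE,
                     chrom = NULL, scale = FALSE) {
  stopifnot(inherits(vm, "variant_matrix"))
  keep <- rep(TRUE, nrow(vm$geno))
  if (!is.null(chrom)) keep <- keep & vm$chrom %in% chrom
  geno <- vm$geno[keep, , drop = FALSE]
  if (require_complete) geno <- geno[rowSums(is.na(geno)) == 0L, ,
                                     drop = FALSE]
  maf <- site_maf(geno)
  geno <- geno[!is.na(maf) & maf >= maf_min & maf > 0, , drop = FALSE]
  if (nrow(geno) == 0L) hetrv_stop("no sites pass the PCA filters")
  x <- t(geno)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, varfrac = varfrac, n_sites = nrow(geno)),
            class = "snp_pca")
}

#' @export
print.snp_pca <- function(x, ...) {
  cat("SNP PCA on", x$n_sites, "sites,", nrow(x$scores), "samples\n")
  k <- min(5, length(x$varfrac))
  cat("  variance explained:",
      paste0("PC", seq_len(k), "=",
             sprintf("%.1f%%", 100 * x$varfrac[seq_len(k)]), collapse = " "),
      "\n")
  invisible(x)
}

#' Assign samples to reproductive-isolation groups from PC1
#'
#' Thresholds PC1 at zero after orienting its sign with a labelled anchor
#' subset: each side of zero inherits the majority label of its anchors.
#' Samples exactly at zero are left unassigned.
#'
#' @param pc1 Named numeric vector of PC1 scores.
#' @param anchors Named character vector of known labels for a subset of
#'   samples; both labels must be represented.
#' @return Data frame with columns sample, label ("unassigned" at the
#'   boundary) and provenance ("PC1" for inferred, "anchor" for anchored
#'   samples).
#' @export
assign_ri_from_pc1 <- function(pc1, anchors) {
  if (is.null(names(pc1))) hetrv_stop("'pc1' must be named by sample")
  anchors <- anchors[names(anchors) %in% names(pc1)]
  labs <- unique(anchors)
  if (length(labs) != 2) hetrv_stop("anchors must contain exactly two labels")
  side <- sign(pc1[names(anchors)])
  maj <- function(s) {
    v <- anchors[side == s]
    if (!length(v)) return(NA_character_)
    tt <- sort(table(v), decreasing = TRUE)
    if (length(tt) > 1 && tt[1] == tt[2]) {
      hetrv_stop("anchor labels tied on one side of PC1 = 0")
    }
    names(tt)[1]
  }
  lab_pos <- maj(1); lab_neg <- maj(-1)
  if (is.na(lab_pos) && is.na(lab_neg)) {
    hetrv_stop("anchors all at PC1 = 0; cannot orient the axis")
  }
  if (is.na(lab_pos)) lab_pos <- setdiff(labs, lab_neg)
  if (is.na(lab_neg)) lab_neg <- setdiff(labs, lab_pos)
  if (lab_pos == lab_neg) {
    hetrv_stop("anchors do not separate along PC1; cannot orient the axis")
  }
  label <- ifelse(pc1 > 0, lab_pos, ifelse(pc1 < 0, lab_neg, "unassigned"))
  data.frame(sample = names(pc1), label = unname(label),
             provenance = ifelse(names(pc1) %in% names(anchors),
                                 "anchor", "PC1"),
             stringsAsFactors = FALSE)
}
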