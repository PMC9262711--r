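# Independent brute-force oracles. These deliberately avoid the package's
# code paths: everything is computed by direct enumeration (pairwise loops,
# explicit constants transcribed from the defining formulas) so estimator
# tests compare two genuinely separate implementations.

# mean pairwise difference summed over sites (pi numerator)
oracle_pi_total <- function(geno) {
  tot <- 0
  for (s in seq_len(nrow(geno))) {
    v <- geno[s, ]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2) next
    diffs <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) diffs <- diffs + as.integer(v[i] != v[j])
    }
    tot <- tot + diffs / choose(n, 2)
  }
  tot
}

# Watterson numerator: sum over segregating sites of 1 / a_{n_site}
oracle_theta_total <- function(geno) {
  tot <- 0
  for (s in seq_len(nrow(geno))) {
    v <- geno[s, ]
    v <- v[!is.na(v)]
    if (length(v) < 2 || length(unique(v)) < 2) next
    tot <- tot + 1 / sum(1 / seq_len(length(v) - 1))
  }
  tot
}

# Tajima's D from complete-call sites, constants written out longhand
oracle_tajima_d <- function(geno) {
  complete <- rowSums(is.na(geno)) == 0
  g <- geno[complete, , drop = FALSE]
  n <- ncol(g)
  if (n < 4) return(NA_real_) # variance term degenerates at n = 3
  seg <- apply(g, 1, function(v) length(unique(v)) == 2)
  S <- sum(seg)
  if (S < 1) return(NA_real_)
  k_hat <- oracle_pi_total(g)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Hudson Fst (ratio of averages) and Dxy numerator by per-site loops
oracle_fst_dxy <- function(geno, idx1, idx2) {
  hw_sum <- hb_sum <- 0
  for (s in seq_len(nrow(geno))) {
    v1 <- geno[s, idx1]; v1 <- v1[!is.na(v1)]
    v2 <- geno[s, idx2]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2 || length(v2) < 2) next
    hw1 <- 0
    for (i in seq_along(v1)) for (j in seq_along(v1)) {
      if (i < j) hw1 <- hw1 + as.integer(v1[i] != v1[j])
    }
    hw1 <- hw1 / choose(length(v1), 2)
    hw2 <- 0
    for (i in seq_along(v2)) for (j in seq_along(v2)) {
      if (i < j) hw2 <- hw2 + as.integer(v2[i] != v2[j])
    }
    hw2 <- hw2 / choose(length(v2), 2)
    hb <- 0
    for (i in seq_along(v1)) for (j in seq_along(v2)) {
      hb <- hb + as.integer(v1[i] != v2[j])
    }
    hb <- hb / (length(v1) * length(v2))
    hw_sum <- hw_sum + (hw1 + hw2) / 2
    hb_sum <- hb_sum + hb
  }
  list(fst = if (hb_sum > 0) 1 - hw_sum / hb_sum else NA_real_,
       dxy_total = hb_sum)
}

# r2 as the squared Pearson correlation on the complete overlap
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

# Pearson chi-squared by explicit expected counts
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# random haploid genotype matrix with optional missingness; guarantees at
# least one usable site
random_geno <- function(n_samples, n_sites, miss = 0.1) {
  repeat {
    g <- matrix(rbinom(n_samples * n_sites, 1,
                       runif(n_sites, 0.1, 0.9)[rep(seq_len(n_sites),
                                                    each = n_samples)]),
                nrow = n_sites, byrow = TRUE)
    if (miss > 0) g[runif(length(g)) < miss] <- NA
    keep <- rowSums(!is.na(g)) >= 2
    if (any(keep)) return(g[keep, , drop = FALSE])
  }
}

# exact per-offspring genotype law by enumeration over ordered parent
# pairs, written independently of the simulator internals
oracle_offspring_law <- function(counts, sigma, b_na, b_a, iota_na, iota_a) {
  genos <- names(counts)
  split_alleles <- function(g) {
    r <- substr(g, 1, 1)
    v <- substr(g, 2, nchar(g))
    c(r, v)
  }
  freq <- counts / sum(counts)
  # incompatible-partner frequencies per system
  x_a <- x_na <- setNames(numeric(length(genos)), genos)
  for (g in genos) {
    ag <- split_alleles(g)
    for (h in genos) {
      ah <- split_alleles(h)
      if (ag[2] != ah[2]) x_a[g] <- x_a[g] + freq[h]
      if ((ag[1] == "R" && ah[2] == "V") || (ah[1] == "R" && ag[2] == "V")) {
        x_na[g] <- x_na[g] + freq[h]
      }
    }
  }
  w <- 1 + b_na * x_na + b_a * x_a
  pm <- counts * w / sum(counts * w)
  # accumulate over every viable genotype, including ones absent from the
  # current population but producible by recombination
  q <- setNames(numeric(3), c("rV", "RV1", "rV1"))
  q[genos] <- sigma * pm[genos]
  for (m in genos) {
    am <- split_alleles(m)
    for (f in genos) {
      af <- split_alleles(f)
      surv <- 1
      if (am[2] != af[2]) surv <- surv * (1 - iota_a)
      if ((am[1] == "R" && af[2] == "V") || (af[1] == "R" && am[2] == "V")) {
        surv <- surv * (1 - iota_na)
      }
      # enumerate the four meiotic products; an RV product is a failed
      # attempt and contributes nothing (neither mass nor normalisation)
      for (rr in c(am[1], af[1])) {
        for (vv in c(am[2], af[2])) {
          g <- paste0(rr, vv)
          if (g == "RV") next
          q[g] <- q[g] + (1 - sigma) * pm[m] * pm[f] * surv * 0.25
        }
      }
    }
  }
  # the redraw conditions on a viable germination, so the law is the
  # accumulated viable mass renormalised
  q / sum(q)
}
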