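# Synthetic-data generators. Every input consumed by the downstream stages
# (variant matrices, coverage tracks, repeat annotations, mating matrices,
# strain tables) can be generated here with known expectations, so the whole
# pipeline is testable without sequencing data.

#' Neutral haploid alignment from the standard coalescent
#'
#' Simulates a Kingman coalescent genealogy for \code{n_samples} haploid
#' sequences and drops infinite-sites mutations on the branches as a Poisson
#' process, so the resulting SNP matrix has closed-form expectations:
#' expected per-site pairwise diversity equals \code{theta_per_site} and the
#' expected number of segregating sites is
#' \code{theta_per_site * seq_length * a_n} with \code{a_n} the Watterson
#' harmonic sum.
#'
#' @param n_samples Number of haploid sequences (>= 2).
#' @param seq_length Sequence length in bp.
#' @param theta_per_site Scaled mutation rate per site (expected
#'   heterozygosity); >= 0.
#' @param seed Optional seed for reproducibility.
#' @param chrom Chromosome name for the output.
#' @return A \code{variant_matrix} of the segregating sites.
#' @examples
#' vm <- generate_neutral_alignment(10, 1e5, 5e-4, seed = 1)
#' @export
generate_neutral_alignment <- function(n_samples, seq_length, theta_per_site,
                                       seed = NULL, chrom = "chr1") {
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  seq_length <- check_count(seq_length, "seq_length", min = 1L)
  if (!is.numeric(theta_per_site) || theta_per_site < 0) {
    hetrv_stop("'theta_per_site' must be >= 0")
  }
  if (!is.null(seed)) set.seed(seed)

  # coalescent genealogy: each completed branch is (descendant tip set,
  # branch length in coalescent time units)
  lineages <- lapply(seq_len(n_samples), identity) # tip sets
  blen <- numeric(n_samples)                        # open branch lengths
  branch_sets <- list(); branch_len <- numeric(0)
  while (length(lineages) > 1L) {
    k <- length(lineages)
    dt <- stats::rexp(1, rate = k * (k - 1) / 2)
    blen <- blen + dt
    pick <- sample.int(k, 2)
    # close the two coalescing branches
    branch_sets <- c(branch_sets, lineages[pick])
    branch_len <- c(branch_len, blen[pick])
    merged <- sort(c(lineages[[pick[1]]], lineages[[pick[2]]]))
    lineages <- c(lineages[-pick], list(merged))
    blen <- c(blen[-pick], 0)
  }

  # Poisson mutations per branch: rate theta/2 per site per unit time
  mu <- theta_per_site * seq_length / 2
  n_mut <- stats::rpois(length(branch_len), branch_len * mu)
  total <- sum(n_mut)
  if (total == 0L) {
    return(variant_matrix(character(0), integer(0),
                          matrix(integer(0), 0, n_samples,
                                 dimnames = list(NULL,
                                                 paste0("sample",
                                                        seq_len(n_samples)))),
                          chrom_lengths = stats::setNames(seq_length, chrom)))
  }
  if (total > seq_length) {
    hetrv_stop("more mutations than sites; infinite-sites assumption broken ",
               "(decrease theta_per_site or increase seq_length)")
  }
  pos <- sort(sample.int(seq_length, total))
  carriers <- rep(seq_along(n_mut), n_mut)[sample.int(total)] # shuffle branches
  geno <- matrix(0L, total, n_samples,
                 dimnames = list(NULL, paste0("sample", seq_len(n_samples))))
  for (i in seq_len(total)) {
    geno[i, branch_sets[[carriers[i]]]] <- 1L
  }
  variant_matrix(rep(chrom, total), pos, geno,
                 chrom_lengths = stats::setNames(seq_length, chrom))
}

#' Two-group SNP matrix with planted divergence islands
#'
#' Emulates a population split into two reproductively isolated groups:
#' background SNPs are drawn from the neutral frequency spectrum
#' independently of group membership, one island carries fixed differences
#' between the groups (relative differentiation of 1) and an optional second
#' island is differentiated to approximately a target Fst (Balding-Nichols
#' allele-frequency model).
#'
#' @param n_per_group Integer vector of length 2: haploid samples per group.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param background_diversity Expected per-site pairwise diversity of the
#'   background (default 5e-4).
#' @param island_chrom,island_span Chromosome and c(start, end) of the fully
#'   differentiated island.
#' @param island_n_sites Number of fixed-difference sites planted in the
#'   island.
#' @param island2_chrom,island2_span,island2_fst_target Optional second,
#'   weakly differentiated island and its target Fst in [0, 1].
#' @param island2_n_sites Number of sites in the second island.
#' @param seed Optional seed.
#' @return List with \code{vm} (a \code{variant_matrix}; group-1 samples are
#'   named g1_*, group-2 samples g2_*) and \code{labels}, the named truth
#'   vector of group memberships.
#' @export
generate_two_group_snps <- function(n_per_group, chrom_lengths,
                                    background_diversity = 5e-4,
                                    island_chrom, island_span,
                                    island_n_sites = 200,
                                    island2_chrom = NULL, island2_span = NULL,
                                    island2_fst_target = 0.5,
                                    island2_n_sites = 100,
                                    seed = NULL) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 2))
  if (is.null(names(chrom_lengths))) {
    hetrv_stop("'chrom_lengths' must be a named vector")
  }
  check_span <- function(ch, span, what) {
    if (!ch %in% names(chrom_lengths)) {
      hetrv_stop(what, " chromosome not in 'chrom_lengths'")
    }
    if (span[1] < 1 || span[2] > chrom_lengths[[ch]] || span[1] > span[2]) {
      hetrv_stop(what, " span must lie within its chromosome")
    }
  }
  check_span(island_chrom, island_span, "island")
  if (!is.null(island2_chrom)) {
    check_span(island2_chrom, island2_span, "island2")
    check_prob(island2_fst_target, "island2_fst_target")
  }
  if (!is.null(seed)) set.seed(seed)
  n1 <- n_per_group[1]; n2 <- n_per_group[2]; n <- n1 + n2
  samples <- c(paste0("g1_", seq_len(n1)), paste0("g2_", seq_len(n2)))
  labels <- stats::setNames(rep(c("group1", "group2"), c(n1, n2)), samples)
  an <- watterson_a(n)

  chroms <- character(0); pos <- integer(0); rows <- list()
  add_site <- function(ch, p, g) {
    chroms <<- c(chroms, ch); pos <<- c(pos, p)
    rows[[length(rows) + 1L]] <<- g
  }
  in_island <- function(ch, p, ich, ispan) {
    if (is.null(ich) || ch != ich) return(rep(FALSE, length(p)))
    p >= ispan[1] & p <= ispan[2]
  }

  # background: S = theta * L * a_n sites per chromosome, derived counts
  # from the neutral spectrum P(i) proportional to 1/i, carriers random
  sfs_p <- (1 / seq_len(n - 1)) / an
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    s_bg <- stats::rpois(1, background_diversity * L * an)
    if (s_bg == 0) next
    p_bg <- sample.int(L, s_bg)
    # keep background out of the islands so island windows stay clean
    drop <- in_island(ch, p_bg, island_chrom, island_span) |
      in_island(ch, p_bg, island2_chrom, island2_span)
    p_bg <- p_bg[!drop]
    for (p in p_bg) {
      i <- sample.int(n - 1, 1, prob = sfs_p)
      g <- integer(n); g[sample.int(n, i)] <- 1L
      add_site(ch, p, g)
    }
  }

  # island: fixed differences between the groups
  p_isl <- sample(seq(island_span[1], island_span[2]), island_n_sites)
  for (p in p_isl) {
    g <- c(rep(0L, n1), rep(1L, n2))
    add_site(island_chrom, p, g)
  }

  # island2: Balding-Nichols differentiation towards the target Fst
  if (!is.null(island2_chrom)) {
    FST <- island2_fst_target
    p_isl2 <- sample(seq(island2_span[1], island2_span[2]), island2_n_sites)
    for (p in p_isl2) {
      repeat {
        anc <- stats::runif(1, 0.2, 0.8)
        pg <- if (FST == 0) c(anc, anc) else if (FST == 1) {
          stats::rbinom(2, 1, anc)
        } else {
          stats::rbeta(2, anc * (1 - FST) / FST, (1 - anc) * (1 - FST) / FST)
        }
        g <- c(stats::rbinom(n1, 1, pg[1]), stats::rbinom(n2, 1, pg[2]))
        if (sum(g) > 0 && sum(g) < n) break
      }
      add_site(island2_chrom, p, as.integer(g))
    }
  }

  geno <- do.call(rbind, rows)
  colnames(geno) <- samples
  # drop accidental duplicate positions within a chromosome
  key <- paste(chroms, pos)
  keep <- !duplicated(key)
  vm <- variant_matrix(chroms[keep], pos[keep], geno[keep, , drop = FALSE],
                       chrom_lengths = chrom_lengths)
  list(vm = vm, labels = labels)
}

#' Per-sample coverage tracks with depth artifacts
#'
#' Draws per-site sequencing depth for each sample. With
#' \code{dispersion = 0} the depth is deterministic at \code{mean_depth};
#' otherwise depth is negative-binomial with variance
#' \code{mu + dispersion * mu^2}. Artifact regions scale the local mean
#' depth (e.g. a 10x multiplier mimics collapsed repeats), which is what
#' the downstream coverage-quantile masking is designed to catch.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_samples Number of samples.
#' @param mean_depth Mean depth of coverage (> 0).
#' @param dispersion Overdispersion parameter (>= 0); 0 = constant depth.
#' @param artifact_regions Optional data frame with columns chrom, start,
#'   end (1-based inclusive) and multiplier.
#' @param seed Optional seed.
#' @return A list (class \code{coverage_track}) with one integer matrix
#'   (positions x samples) per chromosome.
#' @export
generate_coverage <- function(chrom_lengths, n_samples, mean_depth = 80,
                              dispersion = 0.05, artifact_regions = NULL,
                              seed = NULL) {
  if (mean_depth <= 0) hetrv_stop("'mean_depth' must be > 0")
  if (dispersion < 0) hetrv_stop("'dispersion' must be >= 0")
  n_samples <- check_count(n_samples, "n_samples")
  if (!is.null(artifact_regions)) {
    need <- c("chrom", "start", "end", "multiplier")
    if (!all(need %in% names(artifact_regions))) {
      hetrv_stop("'artifact_regions' needs columns ",
                 paste(need, collapse = ", "))
    }
    if (any(artifact_regions$start > artifact_regions$end) ||
        any(artifact_regions$start < 1)) {
      hetrv_stop("invalid artifact intervals")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    mu <- rep(mean_depth, L)
    if (!is.null(artifact_regions)) {
      art <- artifact_regions[artifact_regions$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(art))) {
        idx <- art$start[i]:min(art$end[i], L)
        mu[idx] <- mu[idx] * art$multiplier[i]
      }
    }
    if (dispersion == 0) {
      m <- matrix(rep(round(mu), n_samples), ncol = n_samples)
    } else {
      m <- matrix(stats::rnbinom(L * n_samples, size = 1 / dispersion,
                                 mu = rep(mu, n_samples)),
                  ncol = n_samples)
    }
    colnames(m) <- paste0("sample", seq_len(n_samples))
    out[[ch]] <- m
  }
  structure(out, class = "coverage_track", mean_depth = mean_depth)
}

#' Block-structured mating-outcome matrix
#'
#' Emulates the pairwise crossing outcomes of two reproductively isolated
#' groups: within-group crosses yield mature fruiting bodies on both
#' partners (code 1) while between-group crosses show the sterility codes
#' 4-6, with an optional fraction of cells re-drawn uniformly from 1-6 to
#' mimic scoring noise. The matrix need not be symmetric; the diagonal is
#' NA (no self-cross is recorded).
#'
#' @param group_labels Named vector (or plain vector) of group labels, one
#'   per strain; at least two groups with >= 2 strains each.
#' @param noise_rate Fraction of off-diagonal cells re-drawn uniformly from
#'   codes 1-6; in [0, 0.5).
#' @param seed Optional seed.
#' @return An integer strains x strains matrix of codes 1-6 with NA
#'   diagonal.
#' @export
generate_mating_matrix <- function(group_labels, noise_rate = 0,
                                   seed = NULL) {
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate >= 0.5) {
    hetrv_stop("'noise_rate' must lie in [0, 0.5)")
  }
  labs <- as.character(group_labels)
  tab <- table(labs)
  if (length(tab) < 2) {
    hetrv_stop("degenerate input: need at least two groups of strains")
  }
  if (any(tab < 2)) hetrv_stop("need >= 2 strains per group")
  if (!is.null(seed)) set.seed(seed)
  n <- length(labs)
  ids <- names(group_labels)
  if (is.null(ids)) ids <- paste0("strain", seq_len(n))
  m <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      m[i, j] <- if (labs[i] == labs[j]) 1L else
        sample(4:6, 1)
    }
  }
  if (noise_rate > 0) {
    off <- which(row(m) != col(m))
    redraw <- off[stats::runif(length(off)) < noise_rate]
    m[redraw] <- sample(1:6, length(redraw), replace = TRUE)
  }
  m
}

#' Synthetic strain genotype table
#'
#' Builds a strain-level table (strain, year, substrate, het_r, het_v) in
#' which the het-r and het-v alleles are strongly associated within two
#' groups, with a small rate of recombinant rV1 strains, mimicking a
#' natural collection of two reproductively isolated groups. Entirely
#' synthetic; used to exercise the genotype utilities.
#'
#' @param n_strains Number of strains.
#' @param years Range of collection years to sample from.
#' @param p_group1 Probability a strain belongs to the rV group.
#' @param recombinant_rate Probability an RV1-group strain is instead the
#'   recombinant rV1.
#' @param substrates Substrate categories to sample from.
#' @param seed Optional seed.
#' @return Data frame with columns strain, year, substrate, het_r, het_v.
#' @export
generate_strain_table <- function(n_strains = 100, years = 1991:2016,
                                  p_group1 = 0.5, recombinant_rate = 0.03,
                                  substrates = c("horse", "rabbit"),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grp1 <- stats::runif(n_strains) < p_group1
  het_r <- ifelse(grp1, "r", "R")
  het_v <- ifelse(grp1, "V", "V1")
  rec <- !grp1 & stats::runif(n_strains) < recombinant_rate
  het_r[rec] <- "r" # rV1 recombinants
  data.frame(
    strain = sprintf("Wa%03d", seq_len(n_strains)),
    year = sample(years, n_strains, replace = TRUE),
    substrate = sample(substrates, n_strains, replace = TRUE),
    het_r = het_r,
    het_v = het_v,
    stringsAsFactors = FALSE
  )
}
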