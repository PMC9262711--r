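# Clustering of pairwise mating outcomes: 6-level coding of cross success,
# Gower dissimilarity between strains, partitioning-around-medoids (PAM,
# BUILD + SWAP), cluster-count selection by average silhouette width and the
# gap statistic, principal coordinates embedding, and concordance of the
# mating clusters with genotype-derived group labels.

MATING_CATEGORIES <- c("mature", "perithecial_abortion", "none")

#' Code raw cross observations into the 6-level mating-outcome scheme
#'
#' Each cross records, for the two mating partners, whether mature fruiting
#' bodies were produced (with or without ascospore abortion), whether
#' perithecial abortion was observed, or whether no perithecia formed.
#' The pair of per-partner categories maps onto codes 1-6:
#' mature/mature = 1, mature/abortion = 2, mature/none = 3,
#' abortion/abortion = 4, abortion/none = 5, none/none = 6.
#'
#' @param side1,side2 Character matrices (or vectors) of per-partner
#'   categories, entries in c("mature", "perithecial_abortion", "none");
#'   NA cells are propagated.
#' @return Integer matrix (or vector) of codes 1-6.
#' @export
code_matings <- function(side1, side2) {
  s1 <- as.vector(side1); s2 <- as.vector(side2)
  if (length(s1) != length(s2)) hetrv_stop("the two sides must match in shape")
  ok <- is.na(s1) | s1 %in% MATING_CATEGORIES
  ok2 <- is.na(s2) | s2 %in% MATING_CATEGORIES
  if (!all(ok & ok2)) {
    bad <- which(!(ok & ok2))
    hetrv_stop("unrecognised observation category in cell(s) ",
               paste(utils::head(bad, 5), collapse = ", "),
               "; expected one of: ", paste(MATING_CATEGORIES, collapse = ", "))
  }
  i1 <- match(s1, MATING_CATEGORIES)
  i2 <- match(s2, MATING_CATEGORIES)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  # (1,1)->1 (1,2)->2 (1,3)->3 (2,2)->4 (2,3)->5 (3,3)->6
  code <- ifelse(lo == 1, hi, ifelse(lo == 2, hi + 2L, 6L))
  if (is.matrix(side1)) {
    code <- matrix(as.integer(code), nrow(side1), ncol(side1),
                   dimnames = dimnames(side1))
  } else {
    code <- as.integer(code)
  }
  code
}

#' Gower dissimilarity between strains from a mating-outcome matrix
#'
#' Treats each strain (row) as an observation whose variables are its
#' outcome codes against every partner (the columns). Codes are handled as
#' interval-scaled by default: the per-variable contribution is
#' |x_i - x_j| / range, averaged over the variables both strains share
#' (pairwise deletion of missing cells). The diagonal is ignored. An
#' ordinal option rank-transforms each column first, and a symmetrize
#' option averages each cell with its transpose before computing distances.
#'
#' @param m Integer matrix of codes 1-6 (possibly non-symmetric, NA
#'   allowed).
#' @param ordinal Rank-transform columns before range normalisation.
#' @param symmetrize Average the matrix with its transpose first.
#' @param max_missing Strains missing more than this fraction of cells are
#'   dropped with a warning (default 0.5).
#' @return A symmetric dissimilarity matrix in [0, 1] with zero diagonal.
#' @export
gower_dissimilarity <- function(m, ordinal = FALSE, symmetrize = FALSE,
                                max_missing = 0.5) {
  m <- as.matrix(m)
  if (nrow(m) < 2) hetrv_stop("need at least two strains")
  if (nrow(m) == ncol(m)) diag(m) <- NA
  if (symmetrize) m <- (m + t(m)) / 2
  frac_miss <- rowMeans(is.na(m))
  # the self-cell is always NA, so allow for it
  drop <- frac_miss > max_missing + 1 / ncol(m)
  if (any(drop)) {
    warning("dropping strains with > ", max_missing * 100,
            "% missing cells: ",
            paste(rownames(m)[drop], collapse = ", "))
    m <- m[!drop, !drop, drop = FALSE]
  }
  x <- m
  if (ordinal) x <- apply(m, 2, rank, na.last = "keep")
  rng <- apply(x, 2, function(v) diff(range(v, na.rm = TRUE)))
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- which(!is.na(x[i, ]) & !is.na(x[j, ]))
      if (!length(shared)) {
        hetrv_stop("strains ", rownames(m)[i], " and ", rownames(m)[j],
                   " share no scored partner")
      }
      contrib <- abs(x[i, shared] - x[j, shared])
      r <- rng[shared]
      contrib <- ifelse(r > 0, contrib / r, 0)
      d[i, j] <- d[j, i] <- mean(contrib)
    }
  }
  d
}

#' Partitioning around medoids (BUILD + SWAP)
#'
#' Classical PAM: the BUILD phase seeds k medoids greedily (first the point
#' minimising total dissimilarity, then the point giving the largest cost
#' reduction), and the SWAP phase repeatedly applies the best
#' cost-reducing medoid/non-medoid exchange until none improves. Ties are
#' broken towards the lowest index, so the result is deterministic.
#'
#' @param d Symmetric dissimilarity matrix or \code{dist}.
#' @param k Number of clusters, 2 <= k < n (k = 1 is allowed for internal
#'   use by the gap statistic).
#' @return List with \code{medoids} (indices), \code{labels} (nearest
#'   medoid, 1..k), \code{cost} (total dissimilarity to assigned medoids)
#'   and \code{k}.
#' @export
pam_cluster <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 1 || k >= n) hetrv_stop("'k' must satisfy 1 <= k < n")
  cost_of <- function(med) sum(apply(d[, med, drop = FALSE], 1, min))
  # BUILD
  med <- which.min(rowSums(d))
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    costs <- vapply(cand, function(c2) cost_of(c(med, c2)), numeric(1))
    med <- c(med, cand[which.min(costs)])
  }
  cur <- cost_of(med)
  # SWAP
  repeat {
    best <- NULL; best_cost <- cur
    for (mi in seq_along(med)) {
      for (h in setdiff(seq_len(n), med)) {
        trial <- med; trial[mi] <- h
        cc <- cost_of(trial)
        if (cc < best_cost - 1e-12) {
          best_cost <- cc; best <- trial
        }
      }
    }
    if (is.null(best)) break
    med <- best; cur <- best_cost
  }
  med <- sort(med)
  labels <- apply(d[, med, drop = FALSE], 1, which.min)
  names(labels) <- rownames(d)
  list(medoids = med, labels = labels, cost = cur, k = k)
}

#' Average silhouette width of a clustering
#'
#' @param d Symmetric dissimilarity matrix.
#' @param labels Integer cluster labels.
#' @return List with \code{widths} (per point) and \code{average}.
#'   Points in singleton clusters get width 0.
#' @export
silhouette_width <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  ks <- sort(unique(labels))
  if (length(ks) < 2) hetrv_stop("silhouette undefined for a single cluster")
  w <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { w[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(ks[ks != labels[i]], function(kk)
      mean(d[i, labels == kk]), numeric(1)))
    w[i] <- (b - a) / max(a, b)
  }
  list(widths = w, average = mean(w))
}

#' Choose the number of clusters by silhouette and gap statistic
#'
#' Runs PAM for k = 2..k_max and reports (i) the k maximising the average
#' silhouette width and (ii) the gap-statistic choice: the within-cluster
#' dispersion W_k (sum over clusters of pairwise squared dissimilarities
#' divided by twice the cluster size) is compared with its expectation over
#' \code{B_ref} reference data sets drawn uniformly over each variable's
#' observed range, and the smallest k with
#' gap(k) >= gap(k+1) - se(k+1) is selected (one-standard-error rule,
#' k = 1 included). The silhouette choice is the authoritative label for
#' the pipeline.
#'
#' @param d Symmetric dissimilarity matrix of the strains.
#' @param coded Coded observation matrix (strains x variables) used to build
#'   the uniform reference sets for the gap statistic.
#' @param k_max Largest k considered (must be <= n - 1).
#' @param B_ref Number of reference data sets (default 100).
#' @param seed Optional seed for the reference draws.
#' @return List with \code{k} (chosen, silhouette rule), \code{k_silhouette},
#'   \code{k_gap}, \code{avg_silhouette} (k = 2..k_max), and \code{gap}
#'   (data frame with k, gap, se).
#' @export
choose_k <- function(d, coded, k_max, B_ref = 100L, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) hetrv_stop("need at least 4 strains to choose k")
  if (k_max > n - 1) hetrv_stop("'k_max' must be <= n - 1")
  sil <- vapply(2:k_max, function(k) {
    cl <- pam_cluster(d, k)
    silhouette_width(d, cl$labels)$average
  }, numeric(1))
  names(sil) <- 2:k_max
  k_sil <- as.integer(names(sil)[which.max(sil)])

  wk <- function(dm, labels) {
    sum(vapply(unique(labels), function(kk) {
      idx <- labels == kk
      sum(dm[idx, idx, drop = FALSE]^2) / (2 * sum(idx))
    }, numeric(1)))
  }
  logW <- function(dm, k) {
    labels <- if (k == 1) rep(1L, nrow(dm)) else pam_cluster(dm, k)$labels
    log(wk(dm, labels))
  }
  if (!is.null(seed)) set.seed(seed)
  coded <- as.matrix(coded)
  if (nrow(coded) == ncol(coded)) diag(coded) <- NA
  rngs <- apply(coded, 2, function(v) range(v, na.rm = TRUE))
  ks <- 1:k_max
  obs_lw <- vapply(ks, function(k) logW(d, k), numeric(1))
  ref_lw <- matrix(NA_real_, B_ref, length(ks))
  for (b in seq_len(B_ref)) {
    ref <- apply(rngs, 2, function(r)
      stats::runif(nrow(coded), r[1], r[2]))
    dref <- gower_dissimilarity(ref)
    ref_lw[b, ] <- vapply(ks, function(k) logW(dref, k), numeric(1))
  }
  gap <- colMeans(ref_lw) - obs_lw
  se <- apply(ref_lw, 2, stats::sd) * sqrt(1 + 1 / B_ref)
  k_gap <- k_max
  for (k in ks[-length(ks)]) {
    if (gap[k] >= gap[k + 1] - se[k + 1]) { k_gap <- k; break }
  }
  list(k = k_sil, k_silhouette = k_sil, k_gap = k_gap,
       avg_silhouette = sil,
       gap = data.frame(k = ks, gap = gap, se = se))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared dissimilarities (-1/2 J D^2 J), performs the
#' eigendecomposition and returns coordinates on the positive-eigenvalue
#' axes scaled by the square root of their eigenvalues. Negative
#' eigenvalues (possible for non-Euclidean dissimilarities) are dropped and
#' reported.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes Number of axes to retain (default: all positive ones).
#' @return Object of class \code{pcoa_embedding}: \code{points} (strains x
#'   axes), \code{eigenvalues} (all), \code{varfrac} (fraction of the
#'   positive-eigenvalue variance per retained axis),
#'   \code{n_negative}.
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    hetrv_stop("asymmetric input; build a symmetric dissimilarity first ",
               "(e.g. with gower_dissimilarity)")
  }
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values) * 1e-12 & eig$values > 0)
  if (!length(pos)) {
    pts <- matrix(0, n, 1, dimnames = list(rownames(d), "Axis1"))
    return(structure(list(points = pts, eigenvalues = eig$values,
                          varfrac = 1, n_negative = sum(eig$values < 0)),
                     class = "pcoa_embedding"))
  }
  if (!is.null(n_axes)) pos <- pos[seq_len(min(n_axes, length(pos)))]
  pts <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), length(pos))
  dimnames(pts) <- list(rownames(d), paste0("Axis", seq_along(pos)))
  structure(list(points = pts, eigenvalues = eig$values,
                 varfrac = eig$values[pos] / sum(pmax(eig$values, 0)),
                 n_negative = sum(eig$values < -max(eig$values) * 1e-12)),
            class = "pcoa_embedding")
}

#' @export
print.pcoa_embedding <- function(x, ...) {
  cat("PCoA embedding:", nrow(x$points), "strains,",
      ncol(x$points), "retained axes\n")
  k <- min(3, length(x$varfrac))
  cat("  variance (positive axes):",
      paste0("Axis", seq_len(k), "=",
             sprintf("%.1f%%", 100 * x$varfrac[seq_len(k)]), collapse = " "),
      "\n")
  if (x$n_negative > 0) cat("  dropped", x$n_negative, "negative eigenvalues\n")
  invisible(x)
}

#' Concordance between two labelings
#'
#' Cross-tabulates two label vectors over their common samples, permutes the
#' labels of the second to maximise the confusion-matrix diagonal, and
#' reports the chance-corrected adjusted Rand index.
#'
#' @param labels_a,labels_b Named label vectors (e.g. mating clusters and
#'   genotype-derived groups).
#' @return List with \code{confusion} (diagonal-maximised), \code{agreement}
#'   (fraction on the diagonal) and \code{ari} (adjusted Rand index).
#' @export
concordance <- function(labels_a, labels_b) {
  common <- intersect(names(labels_a), names(labels_b))
  if (!length(common)) hetrv_stop("no samples shared between the labelings")
  a <- as.character(labels_a[common]); b <- as.character(labels_b[common])
  tab <- table(a, b)
  # adjusted Rand index
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
  nn <- choose(length(common), 2)
  expected <- ai * bj / nn
  ari <- if (isTRUE(all.equal((ai + bj) / 2, expected))) 1 else
    (nij - expected) / ((ai + bj) / 2 - expected)
  # permute columns to maximise the diagonal (label matching)
  k <- min(nrow(tab), ncol(tab))
  if (ncol(tab) <= 6) {
    perms <- permutations_of(seq_len(ncol(tab)))
    diags <- vapply(perms, function(p) {
      tt <- tab[, p, drop = FALSE]
      sum(diag(tt[seq_len(k), seq_len(k), drop = FALSE]))
    }, numeric(1))
    tab <- tab[, perms[[which.max(diags)]], drop = FALSE]
  }
  agreement <- sum(diag(tab[seq_len(k), seq_len(k), drop = FALSE])) /
    length(common)
  list(confusion = tab, agreement = agreement, ari = ari)
}

# internal: all permutations of a small vector
permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}
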