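test_that("window estimators match brute-force oracles on random matrices", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    g <- random_geno(n, sample(20:200, 1), miss = 0.15)
    L <- 10000L
    pos <- sort(sample.int(L, nrow(g)))
    vm <- variant_matrix(rep("c", nrow(g)), pos, g,
                         chrom_lengths = c(c = L))
    idx1 <- 1:floor(n / 2); idx2 <- (floor(n / 2) + 1):n
    groups <- setNames(rep(c("A", "B"), c(length(idx1), length(idx2))),
                       vm$samples)
    ws <- if (length(idx1) >= 2 && length(idx2) >= 2) {
      window_stats(vm, window = L, step = L, min_eff = 1, groups = groups)
    } else {
      window_stats(vm, window = L, step = L, min_eff = 1)
    }
    expect_equal(ws$pi * L, oracle_pi_total(vm$geno), tolerance = 1e-10)
    expect_equal(ws$theta_w * L, oracle_theta_total(vm$geno),
                 tolerance = 1e-10)
    od <- oracle_tajima_d(vm$geno)
    if (!is.na(od)) expect_equal(ws$tajima_d, od, tolerance = 1e-10)
    if (!is.null(ws$fst)) {
      o <- oracle_fst_dxy(vm$geno, idx1, idx2)
      if (!is.na(o$fst)) expect_equal(ws$fst, o$fst, tolerance = 1e-10)
      expect_equal(ws$dxy * L, o$dxy_total, tolerance = 1e-10)
    }
  }
})

test_that("worked single-window examples evaluate exactly", {
  # two samples differing at one site over 10 kb: pi = 1e-4
  vm <- variant_matrix("c", 500L, matrix(c(0L, 1L), 1),
                       chrom_lengths = c(c = 10000))
  ws <- window_stats(vm, window = 10000, step = 10000, min_eff = 1)
  expect_equal(ws$pi, 1e-4)
  expect_equal(ws$theta_w, 1e-4) # n = 2: a_n = 1, thetaW = S / L

  # n = 4, 3 sites, pi_total = 10/6 over L_eff = 100; Tajima's D ~ +0.17
  g <- rbind(c(0, 1, 1, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  vm2 <- variant_matrix(rep("c", 3), c(10L, 20L, 30L), g,
                        chrom_lengths = c(c = 100))
  ws2 <- window_stats(vm2, window = 100, step = 100, min_eff = 1)
  expect_equal(ws2$pi, (10 / 6) / 100, tolerance = 1e-12)
  expect_equal(ws2$theta_w, 3 / (watterson_a(4) * 100), tolerance = 1e-12)
  expect_equal(round(ws2$tajima_d, 2), 0.17)

  # fixed differences: Fst = 1, Dxy = S / L_eff; and a p1=p2=0.5 site
  gf <- rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  vmf <- variant_matrix(rep("c", 2), c(100L, 200L), gf,
                        chrom_lengths = c(c = 1000))
  groups <- setNames(c("A", "A", "B", "B"), vmf$samples)
  wsf <- window_stats(vmf, window = 1000, step = 1000, min_eff = 1,
                      groups = groups)
  expect_equal(wsf$fst, 1)
  expect_equal(wsf$dxy, 2 / 1000)
  gh <- matrix(c(0L, 1L, 0L, 1L), 1)
  vmh <- variant_matrix("c", 100L, gh, chrom_lengths = c(c = 1000))
  wsh <- window_stats(vmh, window = 1000, step = 1000, min_eff = 1,
                      groups = groups)
  expect_equal(wsh$dxy, 0.5e-3)
})

test_that("singleton-heavy data give negative D, balanced data positive D", {
  n <- 20
  singletons <- diag(1L, 10, n) # 10 singleton sites
  vs <- variant_matrix(rep("c", 10), seq(10, 100, 10), singletons,
                       chrom_lengths = c(c = 1000))
  d_neg <- window_stats(vs, window = 1000, step = 1000, min_eff = 1)$tajima_d
  expect_lt(d_neg, 0)
  balanced <- matrix(rep(rep(c(0L, 1L), each = n / 2), 10), 10,
                     byrow = TRUE)
  vb <- variant_matrix(rep("c", 10), seq(10, 100, 10), balanced,
                       chrom_lengths = c(c = 1000))
  d_pos <- window_stats(vb, window = 1000, step = 1000, min_eff = 1)$tajima_d
  expect_gt(d_pos, 0)
})

test_that("coverage-quantile masking follows the all-sample intersection rule", {
  # constant depth: strict quantile inequalities mask nothing
  cov <- generate_coverage(c(c = 400), n_samples = 3, mean_depth = 50,
                           dispersion = 0, seed = 1)
  repeats <- data.frame(chrom = "c", start = 50, end = 100)
  mk <- mask_sites(cov, repeats)
  expect_equal(nrow(mk), 0)

  # a spike in every sample inside a repeat is masked (the spiked region
  # must stay below the 1.5% upper-quantile tail to clear the threshold)
  cov2 <- cov
  cov2$c[60:63, ] <- 500L
  mk2 <- mask_sites(cov2, repeats)
  expect_true(all(60:63 %in% attr(mk2, "positions")$c))
  # ... but the same spike outside the repeat annotation is not
  cov3 <- cov
  cov3$c[200:203, ] <- 500L
  mk3 <- mask_sites(cov3, repeats)
  expect_false(any(200:203 %in% attr(mk3, "positions")$c))
  # normal coverage in one sample breaks the intersection
  cov4 <- cov
  cov4$c[60:63, 1:2] <- 500L
  mk4 <- mask_sites(cov4, repeats)
  expect_false(any(60:63 %in% attr(mk4, "positions")$c))

  expect_error(mask_sites(list(), repeats), "empty")
  expect_error(mask_sites(cov, repeats, low_q = 0), "strictly inside")
})

test_that("masked sites are excluded from both numerator and L_eff", {
  # window of 10 kb with 4 usable variant sites
  g <- matrix(rep(c(0L, 1L), 4 * 2), 4, byrow = TRUE)
  vm <- variant_matrix(rep("c", 4), c(1000L, 2000L, 3000L, 4000L), g,
                       samples = paste0("s", 1:4),
                       chrom_lengths = c(c = 10000))
  base <- window_stats(vm, window = 10000, step = 10000, min_eff = 1)

  # extend the chromosome by 5 kb of fully masked sequence containing two
  # more variant sites: pi and thetaW must not change
  g2 <- rbind(g, matrix(rep(c(0L, 1L), 2 * 2), 2, byrow = TRUE))
  vm2 <- variant_matrix(rep("c", 6),
                        c(1000L, 2000L, 3000L, 4000L, 12000L, 13000L), g2,
                        samples = paste0("s", 1:4),
                        chrom_lengths = c(c = 15000))
  mask <- callability_mask(data.frame(chrom = "c", start = 10001,
                                      end = 15000))
  ext <- window_stats(vm2, mask = mask, window = 15000, step = 15000,
                      min_eff = 1)
  expect_equal(ext$l_eff, 10000)
  expect_equal(ext$pi, base$pi)
  expect_equal(ext$theta_w, base$theta_w)

  # all sites masked: window missing
  mask_all <- callability_mask(data.frame(chrom = "c", start = 1,
                                          end = 15000))
  allm <- window_stats(vm2, mask = mask_all, window = 15000, step = 15000,
                       min_eff = 5000)
  expect_true(is.na(allm$pi))
  expect_equal(allm$l_eff, 0)
})

test_that("windows below the minimum effective length are reported missing", {
  g <- matrix(rep(c(0L, 1L), 3 * 2), 3, byrow = TRUE)
  vm <- variant_matrix(rep("c", 3), c(100L, 200L, 300L), g,
                       chrom_lengths = c(c = 10000))
  mask <- callability_mask(data.frame(chrom = "c", start = 1, end = 5500))
  ws <- window_stats(vm, mask = mask, window = 10000, step = 10000,
                     min_eff = 5000)
  expect_equal(ws$l_eff, 4500)
  expect_true(is.na(ws$pi) && is.na(ws$theta_w) && is.na(ws$tajima_d))
})

test_that("window tiling covers interior positions ten times at 10kb/1kb", {
  vm <- variant_matrix("c", 15000L, matrix(c(0L, 1L), 1),
                       chrom_lengths = c(c = 50000))
  ws <- window_stats(vm, window = 10000, step = 1000, min_eff = 1)
  for (p in c(15000, 25000, 30500)) {
    covering <- sum(ws$start <= p & ws$end >= p)
    expect_equal(covering, 10)
  }
  expect_equal(ws$start[1], 1)
})

test_that("Fst permutation null gives p = 1/(n_perm+1) on a planted island", {
  g <- generate_two_group_snps(c(8, 8), c(chr1 = 60000), 5e-4, "chr1",
                               c(20001, 30000), island_n_sites = 60,
                               seed = 14)
  ws <- window_stats(g$vm, window = 10000, step = 10000, min_eff = 1,
                     groups = g$labels, n_perm = 200, seed = 3)
  island <- which(ws$start == 20001)
  expect_equal(ws$fst[island], 1)
  expect_equal(ws$p_perm[island], 1 / 201)
  expect_error(window_stats(g$vm, window = 10000, step = 10000,
                            groups = g$labels, n_perm = -1), ">= 0")
})

test_that("PCA separates planted groups on the island chromosome only", {
  g <- generate_two_group_snps(c(12, 12), c(chr1 = 2e5, chr2 = 2e5), 5e-4,
                               island_chrom = "chr2",
                               island_span = c(50001, 100000),
                               island_n_sites = 150, seed = 2)
  pc_island <- pca_snps(g$vm, chrom = "chr2")
  s <- sign(pc_island$scores[, 1])
  expect_true(all(s[g$labels == "group1"] == s[g$labels == "group1"][1]))
  expect_true(all(s[g$labels == "group2"] == -s[g$labels == "group1"][1]))
  # background chromosome: PC1 uncorrelated with the truth
  pc_bg <- pca_snps(g$vm, chrom = "chr1")
  truth <- as.integer(g$labels == "group1")
  expect_lt(abs(cor(pc_bg$scores[, 1], truth)), 0.6)
  # duplicate samples score identically
  vm <- g$vm
  vm$geno[, 2] <- vm$geno[, 1]
  pc_dup <- pca_snps(vm, chrom = "chr2")
  expect_equal(pc_dup$scores[1, ], pc_dup$scores[2, ], tolerance = 1e-9)
  expect_error(pca_snps(g$vm, maf_min = 0.6), "no sites")
})

test_that("RI assignment from PC1 is anchored, sign-invariant and leaves the boundary unassigned", {
  pc1 <- setNames(c(-3, -2.5, -2, 2, 2.5, 3, 0), paste0("s", 1:7))
  anchors <- setNames(c("rV-group", "RV1-group"), c("s1", "s4"))
  a <- assign_ri_from_pc1(pc1, anchors)
  expect_equal(a$label[a$sample %in% paste0("s", 1:3)], rep("rV-group", 3))
  expect_equal(a$label[a$sample %in% paste0("s", 4:6)], rep("RV1-group", 3))
  expect_equal(a$label[a$sample == "s7"], "unassigned")
  # flipping the axis flips nothing because anchors re-orient it
  a2 <- assign_ri_from_pc1(-pc1, anchors)
  expect_identical(a$label, a2$label)
  expect_error(assign_ri_from_pc1(pc1, setNames("rV-group", "s1")),
               "two labels")
})
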