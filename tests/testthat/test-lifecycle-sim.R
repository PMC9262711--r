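test_that("vegetative incompatibility follows the allelic and non-allelic rules", {
  v <- vegetative_incompatible("rV", "RV1")
  expect_true(v$incompatible)
  expect_setequal(v$systems, c("allelic", "nonallelic"))

  expect_false(vegetative_incompatible("rV", "rV")$incompatible)
  # different het-r alleles alone do not trigger a barrage
  expect_false(vegetative_incompatible("rV1", "RV1")$incompatible)
  # het-v difference alone triggers only the allelic system
  v2 <- vegetative_incompatible("rV", "rV1")
  expect_identical(v2$systems, "allelic")
  # symmetry
  expect_identical(vegetative_incompatible("RV1", "rV")$systems,
                   vegetative_incompatible("rV", "RV1")$systems)
  expect_error(vegetative_incompatible("RV", "rV"), "lethal")
})

test_that("NFDS fitness equals 1 + b * frequency of incompatible partners", {
  p <- sim_params(b_nonallelic = 0.5, b_allelic = 0.5)
  st <- population_state(c(rV = 990, RV1 = 10))
  w <- nfds_fitness(st, p)
  expect_equal(unname(w["RV1"]), 1 + 0.5 * 0.99 + 0.5 * 0.99)
  expect_equal(unname(w["rV"]), 1 + 0.5 * 0.01 + 0.5 * 0.01)
  # monomorphic population: no incompatible partners
  mono <- population_state(c(rV = 100))
  expect_equal(unname(nfds_fitness(mono, p)["rV"]), 1)
  # neutral model
  p0 <- sim_params(b_nonallelic = 0, b_allelic = 0)
  expect_equal(unname(nfds_fitness(st, p0)), c(1, 1, 1))
})

test_that("cross offspring distributions match the segregation arithmetic", {
  p <- sim_params()
  # rV x RV1: 1/4 each raw, RV dies, renormalised to 1/3
  cr <- cross_offspring_distribution("rV", "RV1", p)
  expect_equal(cr$success, 1)
  expect_equal(unname(cr$offspring), rep(1 / 3, 3))
  expect_equal(cr$viable_fraction, 3 / 4)
  # selfing reproduces the parent
  s <- cross_offspring_distribution("rV", "rV", p, selfing = TRUE)
  expect_equal(unname(s$offspring["rV"]), 1)
  expect_equal(s$success, 1)
  # rV x rV1: only het-v segregates, allelic system triggered
  p8 <- sim_params(iota_allelic = 0.8)
  cr2 <- cross_offspring_distribution("rV", "rV1", p8)
  expect_equal(cr2$success, 0.2)
  expect_equal(unname(cr2$offspring[c("rV", "rV1")]), c(0.5, 0.5))
  expect_equal(cr2$viable_fraction, 1)
  expect_error(cross_offspring_distribution("RV", "rV", p), "lethal")
})

test_that("one-generation law matches brute-force enumeration at small N", {
  cases <- list(
    list(counts = c(rV = 3, RV1 = 2, rV1 = 1), sigma = 0.3,
         b_na = 0.5, b_a = 0.2, i_na = 0.4, i_a = 0.1),
    list(counts = c(rV = 4, RV1 = 2), sigma = 0, b_na = 0.5, b_a = 0,
         i_na = 0, i_a = 0),
    list(counts = c(rV = 2, RV1 = 2, rV1 = 2), sigma = 0.9, b_na = 0,
         b_a = 0.5, i_na = 0.9, i_a = 0.9)
  )
  for (cs in cases) {
    p <- sim_params(pop_size = sum(cs$counts), selfing = cs$sigma,
                    b_nonallelic = cs$b_na, b_allelic = cs$b_a,
                    iota_nonallelic = cs$i_na, iota_allelic = cs$i_a)
    st <- population_state(cs$counts)
    q <- hetrv:::offspring_law(st, p)
    cn <- st$counts[st$counts > 0]
    qo <- oracle_offspring_law(cn, cs$sigma, cs$b_na, cs$b_a,
                               cs$i_na, cs$i_a)
    expect_equal(unname(q[names(qo)]), unname(qo), tolerance = 1e-12)
    expect_equal(sum(q), 1)
  }
})

test_that("empirical next-generation draws match the exact law (chi-square)", {
  p <- sim_params(pop_size = 6, selfing = 0.4, b_nonallelic = 0.5,
                  b_allelic = 0.3, iota_nonallelic = 0.5, iota_allelic = 0.2)
  st <- population_state(c(rV = 3, RV1 = 2, rV1 = 1))
  q <- hetrv:::offspring_law(st, p)
  set.seed(42)
  draws <- 20000L
  tot <- c(rV = 0, RV1 = 0, rV1 = 0)
  for (i in seq_len(draws)) {
    tot <- tot + next_generation(st, p)$counts
  }
  obs <- tot # 6 * draws offspring, multinomial with probabilities q
  chi <- sum((obs - 6 * draws * q)^2 / (6 * draws * q))
  # individual offspring are iid given the state, so the aggregate counts
  # are multinomial and the statistic is ~ chi-square with 2 df
  expect_lt(chi, qchisq(0.999, df = 2))
})

test_that("population size is conserved and RV never appears", {
  p <- sim_params(pop_size = 200, selfing = 0.5, b_nonallelic = 0.5,
                  b_allelic = 0.5)
  set.seed(9)
  st <- population_state(c(rV = 150, RV1 = 40, rV1 = 10))
  for (g in 1:50) {
    st <- next_generation(st, p)
    expect_identical(sum(st$counts), 200L)
    expect_named(st$counts, c("rV", "RV1", "rV1"))
  }
  expect_error(population_state(c(rV = 10, RV = 1)), "lethal|exist")
})

test_that("deterministic limits of next_generation hold", {
  # b = 0, selfing = 0, iota = 0, monomorphic: state unchanged
  p <- sim_params(pop_size = 50, selfing = 0, b_nonallelic = 0,
                  b_allelic = 0)
  st <- population_state(c(rV = 50))
  set.seed(1)
  expect_identical(next_generation(st, p)$counts, st$counts)
  # selfing-only limit: law is proportional to count * fitness
  p1 <- sim_params(pop_size = 100, selfing = 1, b_nonallelic = 0.5,
                   b_allelic = 0.5)
  st1 <- population_state(c(rV = 70, RV1 = 30))
  q <- hetrv:::offspring_law(st1, p1)
  w <- nfds_fitness(st1, p1)
  expect_equal(unname(q), unname(st1$counts * w / sum(st1$counts * w)))
})

test_that("neutral drift: invader genotype fixes at its initial frequency", {
  # resident rV, invader rV1: no lethal RV can form, so with b = 0 and
  # iota = 0 the offspring law is exactly Wright-Fisher and the fixation
  # probability equals f0
  p <- sim_params(pop_size = 60, generations = 800, selfing = 0.5,
                  b_nonallelic = 0, b_allelic = 0, resident = "rV",
                  invader = "rV1", f0 = 0.1, replicates = 400, seed = 21)
  sim <- run_invasion(p, keep_trajectories = FALSE)
  expect_true(all(sim$outcome != "polymorphic")) # absorbed
  prop_fixed <- mean(sim$outcome == "fixed")
  se <- sqrt(0.1 * 0.9 / 400)
  expect_lt(abs(prop_fixed - 0.1), 3 * se)
  # and the mean final frequency is a martingale limit at f0
  expect_lt(abs(mean(sim$final[, "rV1"]) - 0.1), 3 * se)
})

test_that("invasion probability increases with selfing (paired seeds)", {
  inv <- function(sigma) {
    p <- sim_params(pop_size = 400, generations = 250, selfing = sigma,
                    b_nonallelic = 0.5, b_allelic = 0, resident = "RV1",
                    invader = "rV", f0 = 0.05, replicates = 25, seed = 77)
    mean(run_invasion(p, keep_trajectories = FALSE)$final[, "rV"])
  }
  freqs <- vapply(c(0, 0.5, 0.9), inv, numeric(1))
  expect_true(all(diff(freqs) >= 0))
  expect_gt(freqs[3], freqs[1])
})

test_that("run_invasion records trajectories with frequencies summing to 1", {
  p <- sim_params(pop_size = 100, generations = 30, selfing = 0.9,
                  b_nonallelic = 0.5, b_allelic = 0.5, replicates = 5,
                  seed = 4)
  sim <- run_invasion(p)
  expect_equal(dim(sim$trajectories), c(5, 31, 3))
  sums <- apply(sim$trajectories, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # reproducibility under the same master seed
  sim2 <- run_invasion(p)
  expect_identical(sim$final, sim2$final)
})

test_that("parameter_sweep returns a tidy, reproducible table", {
  base <- sim_params(pop_size = 100, generations = 20, replicates = 10)
  grid <- expand.grid(selfing = c(0, 0.9), b_allelic = c(0, 0.5))
  sw <- parameter_sweep(grid, base, seed = 5)
  expect_equal(nrow(sw$results), 4 * 10 * 3) # combos x reps x genotypes
  expect_setequal(unique(sw$results$genotype), c("rV", "RV1", "rV1"))
  sw2 <- parameter_sweep(grid, base, seed = 5)
  expect_identical(sw$results, sw2$results)
  # single combination gives reps x 3 rows
  sw1 <- parameter_sweep(data.frame(selfing = 0.5), base, seed = 1)
  expect_equal(nrow(sw1$results), 30)
  expect_error(parameter_sweep(data.frame(), base), "non-empty")
  expect_error(parameter_sweep(data.frame(bogus = 1), base), "unknown")
})

test_that("sim_params validates its inputs", {
  expect_error(sim_params(selfing = 1.2), "probability")
  expect_error(sim_params(resident = "rV", invader = "rV"), "differ")
  expect_error(sim_params(resident = "RV"), "lethal")
  expect_error(sim_params(f0 = 0), "strictly")
  expect_error(sim_params(b_nonallelic = -0.1), ">= 0")
})
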