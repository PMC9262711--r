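# Forward-time simulator of the het-r/het-v incompatibility system.
#
# Individuals are haploid with two unlinked biallelic loci: het-r with
# alleles R/r and het-v with alleles V/V1. Two incompatibility systems act:
# the allelic interaction between different het-v alleles (V/V1) and the
# non-allelic interaction between R and V carried by different individuals.
# The combination R+V inside one individual is lethal upon germination, so
# only three genotypes (rV, RV1, rV1) can exist in a population.

VIABLE_GENOTYPES <- c("rV", "RV1", "rV1")
ALL_GENOTYPES <- c("rV", "RV1", "rV1", "RV")

geno_alleles <- function(g) {
  switch(g,
         rV  = c(het_r = "r", het_v = "V"),
         RV1 = c(het_r = "R", het_v = "V1"),
         rV1 = c(het_r = "r", het_v = "V1"),
         RV  = c(het_r = "R", het_v = "V"),
         hetrv_stop("unknown genotype: ", g))
}

#' Construct a two-locus het genotype
#'
#' @param het_r Allele at het-r, "R" or "r".
#' @param het_v Allele at het-v, "V" or "V1".
#' @return A genotype label ("rV", "RV1", "rV1" or "RV"). The RV combination
#'   is constructed (it arises transiently among meiotic products) but is
#'   rejected by every population-level operation, since RV individuals are
#'   self-incompatible and die upon germination.
#' @export
het_genotype <- function(het_r, het_v) {
  if (!het_r %in% c("R", "r")) hetrv_stop("het_r must be 'R' or 'r'")
  if (!het_v %in% c("V", "V1")) hetrv_stop("het_v must be 'V' or 'V1'")
  paste0(het_r, het_v)
}

check_viable <- function(g, what = "genotype") {
  if (!g %in% VIABLE_GENOTYPES) {
    if (g == "RV") hetrv_stop("RV is self-incompatible (lethal); not a valid ",
                              what)
    hetrv_stop("unknown ", what, ": ", g)
  }
  invisible(g)
}

#' Vegetative incompatibility between two genotypes
#'
#' Somatic fusion of two individuals triggers regulated cell death (a
#' barrage) if their het-v alleles differ (allelic V/V1 system) or if one
#' individual carries R while the other carries V (non-allelic R/V system).
#' Different het-r alleles on their own do not trigger incompatibility.
#'
#' @param g1,g2 Viable genotype labels ("rV", "RV1" or "rV1").
#' @return A list with \code{incompatible} (logical) and \code{systems}, the
#'   subset of c("allelic", "nonallelic") that is triggered. Symmetric in
#'   its arguments.
#' @examples
#' vegetative_incompatible("rV", "RV1")  # both systems fire
#' vegetative_incompatible("rV1", "RV1") # compatible
#' @export
vegetative_incompatible <- function(g1, g2) {
  check_viable(g1); check_viable(g2)
  a1 <- geno_alleles(g1); a2 <- geno_alleles(g2)
  systems <- character(0)
  if (a1[["het_v"]] != a2[["het_v"]]) systems <- c(systems, "allelic")
  if ((a1[["het_r"]] == "R" && a2[["het_v"]] == "V") ||
      (a2[["het_r"]] == "R" && a1[["het_v"]] == "V")) {
    systems <- c(systems, "nonallelic")
  }
  list(incompatible = length(systems) > 0L, systems = systems)
}

#' Simulation parameters for the two-locus invasion model
#'
#' @param pop_size Constant population size N.
#' @param generations Number of generations to iterate.
#' @param selfing Probability that an offspring is produced by selfing, in
#'   which case it inherits the maternal genotype unchanged
#'   (pseudohomothallic selfing of a haploid parent).
#' @param b_nonallelic,b_allelic Intensities of negative frequency-dependent
#'   (balancing) selection attached to the non-allelic R/V and allelic V/V1
#'   systems. Fitness of genotype g is
#'   \code{1 + b_nonallelic * x_RV(g) + b_allelic * x_VV1(g)}, where
#'   \code{x_sys(g)} is the current frequency of individuals incompatible
#'   with g under that system (rare-allele advantage from vegetative
#'   interactions).
#' @param iota_nonallelic,iota_allelic Prezygotic isolation: probability
#'   that an outcross fails before zygote formation, per triggered system.
#'   A cross triggering both systems succeeds with probability
#'   \code{(1 - iota_nonallelic) * (1 - iota_allelic)}.
#' @param resident,invader Viable genotype labels; the population starts
#'   monomorphic for \code{resident} except for a fraction \code{f0} of
#'   \code{invader} individuals.
#' @param f0 Initial invader fraction, in (0, 1).
#' @param replicates Number of replicate simulations.
#' @param seed Master seed; per-replicate streams are derived from it.
#' @return A validated list of class \code{sim_params}.
#' @export
sim_params <- function(pop_size = 1000, generations = 500, selfing = 0,
                       b_nonallelic = 0.5, b_allelic = 0,
                       iota_nonallelic = 0, iota_allelic = 0,
                       resident = "RV1", invader = "rV",
                       f0 = 0.05, replicates = 100, seed = NULL) {
  pop_size <- check_count(pop_size, "pop_size", min = 2L)
  generations <- check_count(generations, "generations", min = 1L)
  replicates <- check_count(replicates, "replicates", min = 1L)
  check_prob(selfing, "selfing")
  check_prob(iota_nonallelic, "iota_nonallelic")
  check_prob(iota_allelic, "iota_allelic")
  if (b_nonallelic < 0 || b_allelic < 0) {
    hetrv_stop("balancing-selection intensities must be >= 0")
  }
  check_viable(resident, "resident genotype")
  check_viable(invader, "invader genotype")
  if (resident == invader) hetrv_stop("resident and invader must differ")
  if (!is.numeric(f0) || f0 <= 0 || f0 >= 1) {
    hetrv_stop("'f0' must lie strictly between 0 and 1")
  }
  structure(list(pop_size = pop_size, generations = generations,
                 selfing = selfing, b_nonallelic = b_nonallelic,
                 b_allelic = b_allelic, iota_nonallelic = iota_nonallelic,
                 iota_allelic = iota_allelic, resident = resident,
                 invader = invader, f0 = f0, replicates = replicates,
                 seed = seed),
            class = "sim_params")
}

#' Population state of the simulator
#'
#' @param counts Named non-negative integer vector of genotype counts over
#'   the viable genotypes rV, RV1 and rV1.
#' @param generation Generation index (0 = founding state).
#' @return An object of class \code{population_state}.
#' @export
population_state <- function(counts, generation = 0L) {
  full <- setNames(integer(3), VIABLE_GENOTYPES)
  if (is.null(names(counts))) hetrv_stop("'counts' must be named by genotype")
  if ("RV" %in% names(counts) && counts[["RV"]] > 0) {
    hetrv_stop("RV individuals cannot exist in a post-selection population")
  }
  extra <- setdiff(names(counts), ALL_GENOTYPES)
  if (length(extra)) hetrv_stop("unknown genotypes: ",
                                paste(extra, collapse = ", "))
  common <- intersect(names(counts), VIABLE_GENOTYPES)
  full[common] <- as.integer(counts[common])
  if (any(full < 0)) hetrv_stop("genotype counts must be non-negative")
  if (sum(full) < 1) hetrv_stop("population is empty")
  structure(list(counts = full, generation = as.integer(generation)),
            class = "population_state")
}

# incompatibility indicator matrices over the viable genotypes,
# computed once at load time
.incompat_matrices <- local({
  n <- length(VIABLE_GENOTYPES)
  allelic <- nonallelic <- matrix(0, n, n,
                                  dimnames = list(VIABLE_GENOTYPES,
                                                  VIABLE_GENOTYPES))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- vegetative_incompatible(VIABLE_GENOTYPES[i], VIABLE_GENOTYPES[j])
      allelic[i, j] <- as.numeric("allelic" %in% v$systems)
      nonallelic[i, j] <- as.numeric("nonallelic" %in% v$systems)
    }
  }
  list(allelic = allelic, nonallelic = nonallelic)
})

#' Negative frequency-dependent fitness from vegetative interactions
#'
#' Each genotype gains fitness proportional to the frequency of individuals
#' it is vegetatively incompatible with, per system: rare genotypes meet
#' mostly incompatible partners and are favoured (rare-allele advantage).
#'
#' @param state A \code{population_state}.
#' @param params A \code{sim_params} object.
#' @return Named vector of fitness values (all >= 1) over viable genotypes.
#' @export
nfds_fitness <- function(state, params) {
  counts <- state$counts
  n <- sum(counts)
  if (n < 1) hetrv_stop("empty population")
  freq <- counts / n
  x_allelic <- as.vector(.incompat_matrices$allelic %*% freq)
  x_nonallelic <- as.vector(.incompat_matrices$nonallelic %*% freq)
  w <- 1 + params$b_nonallelic * x_nonallelic + params$b_allelic * x_allelic
  names(w) <- VIABLE_GENOTYPES
  w
}

#' Cross success and offspring genotype distribution
#'
#' An outcross between incompatible parents fails before zygote formation
#' with probability \code{iota_sys} per triggered system. Given success the
#' two unlinked loci segregate independently (each inherited from either
#' parent with probability 1/2); self-incompatible RV products die upon
#' germination and the offspring distribution is renormalised over the
#' viable genotypes. A selfing event (mother acting as its own father)
#' always succeeds and reproduces the parental genotype.
#'
#' @param mother,father Viable genotype labels.
#' @param params A \code{sim_params} object.
#' @param selfing Logical: is this a selfing event?
#' @return List with \code{success} (probability the cross survives the
#'   prezygotic barriers), \code{offspring}, the genotype distribution over
#'   viable offspring, and \code{viable_fraction}, the share of meiotic
#'   products that escape RV germination death (3/4 for a cross segregating
#'   both loci from an rV x RV1 pairing, 1 otherwise). In the life cycle an
#'   inviable germination counts as a failed mating attempt, so a pairing's
#'   realised weight is \code{success * viable_fraction}.
#' @examples
#' cross_offspring_distribution("rV", "RV1", sim_params())
#' @export
cross_offspring_distribution <- function(mother, father, params,
                                         selfing = FALSE) {
  check_viable(mother, "mother"); check_viable(father, "father")
  if (selfing) {
    off <- setNames(numeric(3), VIABLE_GENOTYPES)
    off[mother] <- 1
    return(list(success = 1, offspring = off, viable_fraction = 1))
  }
  trig <- vegetative_incompatible(mother, father)$systems
  success <- 1
  if ("nonallelic" %in% trig) success <- success * (1 - params$iota_nonallelic)
  if ("allelic" %in% trig) success <- success * (1 - params$iota_allelic)
  am <- geno_alleles(mother); af <- geno_alleles(father)
  raw <- setNames(numeric(4), ALL_GENOTYPES)
  for (r_allele in unique(c(am[["het_r"]], af[["het_r"]]))) {
    for (v_allele in unique(c(am[["het_v"]], af[["het_v"]]))) {
      p_r <- mean(c(am[["het_r"]], af[["het_r"]]) == r_allele)
      p_v <- mean(c(am[["het_v"]], af[["het_v"]]) == v_allele)
      g <- paste0(r_allele, v_allele)
      raw[g] <- raw[g] + p_r * p_v
    }
  }
  viable <- raw[VIABLE_GENOTYPES]
  total <- sum(viable)
  if (total <= 0) hetrv_stop("cross yields no viable offspring")
  list(success = success, offspring = viable / total,
       viable_fraction = total)
}

# internal: exact per-offspring genotype law for one generation.
# Mothers are drawn with probability proportional to count * fitness; with
# probability sigma the offspring is a selfing product, otherwise a father
# is drawn the same way (independently, from the whole population). The
# attempt fails, and is redrawn (soft selection), if the cross is stopped
# prezygotically or if the germinating product is the lethal RV class, so a
# pairing's realised weight is success * viable_fraction and the offspring
# distribution is the law conditional on a viable germination.
offspring_law <- function(state, params) {
  w <- nfds_fitness(state, params)
  pm <- state$counts * w
  pm <- pm / sum(pm)
  sigma <- params$selfing
  q <- sigma * pm  # selfing reproduces the maternal genotype
  succ_total <- sigma
  if (sigma < 1) {
    for (m in VIABLE_GENOTYPES) {
      if (pm[[m]] == 0) next
      for (f in VIABLE_GENOTYPES) {
        if (pm[[f]] == 0) next
        cr <- cross_offspring_distribution(m, f, params)
        wgt <- (1 - sigma) * pm[[m]] * pm[[f]] * cr$success *
          cr$viable_fraction
        succ_total <- succ_total + wgt
        q <- q + wgt * cr$offspring
      }
    }
  }
  if (succ_total <= 0) {
    hetrv_stop("sterile population: every possible mating fails ",
               "(selfing = 0 and full prezygotic isolation)")
  }
  q / succ_total
}

#' Advance the population by one generation
#'
#' Samples N offspring from the exact per-offspring law of the life cycle
#' (fitness-weighted mother choice, selfing with probability
#' \code{params$selfing}, fitness-weighted father choice, prezygotic
#' failure with redraw, meiotic segregation and RV inviability). Because
#' individuals are exchangeable within genotype, the N offspring are a
#' multinomial draw from that law; population size is kept constant (soft
#' selection).
#'
#' @param state A \code{population_state}.
#' @param params A \code{sim_params} object.
#' @return The next \code{population_state}, with counts summing to
#'   \code{params$pop_size} and zero RV individuals.
#' @export
next_generation <- function(state, params) {
  q <- offspring_law(state, params)
  counts <- as.integer(stats::rmultinom(1, params$pop_size, q))
  population_state(setNames(counts, VIABLE_GENOTYPES),
                   generation = state$generation + 1L)
}

#' Run replicated invasion simulations
#'
#' Starts each replicate from a population of \code{round(N * f0)} invader
#' individuals and N - round(N * f0) residents, iterates
#' \code{params$generations} generations and records genotype-frequency
#' trajectories and the invasion outcome.
#'
#' @param params A \code{sim_params} object.
#' @param keep_trajectories Record full per-generation trajectories
#'   (set \code{FALSE} to keep only final states when running many
#'   replicates).
#' @return An object of class \code{het_invasion} with elements
#'   \code{params}, \code{trajectories} (replicate x generation x genotype
#'   array of frequencies, or NULL), \code{final} (replicate x genotype
#'   matrix of final frequencies), \code{outcome} (per replicate: "lost",
#'   "polymorphic" or "fixed", judged on the invader genotype) and
#'   \code{seeds}.
#' @export
run_invasion <- function(params, keep_trajectories = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  n_inv <- round(params$pop_size * params$f0)
  if (n_inv < 1 || n_inv >= params$pop_size) {
    hetrv_stop("f0 yields an empty invader or resident class at this N")
  }
  seeds <- spawn_seeds(params$seed, params$replicates)
  G <- params$generations
  reps <- params$replicates
  final <- matrix(NA_real_, reps, 3,
                  dimnames = list(NULL, VIABLE_GENOTYPES))
  traj <- if (keep_trajectories) {
    array(NA_real_, dim = c(reps, G + 1L, 3),
          dimnames = list(NULL, NULL, VIABLE_GENOTYPES))
  } else NULL
  outcome <- character(reps)
  init <- setNames(integer(3), VIABLE_GENOTYPES)
  init[params$resident] <- params$pop_size - n_inv
  init[params$invader] <- n_inv
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    st <- population_state(init, 0L)
    if (keep_trajectories) traj[r, 1L, ] <- st$counts / params$pop_size
    for (g in seq_len(G)) {
      st <- tryCatch(next_generation(st, params), error = function(e) {
        hetrv_stop("replicate ", r, ": ", conditionMessage(e))
      })
      if (keep_trajectories) traj[r, g + 1L, ] <- st$counts / params$pop_size
      if (any(st$counts == params$pop_size)) {
        # monomorphic populations are absorbing (selfing and same-genotype
        # crosses reproduce the parental genotype exactly)
        if (keep_trajectories && g < G) {
          traj[r, (g + 2L):(G + 1L), ] <-
            matrix(st$counts / params$pop_size, G - g, 3, byrow = TRUE)
        }
        break
      }
    }
    final[r, ] <- st$counts / params$pop_size
    fi <- final[r, params$invader]
    outcome[r] <- if (fi == 0) "lost" else if (fi == 1) "fixed" else
      "polymorphic"
  }
  structure(list(params = params, trajectories = traj, final = final,
                 outcome = outcome, seeds = seeds),
            class = "het_invasion")
}

#' @export
print.het_invasion <- function(x, ...) {
  p <- x$params
  cat("het-r/het-v invasion simulation\n")
  cat(sprintf("  N = %d, G = %d, selfing = %.2f, b = (%.2f, %.2f), iota = (%.2f, %.2f)\n",
              p$pop_size, p$generations, p$selfing, p$b_nonallelic,
              p$b_allelic, p$iota_nonallelic, p$iota_allelic))
  cat(sprintf("  %s invading %s at f0 = %.3f, %d replicates\n",
              p$invader, p$resident, p$f0, p$replicates))
  tab <- table(factor(x$outcome, levels = c("lost", "polymorphic", "fixed")))
  cat("  outcomes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.het_invasion <- function(object, ...) {
  qs <- apply(object$final, 2, stats::quantile,
              probs = c(0.25, 0.5, 0.75))
  out <- list(final_quantiles = qs,
              outcome = table(object$outcome),
              mean_final = colMeans(object$final))
  class(out) <- "summary.het_invasion"
  out
}

#' @export
print.summary.het_invasion <- function(x, ...) {
  cat("Final genotype frequencies (quartiles across replicates):\n")
  print(round(x$final_quantiles, 4))
  cat("Mean final frequencies:\n")
  print(round(x$mean_final, 4))
  invisible(x)
}

#' @export
plot.het_invasion <- function(x, genotype = x$params$invader, ...) {
  if (is.null(x$trajectories)) {
    hetrv_stop("trajectories were not recorded; rerun with keep_trajectories = TRUE")
  }
  tr <- x$trajectories[, , genotype, drop = FALSE]
  gens <- seq_len(dim(tr)[2]) - 1L
  graphics::matplot(gens, t(tr[, , 1]), type = "l", lty = 1,
                    col = grDevices::grey(0.4, 0.3),
                    xlab = "generation", ylab = paste("frequency of", genotype),
                    ...)
  invisible(x)
}

#' Sweep the simulator over a parameter grid
#'
#' Runs \code{run_invasion} for every row of a parameter grid (any subset of
#' the \code{sim_params} fields may vary; unlisted fields come from
#' \code{base}) and returns a tidy table of final genotype frequencies, one
#' row per (combination, replicate, genotype), plus per-combination
#' quantile summaries. Deterministic given the master seed.
#'
#' @param grid Data frame whose columns are \code{sim_params} argument names.
#' @param base A \code{sim_params} object supplying fixed parameters.
#' @param seed Master seed for the sweep.
#' @return List with \code{results} (tidy per-replicate table) and
#'   \code{summary} (median and quartiles per combination and genotype).
#' @export
parameter_sweep <- function(grid, base = sim_params(), seed = NULL) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    hetrv_stop("'grid' must be a non-empty data frame of parameter values")
  }
  bad <- setdiff(names(grid), names(base))
  if (length(bad)) hetrv_stop("unknown parameters in grid: ",
                              paste(bad, collapse = ", "))
  combo_seeds <- spawn_seeds(seed, nrow(grid))
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- unclass(base)
    for (nm in names(grid)) args[[nm]] <- grid[[nm]][i]
    args$seed <- combo_seeds[i]
    p <- do.call(sim_params, args)
    sim <- run_invasion(p, keep_trajectories = FALSE)
    res[[i]] <- data.frame(
      combination = i,
      grid[i, , drop = FALSE],
      replicate = rep(seq_len(p$replicates), times = 3),
      genotype = rep(VIABLE_GENOTYPES, each = p$replicates),
      frequency = c(sim$final),
      row.names = NULL
    )
  }
  results <- do.call(rbind, res)
  agg <- stats::aggregate(frequency ~ combination + genotype, results,
                          function(v) c(q25 = unname(stats::quantile(v, 0.25)),
                                        median = stats::median(v),
                                        q75 = unname(stats::quantile(v, 0.75))))
  summary <- cbind(agg[c("combination", "genotype")],
                   as.data.frame(agg$frequency))
  list(results = results, summary = summary)
}
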