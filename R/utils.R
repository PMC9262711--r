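#' Harmonic number used by Watterson's estimator
#'
#' Computes \eqn{a_n = \sum_{i=1}^{n-1} 1/i}, the normalising constant that
#' makes the count of segregating sites an unbiased estimator of the scaled
#' mutation rate for a sample of \code{n} sequences.
#'
#' @param n Number of sampled sequences (>= 2).
#' @return The harmonic sum \eqn{a_n}.
#' @examples
#' watterson_a(4) # 1 + 1/2 + 1/3
#' @export
watterson_a <- function(n) {
  stopifnot(is.numeric(n), n >= 2)
  sum(1 / seq_len(n - 1))
}

# internal: stop with a consistent message prefix
hetrv_stop <- function(...) stop(..., call. = FALSE)

# internal: validate a probability-like scalar
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    hetrv_stop(sprintf("'%s' must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

# internal: validate a positive count
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    hetrv_stop(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# internal: derive independent per-replicate seeds from one master seed.
# Seeds are kept below 2^31 so they remain valid R integers.
spawn_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# internal: minor allele frequency per site from a 0/1/NA genotype matrix
# (sites in rows, samples in columns)
site_maf <- function(geno) {
  p <- rowMeans(geno, na.rm = TRUE)
  pmin(p, 1 - p)
}
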