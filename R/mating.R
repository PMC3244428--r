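# Random mating and admixture. Offspring are produced by Mendelian
# transmission: two distinct parents drawn uniformly, one allele from each
# parent at every SNP independently (transmission probability dosage/2).

draw_parent_pairs <- function(n_pool, n_offspring) {
  pa <- sample.int(n_pool, n_offspring, replace = TRUE)
  pb <- sample.int(n_pool - 1L, n_offspring, replace = TRUE)
  pb <- pb + (pb >= pa)  # second parent distinct from the first
  list(pa = pa, pb = pb)
}

# Internal: one generation of random mating with optional per-individual
# ancestry bookkeeping (offspring ancestry = mean of parental ancestries).
mate_once <- function(pool, n_offspring, ancestry = NULL) {
  pp <- draw_parent_pairs(nrow(pool), n_offspring)
  off <- cpp_mate(pool, pp$pa - 1L, pp$pb - 1L)
  anc <- if (!is.null(ancestry)) {
    (ancestry[pp$pa, , drop = FALSE] + ancestry[pp$pb, , drop = FALSE]) / 2
  }
  list(genotypes = off, ancestry = anc)
}

#' Randomly mate a population
#'
#' Produces `n_offspring` individuals from one generation of random mating
#' within `pool`: each offspring draws two distinct parents uniformly and, at
#' every SNP independently, receives one allele from each parent (a parent
#' with dosage d transmits the minor allele with probability d/2).
#'
#' @param pool Individuals x SNPs dosage matrix with at least 2 rows.
#' @param n_offspring Number of offspring to produce.
#' @param seed Optional integer seed.
#' @return An `n_offspring` x SNPs dosage matrix.
#' @export
mate_population <- function(pool, n_offspring, seed = NULL) {
  pool <- as.matrix(pool)
  if (nrow(pool) < 2L) abort("`pool` must contain at least 2 individuals.")
  n_offspring <- check_count(n_offspring, "n_offspring", min = 1L)
  with_seed(seed, mate_once(pool, n_offspring)$genotypes)
}

#' Admix two populations
#'
#' Generation 1 offspring draw each parent from `pool_a` with probability `q`
#' and from `pool_b` otherwise; subsequent generations mate at random within
#' the offspring pool. Each individual's realized ancestry (proportion of
#' genome expected from `pool_a`) is tracked through the pedigree.
#'
#' @param pool_a,pool_b Dosage matrices over the same SNP set.
#' @param q Probability that a generation-1 parent comes from `pool_a`.
#' @param generations Number of mating generations (>= 1).
#' @param n_offspring Individuals per generation; defaults to the combined
#'   pool size.
#' @param cross_only If `TRUE`, generation 1 forces one parent from each
#'   pool (an F1 cross) instead of drawing the pools independently.
#' @param seed Optional integer seed.
#' @return List with `genotypes` (matrix) and `ancestry` (numeric vector in
#'   `[0, 1]`, proportion of `pool_a` ancestry).
#' @export
admix_populations <- function(pool_a, pool_b, q = 0.5, generations = 1,
                              n_offspring = NULL, cross_only = FALSE,
                              seed = NULL) {
  pool_a <- as.matrix(pool_a); pool_b <- as.matrix(pool_b)
  if (ncol(pool_a) != ncol(pool_b)) {
    abort("`pool_a` and `pool_b` must share the same SNP set.")
  }
  check_number(q, "q", 0, 1)
  generations <- check_count(generations, "generations", min = 1L)
  n_offspring <- n_offspring %||% (nrow(pool_a) + nrow(pool_b))
  n_offspring <- check_count(n_offspring, "n_offspring", min = 1L)
  with_seed(seed, {
    na <- nrow(pool_a); nb <- nrow(pool_b)
    pool <- rbind(pool_a, pool_b)
    pick <- function(from_a) {
      ifelse(from_a, sample.int(na, n_offspring, replace = TRUE),
             na + sample.int(nb, n_offspring, replace = TRUE))
    }
    if (cross_only) {
      pa <- pick(rep(TRUE, n_offspring))
      pb <- pick(rep(FALSE, n_offspring))
    } else {
      pa <- pick(runif(n_offspring) < q)
      pb <- pick(runif(n_offspring) < q)
    }
    off <- cpp_mate(pool, pa - 1L, pb - 1L)
    anc0 <- c(rep(1, na), rep(0, nb))
    anc <- (anc0[pa] + anc0[pb]) / 2
    g <- 1L
    while (g < generations) {
      res <- mate_once(off, n_offspring, matrix(anc, ncol = 1L))
      off <- res$genotypes
      anc <- as.vector(res$ancestry)
      g <- g + 1L
    }
    list(genotypes = off, ancestry = anc)
  })
}
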