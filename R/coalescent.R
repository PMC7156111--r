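#' Allelic classes of a present-day sample
#'
#' The sample of `n` haploid individuals is drawn at random, without
#' replacement, from the present-day population, so the number of sampled
#' carriers of the derived functional allele is hypergeometric.
#'
#' @param n sample size (`n <= N`).
#' @param final_count derived-allele count in the population at present.
#' @param N haploid population size.
#' @return A list with integer `k_derived` and `k_ancestral`
#'   (`k_derived + k_ancestral == n`).
#' @export
assign_sample_classes <- function(n, final_count, N) {
  stopifnot(n >= 1, n <= N, final_count >= 0, final_count <= N)
  k <- rhyper(1L, final_count, N - final_count, n)
  list(k_derived = as.integer(k), k_ancestral = as.integer(n - k))
}

#' Structured coalescent conditioned on a frequency path
#'
#' Simulates the genealogy of a present-day sample backward in time through a
#' recorded frequency path of the derived functional allele. Lineages belong
#' to two allelic classes whose sizes follow the path; within a class each
#' lineage picks a parent uniformly among the class members of the previous
#' generation (shared picks coalesce, true Wright-Fisher mechanics, so
#' bottlenecks to one copy need no special casing). A lineage switches class
#' with probability `min(1, mu_fwd * X_other(g-1) / X_own(g))` -- functional
#' mutation seen backward, in analogy to gene flow in a two-deme structured
#' coalescent -- and is forced to switch when its class was empty in the
#' previous generation (the origin of the allele). Lineages surviving past the
#' oldest path generation are exchangeable and coalesce as a discrete-time
#' Kingman process in a panmictic population of size `N`.
#'
#' @param counts integer vector of derived-allele counts per generation, the
#'   last entry being the present (a single-species component of a
#'   [simulate_frequency_path()] result).
#' @param N haploid population size.
#' @param n sample size.
#' @param mu_gain forward mutation rate into the derived class (host:
#'   `mu_rtoR`; parasite: `mu_ntoI`).
#' @param mu_loss forward mutation rate out of the derived class (host:
#'   `mu_Rtor`; parasite: `mu_Iton`).
#' @param k_derived number of sampled lineages carrying the derived allele;
#'   drawn by [assign_sample_classes()] when `NULL`.
#' @return An object of class `genealogy`: list with `parent` (0-based node
#'   index, -1 for the root), `time` (generations before present), `n_leaves`,
#'   `k_derived`. Leaves are nodes `0..n-1` at time 0.
#' @examples
#' path <- rep(500L, 201)  # constant polymorphic path, N = 1000
#' g <- simulate_genealogy(path, N = 1000, n = 5, mu_gain = 1e-5, mu_loss = 1e-5)
#' tmrca(g)
#' @export
simulate_genealogy <- function(counts, N, n, mu_gain, mu_loss,
                               k_derived = NULL) {
  counts <- as.integer(counts)
  stopifnot(length(counts) >= 1, all(counts >= 0), all(counts <= N),
            n >= 1, n <= N)
  final_count <- counts[length(counts)]
  if (is.null(k_derived))
    k_derived <- assign_sample_classes(n, final_count, N)$k_derived
  stopifnot(k_derived >= 0, k_derived <= n,
            final_count > 0 || k_derived == 0,
            final_count < N || k_derived == n)
  tr <- cpp_conditioned_genealogy(counts, as.integer(N), as.integer(n),
                                  as.integer(k_derived), mu_gain, mu_loss)
  structure(list(parent = tr$parent, time = tr$time, n_leaves = tr$n_leaves,
                 k_derived = as.integer(k_derived)),
            class = "genealogy")
}

#' Unconditioned discrete-time Kingman genealogy
#'
#' Neutral genealogy of `n` lineages in a panmictic haploid Wright-Fisher
#' population of constant size `N` (pairwise coalescence, geometric waiting
#' times in discrete generations). This is the simulator of the neutral
#' (non-coevolving) model.
#'
#' @param N haploid population size.
#' @param n sample size.
#' @return A `genealogy` object (see [simulate_genealogy()]).
#' @export
simulate_kingman_genealogy <- function(N, n) {
  stopifnot(n >= 1, n <= N)
  tr <- cpp_kingman_genealogy(as.integer(N), as.integer(n))
  structure(list(parent = tr$parent, time = tr$time, n_leaves = tr$n_leaves,
                 k_derived = NA_integer_),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("genealogy of %d leaves, %d nodes, TMRCA %.1f generations\n",
              x$n_leaves, length(x$parent), tmrca(x)))
  invisible(x)
}

#' Time to the most recent common ancestor
#' @param tree a `genealogy` object.
#' @return TMRCA in generations before present.
#' @export
tmrca <- function(tree) {
  if (tree$n_leaves == 1L) return(0)
  max(tree$time)
}

#' Total branch length of a genealogy
#' @param tree a `genealogy` object.
#' @return Sum of all branch lengths in generations.
#' @export
tree_length <- function(tree) {
  keep <- tree$parent >= 0
  sum(tree$time[tree$parent[keep] + 1L] - tree$time[keep])
}

#' Place neutral mutations on a genealogy
#'
#' Infinite-sites neutral mutation: each branch of length `b` generations
#' receives `Poisson(b * L * mu_site)` mutations, each assigned a uniform
#' position on `[0, 1)` (ms convention; the physical length enters only
#' through the product `L * mu_site`). Leaves below a mutated branch carry the
#' derived state 1. Columns are sorted by position. Because every branch
#' subtends between 1 and n-1 leaves, no invariant column can arise.
#'
#' @param tree a `genealogy` object.
#' @param L locus length in base pairs.
#' @param mu_site per-site per-generation mutation rate.
#' @param species optional species tag stored on the result.
#' @return An object of class `snp_matrix`: an `n x S` binary integer matrix
#'   (rows = sampled haplotypes, 0 = ancestral, 1 = derived) with attributes
#'   `positions` (sorted, in `[0,1)`) and `species`.
#' @export
drop_mutations <- function(tree, L = 2500, mu_site = 1e-7, species = NA_character_) {
  stopifnot(L >= 1, mu_site >= 0)
  out <- cpp_drop_mutations(tree$parent, tree$time, tree$n_leaves,
                            L * mu_site)
  snp_matrix(out$genotypes, out$positions, species)
}

#' Construct a polarized SNP matrix
#'
#' @param genotypes binary integer matrix, rows = haplotypes, columns =
#'   segregating sites (0 ancestral, 1 derived). Invariant columns are
#'   rejected.
#' @param positions site positions in `[0, 1)`, one per column.
#' @param species optional species tag.
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(genotypes, positions = NULL, species = NA_character_) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(positions)) positions <- numeric(ncol(genotypes))
  stopifnot(length(positions) == ncol(genotypes),
            all(genotypes %in% c(0L, 1L)))
  if (ncol(genotypes) > 0) {
    dc <- colSums(genotypes)
    if (any(dc == 0L) || any(dc == nrow(genotypes)))
      stop("invariant columns (derived count 0 or n) are not allowed in a snp_matrix")
  }
  structure(genotypes, positions = as.numeric(positions), species = species,
            class = c("snp_matrix", "matrix"))
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d haplotypes x %d segregating sites%s\n",
              nrow(x), ncol(x),
              if (is.na(attr(x, "species"))) "" else
                paste0(" (", attr(x, "species"), ")")))
  invisible(x)
}

#' Neutral polymorphism sample for one species
#'
#' Convenience wrapper: an unconditioned Kingman genealogy at size `N` plus
#' neutral mutations, i.e. one replicate of the neutral model for one species.
#'
#' @inheritParams simulate_kingman_genealogy
#' @inheritParams drop_mutations
#' @return A `snp_matrix`.
#' @export
simulate_neutral_snp <- function(N, n, L = 2500, mu_site = 1e-7,
                                 species = NA_character_) {
  drop_mutations(simulate_kingman_genealogy(N, n), L, mu_site, species)
}

#' Host and parasite SNP matrices for one coevolutionary history
#'
#' Runs the conditioned coalescent for each species on its frequency path
#' (host derived class = RES, parasite derived class = INF) and drops neutral
#' mutations, yielding the polymorphism data of one replicate.
#'
#' @param path a `coev_path` from [simulate_frequency_path()].
#' @return A list with `snp_matrix` elements `host` and `parasite`.
#' @export
simulate_snp_pair <- function(path) {
  stopifnot(inherits(path, "coev_path"))
  cfg <- path$config; par <- path$params
  host_tree <- simulate_genealogy(path$host$count, cfg$N_H, cfg$n_H,
                                  mu_gain = par$mu_rtoR, mu_loss = par$mu_Rtor)
  para_tree <- simulate_genealogy(path$parasite$count, cfg$N_P, cfg$n_P,
                                  mu_gain = par$mu_ntoI, mu_loss = par$mu_Iton)
  list(host = drop_mutations(host_tree, cfg$L, cfg$mu_site, "host"),
       parasite = drop_mutations(para_tree, cfg$L, cfg$mu_site, "parasite"))
}
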