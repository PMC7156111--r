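#' Population and locus configuration
#'
#' Census (= effective) haploid population sizes, sample sizes, and the
#' neutral mutation setup of the coevolutionary locus. The locus is
#' non-recombining with `L` sites mutating at `mu_site` per site per
#' generation, so the population mutation rates are derived as
#' `theta = 2 * N * L * mu_site` and are never set independently.
#'
#' @param N_H,N_P haploid host and parasite population sizes.
#' @param n_H,n_P sample sizes (default 50 haploid individuals each).
#' @param L locus length in base pairs (default 2500).
#' @param mu_site neutral per-site per-generation mutation rate (default 1e-7).
#' @return An object of class `population_config`.
#' @examples
#' population_config(10000, 10000)  # theta_H = theta_P = 5
#' @export
population_config <- function(N_H, N_P, n_H = 50, n_P = 50,
                              L = 2500, mu_site = 1e-7) {
  stopifnot(N_H >= 1, N_P >= 1, n_H >= 1, n_P >= 1,
            n_H <= N_H, n_P <= N_P, L >= 1, mu_site >= 0)
  structure(list(N_H = as.integer(round(N_H)), N_P = as.integer(round(N_P)),
                 n_H = as.integer(n_H), n_P = as.integer(n_P),
                 L = L, mu_site = mu_site,
                 theta_H = 2 * round(N_H) * L * mu_site,
                 theta_P = 2 * round(N_P) * L * mu_site),
            class = "population_config")
}

#' Simulation settings for a coevolutionary history
#'
#' @param R0,a0 initial frequencies of the RES and INF alleles (default 0.2,
#'   a small initial frequency of both functional alleles).
#' @param g_max number of host generations; defaults to
#'   `max(3 * N_H, 3 * N_P)` when left `NULL`, long enough for sweep and
#'   balancing-selection signatures to establish.
#' @param r number of replicate histories.
#' @param seed optional master RNG seed; when given, every downstream draw is
#'   reproducible.
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(R0 = 0.2, a0 = 0.2, g_max = NULL, r = 30, seed = NULL) {
  stopifnot(R0 >= 0, R0 <= 1, a0 >= 0, a0 <= 1, r >= 1,
            is.null(g_max) || g_max >= 1)
  structure(list(R0 = R0, a0 = a0, g_max = g_max, r = as.integer(r),
                 seed = seed),
            class = "sim_settings")
}

default_g_max <- function(config, settings) {
  if (!is.null(settings$g_max)) as.integer(settings$g_max)
  else as.integer(max(3 * config$N_H, 3 * config$N_P))
}

#' Binomial drift plus recurrent functional mutation
#'
#' One generation of genetic drift and mutation for one species: the new
#' allele count is a `Binomial(N, freq)` draw from the post-selection
#' frequency, after which `Binomial(N - count, mu_gain)` individuals mutate
#' into the allele class and `Binomial(count, mu_loss)` mutate out, the result
#' clamped to `[0, N]`. Mutation acts on individuals after drift, keeping the
#' state integer-valued.
#'
#' @param freq post-selection allele frequency in `[0, 1]`.
#' @param N haploid population size.
#' @param mu_gain,mu_loss per-individual per-generation functional mutation
#'   probabilities into and out of the allele class.
#' @return An integer allele count in `0..N`.
#' @export
drift_and_mutate <- function(freq, N, mu_gain = 0, mu_loss = 0) {
  stopifnot(freq >= 0, freq <= 1, N >= 1)
  count <- rbinom(1L, N, freq)
  count <- count + rbinom(1L, N - count, mu_gain) - rbinom(1L, count, mu_loss)
  min(max(count, 0L), as.integer(N))
}

#' Simulate one stochastic coevolutionary frequency path
#'
#' Runs the forward model for `g_max` host generations. Each generation
#' applies (1) the deterministic gene-for-gene recursions to the current
#' frequencies, (2) binomial drift in each species at its population size, and
#' (3) recurrent functional mutation, once per species per host generation
#' (the parasite state carried between host generations is the first-cycle
#' infective frequency). Recorded path entries are the post-drift,
#' post-mutation integer counts at the start of each host generation; these
#' are exactly what the conditioned coalescent consumes.
#'
#' @param params a [gfg_params()] object.
#' @param config a [population_config()] object.
#' @param settings a [sim_settings()] object; `settings$seed`, when non-NULL,
#'   seeds the RNG before simulating.
#' @return An object of class `coev_path`: a list with per-species components
#'   `host` and `parasite` (each holding `count`, `freq`, `N`), the number of
#'   generations `g_max`, and the inputs.
#' @examples
#' p <- simulate_frequency_path(gfg_params(0.5, 0.05, 0.1),
#'                              population_config(1000, 1000),
#'                              sim_settings(g_max = 500, seed = 1))
#' classify_dynamics(p)
#' @export
simulate_frequency_path <- function(params, config, settings = sim_settings()) {
  if (!is.null(settings$seed)) set.seed(settings$seed)
  g_max <- default_g_max(config, settings)
  raw <- cpp_forward_path(config$N_H, config$N_P, settings$R0, settings$a0,
                          g_max, params$s, params$c_H, params$c_P,
                          params$mu_Rtor, params$mu_rtoR,
                          params$mu_ntoI, params$mu_Iton)
  structure(list(
    host = list(count = raw$host, freq = raw$host / config$N_H, N = config$N_H),
    parasite = list(count = raw$parasite, freq = raw$parasite / config$N_P,
                    N = config$N_P),
    g_max = g_max, params = params, config = config, settings = settings),
    class = "coev_path")
}

#' @export
print.coev_path <- function(x, ...) {
  cat(sprintf("coevolutionary frequency path: %d host generations, N_H = %d, N_P = %d\n",
              x$g_max, x$host$N, x$parasite$N))
  cat(sprintf("final RES count %d/%d, final INF count %d/%d (%s)\n",
              x$host$count[x$g_max + 1], x$host$N,
              x$parasite$count[x$g_max + 1], x$parasite$N,
              classify_dynamics(x)))
  invisible(x)
}

#' Simulate independent replicate histories
#'
#' `settings$r` mutually independent frequency paths under identical
#' parameters. Child seeds are derived deterministically from the master seed
#' (one `sample.int` draw per replicate), so any single replicate can be
#' replayed bit-identically.
#'
#' @inheritParams simulate_frequency_path
#' @return A list of `coev_path` objects of length `settings$r`, with the
#'   child seed of each replicate stored in its `settings`.
#' @export
simulate_history_replicates <- function(params, config, settings = sim_settings()) {
  if (!is.null(settings$seed)) set.seed(settings$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, settings$r)
  lapply(child_seeds, function(sd) {
    s <- settings
    s$seed <- sd
    simulate_frequency_path(params, config, s)
  })
}
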