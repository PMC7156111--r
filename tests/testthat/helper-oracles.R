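# Independent oracles used to cross-check the simulators and statistics.
# These deliberately re-implement the target quantities by a different route
# than the package (plain R, brute force) and must stay that way.

# discrete-time Kingman coalescent oracle: geometric waiting times between
# pairwise mergers in a Wright-Fisher population of size N
oracle_kingman <- function(N, n) {
  k <- n
  t <- 0
  total <- 0
  while (k > 1) {
    q <- 1 - prod(1 - seq_len(k - 1) / N)
    w <- rgeom(1, q) + 1
    t <- t + w
    total <- total + k * w
    k <- k - 1
  }
  list(tmrca = t, length = total)
}

# brute-force mean pairwise Hamming distance (nucleotide diversity)
oracle_pi <- function(m) {
  n <- nrow(m)
  if (ncol(m) == 0) return(0)
  d <- 0
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n))
      d <- d + sum(m[i, ] != m[j, ])
  d / choose(n, 2)
}

# brute-force per-column derived-allele tally
oracle_sfs <- function(m) {
  n <- nrow(m)
  xi <- integer(n - 1)
  for (j in seq_len(ncol(m))) {
    k <- sum(m[, j])
    xi[k] <- xi[k] + 1L
  }
  xi
}

# random polarized SNP matrix with interior derived counts
random_snp_matrix <- function(n, S) {
  m <- matrix(0L, n, S)
  for (j in seq_len(S)) {
    k <- sample.int(n - 1, 1)
    m[sample.int(n, k), j] <- 1L
  }
  snp_matrix(m)
}

# leaf sets below every node of a genealogy (for the clade/polarization check)
leaf_sets <- function(tree) {
  n_nodes <- length(tree$parent)
  sets <- vector("list", n_nodes)
  for (i in seq_len(tree$n_leaves)) sets[[i]] <- i - 1L
  ord <- order(tree$time)
  for (i in ord) {
    p <- tree$parent[i]
    if (p >= 0) sets[[p + 1L]] <- sort(c(sets[[p + 1L]], sets[[i]]))
  }
  sets
}

# single-free-parameter prior for synthetic ABC tables
synth_prior <- function(lo = 0, hi = 1, dist = "unif") {
  structure(list(scenario = 2L, fixed = list(),
                 free = list(s = list(dist = dist, lo = lo, hi = hi)),
                 neutral_free = character(0)),
            class = "scenario_prior")
}

# synthetic reference table around a given stats matrix
synth_table <- function(model, params_df, stats, prior = synth_prior(0.1, 0.9),
                        r = 1) {
  colnames(stats) <- sumstat_names()
  df <- data.frame(model = model,
                   s = params_df$s %||% NA_real_,
                   c_H = params_df$c_H %||% NA_real_,
                   c_P = params_df$c_P %||% NA_real_,
                   N_H = params_df$N_H %||% NA_real_,
                   N_P = params_df$N_P %||% NA_real_,
                   stats, check.names = FALSE)
  as_reference_table(df, prior, r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
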