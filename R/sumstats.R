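#' Unfolded site frequency spectrum
#'
#' Counts `xi_i` of segregating sites at which exactly `i` of the `n` sampled
#' haplotypes carry the derived allele, `i = 1..n-1`. Requires polarized data;
#' fixed columns are rejected at [snp_matrix()] construction.
#'
#' @param x a [snp_matrix()] (or a plain 0/1 matrix with haplotypes in rows).
#' @return An integer vector of length `n - 1` with attribute `n`, of class
#'   `unfolded_sfs`.
#' @examples
#' m <- snp_matrix(rbind(c(1, 0, 1), c(0, 0, 1), c(0, 1, 0), c(0, 0, 0)))
#' unfolded_sfs(m)  # xi = (2, 1, 0)
#' @export
unfolded_sfs <- function(x) {
  if (!inherits(x, "snp_matrix")) x <- snp_matrix(x)
  n <- nrow(x)
  stopifnot(n >= 2)
  dc <- if (ncol(x) > 0) colSums(x) else integer(0)
  structure(tabulate(dc, nbins = n - 1L), n = as.integer(n),
            class = "unfolded_sfs")
}

#' @export
print.unfolded_sfs <- function(x, ...) {
  cat(sprintf("unfolded SFS, n = %d, S = %d\n", attr(x, "n"), sum(x)))
  print(as.integer(x))
  invisible(x)
}

harmonic <- function(n) sum(1 / seq_len(n))
harmonic2 <- function(n) sum(1 / seq_len(n)^2)

#' Single-species SFS summary statistics
#'
#' The eight per-species statistics computed from the unfolded site frequency
#' spectrum: the number of segregating sites S, Watterson's `theta_W`,
#' nucleotide diversity `pi`, Tajima's D, Fu and Li's D and F (unfolded
#' variants, with the derived singleton class `xi_1` as the external-branch
#' mutation count), Fay and Wu's `theta_H`, and the normalised H statistic
#' (`H'`, standardising `pi - theta_L`). When `S = 0` all eight statistics
#' are returned as 0 by convention, so replicate averages are always defined.
#'
#' @param sfs an [unfolded_sfs()] (or a bare count vector of length `n - 1`).
#' @param n sample size; taken from the `n` attribute when missing.
#' @return A named numeric vector:
#'   `S, thetaW, pi, tajD, fuliD, fuliF, thetaH, Hprime`.
#' @examples
#' sfs_statistics(unfolded_sfs(snp_matrix(diag(4)[, 1:3])))
#' @export
sfs_statistics <- function(sfs, n = attr(sfs, "n")) {
  stopifnot(!is.null(n), n >= 2, length(sfs) == n - 1)
  xi <- as.numeric(sfs)
  i <- seq_len(n - 1)
  S <- sum(xi)
  zero <- c(S = 0, thetaW = 0, pi = 0, tajD = 0, fuliD = 0, fuliF = 0,
            thetaH = 0, Hprime = 0)
  if (S == 0) return(zero)

  a1 <- harmonic(n - 1)
  a2 <- harmonic2(n - 1)
  nC2 <- n * (n - 1) / 2
  thetaW <- S / a1
  pi <- sum(xi * i * (n - i)) / nC2
  thetaH <- sum(xi * i^2) / nC2
  thetaL <- sum(xi * i) / (n - 1)
  eta_e <- xi[1]

  # Tajima's D
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  vD_taj <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  tajD <- if (vD_taj > 0) (pi - thetaW) / sqrt(vD_taj) else 0

  # Fu & Li's D and F (unfolded, eta_e = derived singletons)
  cn <- if (n == 2) 1 else 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
  uD <- a1 - 1 - vD
  den <- uD * S + vD * S^2
  fuliD <- if (den > 0) (S - a1 * eta_e) / sqrt(den) else 0

  an1 <- a1 + 1 / n  # harmonic number of a sample of n + 1
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (a1^2 + a2)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - vF
  den <- uF * S + vF * S^2
  fuliF <- if (den > 0) (pi - eta_e) / sqrt(den) else 0

  # Zeng et al. normalised H: standardised pi - theta_L
  bn1 <- a2 + 1 / n^2  # sum_{i=1}^{n} 1/i^2
  th <- thetaW
  th2 <- S * (S - 1) / (a1^2 + a2)
  varHL <- th * (n - 2) / (6 * (n - 1)) +
    th2 * (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2)
  Hprime <- if (varHL > 0) (pi - thetaL) / sqrt(varHL) else 0

  c(S = S, thetaW = thetaW, pi = pi, tajD = tajD, fuliD = fuliD,
    fuliF = fuliF, thetaH = thetaH, Hprime = Hprime)
}

#' Pairwise Manhattan distance between host and parasite spectra
#'
#' L1 distance between the proportion-normalised unfolded site frequency
#' spectra of the two species,
#' `PMD = sum_i | xi_Hi / S_H - xi_Pi / S_P |`. Normalising to proportions
#' keeps the statistic comparable across population sizes (it is a shape
#' contrast, not another theta estimator). A species without segregating
#' sites contributes a zero vector, so PMD lies in `[0, 2]` and equals 1 when
#' exactly one species is monomorphic.
#'
#' @param sfs_host,sfs_parasite [unfolded_sfs()] objects with equal sample
#'   sizes.
#' @return The PMD value.
#' @export
pairwise_manhattan_distance <- function(sfs_host, sfs_parasite) {
  if (length(sfs_host) != length(sfs_parasite))
    stop("host and parasite sample sizes differ; SFS bins cannot be aligned")
  ph <- if (sum(sfs_host) > 0) as.numeric(sfs_host) / sum(sfs_host)
        else numeric(length(sfs_host))
  pp <- if (sum(sfs_parasite) > 0) as.numeric(sfs_parasite) / sum(sfs_parasite)
        else numeric(length(sfs_parasite))
  sum(abs(ph - pp))
}

sumstat_base_names <- c("S", "thetaW", "pi", "tajD", "fuliD", "fuliF",
                        "thetaH", "Hprime")

#' Names of the 17 summary statistics
#'
#' Fixed column order used throughout: the eight host statistics, the eight
#' parasite statistics, then PMD.
#' @return Character vector of length 17.
#' @export
sumstat_names <- function() {
  c(paste0("host_", sumstat_base_names),
    paste0("para_", sumstat_base_names), "PMD")
}

#' Summary-statistic vector of one replicate
#'
#' The 17 statistics of one simulated replicate: eight per species plus the
#' pairwise Manhattan distance between the two spectra.
#'
#' @param host,parasite `snp_matrix` objects for the two species.
#' @return Named numeric vector of length 17 in [sumstat_names()] order.
#' @export
pair_sumstats <- function(host, parasite) {
  sfs_h <- unfolded_sfs(host)
  sfs_p <- unfolded_sfs(parasite)
  out <- c(sfs_statistics(sfs_h), sfs_statistics(sfs_p),
           pairwise_manhattan_distance(sfs_h, sfs_p))
  names(out) <- sumstat_names()
  out
}

#' Average summary statistics over replicate histories
#'
#' Elementwise arithmetic mean of the per-replicate statistic vectors; the
#' averaged vector is one ABC datapoint.
#'
#' @param stats a non-empty list of equally named numeric vectors.
#' @return The mean vector.
#' @export
replicate_average <- function(stats) {
  if (length(stats) == 0) stop("no replicate statistics to average")
  m <- do.call(rbind, stats)
  colMeans(m)
}
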