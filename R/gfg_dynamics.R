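#' Gene-for-gene model parameters
#'
#' Bundles the selection costs and functional (allele-switching) mutation
#' rates of the haploid gene-for-gene coevolution model with two parasite
#' infection cycles per host generation (auto-infection). Infection of a host
#' in the first cycle costs `s`; a resistant host infected only in the second
#' cycle pays the reduced cost `s/2`. Carrying the resistance allele RES costs
#' `c_H`; carrying the infectivity allele INF costs `c_P`.
#'
#' Coevolutionary cycling requires `s > c_H`; parameter sets with `s <= c_H`
#' are accepted (the susceptible host allele then fixes).
#'
#' @param s cost of infection, in `[0, 1)`.
#' @param c_H cost of resistance, in `[0, 1)`.
#' @param c_P cost of infectivity, in `[0, 1)`.
#' @param mu_Rtor,mu_rtoR host functional mutation probabilities per
#'   individual per host generation (RES to res, res to RES).
#' @param mu_ntoI,mu_Iton parasite functional mutation probabilities
#'   (ninf to INF, INF to ninf).
#' @return An object of class `gfg_params`.
#' @examples
#' gfg_params(s = 0.5, c_H = 0.05, c_P = 0.1)
#' @export
gfg_params <- function(s, c_H, c_P, mu_Rtor = 1e-5, mu_rtoR = 1e-5,
                       mu_ntoI = 1e-5, mu_Iton = 1e-5) {
  stopifnot(s >= 0, s < 1, c_H >= 0, c_H < 1, c_P >= 0, c_P < 1)
  mus <- c(mu_Rtor, mu_rtoR, mu_ntoI, mu_Iton)
  stopifnot(all(mus >= 0), all(mus < 1))
  structure(list(s = s, c_H = c_H, c_P = c_P,
                 mu_Rtor = mu_Rtor, mu_rtoR = mu_rtoR,
                 mu_ntoI = mu_ntoI, mu_Iton = mu_Iton),
            class = "gfg_params")
}

#' @export
print.gfg_params <- function(x, ...) {
  cat(sprintf("gene-for-gene parameters: s = %g, c_H = %g, c_P = %g\n",
              x$s, x$c_H, x$c_P))
  cat(sprintf("functional mutation rates: RES->res %g, res->RES %g, ninf->INF %g, INF->ninf %g\n",
              x$mu_Rtor, x$mu_rtoR, x$mu_ntoI, x$mu_Iton))
  invisible(x)
}

#' One deterministic gene-for-gene generation
#'
#' Advances the infinite-population recursions by one host generation (two
#' parasite infection cycles). No drift, no mutation.
#'
#' @param state numeric: frequencies `c(R = ..., a1 = ...)` of resistant hosts
#'   and of infective parasites at the first cycle, or a list with elements
#'   `R` and `a1`.
#' @param params a [gfg_params()] object.
#' @return A list with the next-generation frequencies `R` and `a1`, and the
#'   within-generation second-cycle infective frequency `a2`.
#' @examples
#' gfg_step(c(R = 0.2, a1 = 0.2), gfg_params(0.5, 0.05, 0.1))
#' @export
gfg_step <- function(state, params) {
  state <- as.list(state)
  R <- state$R; a1 <- state$a1
  stopifnot(is.finite(R), is.finite(a1), R >= 0, R <= 1, a1 >= 0, a1 <= 1)
  out <- cpp_gfg_step(R, a1, params$s, params$c_H, params$c_P)
  list(R = out[["R"]], a1 = out[["a1"]], a2 = out[["a2"]])
}

#' Closed-form internal equilibrium of the gene-for-gene model
#'
#' Approximate internal equilibrium frequencies of the infective-parasite
#' allele (`a_hat`) and resistant-host allele (`R_hat`), with `s1 = s`,
#' `s2 = s/2`:
#' \deqn{\hat a = \frac{s_2 + s_1 - \sqrt{(s_2+s_1)^2 - 4 s_2 (s_1 - c_H)}}
#'   {2 s_2 (1 - c_H)}, \qquad \hat R = \frac{c_P}{2 - c_P - \hat a}.}
#' The equilibrium in the parasite depends only on host costs (`s`, `c_H`) and
#' the equilibrium in the host is driven by the parasite cost `c_P`. Both are
#' centres of the coevolutionary cycles rather than exact fixed points.
#'
#' @param params a [gfg_params()] object with `s > 0`.
#' @return A list of class `gfg_equilibrium` with `a_hat`, `R_hat`, and
#'   `valid` (`TRUE` when both lie strictly inside (0, 1)). A negative
#'   discriminant yields `valid = FALSE` with `NA` frequencies, not an error.
#' @examples
#' gfg_equilibrium(gfg_params(0.5, 0.05, 0.1))
#' @export
gfg_equilibrium <- function(params) {
  stopifnot(params$s > 0)
  s1 <- params$s; s2 <- params$s / 2
  c_H <- params$c_H; c_P <- params$c_P
  disc <- (s2 + s1)^2 - 4 * s2 * (s1 - c_H)
  if (disc < 0) {
    return(structure(list(a_hat = NA_real_, R_hat = NA_real_, valid = FALSE),
                     class = "gfg_equilibrium"))
  }
  a_hat <- (s2 + s1 - sqrt(disc)) / (2 * s2 * (1 - c_H))
  R_hat <- c_P / (2 - c_P - a_hat)
  valid <- is.finite(a_hat) && is.finite(R_hat) &&
    a_hat > 0 && a_hat < 1 && R_hat > 0 && R_hat < 1
  structure(list(a_hat = a_hat, R_hat = R_hat, valid = valid),
            class = "gfg_equilibrium")
}

#' @export
print.gfg_equilibrium <- function(x, ...) {
  cat(sprintf("internal equilibrium: a_hat = %.6g, R_hat = %.6g (%s)\n",
              x$a_hat, x$R_hat,
              if (isTRUE(x$valid)) "valid" else "outside (0,1)"))
  invisible(x)
}

#' Iterate the deterministic recursions
#'
#' Pure iteration of [gfg_step()] for `g_max` host generations from the given
#' initial frequencies.
#'
#' @param params a [gfg_params()] object.
#' @param R0,a0 initial frequencies of RES hosts and INF parasites.
#' @param g_max number of host generations (the trajectory has `g_max + 1`
#'   rows including the initial state).
#' @return A data frame with columns `gen` (0..`g_max`), `R`, `a1`, and `a2`
#'   (the within-generation second-cycle value of the step leaving each row;
#'   `NA` for the final row).
#' @examples
#' traj <- gfg_iterate(gfg_params(0.5, 0.05, 0.1), g_max = 1000)
#' tail(traj, 2)
#' @export
gfg_iterate <- function(params, R0 = 0.2, a0 = 0.2, g_max = 30000) {
  stopifnot(g_max >= 1, R0 >= 0, R0 <= 1, a0 >= 0, a0 <= 1)
  m <- cpp_gfg_iterate(R0, a0, as.integer(g_max),
                       params$s, params$c_H, params$c_P)
  data.frame(gen = 0:g_max, R = m[, 1], a1 = m[, 2], a2 = m[, 3])
}

#' Long-run equilibrium from an iterated trajectory
#'
#' Mean of the last fraction of a deterministic trajectory. The mean over a
#' terminal window (default the last 10% of generations) is used rather than
#' the terminal point because the dynamics may still be cycling around the
#' internal equilibrium; the window average estimates the cycle centre.
#'
#' @param traj a trajectory from [gfg_iterate()].
#' @param tail_frac fraction of terminal generations to average over.
#' @return A list with `a_hat` and `R_hat`.
#' @export
equilibrium_from_trajectory <- function(traj, tail_frac = 0.1) {
  stopifnot(nrow(traj) >= 2, tail_frac > 0, tail_frac <= 1)
  keep <- seq.int(nrow(traj) - ceiling(tail_frac * (nrow(traj) - 1)) + 1, nrow(traj))
  list(a_hat = mean(traj$a1[keep]), R_hat = mean(traj$R[keep]))
}

#' Classify coevolutionary dynamics of a frequency path
#'
#' Labels a simulated history as `"arms_race"` (either species' functional
#' allele fixed or lost at the final generation), `"trench_warfare"` (both
#' species still segregating at the final generation), or `"degenerate"`
#' (polymorphism in both species was never simultaneously present at any
#' generation). For stochastic paths fixation means an integer count of 0 or
#' N; for deterministic trajectories a frequency below `1/(2N)` or above
#' `1 - 1/(2N)`, so that matched deterministic and stochastic runs receive
#' the same label.
#'
#' @param path a `coev_path` from [simulate_frequency_path()], or a
#'   deterministic trajectory from [gfg_iterate()].
#' @param N_H,N_P population sizes used for the deterministic fixation
#'   threshold (required for deterministic trajectories).
#' @return One of `"arms_race"`, `"trench_warfare"`, `"degenerate"`.
#' @export
classify_dynamics <- function(path, N_H = NULL, N_P = NULL) {
  if (inherits(path, "coev_path")) {
    h <- path$host$count / path$host$N
    p <- path$parasite$count / path$parasite$N
    thr_h <- 1 / (2 * path$host$N)
    thr_p <- 1 / (2 * path$parasite$N)
  } else if (is.data.frame(path) && all(c("R", "a1") %in% names(path))) {
    stopifnot(!is.null(N_H), !is.null(N_P))
    h <- path$R; p <- path$a1
    thr_h <- 1 / (2 * N_H); thr_p <- 1 / (2 * N_P)
  } else {
    stop("`path` must be a coev_path or a deterministic trajectory")
  }
  stopifnot(length(h) >= 1)
  seg_h <- h > thr_h & h < 1 - thr_h
  seg_p <- p > thr_p & p < 1 - thr_p
  if (!any(seg_h & seg_p)) return("degenerate")
  n <- length(h)
  if (!seg_h[n] || !seg_p[n]) "arms_race" else "trench_warfare"
}
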