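#' Prior specification for an inference scenario
#'
#' Two study designs are built in. Scenario 1 infers the cost of infection and
#' both population sizes while the costs of resistance and infectivity are
#' known (`c_H = 0.05`, `c_P = 0.1`): `s ~ U(0.1, 0.9)`,
#' `N_H, N_P ~ logU(2000, 40000)`. Scenario 2 infers all three costs while the
#' population sizes are known (`N_H = N_P = 10000`, so `theta = 5`):
#' `s ~ U(0.1, 0.9)`, `c_H, c_P ~ U(0.01, 0.35)`. The neutral model of
#' scenario 1 shares the population-size priors; the neutral model of
#' scenario 2 has no free parameter.
#'
#' @param scenario 1 or 2.
#' @return An object of class `scenario_prior`.
#' @examples
#' scenario_prior(2)
#' @export
scenario_prior <- function(scenario) {
  scenario <- as.integer(scenario)
  if (scenario == 1L) {
    structure(list(
      scenario = 1L,
      fixed = list(c_H = 0.05, c_P = 0.1),
      free = list(
        s = list(dist = "unif", lo = 0.1, hi = 0.9),
        N_H = list(dist = "logunif", lo = 2000, hi = 40000),
        N_P = list(dist = "logunif", lo = 2000, hi = 40000)),
      neutral_free = c("N_H", "N_P")),
      class = "scenario_prior")
  } else if (scenario == 2L) {
    structure(list(
      scenario = 2L,
      fixed = list(N_H = 10000, N_P = 10000),
      free = list(
        s = list(dist = "unif", lo = 0.1, hi = 0.9),
        c_H = list(dist = "unif", lo = 0.01, hi = 0.35),
        c_P = list(dist = "unif", lo = 0.01, hi = 0.35)),
      neutral_free = character(0)),
      class = "scenario_prior")
  } else stop("scenario must be 1 or 2")
}

#' @export
print.scenario_prior <- function(x, ...) {
  cat(sprintf("scenario %d prior; free: %s; fixed: %s\n", x$scenario,
              paste(names(x$free), collapse = ", "),
              paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                    collapse = ", ")))
  invisible(x)
}

draw_one <- function(spec) {
  switch(spec$dist,
         unif = runif(1, spec$lo, spec$hi),
         logunif = exp(runif(1, log(spec$lo), log(spec$hi))),
         stop("unknown prior distribution: ", spec$dist))
}

#' Draw one parameter set from a scenario prior
#'
#' Coevolution draws contain the scenario's free parameters plus the fixed
#' values; neutral draws contain only the parameters the neutral model has
#' (population sizes in scenario 1, nothing free in scenario 2). Log-uniform
#' draws are the exponential of a uniform draw on the log bounds.
#'
#' @param prior a [scenario_prior()].
#' @param model `"coevolution"` or `"neutral"`.
#' @return A named list with elements among `s`, `c_H`, `c_P`, `N_H`, `N_P`
#'   (`NA` for parameters absent from the model).
#' @export
draw_prior <- function(prior, model = c("coevolution", "neutral")) {
  model <- match.arg(model)
  draw <- list(s = NA_real_, c_H = NA_real_, c_P = NA_real_,
               N_H = NA_real_, N_P = NA_real_)
  draw[names(prior$fixed)] <- prior$fixed
  if (model == "coevolution") {
    for (p in names(prior$free)) draw[[p]] <- draw_one(prior$free[[p]])
  } else {
    for (p in prior$neutral_free) draw[[p]] <- draw_one(prior$free[[p]])
    draw[c("s", "c_H", "c_P")] <- NA_real_
  }
  if (!is.na(draw$N_H)) draw$N_H <- as.integer(round(draw$N_H))
  if (!is.na(draw$N_P)) draw$N_P <- as.integer(round(draw$N_P))
  draw
}

#' Averaged summary statistics of one reference-table entry
#'
#' One ABC datapoint: `r` independent replicate histories simulated at one
#' parameter draw, each summarised by the 17 statistics, then averaged. Under
#' the coevolution model each replicate is a full forward path plus two
#' conditioned coalescents; under the neutral model each replicate is an
#' unconditioned Kingman genealogy per species at the drawn or fixed
#' population size. Sample sizes are 50/50, the locus 2500 bp at site rate
#' 1e-7, so `theta = 2 N * 2500 * 1e-7`.
#'
#' @param draw a parameter draw from [draw_prior()].
#' @param prior the [scenario_prior()] the draw came from (supplies fixed
#'   values where the draw has `NA`).
#' @param model `"coevolution"` or `"neutral"`.
#' @param r number of replicate histories.
#' @param config_args optional overrides passed to [population_config()]
#'   (e.g. sample sizes).
#' @param g_max optional override of the `max(3 N_H, 3 N_P)` default
#'   (scaled-down test runs only).
#' @return Named numeric vector of the 17 averaged statistics.
#' @export
simulate_reference_entry <- function(draw, prior,
                                     model = c("coevolution", "neutral"),
                                     r = 30, config_args = list(),
                                     g_max = NULL) {
  model <- match.arg(model)
  stopifnot(r >= 1)
  config <- do.call(population_config,
                    c(list(N_H = draw$N_H, N_P = draw$N_P), config_args))
  reps <- vector("list", r)
  if (model == "coevolution") {
    params <- gfg_params(draw$s, draw$c_H, draw$c_P)
    settings <- sim_settings(r = 1, g_max = g_max)
    for (k in seq_len(r)) {
      path <- simulate_frequency_path(params, config, settings)
      snp <- simulate_snp_pair(path)
      reps[[k]] <- pair_sumstats(snp$host, snp$parasite)
    }
  } else {
    for (k in seq_len(r)) {
      h <- simulate_neutral_snp(config$N_H, config$n_H, config$L,
                                config$mu_site, "host")
      p <- simulate_neutral_snp(config$N_P, config$n_P, config$L,
                                config$mu_site, "parasite")
      reps[[k]] <- pair_sumstats(h, p)
    }
  }
  replicate_average(reps)
}

#' Assemble a data frame into a reference table
#'
#' @param df data frame with a `model` column, the parameter columns
#'   `s, c_H, c_P, N_H, N_P`, and the 17 statistic columns.
#' @param prior the [scenario_prior()] used to generate it.
#' @param r replicates per entry.
#' @param seed master seed (bookkeeping only).
#' @return The data frame with class `reference_table` and the metadata in
#'   attributes.
#' @export
as_reference_table <- function(df, prior, r, seed = NA_integer_) {
  stopifnot(all(c("model", sumstat_names()) %in% names(df)))
  structure(df, prior = prior, r = r, seed = seed,
            class = c("reference_table", "data.frame"))
}

#' Simulate an ABC reference table
#'
#' Draws parameters from the scenario prior and simulates the averaged
#' summary statistics of every entry, for both the coevolution and the
#' neutral model.
#'
#' @param prior a [scenario_prior()].
#' @param n_coevolution,n_neutral entries per model.
#' @param r replicate histories per entry.
#' @param seed master RNG seed.
#' @param g_max optional generation override for scaled-down runs.
#' @param verbose print progress every 100 entries.
#' @return A `reference_table` (data frame: `model`, parameters, 17 averaged
#'   statistics).
#' @export
build_reference_table <- function(prior, n_coevolution, n_neutral, r = 30,
                                  seed = NULL, g_max = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  models <- c(rep("coevolution", n_coevolution), rep("neutral", n_neutral))
  rows <- vector("list", length(models))
  for (i in seq_along(models)) {
    draw <- draw_prior(prior, models[i])
    stats <- simulate_reference_entry(draw, prior, models[i], r = r,
                                      g_max = g_max)
    rows[[i]] <- data.frame(model = models[i], s = draw$s, c_H = draw$c_H,
                            c_P = draw$c_P, N_H = draw$N_H, N_P = draw$N_P,
                            as.list(stats), check.names = FALSE)
    if (verbose && i %% 100 == 0)
      message(sprintf("reference table: %d / %d entries", i, length(models)))
  }
  as_reference_table(do.call(rbind, rows), prior, r,
                     if (is.null(seed)) NA_integer_ else seed)
}

stat_subset_columns <- function(stat_subset = c("joint", "host_only",
                                                "parasite_only")) {
  stat_subset <- match.arg(stat_subset)
  switch(stat_subset,
         joint = sumstat_names(),
         host_only = paste0("host_", sumstat_base_names),
         parasite_only = paste0("para_", sumstat_base_names))
}

#' ABC rejection model choice
#'
#' Standardises every statistic by its median absolute deviation over the
#' pooled two-model table, ranks all entries by Euclidean distance to the
#' observed vector, retains the closest `ceiling(tolerance * nrow)` entries,
#' and reports each model's share among them as its posterior probability.
#'
#' @param observed named numeric vector of the 17 averaged statistics (an ABC
#'   datapoint, e.g. one pseudo-observed dataset).
#' @param table a `reference_table` containing both models.
#' @param tolerance retained fraction of the pooled table (default 1%).
#' @return An object of class `model_choice`: `posterior` (named, sums to 1),
#'   `retained` (row indices), `tolerance`, `n_retained`.
#' @export
model_choice <- function(observed, table, tolerance = 0.01) {
  stopifnot(all(c("coevolution", "neutral") %in% table$model))
  cols <- sumstat_names()
  X <- as.matrix(as.data.frame(table)[, cols])
  obs <- observed[cols]
  mads <- apply(X, 2, mad)
  if (any(mads == 0)) {
    warning("dropping zero-MAD statistic column(s): ",
            paste(cols[mads == 0], collapse = ", "))
    X <- X[, mads > 0, drop = FALSE]
    obs <- obs[mads > 0]
    mads <- mads[mads > 0]
  }
  Z <- sweep(X, 2, mads, "/")
  zobs <- obs / mads
  d <- sqrt(rowSums(sweep(Z, 2, zobs)^2))
  n_keep <- as.integer(ceiling(tolerance * nrow(X)))
  retained <- order(d)[seq_len(n_keep)]
  n_coev <- sum(table$model[retained] == "coevolution")
  structure(list(posterior = c(coevolution = n_coev / n_keep,
                               neutral = 1 - n_coev / n_keep),
                 retained = retained, tolerance = tolerance,
                 n_retained = n_keep),
            class = "model_choice")
}

#' @export
print.model_choice <- function(x, ...) {
  cat(sprintf("ABC model choice (%d retained, tolerance %.3g):\n",
              x$n_retained, x$tolerance))
  print(round(x$posterior, 4))
  invisible(x)
}

#' Leave-one-out cross-validation of model choice
#'
#' For randomly chosen validation entries of each model, removes the entry,
#' reruns [model_choice()] against the remainder, and classifies by the larger
#' posterior (exact ties, which occur when few entries are retained, are
#' resolved by a fair coin so neither rate is biased). Reports the confusion
#' matrix, the false negative rate (truly coevolving entries classified
#' neutral) and the false positive rate (truly neutral entries classified
#' coevolving), both in percent.
#'
#' @param table a `reference_table`.
#' @param n_val validation entries per model (capped at the rows available).
#' @param tolerance retained fraction for each model choice.
#' @param seed optional RNG seed for the validation sample.
#' @return An object of class `confusion_matrix`: `counts` (true model by
#'   predicted model), `FNR`, `FPR` (percent), `n_val`, `tolerance`.
#' @export
cross_validate <- function(table, n_val = 500, tolerance = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- sumstat_names()
  counts <- matrix(0L, 2, 2,
                   dimnames = list(true = c("coevolution", "neutral"),
                                   predicted = c("coevolution", "neutral")))
  for (m in c("coevolution", "neutral")) {
    pool <- which(table$model == m)
    take <- sample(pool, min(n_val, length(pool)))
    for (i in take) {
      obs <- unlist(as.data.frame(table)[i, cols])
      mc <- model_choice(obs, table[-i, , drop = FALSE], tolerance)
      pc <- mc$posterior[["coevolution"]]
      pred <- if (pc > 0.5) "coevolution"
              else if (pc < 0.5) "neutral"
              else sample(c("coevolution", "neutral"), 1)
      counts[m, pred] <- counts[m, pred] + 1L
    }
  }
  structure(list(counts = counts,
                 FNR = 100 * counts["coevolution", "neutral"] /
                   sum(counts["coevolution", ]),
                 FPR = 100 * counts["neutral", "coevolution"] /
                   sum(counts["neutral", ]),
                 n_val = n_val, tolerance = tolerance),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  cat(sprintf("FNR = %.2f%%, FPR = %.2f%%\n", x$FNR, x$FPR))
  invisible(x)
}

param_transform <- function(values, spec) {
  if (spec$dist == "logunif") log(values) else values
}
param_backtransform <- function(values, spec) {
  if (spec$dist == "logunif") exp(values) else values
}

# median of an equal-weight Gaussian mixture centred at x with common sd h
mixture_median <- function(x, h, lo, hi) {
  if (h <= 0) return(stats::median(x))
  cdf <- function(q) mean(pnorm((q - x) / h))
  if (cdf(lo) >= 0.5) return(lo)
  if (cdf(hi) <= 0.5) return(hi)
  uniroot(function(q) cdf(q) - 0.5, c(lo, hi), tol = 1e-10)$root
}

#' ABC parameter estimation with regression adjustment
#'
#' Rejection on the coevolution entries of the reference table using
#' unnormalised Euclidean distance over the selected statistics (all 17, the
#' 8 host statistics, or the 8 parasite statistics; the cross-species PMD only
#' enters the joint set). The `n_retain` closest entries are kept; each free
#' parameter is regressed linearly on the selected statistics and the retained
#' values are shifted to the observed statistics (local-linear post
#' adjustment). The adjusted sample is smoothed with a Gaussian kernel whose
#' width is `kernel_width` on the parameter scale normalised to its prior
#' range, values are clamped to the prior support, and the marginal posterior
#' median is reported. Population sizes (log-uniform priors) are handled on
#' the log scale throughout.
#'
#' @param observed named numeric vector of the 17 averaged statistics.
#' @param table a `reference_table` (its coevolution rows are used).
#' @param n_retain retained simulations (default 1000).
#' @param stat_subset `"joint"`, `"host_only"` or `"parasite_only"`.
#' @param kernel_width Gaussian kernel width on the range-normalised
#'   parameter scale (default 0.01).
#' @return An object of class `param_posterior`: `median` (named vector on
#'   the natural scale), and per-parameter `posterior` lists with the
#'   retained and adjusted values.
#' @export
estimate_parameters <- function(observed, table, n_retain = 1000,
                                stat_subset = c("joint", "host_only",
                                                "parasite_only"),
                                kernel_width = 0.01) {
  stat_subset <- match.arg(stat_subset)
  prior <- attr(table, "prior")
  stopifnot(!is.null(prior))
  coev <- as.data.frame(table)[table$model == "coevolution", , drop = FALSE]
  if (nrow(coev) < n_retain)
    stop(sprintf("table has %d coevolution rows, fewer than n_retain = %d",
                 nrow(coev), n_retain))
  cols <- stat_subset_columns(stat_subset)
  X <- as.matrix(coev[, cols])
  obs <- observed[cols]
  d <- sqrt(rowSums(sweep(X, 2, obs)^2))
  keep <- order(d)[seq_len(n_retain)]
  Xr <- X[keep, , drop = FALSE]

  # drop constant columns from the regression design
  usable <- apply(Xr, 2, function(v) diff(range(v)) > 0)
  if (!all(usable))
    warning("constant statistic column(s) dropped from the regression: ",
            paste(cols[!usable], collapse = ", "))
  Xd <- Xr[, usable, drop = FALSE]
  obs_d <- obs[usable]

  posterior <- list()
  med <- c()
  for (p in names(prior$free)) {
    spec <- prior$free[[p]]
    vals <- param_transform(coev[[p]][keep], spec)
    lo <- param_transform(spec$lo, spec)
    hi <- param_transform(spec$hi, spec)
    if (ncol(Xd) > 0) {
      fit <- lm(vals ~ Xd)
      beta <- coef(fit)[-1]
      beta[is.na(beta)] <- 0
      adj <- vals - as.vector(sweep(Xd, 2, obs_d) %*% beta)
    } else {
      warning("no usable statistic columns; falling back to pure rejection")
      adj <- vals
    }
    adj <- pmin(pmax(adj, lo), hi)
    h <- kernel_width * (hi - lo)
    m <- mixture_median(adj, h, lo, hi)
    posterior[[p]] <- list(retained = param_backtransform(vals, spec),
                           adjusted = param_backtransform(adj, spec),
                           median = param_backtransform(m, spec))
    med[p] <- param_backtransform(m, spec)
  }
  structure(list(median = med, posterior = posterior,
                 stat_subset = stat_subset, n_retain = n_retain,
                 kernel_width = kernel_width),
            class = "param_posterior")
}

#' @export
print.param_posterior <- function(x, ...) {
  cat(sprintf("ABC posterior medians (%s statistics, %d retained):\n",
              x$stat_subset, x$n_retain))
  print(signif(x$median, 4))
  invisible(x)
}
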