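#' Pseudo-observed dataset (POD) grid specification
#'
#' The study grids: scenario 1 varies the cost of infection
#' `s = 0.15, 0.20, ..., 0.85` (15 values) at `c_H = 0.05`, `c_P = 0.1`,
#' `N_H = N_P = 10000`, with 30 PODs per value; scenario 2 crosses
#' `c_H in {0.05, 0.1}` and `c_P in {0.1, 0.3}` with the same 15 `s` values
#' (60 combinations) at 15 PODs each. Each POD is the average of `r`
#' replicate histories at the true parameters.
#'
#' @param scenario 1 or 2.
#' @param pods_per_point PODs per grid point (defaults: 30 for scenario 1,
#'   15 for scenario 2).
#' @param r replicate histories per POD.
#' @param seed master seed.
#' @param s_values grid of costs of infection.
#' @param g_max optional generation override for scaled-down runs.
#' @return An object of class `pod_spec` with the expanded grid.
#' @export
pod_spec <- function(scenario, pods_per_point = NULL, r = 30, seed = NULL,
                     s_values = seq(0.15, 0.85, by = 0.05), g_max = NULL) {
  scenario <- as.integer(scenario)
  if (is.null(pods_per_point))
    pods_per_point <- if (scenario == 1L) 30L else 15L
  grid <- if (scenario == 1L) {
    expand.grid(s = s_values, c_H = 0.05, c_P = 0.1)
  } else {
    expand.grid(s = s_values, c_H = c(0.05, 0.1), c_P = c(0.1, 0.3))
  }
  grid$N_H <- 10000L
  grid$N_P <- 10000L
  structure(list(scenario = scenario, grid = grid,
                 pods_per_point = as.integer(pods_per_point),
                 r = as.integer(r), seed = seed, g_max = g_max),
            class = "pod_spec")
}

#' Generate pseudo-observed datasets
#'
#' One averaged 17-statistic vector per POD, simulated under the coevolution
#' model at the true grid parameters, deterministic from the master seed.
#'
#' @param spec a [pod_spec()].
#' @return A data frame: true parameters plus the 17 averaged statistics,
#'   one row per POD.
#' @export
generate_pods <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  prior <- scenario_prior(spec$scenario)
  rows <- vector("list", nrow(spec$grid) * spec$pods_per_point)
  k <- 0
  for (i in seq_len(nrow(spec$grid))) {
    g <- spec$grid[i, ]
    draw <- list(s = g$s, c_H = g$c_H, c_P = g$c_P,
                 N_H = g$N_H, N_P = g$N_P)
    for (j in seq_len(spec$pods_per_point)) {
      stats <- tryCatch(
        simulate_reference_entry(draw, prior, "coevolution", r = spec$r,
                                 g_max = spec$g_max),
        error = function(e) stop(sprintf(
          "POD simulation failed at s=%g, c_H=%g, c_P=%g (pod %d): %s",
          g$s, g$c_H, g$c_P, j, conditionMessage(e))))
      k <- k + 1
      rows[[k]] <- data.frame(pod = j, s = g$s, c_H = g$c_H, c_P = g$c_P,
                              N_H = g$N_H, N_P = g$N_P, as.list(stats),
                              check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write SNP samples in ms format
#'
#' Standard ms-style blocks: `//`, `segsites: k`, `positions: ...` and one
#' 0/1 row per haplotype. A monomorphic sample writes `segsites: 0` with no
#' positions line.
#'
#' @param samples a `snp_matrix` or list of them.
#' @param file path or connection.
#' @export
write_ms <- function(samples, file) {
  if (inherits(samples, "snp_matrix")) samples <- list(samples)
  con <- if (is.character(file)) file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  for (m in samples) {
    writeLines("//", con)
    S <- ncol(m)
    writeLines(sprintf("segsites: %d", S), con)
    if (S > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.8f", attr(m, "positions")),
                             collapse = " ")), con)
      writeLines(apply(m, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(NULL)
}

#' Read ms-format SNP blocks
#'
#' @param file path or connection with ms-style output (`//` block headers,
#'   `segsites:`, `positions:`, 0/1 haplotype rows). Any simulator preamble
#'   before the first `//` is skipped.
#' @return A list of `snp_matrix` objects. A `segsites: 0` block yields a
#'   0-column matrix with zero rows (the sample size is not recorded by the
#'   format in that case).
#' @export
read_ms <- function(file) {
  lines <- readLines(file)
  starts <- which(lines == "//")
  if (length(starts) == 0) stop("no ms blocks ('//' lines) found")
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (b in seq_along(starts)) {
    i <- starts[b] + 1L
    if (i > length(lines) || !startsWith(lines[i], "segsites:"))
      stop("malformed ms block at line ", starts[b], ": missing segsites")
    S <- as.integer(sub("segsites:\\s*", "", lines[i]))
    if (is.na(S)) stop("malformed segsites count at line ", i)
    if (S == 0) {
      out[[b]] <- snp_matrix(matrix(integer(0), 0, 0), numeric(0))
      next
    }
    i <- i + 1L
    if (!startsWith(lines[i], "positions:"))
      stop("malformed ms block: missing positions at line ", i)
    pos <- as.numeric(strsplit(trimws(sub("positions:", "", lines[i])),
                               "\\s+")[[1]])
    if (length(pos) != S) stop("positions count mismatch at line ", i)
    i <- i + 1L
    rows <- character(0)
    while (i < bounds[b + 1L] && i <= length(lines) &&
           grepl("^[01]+$", lines[i])) {
      rows <- c(rows, lines[i])
      i <- i + 1L
    }
    if (length(rows) == 0) stop("ms block without haplotype rows before line ", i)
    if (any(nchar(rows) != S)) stop("haplotype row length mismatch near line ", i)
    geno <- t(vapply(strsplit(rows, ""), function(ch) as.integer(ch),
                     integer(S)))
    if (S == 1) geno <- matrix(as.integer(unlist(strsplit(rows, ""))),
                               ncol = 1)
    out[[b]] <- snp_matrix(geno, pos)
  }
  out
}

#' Write / read a reference table as TSV
#'
#' Plain tab-separated persistence with the scenario, replicate count and
#' master seed in `#`-prefixed header lines, so a saved table round-trips
#' with its metadata.
#'
#' @param table a `reference_table`.
#' @param file path.
#' @export
write_reference_table <- function(table, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# scenario: %d", attr(table, "prior")$scenario), con)
  writeLines(sprintf("# r: %d", attr(table, "r")), con)
  writeLines(sprintf("# seed: %s", attr(table, "seed")), con)
  write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(file) {
  hdr <- readLines(file, n = 3)
  meta <- function(key) sub(sprintf("^# %s: ", key), "", grep(
    sprintf("^# %s:", key), hdr, value = TRUE))
  df <- read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE)
  seed <- suppressWarnings(as.integer(meta("seed")))
  as_reference_table(df, scenario_prior(as.integer(meta("scenario"))),
                     as.integer(meta("r")), seed)
}

#' Run a full scenario experiment
#'
#' End-to-end workflow for one scenario: build the two-model reference table,
#' leave-one-out cross-validation, model choice for every POD, and parameter
#' estimation for every POD under the three statistic subsets. All reports are
#' written as TSV plus a JSON manifest with every seed and size needed to
#' reproduce the run byte-identically.
#'
#' @param scenario 1 or 2.
#' @param n_ref reference entries per model.
#' @param n_val cross-validation entries per model.
#' @param r replicate histories per entry and per POD.
#' @param pods_per_point PODs per grid point (`NULL` for the scenario
#'   default), forwarded to [pod_spec()].
#' @param s_values POD grid of infection costs.
#' @param tolerance model-choice retained fraction.
#' @param n_retain retained simulations for parameter estimation.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param seed master seed.
#' @param g_max optional generation override for scaled-down runs (recorded
#'   in the manifest so reduced runs are never confused with full-scale ones).
#' @param stat_subsets statistic subsets to estimate under.
#' @param verbose progress messages.
#' @return Invisibly, a list with `table`, `crossval`, `pod_table`,
#'   `model_choice` (per POD), `estimates` (per POD and subset), `manifest`.
#' @export
run_experiment <- function(scenario, n_ref = 200, n_val = 50, r = 30,
                           pods_per_point = NULL,
                           s_values = seq(0.15, 0.85, by = 0.05),
                           tolerance = 0.01, n_retain = NULL,
                           out_dir = NULL, seed = 1, g_max = NULL,
                           stat_subsets = c("joint", "host_only",
                                            "parasite_only"),
                           verbose = FALSE) {
  stage <- "reference table"
  res <- tryCatch({
    prior <- scenario_prior(scenario)
    table <- build_reference_table(prior, n_ref, n_ref, r = r,
                                   seed = seed, g_max = g_max,
                                   verbose = verbose)
    if (is.null(n_retain))
      n_retain <- max(50L, ceiling(0.1 * n_ref))

    stage <- "cross-validation"
    cv <- cross_validate(table, n_val = n_val, tolerance = tolerance,
                         seed = seed + 1L)

    stage <- "POD generation"
    spec <- pod_spec(scenario, pods_per_point = pods_per_point, r = r,
                     seed = seed + 2L, s_values = s_values, g_max = g_max)
    pods <- generate_pods(spec)

    stage <- "POD model choice"
    cols <- sumstat_names()
    pods$post_coevolution <- vapply(seq_len(nrow(pods)), function(i) {
      model_choice(unlist(pods[i, cols]), table, tolerance)$posterior[
        "coevolution"]
    }, numeric(1))

    stage <- "POD parameter estimation"
    est <- list()
    for (subset in stat_subsets) {
      em <- t(vapply(seq_len(nrow(pods)), function(i) {
        estimate_parameters(unlist(pods[i, cols]), table,
                            n_retain = n_retain, stat_subset = subset)$median
      }, setNames(numeric(length(names(prior$free))), names(prior$free))))
      est[[subset]] <- data.frame(pods[, c("pod", "s", "c_H", "c_P")],
                                  subset = subset, em, check.names = FALSE)
    }

    manifest <- list(scenario = scenario, n_ref = n_ref, n_val = n_val,
                     r = r, tolerance = tolerance, n_retain = n_retain,
                     seed = seed, g_max = g_max,
                     s_values = s_values,
                     pods_per_point = spec$pods_per_point,
                     package_version = as.character(
                       utils::packageVersion("gfgcoal")))
    out <- list(table = table, crossval = cv, pod_table = pods,
                estimates = est, manifest = manifest)

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_reference_table(table, file.path(out_dir, "reference_table.tsv"))
      write.table(pods, file.path(out_dir, "pods.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(as.data.frame(cv$counts),
                  file.path(out_dir, "confusion_matrix.tsv"), sep = "\t",
                  quote = FALSE)
      write.table(do.call(rbind, est),
                  file.path(out_dir, "estimates.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        c(manifest, list(FNR = cv$FNR, FPR = cv$FPR)),
        file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    }
    out
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s' (seed %d): %s",
                 stage, seed, conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
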