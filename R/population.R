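## Population-level variability: lognormal per-cell copy-number
## sampling around a base profile, per-cell steady-state recruitment,
## and pairwise Pearson correlations between partners.

#' Specify a simulated cell population
#'
#' Cell-to-cell variability is modeled by sampling each protein's copy
#' number per cell from a lognormal distribution,
#' `X_k,i = exp(log(mean_i) + sigma * N_k,i)` with `N` standard normal:
#' the log-mean is the natural logarithm of the population-averaged
#' copy number of the base profile, and a common `sigma = 0.2` (natural
#' log units) is applied to every varied protein — IGF1R and all
#' expressed partners; the IGF1 dose is not varied. Proteins at zero
#' copies stay at zero in every cell.
#'
#' @param base a [cell_profile()]: the population-average profile.
#' @param n_cells cells per population (default 5000).
#' @param sigma lognormal standard deviation in log units (default 0.2).
#' @param dose IGF1 dose in nanomolar (default 1).
#' @param seed RNG seed for reproducible sampling.
#' @return a `population_spec` object.
#' @export
population_spec <- function(base, n_cells = 5000, sigma = 0.2, dose = 1,
                            seed = 1) {
  stopifnot(inherits(base, "cell_profile"), n_cells >= 2, sigma >= 0,
            dose >= 0)
  structure(list(base = base, n_cells = n_cells, sigma = sigma,
                 dose = dose, seed = seed),
            class = "population_spec")
}

#' Sample a population of single-cell profiles
#'
#' @param spec a [population_spec()].
#' @return a matrix (cells x proteins) of copy numbers with attribute
#'   `"spec"`; rows are individual cells.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  mu <- spec$base$copies
  vary <- names(mu)[mu > 0]
  out <- matrix(rep(mu, each = spec$n_cells), nrow = spec$n_cells,
                dimnames = list(NULL, names(mu)))
  if (spec$sigma > 0 && length(vary)) {
    withr_seed <- function(code) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(spec$seed)
      code
    }
    noise <- withr_seed(matrix(stats::rnorm(spec$n_cells * length(vary)),
                               nrow = spec$n_cells))
    out[, vary] <- exp(sweep(spec$sigma * noise, 2, log(mu[vary]), "+"))
  }
  attr(out, "spec") <- spec
  out
}

#' Steady-state recruitment across a population
#'
#' Runs the algebraic steady-state solver for every sampled cell and
#' collects the bound copies per partner. Cells whose fixed-point
#' iteration fails to converge are excluded with a warning; the result
#' rows are independent, so the outcome does not depend on evaluation
#' order.
#'
#' @param cells matrix from [sample_population()] (cells x proteins),
#'   or a list of [cell_profile()]s.
#' @param map an [interaction_map()].
#' @param params a [ligand_params()] object.
#' @param dose IGF1 dose in nanomolar.
#' @param base optional base [cell_profile()]; required when `cells`
#'   is a bare matrix without a `"spec"` attribute.
#' @param volume cell volume in litres.
#' @return matrix `Y` (cells x partners) of steady-state bound copies,
#'   with the failing-cell indices in attribute `"failed"`.
#' @export
population_recruitment <- function(cells, map, params = table1_params(),
                                   dose = 1, base = NULL, volume = 2e-12) {
  if (is.list(cells) && !is.matrix(cells)) {
    proteins <- names(cells[[1]]$copies)
    cells <- do.call(rbind, lapply(cells, function(p) p$copies[proteins]))
    colnames(cells) <- proteins
  }
  if (is.null(base)) {
    spec <- attr(cells, "spec")
    if (!is.null(spec)) base <- spec$base
  }
  if (is.null(base))
    base <- cell_profile("population-base",
                         colMeans(cells))
  model <- build_cell_model(base, map, params, volume = volume)
  partners <- model$partners
  n <- nrow(cells)
  Y <- matrix(NA_real_, n, length(partners),
              dimnames = list(NULL, partners))
  failed <- integer(0)
  igf1r <- if ("IGF1R" %in% colnames(cells)) cells[, "IGF1R"]
           else rep(base$copies[["IGF1R"]], n)
  for (k in seq_len(n)) {
    sol <- tryCatch(
      .algebraic_steady(model, dose * 1e-9, copies_override = cells[k, ]),
      error = function(e) NULL)
    if (is.null(sol) || !sol$converged) { failed <- c(failed, k); next }
    Y[k, ] <- molar_to_copies(colSums(sol$bound), model$volume)
  }
  if (length(failed)) {
    warning(sprintf("%d cell(s) failed to converge and were excluded",
                    length(failed)))
    Y <- Y[-failed, , drop = FALSE]
    igf1r <- igf1r[-failed]
  }
  attr(Y, "failed") <- failed
  attr(Y, "dose") <- dose
  attr(Y, "igf1r") <- igf1r
  Y
}

#' Pairwise Pearson correlations of population recruitment
#'
#' Sample Pearson correlation coefficients between the bound copies of
#' every pair of partners across cells. Partners with zero variance
#' across the population get `NA` entries and are listed in the
#' `degenerate` field.
#'
#' @param Y matrix (cells x partners) from [population_recruitment()].
#' @return a `correlation_result`: `pearson` (symmetric matrix),
#'   `mean`, `sd`, `n_cells`, `degenerate`.
#' @export
pairwise_correlations <- function(Y) {
  if (nrow(Y) < 2) stop("at least two cells are required")
  s <- apply(Y, 2, stats::sd)
  degenerate <- colnames(Y)[s == 0]
  P <- suppressWarnings(stats::cor(Y))
  P[degenerate, ] <- NA
  P[, degenerate] <- NA
  diag(P)[!(colnames(Y) %in% degenerate)] <- 1
  structure(list(pearson = P, mean = colMeans(Y), sd = s,
                 n_cells = nrow(Y), degenerate = degenerate),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: %d partners over %d cells\n",
              ncol(x$pearson), x$n_cells))
  invisible(x)
}

#' One-call population correlation analysis
#'
#' Samples the population, simulates every cell to steady state and
#' returns the pairwise correlation structure. By default the per-cell
#' observable entering the correlations is the normalized recruitment
#' (bound copies divided by that cell's IGF1R copies): because IGF1R
#' itself varies from cell to cell, raw bound copies of every partner
#' share a common receptor-abundance mode that induces positive
#' correlation across the board and masks competition; normalizing by
#' the per-cell receptor exposes the competition structure. Set
#' `observable = "bound"` for raw bound copies.
#'
#' @param spec a [population_spec()].
#' @param map an [interaction_map()].
#' @param params a [ligand_params()] object.
#' @param volume cell volume in litres.
#' @param observable `"normalized"` (default) or `"bound"`.
#' @return a `correlation_result` with the recruitment matrix attached
#'   as `Y` (raw bound copies) and the correlated observable as `obs`.
#' @export
population_correlations <- function(spec, map, params = table1_params(),
                                    volume = 2e-12,
                                    observable = c("normalized", "bound")) {
  observable <- match.arg(observable)
  cells <- sample_population(spec)
  Y <- population_recruitment(cells, map, params, dose = spec$dose,
                              base = spec$base, volume = volume)
  obs <- if (observable == "normalized") Y / attr(Y, "igf1r") else Y
  out <- pairwise_correlations(obs)
  out$Y <- Y
  out$obs <- obs
  out$observable <- observable
  out$spec <- spec
  out
}

#' Export population outputs
#'
#' Writes the recruitment matrix and the correlation matrix as CSV and
#' a JSON sidecar echoing the sampling spec and seed.
#'
#' @param result a `correlation_result` from
#'   [population_correlations()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @export
write_population_result <- function(result, dir, prefix = "population") {
  stopifnot(inherits(result, "correlation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$Y))
    utils::write.csv(data.frame(cell = seq_len(nrow(result$Y)), result$Y),
                     file.path(dir, paste0(prefix, "_bound.csv")),
                     row.names = FALSE)
  utils::write.csv(data.frame(protein = rownames(result$pearson),
                              result$pearson),
                   file.path(dir, paste0(prefix, "_pearson.csv")),
                   row.names = FALSE)
  if (!is.null(result$spec)) {
    sidecar <- file.path(dir, paste0(prefix, "_spec.json"))
    sp <- result$spec
    json <- sprintf(paste0(
      '{"base": "%s", "n_cells": %d, "sigma": %.17g, ',
      '"dose_nM": %.17g, "seed": %d}'),
      sp$base$name, sp$n_cells, sp$sigma, sp$dose, sp$seed)
    writeLines(json, sidecar)
  }
  invisible(dir)
}
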