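## Comparative analyses: five recruitment-ranking metrics, rank
## deviations, cross-cell-line summaries, numerical-vs-analytical
## comparison and Ward clustering of recruitment profiles.

RANK_METRICS <- c("simulation", "analytical", "copy_number", "kd",
                  "copy_over_kd")

#' Rank binding partners of a cell model by one of five metrics
#'
#' Metrics: `"simulation"` — steady-state bound copies from the
#' mechanistic model (default at 1 nM IGF1, the reference condition);
#' `"analytical"` — the single-occupancy equilibrium approximation;
#' `"copy_number"` — total copies per cell; `"kd"` — binding affinity
#' (strongest first; a multi-site partner is scored by its minimum
#' K_D); `"copy_over_kd"` — copies divided by minimum K_D. Rank 1 is
#' the partner predicted to be most recruited / most favored.
#' Unexpressed proteins are excluded from the permutation and reported
#' separately. Ties break alphabetically.
#'
#' @param model a [build_cell_model()] object.
#' @param metric one of `RANK_METRICS`.
#' @param dose IGF1 dose in nanomolar (simulation / analytical).
#' @param result optional precomputed `recruitment_result` (avoids
#'   re-simulation for `metric = "simulation"`).
#' @return a `ranking` object: data frame (protein, value, rank) plus
#'   attributes `metric` and `unexpressed`.
#' @export
rank_partners <- function(model, metric = RANK_METRICS, dose = 1,
                          result = NULL) {
  stopifnot(inherits(model, "cell_model"))
  metric <- match.arg(metric)
  partners <- model$partners
  if (length(partners) == 0) stop("empty partner set")
  value <- switch(
    metric,
    simulation = {
      if (is.null(result)) result <- simulate_to_steady_state(model, dose)
      result$bound[partners]
    },
    analytical = analytical_recruitment(model, dose)$bound_copies[partners],
    copy_number = model$partner_copies[partners],
    kd = {
      mk <- .min_kd(model$map)
      -mk[partners]  # stronger affinity (lower KD) ranks first
    },
    copy_over_kd = {
      mk <- .min_kd(model$map)
      model$partner_copies[partners] / mk[partners]
    })
  ord <- order(-value, partners)
  out <- data.frame(protein = partners[ord],
                    value = if (metric == "kd") -value[ord] else value[ord],
                    rank = seq_along(partners), row.names = NULL)
  unexpr <- setdiff(names(model$profile$copies),
                    c("IGF1R", partners))
  structure(out, class = c("ranking", "data.frame"), metric = metric,
            unexpressed = unexpr)
}

#' Signed rank deviation between two rankings
#'
#' Per-protein deviation `(simulation rank) - (alternative rank)`. A
#' negative deviation means the alternative metric predicted less
#' binding (a larger rank number) than the simulation. Over a complete
#' pair of permutations the deviations sum to zero.
#'
#' @param sim_ranking,alt_ranking `ranking` objects over the same
#'   partner set.
#' @return a `rank_deviation` data frame (protein, deviation) with
#'   attribute `n_nonzero`.
#' @export
rank_deviation <- function(sim_ranking, alt_ranking) {
  stopifnot(inherits(sim_ranking, "ranking"), inherits(alt_ranking, "ranking"))
  if (!setequal(sim_ranking$protein, alt_ranking$protein))
    stop("rankings cover different partner sets")
  prot <- sort(sim_ranking$protein)
  dev <- sim_ranking$rank[match(prot, sim_ranking$protein)] -
    alt_ranking$rank[match(prot, alt_ranking$protein)]
  out <- data.frame(protein = prot, deviation = dev, row.names = NULL)
  structure(out, class = c("rank_deviation", "data.frame"),
            n_nonzero = sum(dev != 0),
            metrics = c(attr(sim_ranking, "metric"),
                        attr(alt_ranking, "metric")))
}

#' Summarize rankings across cell lines
#'
#' For each protein: mean and standard deviation of its rank over the
#' cell lines where it is expressed, the expression count, and the
#' share of lines in which it ranks first, second, ..., up to `top_k`.
#'
#' @param rankings named list of `ranking` objects, one per cell line.
#' @param top_k number of leading rank positions to tabulate.
#' @return a data frame (protein, mean_rank, sd_rank, n_expressed,
#'   top1 ... top`k` shares), ordered by mean rank.
#' @export
cross_cell_summary <- function(rankings, top_k = 5) {
  stopifnot(length(rankings) >= 1)
  long <- do.call(rbind, lapply(seq_along(rankings), function(i) {
    r <- rankings[[i]]
    data.frame(line = i, protein = r$protein, rank = r$rank)
  }))
  prot <- sort(unique(long$protein))
  out <- data.frame(
    protein = prot,
    mean_rank = vapply(prot, function(p) mean(long$rank[long$protein == p]),
                       numeric(1)),
    sd_rank = vapply(prot, function(p) {
      r <- long$rank[long$protein == p]
      if (length(r) > 1) stats::sd(r) else 0
    }, numeric(1)),
    n_expressed = vapply(prot, function(p) sum(long$protein == p),
                         integer(1)),
    row.names = NULL)
  for (k in seq_len(top_k)) {
    out[[paste0("top", k)]] <- vapply(prot, function(p)
      sum(long$rank[long$protein == p] == k) / length(rankings), numeric(1))
  }
  out[order(out$mean_rank), ]
}

#' Compare numerical and analytical recruitment predictions
#'
#' Pearson correlation (via [stats::cor.test()]) between the
#' steady-state bound molecules predicted by the mechanistic model and
#' by the analytical single-occupancy approximation, over the expressed
#' partner set, with the per-protein scatter table.
#'
#' @param model a [build_cell_model()] object.
#' @param dose IGF1 dose in nanomolar.
#' @param result optional precomputed simulation `recruitment_result`.
#' @return list with `r`, `p_value`, `table` (protein, numerical,
#'   analytical).
#' @export
compare_numerical_vs_analytical <- function(model, dose = 1, result = NULL) {
  stopifnot(inherits(model, "cell_model"))
  if (length(model$partners) < 3)
    stop("at least three partners are needed for a correlation")
  if (is.null(result)) result <- simulate_to_steady_state(model, dose)
  ana <- analytical_recruitment(model, dose)
  tab <- data.frame(protein = model$partners,
                    numerical = as.numeric(result$bound[model$partners]),
                    analytical = as.numeric(ana$bound_copies[model$partners]))
  ct <- stats::cor.test(tab$numerical, tab$analytical)
  list(r = unname(ct$estimate), p_value = ct$p.value, table = tab)
}

#' Ward hierarchical clustering of cell-line recruitment profiles
#'
#' Clusters cell lines (rows) and proteins (columns) of a normalized
#' recruitment matrix by Ward's minimum-variance linkage on Euclidean
#' distances (the `ward.D2` implementation, equivalent to scipy's
#' `ward`). Unexpressed proteins must be encoded as 0; missing values
#' are rejected.
#'
#' @param mat numeric matrix, cell lines x proteins.
#' @return list with `row_hclust`, `col_hclust`, `row_order`,
#'   `col_order` and `matrix` (input reordered by the dendrograms).
#' @export
cluster_cell_lines <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(!is.finite(mat))) stop("matrix contains missing or non-finite values")
  if (nrow(mat) < 2) stop("at least two cell lines are required")
  rh <- stats::hclust(stats::dist(mat), method = "ward.D2")
  ch <- if (ncol(mat) >= 2)
    stats::hclust(stats::dist(t(mat)), method = "ward.D2") else NULL
  ro <- rh$order
  co <- if (is.null(ch)) seq_len(ncol(mat)) else ch$order
  list(row_hclust = rh, col_hclust = ch,
       row_order = rownames(mat)[ro], col_order = colnames(mat)[co],
       matrix = mat[ro, co, drop = FALSE])
}

#' Build the normalized recruitment matrix for a set of cell lines
#'
#' Simulates each profile to steady state at the given dose and stacks
#' normalized recruitment (bound / total IGF1R) into a cell-line x
#' protein matrix; proteins not expressed in a line get 0.
#'
#' @param profiles named list of [cell_profile()]s.
#' @param map an [interaction_map()].
#' @param params a [ligand_params()] object.
#' @param dose IGF1 dose in nanomolar.
#' @param volume cell volume in litres.
#' @param proteins column order (default: all partners in `map`).
#' @return matrix (lines x proteins) with per-line
#'   `recruitment_result`s attached as attribute `"results"`.
#' @export
recruitment_matrix <- function(profiles, map, params = table1_params(),
                               dose = 1, volume = 2e-12,
                               proteins = sort(unique(map$protein))) {
  results <- lapply(profiles, function(p) {
    m <- build_cell_model(p, map, params, volume = volume)
    simulate_to_steady_state(m, dose)
  })
  mat <- matrix(0, length(profiles), length(proteins),
                dimnames = list(names(profiles), proteins))
  for (i in seq_along(results)) {
    nr <- normalized_recruitment(results[[i]])
    mat[i, names(nr)] <- nr
  }
  attr(mat, "results") <- results
  mat
}
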