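## Synthetic input generators. These emulate the statistical structure
## of the study's inputs — copy-number tables spanning ~1e2-1e7 copies
## per cell, a bipartite protein/site interaction map over 6 sites and
## up to 18 proteins with K_D roughly 0.1-10 uM, and lognormal
## cell-to-cell variability — so that every pipeline stage is testable
## without external data. The fixtures are synthetic transcriptions of
## facts stated in the main text; they are NOT the study's
## supplementary tables, and quantitative results computed from them
## are stand-ins.

#' Specify a synthetic data generator
#'
#' @param seed RNG seed; all generators are seed-deterministic.
#' @param n_proteins number of binding partners (max 18; names are
#'   taken from [IGF1R_PARTNERS]).
#' @param n_sites number of tyrosine sites (default 6, named from
#'   [IGF1R_SITES]).
#' @param abundance_range copies-per-cell range, sampled log-uniformly.
#' @param kd_range K_D range in molar, sampled log-uniformly.
#' @param edge_density probability that a (site, protein) pair is an
#'   edge; ignored when `n_edges` is given.
#' @param n_edges optional exact total edge count.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(seed = 1, n_proteins = 18, n_sites = 6,
                           abundance_range = c(1e2, 1e7),
                           kd_range = c(1e-7, 1e-5),
                           edge_density = 0.5, n_edges = NULL) {
  stopifnot(n_proteins >= 1, n_proteins <= length(IGF1R_PARTNERS),
            n_sites >= 1, n_sites <= length(IGF1R_SITES),
            all(abundance_range > 0), all(kd_range > 0),
            edge_density > 0, edge_density <= 1)
  structure(list(seed = seed, n_proteins = n_proteins, n_sites = n_sites,
                 abundance_range = sort(abundance_range),
                 kd_range = sort(kd_range),
                 edge_density = edge_density, n_edges = n_edges),
            class = "synthetic_spec")
}

.log_uniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Generate a synthetic cell profile
#'
#' Copies per cell are drawn log-uniformly over the spec's abundance
#' range for IGF1R and each partner. An optional mask forces selected
#' proteins to zero (not expressed).
#'
#' @param spec a [synthetic_spec()].
#' @param name profile name.
#' @param mask character vector of proteins set to zero copies.
#' @return a [cell_profile()].
#' @export
generate_cell_profile <- function(spec, name = "synthetic", mask = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  proteins <- c("IGF1R", IGF1R_PARTNERS[seq_len(spec$n_proteins)])
  copies <- stats::setNames(.log_uniform(length(proteins),
                                         spec$abundance_range), proteins)
  if (!is.null(mask)) copies[intersect(mask, proteins)] <- 0
  cell_profile(name, copies)
}

#' Generate a synthetic interaction map
#'
#' Draws a bipartite edge set between the spec's sites and proteins
#' (each pair an edge with probability `edge_density`, or exactly
#' `n_edges` pairs when given) with log-uniform K_D values, guaranteeing
#' at least one partner per site.
#'
#' @param spec a [synthetic_spec()].
#' @return an [interaction_map()].
#' @export
generate_interaction_map <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  sites <- IGF1R_SITES[seq_len(spec$n_sites)]
  proteins <- IGF1R_PARTNERS[seq_len(spec$n_proteins)]
  grid <- expand.grid(site = sites, protein = proteins,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(spec$n_edges)) {
    if (spec$n_edges < spec$n_sites || spec$n_edges > nrow(grid))
      stop(sprintf("n_edges must be in [%d, %d] to cover every site",
                   spec$n_sites, nrow(grid)))
    ## one guaranteed partner per site, remainder sampled uniformly
    first <- vapply(sites, function(s)
      sample(which(grid$site == s), 1L), integer(1))
    rest <- sample(setdiff(seq_len(nrow(grid)), first),
                   spec$n_edges - length(first))
    pick <- sort(c(first, rest))
  } else {
    pick <- which(stats::runif(nrow(grid)) < spec$edge_density)
    missing <- setdiff(sites, grid$site[pick])
    if (length(missing) * 2 > length(pick))
      stop("edge density too low to cover every site")
    pick <- sort(union(pick, vapply(missing, function(s)
      sample(which(grid$site == s), 1L), integer(1))))
  }
  edges <- grid[pick, , drop = FALSE]
  edges$KD <- .log_uniform(nrow(edges), spec$kd_range)
  interaction_map(edges, sites = IGF1R_SITES)
}

## ---- HeLa-S3-like synthetic fixture ------------------------------------

## Copies per cell. Synthetic transcription of main-text facts: SHC1 at
## 1e5 copies with IRS1 two orders lower; STAT1 and CRKL the two most
## abundant partners (~1e5); VAV2 comparable to STAT1; ABL2 the ninth
## most abundant (~1e4); the remaining pY1161 competitors (PIK3R3, SRC,
## YES1, SYK, BLK) at comparatively low expression; ITK and ZAP70 not
## expressed. Other values are plausible fill-ins.
.HELA_LIKE_COPIES <- c(
  IGF1R = 2e4,
  SHC1 = 1e5, IRS1 = 1e3, ZAP70 = 0,
  STAT1 = 1.5e5, CRKL = 1.2e5, VAV2 = 1e5,
  RASA1 = 5e4, CRK = 4e4, PIK3R1 = 3e4,
  YES1 = 2e4, ABL2 = 1.2e4, SRC = 1e4,
  PIK3R2 = 9e3, PLCG2 = 8e3, SYK = 5e3,
  PIK3R3 = 3e3, BLK = 2e3, ITK = 0)

## Interaction edges with K_D in micromolar. Synthetic: anchored on the
## main-text constraints (SHC1 only at Y980, 20-fold stronger than
## IRS1; STAT1 and VAV2 only at Y1161 with similar affinities; YES1 at
## Y1161/Y1165 with K_D 0.9 uM; CRKL at Y973 and Y1166; ABL2 ~40-fold
## stronger than CRKL at Y973; nine partners at Y1161; PIK3R2 at
## Y1346), with remaining edges and affinities filled in over the
## 0.1-10 uM SH2/PTB range. Sum of edges = 50 over 18 partners.
.HELA_LIKE_EDGES <- local({
  e <- rbind(
    c("Y973",  "ABL2",   0.1), c("Y973",  "CRKL",   4.0),
    c("Y973",  "CRK",    2.0), c("Y973",  "SRC",    3.0),
    c("Y973",  "SYK",    5.0), c("Y973",  "PIK3R3", 3.5),
    c("Y980",  "SHC1",   0.5), c("Y980",  "IRS1",  10.0),
    c("Y980",  "ZAP70",  2.0),
    c("Y1161", "STAT1",  1.0), c("Y1161", "VAV2",   1.2),
    c("Y1161", "YES1",   0.9), c("Y1161", "SRC",    2.5),
    c("Y1161", "PIK3R3", 3.0), c("Y1161", "SYK",    3.0),
    c("Y1161", "BLK",    5.0), c("Y1161", "ITK",    6.0),
    c("Y1161", "CRK",    4.0),
    c("Y1165", "YES1",   0.9), c("Y1165", "RASA1",  1.5),
    c("Y1165", "SRC",    2.0), c("Y1165", "SYK",    3.5),
    c("Y1165", "BLK",    4.0), c("Y1165", "ITK",    5.0),
    c("Y1165", "CRK",    2.5), c("Y1165", "PIK3R3", 4.0),
    c("Y1165", "PLCG2",  2.0), c("Y1165", "ABL2",   2.0),
    c("Y1165", "PIK3R1", 1.5),
    c("Y1166", "CRKL",   1.0), c("Y1166", "RASA1",  1.8),
    c("Y1166", "SRC",    2.2), c("Y1166", "SYK",    4.5),
    c("Y1166", "BLK",    6.0), c("Y1166", "ITK",    7.0),
    c("Y1166", "CRK",    3.0), c("Y1166", "PIK3R3", 5.0),
    c("Y1166", "PLCG2",  2.8), c("Y1166", "ABL2",   2.4),
    c("Y1166", "PIK3R1", 1.8),
    c("Y1346", "PIK3R1", 1.2), c("Y1346", "PIK3R2", 0.6),
    c("Y1346", "PLCG2",  2.5), c("Y1346", "RASA1",  2.0),
    c("Y1346", "CRK",    3.5), c("Y1346", "SRC",    4.0),
    c("Y1346", "SYK",    5.5), c("Y1346", "ITK",    8.0),
    c("Y1346", "BLK",    7.0), c("Y1346", "ABL2",   3.0))
  data.frame(site = e[, 1], protein = e[, 2],
             KD = as.numeric(e[, 3]) * 1e-6, stringsAsFactors = FALSE)
})

#' Synthetic HeLa-S3-like fixture
#'
#' A synthetic copy-number profile and interaction map transcribing
#' only facts stated in the main text (abundance orders of magnitude,
#' affinity ratios, site assignments; ITK and ZAP70 unexpressed), with
#' the remaining values filled in over realistic SH2/PTB ranges. It is
#' explicitly NOT the study's supplementary data; checks built on it
#' are qualitative stand-ins. The full 18-partner map carries 50 edges.
#'
#' @return list with elements `profile` (a [cell_profile()]) and `map`
#'   (an [interaction_map()]).
#' @export
hela_like_fixture <- function() {
  list(profile = cell_profile("HeLa-S3-like", .HELA_LIKE_COPIES,
                              type = "cervical"),
       map = interaction_map(.HELA_LIKE_EDGES))
}

#' Synthetic multi-cell-line panel
#'
#' Generates a panel of synthetic cell-line profiles by perturbing the
#' HeLa-S3-like base profile: each expressed protein's copy number is
#' drawn lognormally around the base value with a cross-line spread of
#' `sdlog` natural-log units (default 1.5, i.e. roughly +/- 1.3 orders
#' of magnitude at 2 sd, emulating the order-of-magnitude differences
#' between cell lines), and each partner is knocked out (zero copies)
#' with probability `dropout`. ITK and ZAP70, unexpressed in the base,
#' are given immune-lineage-like expression: present in a minority of
#' lines (probability `immune_frac`) at modest abundance.
#'
#' @param n_lines number of cell lines (default 45).
#' @param seed RNG seed.
#' @param sdlog cross-line lognormal spread (natural-log units).
#' @param dropout per-protein knockout probability.
#' @param immune_frac probability that ITK / ZAP70 are expressed.
#' @return named list of [cell_profile()]s.
#' @export
synthetic_cell_panel <- function(n_lines = 45, seed = 1, sdlog = 1.5,
                                 dropout = 0.1, immune_frac = 0.25) {
  stopifnot(n_lines >= 1, sdlog >= 0, dropout >= 0, dropout < 1)
  set.seed(seed)
  base <- .HELA_LIKE_COPIES
  immune <- c("ITK", "ZAP70")
  out <- vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    cp <- base
    vary <- names(cp)[cp > 0]
    cp[vary] <- cp[vary] * exp(stats::rnorm(length(vary), 0, sdlog))
    for (im in immune)
      if (stats::runif(1) < immune_frac)
        cp[im] <- 5e3 * exp(stats::rnorm(1, 0, sdlog))
    partners <- setdiff(names(cp), "IGF1R")
    ko <- partners[stats::runif(length(partners)) < dropout]
    cp[ko] <- 0
    out[[i]] <- cell_profile(sprintf("SYN%02d", i), cp, type = "synthetic")
  }
  names(out) <- vapply(out, function(p) p$name, character(1))
  out
}

#' Read the supplementary-style input tables
#'
#' Loads a copy-number table (protein x cell line, tab-separated) and
#' an interaction-map table (protein, site, KD_uM) in the documented
#' layouts, validates them, and optionally rescales relative-abundance
#' profiles onto an absolute IGF1R anchor. Unknown protein symbols are
#' excluded with a warning and reported.
#'
#' @param profiles_path path of the copy-number table.
#' @param map_path path of the interaction-map table.
#' @param relative character vector of cell-line names whose columns
#'   are relative abundances; they are rescaled with
#'   [rescale_profile()] using `anchor_igf1r`.
#' @param anchor_igf1r absolute IGF1R copies used as anchor.
#' @return list with `profiles` (named list of [cell_profile()]s),
#'   `map` (an [interaction_map()]) and `parse_report`.
#' @export
read_supplementary_tables <- function(profiles_path, map_path,
                                      relative = character(0),
                                      anchor_igf1r = NULL) {
  profiles <- read_cell_profiles(profiles_path)
  report <- attr(profiles, "parse_report")
  if (length(relative)) {
    if (is.null(anchor_igf1r))
      stop("anchor_igf1r is required to rescale relative profiles")
    for (ln in intersect(relative, names(profiles)))
      profiles[[ln]] <- rescale_profile(profiles[[ln]], anchor_igf1r)
  }
  map <- read_interaction_map(map_path)
  list(profiles = profiles, map = map, parse_report = report)
}
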