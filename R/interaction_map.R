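## Bipartite protein <-> phosphotyrosine-site interaction map with
## per-edge equilibrium dissociation constants.

#' Canonical IGF1R tyrosine sites and binding-partner symbols
#'
#' The six autophosphorylation sites of human IGF1R considered by the
#' model, and the panel of SH2/PTB-domain proteins (HGNC symbols) used
#' by the synthetic data generators.
#'
#' @export
IGF1R_SITES <- paste0("Y", c(973, 980, 1161, 1165, 1166, 1346))

#' @rdname IGF1R_SITES
#' @export
IGF1R_PARTNERS <- c("ABL2", "BLK", "CRK", "CRKL", "IRS1", "ITK",
                    "PIK3R1", "PIK3R2", "PIK3R3", "PLCG2", "RASA1",
                    "SHC1", "SRC", "STAT1", "SYK", "VAV2", "YES1",
                    "ZAP70")

#' Build a protein-site interaction map
#'
#' An interaction map lists which SH2/PTB-domain protein can bind which
#' receptor phosphotyrosine site, with an equilibrium dissociation
#' constant per edge. The association rate constant `ka` is shared by
#' all edges (default 1e6 per molar per second, a typical diffusion-
#' limited SH2-phosphopeptide on-rate); the per-edge off-rate follows as
#' `kd = ka * KD`. When a protein has multiple SH2/PTB domains measured
#' against the same site, supply multiple rows: the strongest (minimum)
#' `KD` is kept, on the assumption that the higher-affinity domain
#' dominates binding. An `NA` `KD` for IRS1 at Y980 is filled in as
#' 20-fold the SHC1 `KD` at that site (the PTB-domain affinity ratio
#' carried over from the insulin receptor).
#'
#' @param edges data frame with columns `protein`, `site`, `KD`
#'   (molar).
#' @param ka association rate constant, 1/(M s).
#' @param sites allowed site identifiers.
#' @return an `interaction_map` object: a data frame with columns
#'   `protein`, `site`, `KD`, `ka`, `kd`.
#' @export
interaction_map <- function(edges, ka = 1e6, sites = IGF1R_SITES) {
  stopifnot(is.data.frame(edges),
            all(c("protein", "site", "KD") %in% names(edges)),
            ka > 0)
  edges <- edges[, c("protein", "site", "KD")]
  edges$protein <- as.character(edges$protein)
  edges$site <- as.character(edges$site)
  bad <- setdiff(edges$site, sites)
  if (length(bad))
    stop("unknown site identifier(s): ", paste(bad, collapse = ", "))
  ## IRS1 rule: unmeasured IRS1 at Y980 inherits 20 x SHC1's KD there
  na_irs1 <- is.na(edges$KD) & edges$protein == "IRS1" & edges$site == "Y980"
  if (any(na_irs1)) {
    shc1 <- edges$KD[edges$protein == "SHC1" & edges$site == "Y980" &
                       !is.na(edges$KD)]
    if (length(shc1) == 0)
      stop("IRS1 KD at Y980 is NA and no SHC1 KD at Y980 to scale from")
    edges$KD[na_irs1] <- 20 * min(shc1)
  }
  if (any(is.na(edges$KD) | edges$KD <= 0))
    stop("all KD values must be positive (only IRS1@Y980 may be NA)")
  ## one edge per (site, protein): keep the minimum KD
  key <- paste(edges$protein, edges$site, sep = "\r")
  edges <- edges[order(key, edges$KD), ]
  edges <- edges[!duplicated(paste(edges$protein, edges$site, sep = "\r")), ]
  edges <- edges[order(match(edges$site, sites), edges$protein), ]
  edges$ka <- ka
  edges$kd <- ka * edges$KD
  rownames(edges) <- NULL
  structure(edges, class = c("interaction_map", "data.frame"),
            sites = sites)
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("interaction_map: %d edges, %d proteins, %d sites\n",
              nrow(x), length(unique(x$protein)), length(unique(x$site))))
  print.data.frame(x, ...)
  invisible(x)
}

## Edges of one site, or of one protein.
.site_edges <- function(map, site) map[map$site == site, , drop = FALSE]

## Minimum KD per protein across its edges (used by the kd and
## copy/kd ranking metrics).
.min_kd <- function(map) {
  tapply(map$KD, map$protein, min)
}

#' Read / write an interaction map in the supplementary-table layout
#'
#' Tab-separated, UTF-8, one header row; columns `protein` (HGNC
#' symbol), `site` (e.g. "Y980") and `KD_uM` (micromolar).
#'
#' @param path file path.
#' @param ka association rate constant passed to [interaction_map()].
#' @return for the reader, an `interaction_map`.
#' @export
read_interaction_map <- function(path, ka = 1e6) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "site", "KD_uM")
  if (!all(need %in% names(tab)))
    stop("interaction map table must have columns: ",
         paste(need, collapse = ", "))
  if (any(is.na(tab$KD_uM) | tab$KD_uM <= 0))
    stop("malformed KD_uM at line(s): ",
         paste(which(is.na(tab$KD_uM) | tab$KD_uM <= 0) + 1L, collapse = ", "))
  interaction_map(data.frame(protein = tab$protein, site = tab$site,
                             KD = tab$KD_uM * 1e-6), ka = ka)
}

#' @rdname read_interaction_map
#' @param map an `interaction_map` object.
#' @export
write_interaction_map <- function(map, path) {
  stopifnot(inherits(map, "interaction_map"))
  out <- data.frame(protein = map$protein, site = map$site,
                    KD_uM = map$KD * 1e6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-cell-line protein copy numbers
#'
#' A cell profile holds copies-per-cell for IGF1R and each candidate
#' binding partner of one cell line (or one sampled cell). Zero copies
#' means the protein is not expressed. Profiles from relative-abundance
#' proteomics carry `provenance = "relative"` and must be rescaled via
#' [rescale_profile()] before simulation.
#'
#' @param name cell line identifier.
#' @param copies named numeric vector of copies per cell; must include
#'   `IGF1R`.
#' @param type tissue/type tag (free text).
#' @param provenance `"absolute"` or `"relative"`.
#' @param anchor for relative profiles, the IGF1R copy number used as
#'   rescaling anchor (recorded by [rescale_profile()]).
#' @return a `cell_profile` object.
#' @export
cell_profile <- function(name, copies, type = NA_character_,
                         provenance = c("absolute", "relative"),
                         anchor = NA_real_) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(copies), !is.null(names(copies)))
  if (any(is.na(copies) | copies < 0))
    stop("copy numbers must be nonnegative")
  if (!"IGF1R" %in% names(copies))
    stop("profile must include IGF1R")
  structure(list(name = name, copies = copies, type = type,
                 provenance = provenance, anchor = anchor),
            class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("cell_profile '%s' (%s): IGF1R %.3g copies, %d partners expressed\n",
              x$name, x$provenance, x$copies[["IGF1R"]],
              sum(x$copies[names(x$copies) != "IGF1R"] > 0)))
  invisible(x)
}

#' Rescale a relative-abundance profile to absolute copy numbers
#'
#' Relative-abundance proteomics profiles are anchored on a reference
#' IGF1R copy number: all proteins are scaled by
#' `igf1r_copies / profile IGF1R value`, preserving partner/IGF1R
#' ratios.
#'
#' @param profile a [cell_profile()] with `provenance = "relative"`.
#' @param igf1r_copies absolute IGF1R copies per cell used as anchor.
#' @return an absolute-provenance `cell_profile`.
#' @export
rescale_profile <- function(profile, igf1r_copies) {
  stopifnot(inherits(profile, "cell_profile"), igf1r_copies > 0)
  if (profile$copies[["IGF1R"]] <= 0)
    stop("cannot anchor: profile has zero IGF1R")
  sc <- igf1r_copies / profile$copies[["IGF1R"]]
  cell_profile(profile$name, profile$copies * sc, type = profile$type,
               provenance = "absolute", anchor = igf1r_copies)
}

#' Read / write cell profiles in the supplementary-table layout
#'
#' Tab-separated, UTF-8, one header row: a `protein` column of HGNC
#' symbols and one numeric column of copies-per-cell per cell line.
#'
#' @param path file path.
#' @param known optional vector of recognized protein symbols
#'   (default: IGF1R plus [IGF1R_PARTNERS]); unknown rows are dropped
#'   with a warning.
#' @return for the reader, a named list of [cell_profile()] objects;
#'   the parse report (dropped symbols) is attached as attribute
#'   `"parse_report"`.
#' @export
read_cell_profiles <- function(path, known = c("IGF1R", IGF1R_PARTNERS)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"protein" %in% names(tab) || ncol(tab) < 2)
    stop("profile table must have a 'protein' column plus cell-line columns")
  unknown <- setdiff(tab$protein, known)
  if (length(unknown)) {
    warning(sprintf("%d unknown protein symbol(s) excluded: %s",
                    length(unknown), paste(unknown, collapse = ", ")))
    tab <- tab[tab$protein %in% known, , drop = FALSE]
  }
  lines <- setdiff(names(tab), "protein")
  bad <- which(vapply(tab[lines], function(v) any(is.na(suppressWarnings(as.numeric(v)))), logical(1)))
  if (length(bad))
    stop("non-numeric copy numbers in column(s): ",
         paste(lines[bad], collapse = ", "))
  profs <- lapply(lines, function(ln) {
    cp <- stats::setNames(as.numeric(tab[[ln]]), tab$protein)
    if (!"IGF1R" %in% names(cp))
      stop("profile '", ln, "' lacks an IGF1R row (anchor missing)")
    cell_profile(ln, cp)
  })
  names(profs) <- lines
  attr(profs, "parse_report") <- list(dropped = unknown,
                                      n_dropped = length(unknown))
  profs
}

#' @rdname read_cell_profiles
#' @param profiles a named list of [cell_profile()] objects.
#' @export
write_cell_profiles <- function(profiles, path) {
  if (inherits(profiles, "cell_profile")) profiles <- list(profiles)
  nm <- vapply(profiles, function(p) p$name, character(1))
  proteins <- Reduce(union, lapply(profiles, function(p) names(p$copies)))
  out <- data.frame(protein = proteins)
  for (i in seq_along(profiles)) {
    v <- profiles[[i]]$copies[proteins]
    v[is.na(v)] <- 0
    out[[nm[i]]] <- as.numeric(v)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
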