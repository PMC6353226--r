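## Ligand-configuration state space of the IGF1R dimer.
##
## Each preformed receptor dimer carries two equivalent ligand-binding
## pockets. A pocket is EMPTY, bound by one IGF1 at site S1 or at site
## S2, or CROSSLINKED (both sites engaged by the same IGF1). At most one
## pocket of a dimer can be crosslinked: crosslinking one pocket moves
## the S1/S2 sites of the other pocket too far apart to be bridged.

.POCKET_LEVELS <- c("CROSSLINKED", "EMPTY", "S1_BOUND", "S2_BOUND")

## Pocket state labels for a given ligand-species set. For a single
## unnamed ligand the labels are the four canonical ones; for multiple
## ligand species (e.g. tracer/competitor) the occupied states carry the
## ligand name as a suffix.
.pocket_states <- function(ligands = "") {
  if (identical(ligands, "")) return(.POCKET_LEVELS)
  c("EMPTY",
    unlist(lapply(c("S1_BOUND", "S2_BOUND", "CROSSLINKED"),
                  function(s) paste0(s, ".", ligands))))
}

.is_crosslinked <- function(pocket) startsWith(pocket, "CROSSLINKED")

## All admissible dimer configurations over a pocket alphabet: unordered
## pairs with at most one crosslinked pocket, ordered lexicographically
## by the canonical label (sorted pocket labels joined with "+").
.dimer_states <- function(pockets) {
  grid <- expand.grid(p1 = pockets, p2 = pockets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sorted <- t(apply(grid, 1, sort))
  keep <- !duplicated(sorted)
  st <- data.frame(pocket1 = sorted[keep, 1], pocket2 = sorted[keep, 2],
                   stringsAsFactors = FALSE)
  st <- st[!(.is_crosslinked(st$pocket1) & .is_crosslinked(st$pocket2)), ]
  st$active <- .is_crosslinked(st$pocket1) | .is_crosslinked(st$pocket2)
  st$label <- paste(st$pocket1, st$pocket2, sep = "+")
  st <- st[order(st$label), ]
  rownames(st) <- NULL
  st
}

#' Enumerate the ligand configurations of an IGF1R dimer
#'
#' Lists every admissible combination of the two binding-pocket states
#' (unordered; at most one pocket crosslinked), in deterministic
#' lexicographic order of the canonical label. With the single-ligand
#' pocket alphabet there are nine configurations, three of which are
#' crosslinked and hence kinase-active.
#'
#' @param ligands character vector of ligand species names; `""`
#'   (default) for a single unnamed ligand.
#' @return a data frame with columns `pocket1`, `pocket2` (pocket state
#'   labels, sorted within each row), `active` (TRUE if crosslinked) and
#'   `label` (canonical configuration key).
#' @examples
#' cfg <- enumerate_dimer_configs()
#' nrow(cfg)        # 9
#' sum(cfg$active)  # 3
#' @export
enumerate_dimer_configs <- function(ligands = "") {
  .dimer_states(.pocket_states(ligands))
}

## Pocket-level transition table for the cyclic binding scheme.
## Columns: from, to, const (name of the rate constant), ligand (ligand
## species for bimolecular association, NA otherwise), type in
## {"bind", "release", "iso"}. Crosslink-entry transitions are the ones
## that must be suppressed when the partner pocket is crosslinked.
.pocket_transitions <- function(ligands = "") {
  one <- function(lig) {
    sfx <- if (nzchar(lig)) paste0(".", lig) else ""
    s1 <- paste0("S1_BOUND", sfx); s2 <- paste0("S2_BOUND", sfx)
    x <- paste0("CROSSLINKED", sfx)
    data.frame(
      from  = c("EMPTY", s1, "EMPTY", s2, s1,    s2,    x,     x),
      to    = c(s1,      "EMPTY", s2, "EMPTY", x, x,     s1,    s2),
      const = c("a1", "d1", "a2", "d2", "a2p", "a1p", "d2p", "d1p"),
      ligand = c(lig, NA, lig, NA, NA, NA, NA, NA),
      type  = c("bind", "release", "bind", "release", "iso", "iso",
                "iso", "iso"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(ligands, one))
}

## Dimer-level transition list over the canonical configuration states.
## Applies each pocket transition to each pocket slot; transitions into
## a crosslinked state are blocked when the other pocket is crosslinked.
## Returns list(states, trans) where trans has columns from, to
## (state indices), const, ligand, type. Parallel (slot 1 vs slot 2)
## instances of the same macroscopic transition appear as separate rows
## so symmetric multiplicities (e.g. 2 a1 L out of EMPTY+EMPTY) are
## accounted for by summation.
.dimer_transitions <- function(ligands = "") {
  states <- .dimer_states(.pocket_states(ligands))
  pt <- .pocket_transitions(ligands)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "+")
  idx <- stats::setNames(seq_len(nrow(states)), states$label)
  rows <- list()
  for (s in seq_len(nrow(states))) {
    pk <- c(states$pocket1[s], states$pocket2[s])
    for (slot in 1:2) {
      other <- pk[3 - slot]
      tr <- pt[pt$from == pk[slot], , drop = FALSE]
      if (.is_crosslinked(other))
        tr <- tr[!.is_crosslinked(tr$to), , drop = FALSE]
      if (nrow(tr) == 0) next
      to_lab <- key(tr$to, other)
      rows[[length(rows) + 1L]] <- data.frame(
        from = s, to = unname(idx[to_lab]), const = tr$const,
        ligand = tr$ligand, type = tr$type, stringsAsFactors = FALSE)
    }
  }
  list(states = states, trans = do.call(rbind, rows))
}

## Generator matrix A (dx/dt = A %*% x) for the dimer-configuration
## process at fixed ligand concentrations. `ligand_conc` is a named
## vector (name "" allowed for the single-ligand alphabet).
.config_generator <- function(params, ligand_conc, ligands = names(ligand_conc)) {
  if (is.null(ligands)) ligands <- ""
  dt <- .dimer_transitions(ligands)
  n <- nrow(dt$states)
  A <- matrix(0, n, n)
  k <- vapply(seq_len(nrow(dt$trans)), function(i) {
    r <- params[[dt$trans$const[i]]]
    if (dt$trans$type[i] == "bind") {
      lig <- dt$trans$ligand[i]
      r <- r * ligand_conc[[if (nzchar(lig)) lig else 1L]]
    }
    r
  }, numeric(1))
  for (i in seq_len(nrow(dt$trans))) {
    A[dt$trans$to[i], dt$trans$from[i]] <- A[dt$trans$to[i], dt$trans$from[i]] + k[i]
    A[dt$trans$from[i], dt$trans$from[i]] <- A[dt$trans$from[i], dt$trans$from[i]] - k[i]
  }
  dimnames(A) <- list(dt$states$label, dt$states$label)
  A
}

## Stationary distribution of a generator matrix (columns = from), by
## replacing one balance equation with the normalization constraint.
.stationary <- function(A) {
  n <- nrow(A)
  M <- A
  M[n, ] <- 1
  x <- solve(M, c(rep(0, n - 1), 1))
  stats::setNames(pmax(x, 0) / sum(pmax(x, 0)), rownames(A))
}

## Number of ligand molecules (of each species) held by each dimer
## configuration; matrix states x ligands.
.ligand_load <- function(states, ligands = "") {
  occ <- function(pocket, lig) {
    sfx <- if (nzchar(lig)) paste0(".", lig) else ""
    as.numeric(pocket %in% paste0(c("S1_BOUND", "S2_BOUND", "CROSSLINKED"), sfx))
  }
  out <- sapply(ligands, function(l) occ(states$pocket1, l) + occ(states$pocket2, l))
  matrix(out, nrow = nrow(states), dimnames = list(states$label, ligands))
}
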