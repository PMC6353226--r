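## Independent oracles used by the tests. These deliberately re-derive
## quantities with different representations/algorithms than the
## package code paths they check.

## Closed-form equilibrium of the single-ligand dimer-configuration
## process for a detailed-balanced parameter set at clamped ligand L:
## the truncated state graph remains reversible, so the stationary
## distribution is proportional to products of per-pocket Boltzmann
## weights (with multiplicity 2 for mixed pairs), restricted to the
## admissible states.
boltzmann_config_equilibrium <- function(p, L) {
  w <- c(EMPTY = 1,
         S1_BOUND = p$a1 * L / p$d1,
         S2_BOUND = p$a2 * L / p$d2,
         CROSSLINKED = (p$a1 * L / p$d1) * (p$a2p / p$d2p))
  labs <- names(w)
  states <- list()
  for (i in seq_along(labs)) for (j in i:length(labs)) {
    if (labs[i] == "CROSSLINKED" && labs[j] == "CROSSLINKED") next
    key <- paste(sort(c(labs[i], labs[j])), collapse = "+")
    states[[key]] <- unname(w[i] * w[j]) * (if (i == j) 1 else 2)
  }
  v <- unlist(states)
  v / sum(v)
}

## Brute-force equilibrium of the two-ligand (tracer A / competitor B)
## system at clamped doses: independent enumeration of pocket pairs and
## transition rates, stationary solve, tracer molecules bound per dimer.
two_ligand_bound_oracle <- function(p, LA, LB) {
  pocket <- c("E", "1A", "1B", "2A", "2B", "XA", "XB")
  moves <- function(pk, other_x) {
    out <- list()
    addm <- function(to, rate) out[[length(out) + 1L]] <<- list(to = to, rate = rate)
    if (pk == "E") {
      addm("1A", p$a1 * LA); addm("1B", p$a1 * LB)
      addm("2A", p$a2 * LA); addm("2B", p$a2 * LB)
    } else if (pk %in% c("1A", "1B")) {
      addm("E", p$d1)
      if (!other_x) addm(sub("1", "X", pk), p$a2p)
    } else if (pk %in% c("2A", "2B")) {
      addm("E", p$d2)
      if (!other_x) addm(sub("2", "X", pk), p$a1p)
    } else {
      addm(sub("X", "1", pk), p$d2p)
      addm(sub("X", "2", pk), p$d1p)
    }
    out
  }
  keyf <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  keys <- character(0)
  for (i in seq_along(pocket)) for (j in i:length(pocket)) {
    if (startsWith(pocket[i], "X") && startsWith(pocket[j], "X")) next
    keys <- c(keys, keyf(pocket[i], pocket[j]))
  }
  keys <- sort(unique(keys))
  n <- length(keys)
  Q <- matrix(0, n, n, dimnames = list(keys, keys))
  for (k in keys) {
    pks <- strsplit(k, "|", fixed = TRUE)[[1]]
    for (slot in 1:2) {
      me <- pks[slot]; other <- pks[3 - slot]
      for (mv in moves(me, startsWith(other, "X"))) {
        to <- keyf(mv$to, other)
        Q[to, k] <- Q[to, k] + mv$rate
        Q[k, k] <- Q[k, k] - mv$rate
      }
    }
  }
  M <- Q
  M[n, ] <- 1
  pi <- solve(M, c(rep(0, n - 1), 1))
  names(pi) <- keys
  loadA <- vapply(keys, function(k) {
    pks <- strsplit(k, "|", fixed = TRUE)[[1]]
    sum(pks %in% c("1A", "2A", "XA"))
  }, numeric(1))
  list(states = keys, pi = pi, bound_tracer = sum(pi * loadA))
}

## Small fully specified toy fixtures.
toy_map_1s1p <- function(KD = 1e-6)
  interaction_map(data.frame(protein = "SHC1", site = "Y980", KD = KD))

toy_map_2s2p <- function()
  interaction_map(data.frame(
    protein = c("SHC1", "STAT1", "STAT1"),
    site = c("Y980", "Y980", "Y1161"),
    KD = c(1e-6, 5e-7, 2e-6)))

toy_profile <- function(copies, name = "toy") cell_profile(name, copies)

## Relative observable agreement along a trajectory.
expect_obs_equal <- function(net1, sol1, net2, sol2, rows, tol = 1e-6) {
  for (r in rows) {
    o1 <- network_observables(net1, sol1[r, -1])
    o2 <- network_observables(net2, sol2[r, -1])
    ref <- max(abs(unlist(o2)), 1e-15)
    expect_lt(max(abs(unlist(o1) - unlist(o2))) / ref, tol)
  }
}
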