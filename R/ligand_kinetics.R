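## Mass-action kinetics of IGF1 binding to IGF1R dimers over the
## dimer-configuration state space, with ligand either clamped at a
## fixed concentration (dose-controlled stimulation) or treated as a
## depleting pool.

#' Describe how free ligand is handled in a simulation
#'
#' `clamped_ligand()` holds the free ligand concentration fixed
#' (dose-controlled stimulation, the default protocol).
#' `depleting_ligand()` tracks free ligand as a dynamic pool consumed by
#' binding; the optional `volume` (litres) is only needed to convert
#' between molecule counts and concentrations.
#'
#' @param conc free ligand concentration in molar.
#' @param volume compartment volume in litres (depleting mode).
#' @return a `ligand_schedule` object.
#' @export
clamped_ligand <- function(conc) {
  stopifnot(is.numeric(conc), length(conc) == 1, conc >= 0)
  structure(list(mode = "clamped", conc = conc), class = "ligand_schedule")
}

#' @rdname clamped_ligand
#' @export
depleting_ligand <- function(conc, volume = 2e-12) {
  stopifnot(is.numeric(conc), length(conc) == 1, conc >= 0, volume > 0)
  structure(list(mode = "depleting", conc = conc, volume = volume),
            class = "ligand_schedule")
}

## Precompiled kinetic structure for a dimer-configuration system:
## transition rate constants, ligand index per bimolecular transition,
## and the +/-1 incidence matrix mapping transition fluxes to state
## derivatives. Concentration unit inside integrators is nanomolar.
.config_kinetics <- function(params, ligands = "") {
  dt <- .dimer_transitions(ligands)
  tr <- dt$trans
  n <- nrow(dt$states)
  inc <- matrix(0, n, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    inc[tr$from[i], i] <- inc[tr$from[i], i] - 1
    inc[tr$to[i], i] <- inc[tr$to[i], i] + 1
  }
  k <- vapply(tr$const, function(cn) params[[cn]], numeric(1))
  is_bind <- tr$type == "bind"
  k[is_bind] <- k[is_bind] * 1e-9  # second order: per nM per second
  list(states = dt$states, trans = tr, inc = inc, k = k,
       is_bind = is_bind, is_release = tr$type == "release",
       ligand_of = match(tr$ligand, ligands))
}

## Flux vector at receptor state xr (nM) and ligand concentrations
## lig (nM, one per ligand species).
.config_flux <- function(kin, xr, lig) {
  v <- kin$k * xr[kin$trans$from]
  v[kin$is_bind] <- v[kin$is_bind] * lig[kin$ligand_of[kin$is_bind]]
  v
}

#' Simulate IGF1 binding to receptor dimers
#'
#' Integrates the mass-action kinetics of the cyclic binding scheme over
#' the nine dimer configurations (plus the free-ligand pool when the
#' ligand depletes). The rate equations conserve the receptor-dimer
#' total; the trajectory is checked for relative drift.
#'
#' @param params a [ligand_params()] object.
#' @param receptor_dimers total receptor-dimer concentration, molar.
#' @param ligand a `ligand_schedule` (see [clamped_ligand()]), or a
#'   plain number interpreted as a clamped molar concentration.
#' @param t_grid increasing vector of output times in seconds, starting
#'   at 0.
#' @param init optional initial configuration concentrations (molar,
#'   length 9, canonical order); default all dimers ligand-free.
#' @param rtol,atol integrator tolerances (state in nanomolar units).
#' @return a data frame: `time`, one column per configuration label
#'   (molar), `crosslinked` (active dimer fraction) and `ligand` (free
#'   ligand, molar).
#' @export
simulate_ligand_binding <- function(params, receptor_dimers, ligand, t_grid,
                                    init = NULL, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "ligand_params"))
  if (!inherits(ligand, "ligand_schedule")) ligand <- clamped_ligand(ligand)
  if (receptor_dimers < 0 || ligand$conc < 0)
    stop("amounts must be nonnegative")
  if (length(t_grid) < 2 || is.unsorted(t_grid, strictly = TRUE) || t_grid[1] < 0)
    stop("t_grid must be strictly increasing and nonnegative")

  kin <- .config_kinetics(params, "")
  states <- kin$states
  n <- nrow(states)
  if (is.null(init)) {
    init <- numeric(n)
    init[states$label == "EMPTY+EMPTY"] <- receptor_dimers
  }
  if (length(init) != n || any(init < 0))
    stop("init must be a nonnegative vector over the 9 configurations")
  load <- .ligand_load(states, "")[, 1]

  x0 <- init * 1e9
  depleting <- ligand$mode == "depleting"
  if (depleting) x0 <- c(x0, ligand$conc * 1e9)

  rhs <- function(t, x, p) {
    lig <- if (depleting) max(x[n + 1], 0) else ligand$conc * 1e9
    v <- .config_flux(kin, x[1:n], lig)
    dx <- as.numeric(kin$inc %*% v)
    if (depleting)
      dx <- c(dx, sum(v[kin$is_release]) - sum(v[kin$is_bind]))
    list(dx)
  }
  sol <- deSolve::ode(y = x0, times = t_grid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integrator failure; final state (nM): ",
         paste(signif(sol[nrow(sol), -1], 4), collapse = ", "))
  conf <- sol[, 2:(n + 1), drop = FALSE] / 1e9
  drift <- abs(rowSums(conf) - receptor_dimers) /
    max(receptor_dimers, .Machine$double.eps)
  if (any(drift > 1e-8))
    warning(sprintf("receptor conservation drift up to %.2g", max(drift)))
  out <- data.frame(time = sol[, 1])
  out[states$label] <- conf
  out$crosslinked <- as.numeric(conf %*% states$active) /
    max(receptor_dimers, .Machine$double.eps)
  out$ligand <- if (depleting) sol[, n + 2] / 1e9 else ligand$conc
  attr(out, "states") <- states
  attr(out, "bound_ligand") <- as.numeric(conf %*% load)
  out
}

#' Equilibrium configuration distribution at fixed ligand
#'
#' Solves the linear stationary problem of the nine-configuration
#' process at a clamped free-ligand concentration.
#'
#' @param params a [ligand_params()] object.
#' @param conc clamped free ligand concentration, molar.
#' @return named probability vector over the nine configuration labels.
#' @export
equilibrium_configs <- function(params, conc) {
  stopifnot(inherits(params, "ligand_params"), conc >= 0)
  .stationary(.config_generator(params, c(conc)))
}

#' Equilibrium fraction of crosslinked (active) dimers
#'
#' @inheritParams equilibrium_configs
#' @return scalar in [0, 1].
#' @export
crosslinked_fraction <- function(params, conc) {
  pi <- equilibrium_configs(params, conc)
  st <- .dimer_states(.pocket_states(""))
  sum(pi[st$active])
}

## Integrate the two-ligand (tracer "A" / competitor "B") 25-state
## system at clamped ligand concentrations from a given start, until
## t_end or until the relative derivative norm drops below steady_tol.
.integrate_two_ligand <- function(params, x0, concs, t_out,
                                  rtol = 1e-10, atol = 1e-14) {
  kin <- .config_kinetics(params, c("A", "B"))
  n <- nrow(kin$states)
  lig <- c(concs[["A"]], concs[["B"]]) * 1e9
  rhs <- function(t, x, p) {
    v <- .config_flux(kin, x, lig)
    list(as.numeric(kin$inc %*% v))
  }
  sol <- deSolve::ode(y = x0, times = t_out, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integrator failure in two-ligand protocol")
  sol
}

#' Steady-state equilibrium competition curve
#'
#' Emulates the equilibrium competition protocol: a fixed dose of
#' labeled tracer IGF1 plus increasing doses of unlabeled competitor
#' (identical rate constants; the label is kinetically silent) are
#' incubated with receptor to steady state, and the bound-tracer signal
#' is reported normalized to its zero-competitor value. Both ligands
#' are clamped (large-reservoir incubation) and the 25-configuration
#' two-ligand system is integrated to steady state.
#'
#' @param params a [ligand_params()] object.
#' @param tracer_dose tracer concentration, molar.
#' @param competitor_doses vector of competitor concentrations, molar.
#' @param t_end integration horizon in seconds; steady state is reached
#'   well before the default for the published rate constants.
#' @return data frame with columns `dose` (competitor, molar), `bound`
#'   (tracer molecules bound per dimer) and `normalized` (bound divided
#'   by the zero-competitor value), rows ordered by dose.
#' @export
competition_equilibrium_curve <- function(params, tracer_dose, competitor_doses,
                                          t_end = 3e6) {
  stopifnot(inherits(params, "ligand_params"), tracer_dose > 0)
  if (length(competitor_doses) == 0) stop("empty competitor dose list")
  if (any(competitor_doses < 0)) stop("competitor doses must be nonnegative")
  states <- .dimer_states(.pocket_states(c("A", "B")))
  n <- nrow(states)
  loadA <- .ligand_load(states, c("A", "B"))[, "A"]
  x0 <- numeric(n)
  x0[states$label == "EMPTY+EMPTY"] <- 1  # dimer fractions
  bound_at <- function(comp) {
    sol <- .integrate_two_ligand(params, x0, c(A = tracer_dose, B = comp),
                                 c(0, t_end))
    sum(sol[2, -1] * loadA)
  }
  doses <- sort(unique(c(0, competitor_doses)))
  bound <- vapply(doses, bound_at, numeric(1))
  b0 <- bound[doses == 0]
  out <- data.frame(dose = doses, bound = bound, normalized = bound / b0)
  rownames(out) <- NULL
  out[out$dose %in% c(0, competitor_doses), , drop = FALSE]
}

#' Washout (ligand dissociation) curve
#'
#' Emulates the washout dissociation protocol: receptor is preincubated
#' with labeled tracer, free ligand is then removed (free tracer
#' clamped at zero), unlabeled competitor is added at a range of doses,
#' and the retained bound tracer is read after a chase period.
#' Retention at high competitor falls below retention in plain buffer:
#' competitor crosslinking of the second pocket blocks tracer
#' re-crosslinking and thereby accelerates its release — the signature
#' of the cyclic two-site binding mechanism.
#'
#' @param params a [ligand_params()] object.
#' @param tracer_dose preincubation tracer concentration, molar.
#' @param competitor_doses competitor concentrations during the chase,
#'   molar.
#' @param preincubation preincubation time, seconds (default 2 h).
#' @param chase chase durations, seconds (default 20 and 60 min).
#' @return data frame with columns `dose`, `chase` and `retained`
#'   (bound tracer relative to the end of preincubation).
#' @export
washout_dissociation_curve <- function(params, tracer_dose, competitor_doses,
                                       preincubation = 7200,
                                       chase = c(1200, 3600)) {
  stopifnot(inherits(params, "ligand_params"), tracer_dose > 0,
            preincubation > 0, all(chase >= 0))
  if (length(competitor_doses) == 0) stop("empty competitor dose list")
  if (any(competitor_doses < 0)) stop("competitor doses must be nonnegative")
  states <- .dimer_states(.pocket_states(c("A", "B")))
  n <- nrow(states)
  loadA <- .ligand_load(states, c("A", "B"))[, "A"]

  x0 <- numeric(n)
  x0[states$label == "EMPTY+EMPTY"] <- 1
  pre <- .integrate_two_ligand(params, x0, c(A = tracer_dose, B = 0),
                               c(0, preincubation))
  x_pre <- pre[2, -1]
  b0 <- sum(x_pre * loadA)

  chs <- sort(unique(chase))
  out <- expand.grid(dose = sort(unique(competitor_doses)), chase = chs,
                     KEEP.OUT.ATTRS = FALSE)
  out$retained <- NA_real_
  times <- unique(c(0, chs))
  for (d in unique(out$dose)) {
    traj <- .integrate_two_ligand(params, x_pre, c(A = 0, B = d), times)
    ret <- as.numeric(traj[, -1, drop = FALSE] %*% loadA) / b0
    out$retained[out$dose == d] <-
      ret[match(out$chase[out$dose == d], times)]
  }
  rownames(out) <- NULL
  out
}

#' Export a dose-response curve as CSV
#'
#' Writes a `(dose, value)` table with a header line naming the
#' protocol (and chase time, when applicable).
#'
#' @param curve data frame produced by [competition_equilibrium_curve()]
#'   or [washout_dissociation_curve()].
#' @param path output file.
#' @param protocol label written into the header comment.
#' @export
write_binding_curve <- function(curve, path, protocol = "competition") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protocol: %s", protocol), con)
  utils::write.csv(curve, con, row.names = FALSE)
  invisible(path)
}
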