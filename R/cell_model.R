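## Cell-line-specific recruitment models: assembly from a copy-number
## profile and an interaction map, steady states, time courses and dose
## responses.

#' Assemble a simulatable cell-line model
#'
#' Combines a copy-number profile with an interaction map and the
#' ligand-binding rate constants. Copy numbers are converted to molar
#' concentrations with a configurable cell volume; partners with zero
#' copies (not expressed) are dropped, so the generated network is
#' cell-line specific. Profiles without detectable IGF1R are rejected.
#'
#' @param profile a [cell_profile()] with absolute copy numbers.
#' @param map an [interaction_map()].
#' @param params a [ligand_params()] object (default: the published
#'   best-fit constants, detailed-balance completed).
#' @param volume cell volume in litres (default 2e-12).
#' @return a `cell_model` object.
#' @export
build_cell_model <- function(profile, map, params = table1_params(),
                             volume = 2e-12) {
  stopifnot(inherits(profile, "cell_profile"),
            inherits(map, "interaction_map"),
            inherits(params, "ligand_params"), volume > 0)
  if (profile$provenance == "relative")
    stop("relative-abundance profile: rescale with rescale_profile() first")
  igf1r <- profile$copies[["IGF1R"]]
  if (is.na(igf1r) || igf1r <= 0)
    stop(sprintf("profile '%s' rejected: IGF1R not detected", profile$name))
  copies <- profile$copies[setdiff(names(profile$copies), "IGF1R")]
  expressed <- names(copies)[copies > 0]
  emap <- map[map$protein %in% expressed, , drop = FALSE]
  partners <- sort(intersect(expressed, emap$protein))
  sites <- attr(map, "sites")

  forms <- lapply(sites, function(s) {
    e <- emap[emap$site == s, , drop = FALSE]
    list(site = s, partners = e$protein, ka = e$ka, kd = e$kd, KD = e$KD)
  })
  names(forms) <- sites

  structure(list(
    profile = profile, map = emap, full_map = map, params = params,
    volume = volume, sites = sites, partners = partners,
    igf1r_copies = igf1r,
    receptor_dimer_conc = copies_to_molar(igf1r / 2, volume),
    partner_copies = copies[partners],
    partner_conc = copies_to_molar(copies[partners], volume),
    forms = forms, cache = new.env(parent = emptyenv())),
    class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("cell_model '%s': %d partners, %d interaction edges, IGF1R %.3g copies\n",
              x$profile$name, length(x$partners), nrow(x$map), x$igf1r_copies))
  invisible(x)
}

## Restructured reaction network of a cell model (built lazily; the
## ligand dose only enters through the clamped initial concentration).
.cell_network <- function(model, dose_M) {
  if (is.null(model$cache$network)) {
    spec <- model_spec(map = structure(model$map,
                                       class = c("interaction_map", "data.frame"),
                                       sites = model$sites),
                       params = model$params,
                       receptor_dimers = model$receptor_dimer_conc,
                       ligand_conc = dose_M,
                       partner_conc = model$partner_conc,
                       sites = model$sites, ligand_mode = "clamped")
    model$cache$network <- generate_network(restructure(spec))
  }
  net <- model$cache$network
  ## clamped (and restructure-doubled) ligand concentration
  net$init[net$species$name == "IGF1"] <- 2 * dose_M
  net
}

## ---- algebraic steady state --------------------------------------------
##
## At a clamped ligand concentration the receptor species of each form
## obey linear kinetics given the free-partner concentrations, so the
## per-form distribution is the stationary vector of a
## 9*(2+n_i)-state generator. The free-partner concentrations are the
## only nonlinear unknowns and are closed by conservation
## (free + bound = total), solved by a damped fixed-point iteration.

## Precompute per-form constant structures for a given model.
.form_machinery <- function(model, dose_M) {
  key <- paste0("forms_", format(dose_M, digits = 17))
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  A9 <- .config_generator(model$params, c(dose_M))
  cfgs <- .dimer_states(.pocket_states(""))
  act <- which(cfgs$active)
  out <- lapply(model$forms, function(f) {
    n <- length(f$partners)
    m <- 9L * (2L + n)
    blk <- function(si) ((si - 1L) * 9L + 1L):(si * 9L)  # status block
    G0 <- matrix(0, m, m)
    for (si in seq_len(2L + n)) G0[blk(si), blk(si)] <- A9
    iu <- blk(1L); ip <- blk(2L)
    ## phosphorylation (active configs only) and dephosphorylation
    for (ci in act) {
      G0[ip[ci], iu[ci]] <- G0[ip[ci], iu[ci]] + model$params$kp
      G0[iu[ci], iu[ci]] <- G0[iu[ci], iu[ci]] - model$params$kp
    }
    for (ci in 1:9) {
      G0[iu[ci], ip[ci]] <- G0[iu[ci], ip[ci]] + model$params$kdp
      G0[ip[ci], ip[ci]] <- G0[ip[ci], ip[ci]] - model$params$kdp
    }
    ## partner release (constant); binding added per iteration
    bind_idx <- vector("list", n)
    for (j in seq_len(n)) {
      ib <- blk(2L + j)
      for (ci in 1:9) {
        G0[ip[ci], ib[ci]] <- G0[ip[ci], ib[ci]] + f$kd[j]
        G0[ib[ci], ib[ci]] <- G0[ib[ci], ib[ci]] - f$kd[j]
      }
      bind_idx[[j]] <- cbind(ib, ip)  # (row = b_j state, col = p state)
    }
    pdiag_idx <- cbind(ip, ip)
    list(site = f$site, partners = f$partners, ka = f$ka, m = m,
         G0 = G0, bind_idx = bind_idx, pdiag_idx = pdiag_idx,
         status_of = rep(seq_len(2L + n), each = 9L))
  })
  model$cache[[key]] <- out
  out
}

## Stationary distribution of a form generator given free-partner
## concentrations x (named molar vector over model partners).
.form_stationary <- function(fm, x) {
  G <- fm$G0
  if (length(fm$partners)) {
    rates <- fm$ka * as.numeric(x[fm$partners])
    for (j in seq_along(fm$partners))
      G[fm$bind_idx[[j]]] <- G[fm$bind_idx[[j]]] + rates[j]
    G[fm$pdiag_idx] <- G[fm$pdiag_idx] - sum(rates)
  }
  m <- fm$m
  G[m, ] <- 1
  pi <- solve(G, c(rep(0, m - 1L), 1))
  pmax(pi, 0) / sum(pmax(pi, 0))
}

## Core fixed-point solver. Returns list(bound matrix forms x partners
## in molar, free x, phospho per site, iterations, converged).
.algebraic_steady <- function(model, dose_M, copies_override = NULL,
                              tol = 1e-10, max_iter = 500) {
  partner_conc <- model$partner_conc
  r_dimer <- model$receptor_dimer_conc
  if (!is.null(copies_override)) {
    if ("IGF1R" %in% names(copies_override))
      r_dimer <- copies_to_molar(copies_override[["IGF1R"]] / 2, model$volume)
    shared <- intersect(names(copies_override), names(partner_conc))
    partner_conc[shared] <- copies_to_molar(copies_override[shared],
                                            model$volume)
  }
  fms <- .form_machinery(model, dose_M)
  partners <- model$partners
  np <- length(partners)
  r_form <- 2 * r_dimer  # decoupled single-site entities per form

  if (dose_M == 0 || np == 0) {
    ## no ligand -> no activation -> nothing bound; or no partners
    bound <- matrix(0, length(fms), np,
                    dimnames = list(names(fms), partners))
    pis <- lapply(fms, function(fm) .form_stationary(fm, stats::setNames(
      partner_conc * 0, partners)))
    phospho <- vapply(seq_along(fms), function(i)
      sum(pis[[i]][fms[[i]]$status_of >= 2L]), numeric(1))
    if (np > 0 && dose_M > 0) {
      ## no partners but ligand present: phospho from pis already right
    }
    return(list(bound = bound, free = partner_conc, phospho = phospho,
                pis = pis, r_form = r_form, iterations = 0L,
                converged = TRUE))
  }

  x <- partner_conc
  bound <- matrix(0, length(fms), np, dimnames = list(names(fms), partners))
  converged <- FALSE
  pis <- vector("list", length(fms))
  for (it in seq_len(max_iter)) {
    for (i in seq_along(fms)) {
      fm <- fms[[i]]
      pis[[i]] <- .form_stationary(fm, x)
      b <- numeric(np)
      if (length(fm$partners)) {
        bstat <- vapply(seq_along(fm$partners), function(j)
          sum(pis[[i]][fm$status_of == 2L + j]), numeric(1))
        b[match(fm$partners, partners)] <- r_form * bstat
      }
      bound[i, ] <- b
    }
    tot_bound <- colSums(bound)
    beta <- tot_bound / x
    x_new <- partner_conc / (1 + beta)
    delta <- max(abs(x_new - x) / partner_conc)
    x <- x_new
    if (delta < tol) { converged <- TRUE; break }
  }
  phospho <- vapply(seq_along(fms), function(i)
    sum(pis[[i]][fms[[i]]$status_of >= 2L]), numeric(1))
  list(bound = bound, free = x, phospho = phospho, pis = pis,
       r_form = r_form, iterations = it, converged = converged)
}

#' Simulate a cell model to steady state
#'
#' Computes the steady-state recruitment of every expressed partner at
#' a clamped IGF1 dose. Two routes are available: `"algebraic"`
#' (default) solves the per-form linear stationary problem coupled
#' through the shared free-partner pools by fixed-point iteration —
#' exact at steady state and fast enough for population-scale runs;
#' `"ode"` integrates the full restructured reaction network until the
#' relative derivative norm falls below `tol`. The two agree to
#' integrator accuracy.
#'
#' @param model a [build_cell_model()] object.
#' @param dose IGF1 dose in nanomolar.
#' @param method `"algebraic"` or `"ode"`.
#' @param tol convergence tolerance.
#' @param t_max ODE-route fallback horizon, seconds.
#' @return a `recruitment_result`: bound copies per partner, per-site
#'   phospho occupancy, crosslinked dimer fraction, free-partner
#'   copies, dose and bookkeeping fields.
#' @export
simulate_to_steady_state <- function(model, dose,
                                     method = c("algebraic", "ode"),
                                     tol = NULL, t_max = 1e5) {
  stopifnot(inherits(model, "cell_model"), dose >= 0)
  method <- match.arg(method)
  dose_M <- dose * 1e-9
  if (method == "algebraic") {
    sol <- .algebraic_steady(model, dose_M,
                             tol = if (is.null(tol)) 1e-10 else tol)
    if (!sol$converged)
      stop(sprintf("fixed-point iteration did not converge (%d iterations)",
                   sol$iterations))
    bound_conc <- colSums(sol$bound)
    res <- list(
      cell = model$profile$name, dose = dose,
      bound = molar_to_copies(bound_conc, model$volume),
      free = molar_to_copies(sol$free, model$volume),
      phospho = stats::setNames(sol$phospho, model$sites),
      crosslinked = crosslinked_fraction(model$params, dose_M),
      igf1r_copies = model$igf1r_copies, volume = model$volume,
      method = method, iterations = sol$iterations)
  } else {
    net <- .cell_network(model, dose_M)
    ss <- steady_state_network(net, tol = if (is.null(tol)) 1e-8 else tol,
                               t_max = t_max)
    if (!ss$converged)
      stop(sprintf("steady state not reached by t = %g s (residual %.3g)",
                   ss$time, ss$residual))
    obs <- network_observables(net, ss$state)
    site_total <- 2 * model$receptor_dimer_conc
    res <- list(
      cell = model$profile$name, dose = dose,
      bound = molar_to_copies(obs$bound[model$partners], model$volume),
      free = molar_to_copies(ss$state[match(model$partners,
                                            net$species$name)],
                             model$volume),
      phospho = obs$phospho / site_total,
      crosslinked = obs$crosslinked / model$receptor_dimer_conc,
      igf1r_copies = model$igf1r_copies, volume = model$volume,
      method = method, time = ss$time)
  }
  class(res) <- "recruitment_result"
  res
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat(sprintf("recruitment_result '%s' at %g nM IGF1 (%s)\n",
              x$cell, x$dose, x$method))
  ord <- order(-x$bound)
  print(round(x$bound[ord], 1))
  invisible(x)
}

#' Simulate a recruitment time course
#'
#' Integrates the restructured network from the resting state (all
#' receptors ligand-free and unphosphorylated, all partners free) at a
#' clamped IGF1 dose.
#'
#' @param model a [build_cell_model()] object.
#' @param dose IGF1 dose in nanomolar.
#' @param t_grid increasing output times (seconds) starting at 0.
#' @return a `recruitment_timecourse`: data frame with `time`, bound
#'   copies per partner, per-site phospho occupancy and the
#'   crosslinked fraction.
#' @export
simulate_timecourse <- function(model, dose, t_grid) {
  stopifnot(inherits(model, "cell_model"), dose >= 0)
  if (t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing and start at 0")
  net <- .cell_network(model, dose * 1e-9)
  sol <- simulate_network(net, t_grid)
  site_total <- 2 * model$receptor_dimer_conc
  rows <- lapply(seq_len(nrow(sol)), function(r) {
    obs <- network_observables(net, sol[r, -1])
    c(time = sol[r, 1],
      molar_to_copies(obs$bound[model$partners], model$volume),
      stats::setNames(obs$phospho / site_total, paste0("p", model$sites)),
      crosslinked = obs$crosslinked / model$receptor_dimer_conc)
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("recruitment_timecourse", "data.frame")
  out
}

#' Steady-state dose response
#'
#' @param model a [build_cell_model()] object.
#' @param doses IGF1 doses in nanomolar.
#' @param method solver passed to [simulate_to_steady_state()].
#' @return matrix of normalized recruitment (partners x doses), with
#'   the per-dose `recruitment_result`s attached as attribute
#'   `"results"`.
#' @export
dose_response <- function(model, doses, method = "algebraic") {
  stopifnot(inherits(model, "cell_model"), all(doses >= 0))
  results <- lapply(doses, function(d)
    simulate_to_steady_state(model, d, method = method))
  mat <- vapply(results, normalized_recruitment,
                numeric(length(model$partners)))
  mat <- matrix(mat, nrow = length(model$partners),
                dimnames = list(model$partners, as.character(doses)))
  attr(mat, "results") <- results
  mat
}

#' Normalized recruitment of a result
#'
#' Bound copies of each partner divided by the total amount of IGF1R.
#' The default denominator is IGF1R monomers (copies per cell); set
#' `denominator = "dimer"` to normalize by receptor dimers. The ratio
#' can exceed one because a single receptor presents multiple sites.
#'
#' @param result a `recruitment_result`.
#' @param denominator `"monomer"` (default) or `"dimer"`.
#' @return named vector of ratios.
#' @export
normalized_recruitment <- function(result, denominator = c("monomer", "dimer")) {
  stopifnot(inherits(result, "recruitment_result"))
  denominator <- match.arg(denominator)
  denom <- if (denominator == "monomer") result$igf1r_copies
           else result$igf1r_copies / 2
  if (denom <= 0) stop("undefined: zero IGF1R in denominator")
  result$bound / denom
}

#' Tidy export of recruitment results
#'
#' @param results a list of `recruitment_result`s.
#' @param path CSV output path.
#' @return the tidy data frame, invisibly written to `path` if given.
#' @export
recruitment_table <- function(results, path = NULL) {
  if (inherits(results, "recruitment_result")) results <- list(results)
  rows <- lapply(results, function(r)
    data.frame(cell = r$cell, protein = names(r$bound), dose = r$dose,
               bound = as.numeric(r$bound),
               normalized = as.numeric(normalized_recruitment(r))))
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
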