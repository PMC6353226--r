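## Generation of the mass-action reaction network implied by the
## binding / phosphorylation / recruitment rules, in two formulations:
##
## * the natural formulation, which tracks complete dimer states (both
##   pockets and all tyrosine sites jointly, symmetry-deduplicated) and
##   is tractable only for small instances — it serves as the exactness
##   oracle;
## * the restructured formulation obtained by decoupling (each tyrosine
##   lives on its own receptor form), bunching (the four ligand-contact
##   sites are represented as two pocket variables) and scaling
##   (receptor and ligand amounts doubled, the bimolecular association
##   rates a1 and a2 halved), which shrinks the state space without
##   approximation.

#' Specify a receptor-recruitment model instance
#'
#' Collects everything needed to generate a reaction network: the
#' tyrosine sites, the binding partners and their interaction map, the
#' ligand-binding rate constants and the abundances.
#'
#' @param map an [interaction_map()]; its edges define which partner
#'   binds which site.
#' @param params a [ligand_params()] object.
#' @param receptor_dimers total receptor-dimer concentration, molar.
#' @param ligand_conc IGF1 concentration (dose), molar.
#' @param partner_conc named vector of total partner concentrations,
#'   molar; proteins at zero are dropped.
#' @param sites ordered site identifiers.
#' @param ligand_mode `"clamped"` (default) or `"depleting"`.
#' @return a `model_spec` object.
#' @export
model_spec <- function(map, params, receptor_dimers, ligand_conc,
                       partner_conc, sites = IGF1R_SITES,
                       ligand_mode = c("clamped", "depleting")) {
  ligand_mode <- match.arg(ligand_mode)
  stopifnot(inherits(map, "interaction_map"),
            inherits(params, "ligand_params"),
            receptor_dimers >= 0, ligand_conc >= 0,
            !is.null(names(partner_conc)))
  if (anyDuplicated(sites)) stop("site identifiers must be unique")
  partner_conc <- partner_conc[partner_conc > 0]
  partners <- sort(names(partner_conc))
  map <- map[map$site %in% sites & map$protein %in% partners, , drop = FALSE]
  dangling <- setdiff(partners, map$protein)
  partners <- setdiff(partners, dangling)  # partners without edges are inert
  partner_conc <- partner_conc[partners]
  structure(list(sites = sites, partners = partners, map = map,
                 params = params, receptor_dimers = receptor_dimers,
                 ligand_conc = ligand_conc, partner_conc = partner_conc,
                 ligand_mode = ligand_mode, restructured = FALSE),
            class = "model_spec")
}

#' Restructure a model specification
#'
#' Applies the three exact state-reduction transformations: bunching
#' (pocket-level ligand states — already intrinsic to the
#' configuration alphabet used here), decoupling (each of the tyrosine
#' sites becomes its own single-site receptor form) and scaling
#' (receptor and ligand abundances doubled; the second-order rates a1
#' and a2 halved, so each form with one site stands in for the two
#' copies of that site in a dimer). The observable mapping back to
#' natural units is attached as attribute `"observable_map"`:
#' bound-partner and phospho-site observables carry factor 1, the
#' crosslinked-dimer and free-ligand observables factor 1/2.
#'
#' @param spec a [model_spec()].
#' @return a restructured `model_spec`.
#' @export
restructure <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$restructured) return(spec)
  p <- spec$params
  p$a1 <- p$a1 / 2
  p$a2 <- p$a2 / 2
  out <- spec
  out$params <- p
  out$receptor_dimers <- 2 * spec$receptor_dimers  # per-form entities
  out$ligand_conc <- 2 * spec$ligand_conc
  out$restructured <- TRUE
  attr(out, "observable_map") <- list(bound = 1, phospho = 1,
                                      crosslinked = 0.5, ligand = 0.5)
  out
}

.status_labels <- function(partners) c("u", "p", paste0("b:", partners))

#' Generate the restructured reaction network
#'
#' Enumerates all species and elementary mass-action reactions of the
#' restructured formulation: one receptor form per tyrosine site, each
#' form combining the 9 dimer ligand configurations with `2 + n_i` site
#' statuses (unphosphorylated, phospho-free, or phospho-bound to one of
#' the site's `n_i` partners), plus the free ligand and the free
#' partner pools. Phosphorylation fires only on crosslinked (active)
#' configurations; dephosphorylation only on phospho-free sites;
#' recruitment requires phosphorylation but not activity and persists
#' after de-crosslinking.
#'
#' @param spec a restructured [model_spec()] (see [restructure()]).
#' @return a `reaction_network` object.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$restructured)
    stop("generate_network expects a restructured spec; see restructure()")
  sites <- spec$sites
  partners <- spec$partners
  cfg <- .dimer_states(.pocket_states(""))
  ncfg <- nrow(cfg)
  load <- .ligand_load(cfg, "")[, 1]

  species <- data.frame(name = "IGF1", type = "ligand", form = NA,
                        config = NA, status = NA, nligand = 0,
                        stringsAsFactors = FALSE)
  if (length(partners))
    species <- rbind(species,
                     data.frame(name = partners, type = "protein", form = NA,
                                config = NA, status = NA, nligand = 0))
  for (s in sites) {
    n_i <- spec$map$protein[spec$map$site == s]
    st <- .status_labels(n_i)
    grid <- expand.grid(config = cfg$label, status = st,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    species <- rbind(species, data.frame(
      name = sprintf("R[%s][%s][%s]", s, grid$config, grid$status),
      type = "receptor", form = s, config = grid$config,
      status = grid$status,
      nligand = load[match(grid$config, cfg$label)]))
  }
  idx <- stats::setNames(seq_len(nrow(species)), species$name)
  rname <- function(s, c, st) sprintf("R[%s][%s][%s]", s, c, st)

  dt <- .dimer_transitions("")
  rx <- vector("list", 4096); nr <- 0L
  add <- function(r1, r2, p1, p2, k) {
    nr <<- nr + 1L
    if (nr > length(rx)) length(rx) <<- 2L * nr
    rx[[nr]] <<- c(r1, ifelse(is.na(r2), 0L, r2), p1,
                   ifelse(is.na(p2), 0L, p2), k)
  }
  lig <- idx[["IGF1"]]
  for (s in sites) {
    n_i <- spec$map$protein[spec$map$site == s]
    kd_i <- stats::setNames(spec$map$kd[spec$map$site == s], n_i)
    ka_i <- stats::setNames(spec$map$ka[spec$map$site == s], n_i)
    st <- .status_labels(n_i)
    for (status in st) {
      ## ligand-configuration moves (status unchanged)
      for (i in seq_len(nrow(dt$trans))) {
        from <- idx[[rname(s, cfg$label[dt$trans$from[i]], status)]]
        to <- idx[[rname(s, cfg$label[dt$trans$to[i]], status)]]
        k <- spec$params[[dt$trans$const[i]]]
        type <- dt$trans$type[i]
        if (type == "bind") add(from, lig, to, NA, k)
        else if (type == "release") add(from, NA, to, lig, k)
        else add(from, NA, to, NA, k)
      }
    }
    for (ci in seq_len(ncfg)) {
      cl <- cfg$label[ci]
      if (cfg$active[ci])  # phosphorylation only on active dimers
        add(idx[[rname(s, cl, "u")]], NA, idx[[rname(s, cl, "p")]], NA,
            spec$params$kp)
      add(idx[[rname(s, cl, "p")]], NA, idx[[rname(s, cl, "u")]], NA,
          spec$params$kdp)
      for (j in n_i) {
        add(idx[[rname(s, cl, "p")]], idx[[j]],
            idx[[rname(s, cl, paste0("b:", j))]], NA, ka_i[[j]])
        add(idx[[rname(s, cl, paste0("b:", j))]], NA,
            idx[[rname(s, cl, "p")]], idx[[j]], kd_i[[j]])
      }
    }
  }
  reactions <- do.call(rbind, rx[seq_len(nr)])
  colnames(reactions) <- c("r1", "r2", "p1", "p2", "k")

  init <- numeric(nrow(species))
  init[lig] <- spec$ligand_conc
  init[match(partners, species$name)] <- spec$partner_conc[partners]
  free_form <- rname(sites, "EMPTY+EMPTY", "u")
  init[match(free_form, species$name)] <- spec$receptor_dimers

  .finish_network(species, reactions, init,
                  clamped = if (spec$ligand_mode == "clamped") lig else integer(0),
                  formulation = "restructured", spec = spec)
}

## Assemble the network object: sparse stoichiometry, reactant index
## vectors, conservation-law basis.
.finish_network <- function(species, reactions, init, clamped,
                            formulation, spec, dimer_info = NULL) {
  nsp <- nrow(species)
  nr <- nrow(reactions)
  ii <- c(reactions[, "r1"], reactions[, "r2"], reactions[, "p1"],
          reactions[, "p2"])
  jj <- rep(seq_len(nr), 4)
  vv <- rep(c(-1, -1, 1, 1), each = nr)
  keep <- ii > 0
  S <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = vv[keep],
                            dims = c(nsp, nr))
  net <- structure(list(species = species, reactions = reactions,
                        stoich = S, init = init, clamped = clamped,
                        formulation = formulation, spec = spec,
                        dimer_info = dimer_info),
                   class = "reaction_network")
  net$conservation <- conservation_basis(net)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("reaction_network (%s): %d species, %d reactions%s\n",
              x$formulation, nrow(x$species), nrow(x$reactions),
              if (length(x$clamped)) ", ligand clamped" else ""))
  invisible(x)
}

#' Generate the natural-formulation network (small instances)
#'
#' Enumerates the unreduced dimer state space — both pockets and all
#' tyrosine sites of both protomers jointly, deduplicated under the
#' protomer-exchange symmetry — together with the same binding,
#' phosphorylation and recruitment rules. Intended as an exactness
#' oracle on toy instances; refuses to enumerate above `size_cap`.
#'
#' @param spec a non-restructured [model_spec()].
#' @param size_cap maximum admissible species count (default 20000).
#' @return a `reaction_network` object.
#' @export
generate_natural_network <- function(spec, size_cap = 20000) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$restructured)
    stop("generate_natural_network expects the natural (non-restructured) spec")
  sites <- spec$sites
  partners <- spec$partners
  st_per_site <- lapply(sites, function(s)
    .status_labels(spec$map$protein[spec$map$site == s]))
  tuples_per_protomer <- 4 * prod(vapply(st_per_site, length, 1L))
  x_tuples <- prod(vapply(st_per_site, length, 1L))
  est <- tuples_per_protomer * (tuples_per_protomer + 1) / 2 -
    x_tuples * (x_tuples + 1) / 2 + 1 + length(partners)
  if (est > size_cap)
    stop(sprintf("natural formulation would contain %.4g species (cap %d)",
                 est, size_cap))

  ## protomer tuples: pocket state x per-site status
  pockets <- .pocket_states("")
  status_grid <- expand.grid(st_per_site, KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
  names(status_grid) <- sites
  protomer_key <- function(pocket, statuses)
    paste(pocket, paste(statuses, collapse = ","), sep = "|")
  protomers <- list()
  for (pk in pockets)
    for (r in seq_len(nrow(status_grid)))
      protomers[[protomer_key(pk, as.character(status_grid[r, ]))]] <-
        list(pocket = pk, statuses = as.character(status_grid[r, ]))

  pkeys <- names(protomers)
  dimer_key <- function(k1, k2) paste(sort(c(k1, k2)), collapse = " ++ ")
  dimers <- character(0)
  for (a in seq_along(pkeys)) for (b in a:length(pkeys)) {
    p1 <- protomers[[pkeys[a]]]; p2 <- protomers[[pkeys[b]]]
    if (.is_crosslinked(p1$pocket) && .is_crosslinked(p2$pocket)) next
    dimers <- c(dimers, dimer_key(pkeys[a], pkeys[b]))
  }
  dimers <- sort(unique(dimers))

  species <- data.frame(name = c("IGF1", partners, dimers),
                        type = c("ligand", rep("protein", length(partners)),
                                 rep("receptor", length(dimers))),
                        form = NA, config = NA, status = NA,
                        nligand = 0, stringsAsFactors = FALSE)
  is_dimer <- species$type == "receptor"
  idx <- stats::setNames(seq_len(nrow(species)), species$name)
  lig <- idx[["IGF1"]]

  split_dimer <- function(key) {
    ks <- strsplit(key, " ++ ", fixed = TRUE)[[1]]
    lapply(ks, function(k) protomers[[k]])
  }
  nlig <- function(prots) sum(vapply(prots, function(p)
    p$pocket != "EMPTY", logical(1)))
  active <- function(prots) any(vapply(prots, function(p)
    .is_crosslinked(p$pocket), logical(1)))
  species$nligand[is_dimer] <- vapply(species$name[is_dimer], function(k)
    nlig(split_dimer(k)), numeric(1))

  pt <- .pocket_transitions("")
  rx <- list(); nr <- 0L
  add <- function(r1, r2, p1, p2, k) {
    nr <<- nr + 1L
    rx[[nr]] <<- c(r1, ifelse(is.na(r2), 0L, r2), p1,
                   ifelse(is.na(p2), 0L, p2), k)
  }
  kd_edge <- function(s, j) spec$map$kd[spec$map$site == s & spec$map$protein == j]
  ka_edge <- function(s, j) spec$map$ka[spec$map$site == s & spec$map$protein == j]

  for (key in dimers) {
    prots <- split_dimer(key)
    from <- idx[[key]]
    act <- active(prots)
    for (slot in 1:2) {
      me <- prots[[slot]]; other <- prots[[3 - slot]]
      ## pocket transitions
      tr <- pt[pt$from == me$pocket, , drop = FALSE]
      if (.is_crosslinked(other$pocket))
        tr <- tr[!.is_crosslinked(tr$to), , drop = FALSE]
      for (i in seq_len(nrow(tr))) {
        new <- me; new$pocket <- tr$to[i]
        to <- idx[[dimer_key(protomer_key(new$pocket, new$statuses),
                             protomer_key(other$pocket, other$statuses))]]
        k <- spec$params[[tr$const[i]]]
        if (tr$type[i] == "bind") add(from, lig, to, NA, k)
        else if (tr$type[i] == "release") add(from, NA, to, lig, k)
        else add(from, NA, to, NA, k)
      }
      ## site status transitions on this protomer
      for (si in seq_along(sites)) {
        stt <- me$statuses[si]
        emit <- function(newst, r2, p2, k) {
          new <- me; new$statuses[si] <- newst
          to <- idx[[dimer_key(protomer_key(new$pocket, new$statuses),
                               protomer_key(other$pocket, other$statuses))]]
          add(from, r2, to, p2, k)
        }
        if (stt == "u") {
          if (act) emit("p", NA, NA, spec$params$kp)
        } else if (stt == "p") {
          emit("u", NA, NA, spec$params$kdp)
          for (j in spec$map$protein[spec$map$site == sites[si]])
            emit(paste0("b:", j), idx[[j]], NA, ka_edge(sites[si], j))
        } else {
          j <- sub("^b:", "", stt)
          emit2 <- function() {
            new <- me; new$statuses[si] <- "p"
            to <- idx[[dimer_key(protomer_key(new$pocket, new$statuses),
                                 protomer_key(other$pocket, other$statuses))]]
            add(from, NA, to, idx[[j]], kd_edge(sites[si], j))
          }
          emit2()
        }
      }
    }
  }
  reactions <- do.call(rbind, rx)
  colnames(reactions) <- c("r1", "r2", "p1", "p2", "k")

  init <- numeric(nrow(species))
  init[lig] <- spec$ligand_conc
  init[match(partners, species$name)] <- spec$partner_conc[partners]
  empty_key <- dimer_key(protomer_key("EMPTY", rep("u", length(sites))),
                         protomer_key("EMPTY", rep("u", length(sites))))
  init[idx[[empty_key]]] <- spec$receptor_dimers

  ## per-dimer annotation used by observables and conservation laws
  dimer_info <- list(
    active = vapply(species$name[is_dimer], function(k) active(split_dimer(k)),
                    logical(1)),
    bound_count = matrix(
      unlist(lapply(partners, function(j)
        vapply(species$name[is_dimer], function(k)
          sum(vapply(split_dimer(k), function(p)
            sum(p$statuses == paste0("b:", j)), numeric(1))), numeric(1)))),
      ncol = length(partners), dimnames = list(NULL, partners)),
    phospho_count = matrix(
      unlist(lapply(seq_along(sites), function(si)
        vapply(species$name[is_dimer], function(k)
          sum(vapply(split_dimer(k), function(p)
            as.numeric(p$statuses[si] != "u"), numeric(1))), numeric(1)))),
      ncol = length(sites), dimnames = list(NULL, sites)))

  .finish_network(species, reactions, init,
                  clamped = if (spec$ligand_mode == "clamped") lig
                            else integer(0),
                  formulation = "natural", spec = spec,
                  dimer_info = dimer_info)
}

#' Mass-action derivative of a reaction network
#'
#' Standard elementary mass-action rate law: every reaction has order
#' at most two, the flux is the rate constant times the product of its
#' reactant concentrations, and the species derivative is the
#' stoichiometry-weighted sum of fluxes. Clamped species (the ligand
#' under dose control) have derivative zero.
#'
#' @param network a `reaction_network`.
#' @param state species concentrations (molar), in network species
#'   order.
#' @return derivative vector, molar per second.
#' @export
mass_action_rhs <- function(network, state) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(state) != nrow(network$species))
    stop("state length must equal the species count")
  rx <- network$reactions
  v <- rx[, "k"] * state[rx[, "r1"]]
  bi <- rx[, "r2"] > 0
  v[bi] <- v[bi] * state[rx[bi, "r2"]]
  dx <- as.numeric(network$stoich %*% v)
  dx[network$clamped] <- 0
  dx
}

#' Conservation-law basis of a network
#'
#' Returns a matrix whose rows are left null vectors of the (effective)
#' stoichiometry: total receptor per form (or total dimers), total of
#' each partner protein (free plus bound), and the total ligand when
#' the ligand pool depletes.
#'
#' @param network a `reaction_network`.
#' @return matrix (laws x species) with named rows.
#' @export
conservation_basis <- function(network) {
  sp <- network$species
  spec <- network$spec
  laws <- list()
  if (network$formulation == "restructured") {
    for (s in spec$sites) {
      v <- as.numeric(sp$type == "receptor" & sp$form == s)
      laws[[paste0("form_", s)]] <- v
    }
  } else {
    laws[["dimers"]] <- as.numeric(sp$type == "receptor")
  }
  for (j in spec$partners) {
    v <- as.numeric(sp$name == j)
    if (network$formulation == "restructured") {
      v <- v + as.numeric(sp$type == "receptor" &
                            !is.na(sp$status) & sp$status == paste0("b:", j))
    } else {
      bc <- network$dimer_info$bound_count
      if (!is.null(bc)) v[sp$type == "receptor"] <-
          v[sp$type == "receptor"] + bc[, j]
    }
    laws[[paste0("total_", j)]] <- v
  }
  if (length(network$clamped) == 0 &&
      (network$formulation == "natural" || length(spec$sites) == 1)) {
    v <- as.numeric(sp$name == "IGF1") + sp$nligand
    laws[["ligand"]] <- v
  }
  do.call(rbind, laws)
}

#' Integrate a reaction network
#'
#' @param network a `reaction_network`.
#' @param times output times, seconds (increasing, starting at 0).
#' @param init optional initial state (molar); defaults to the
#'   network's initial condition.
#' @param rtol,atol integrator tolerances (applied on nanomolar-scaled
#'   states).
#' @return matrix with a `time` column and one column per species
#'   (molar).
#' @export
simulate_network <- function(network, times, init = NULL,
                             rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(init)) init <- network$init
  if (any(init < 0)) stop("initial amounts must be nonnegative")
  x0 <- init * 1e9
  rx <- network$reactions
  k <- rx[, "k"]
  bi <- rx[, "r2"] > 0
  k[bi] <- k[bi] * 1e-9  # bimolecular rate per nM
  S <- network$stoich
  clamped <- network$clamped
  rhs <- function(t, x, p) {
    v <- k * x[rx[, "r1"]]
    v[bi] <- v[bi] * x[rx[bi, "r2"]]
    dx <- as.numeric(S %*% v)
    dx[clamped] <- 0
    list(dx)
  }
  sol <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integrator failure at t = ", sol[nrow(sol), 1])
  out <- sol
  out[, -1] <- out[, -1] / 1e9
  colnames(out) <- c("time", network$species$name)
  out
}

#' Integrate a network to steady state
#'
#' Integrates in geometrically growing time chunks until the relative
#' derivative norm `||dx/dt|| / (||x|| + eps)` falls below `tol`, or
#' errors (carrying the last state and residual) at `t_max`.
#'
#' @param network a `reaction_network`.
#' @param tol relative derivative-norm criterion (default 1e-8 1/s).
#' @param t_max horizon in seconds.
#' @param init optional initial state.
#' @return list with `state` (molar), `time`, `residual`.
#' @export
steady_state_network <- function(network, tol = 1e-8, t_max = 1e5,
                                 init = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  state <- if (is.null(init)) network$init else init
  t_now <- 0
  t_chunk <- 10
  repeat {
    sol <- simulate_network(network, c(0, t_chunk), init = state)
    state <- sol[nrow(sol), -1]
    t_now <- t_now + t_chunk
    dx <- mass_action_rhs(network, state)
    res <- sqrt(sum(dx^2)) / (sqrt(sum(state^2)) + .Machine$double.eps)
    if (res < tol)
      return(list(state = state, time = t_now, residual = res,
                  converged = TRUE))
    if (t_now >= t_max) {
      warning(sprintf("steady state not reached by t = %g s (residual %.3g)",
                      t_now, res))
      return(list(state = state, time = t_now, residual = res,
                  converged = FALSE))
    }
    t_chunk <- min(t_chunk * 4, t_max - t_now)
  }
}

#' Observables of a network state, in natural model units
#'
#' Computes the mapped observables shared by the two formulations:
#' bound concentration per partner, phosphorylated concentration per
#' site (phospho-free plus bound, counting site copies), the
#' crosslinked-dimer concentration and the free ligand. For the
#' restructured formulation the scaling factors recorded by
#' [restructure()] are applied, so the two formulations report
#' identical quantities.
#'
#' @param network a `reaction_network`.
#' @param state species concentrations (molar).
#' @return list with `bound` (named), `phospho` (named),
#'   `crosslinked`, `ligand`.
#' @export
network_observables <- function(network, state) {
  sp <- network$species
  spec <- network$spec
  if (network$formulation == "restructured") {
    fmap <- attr(spec, "observable_map")
    bound <- vapply(spec$partners, function(j)
      sum(state[sp$type == "receptor" & !is.na(sp$status) &
                  sp$status == paste0("b:", j)]), numeric(1)) * fmap$bound
    phospho <- vapply(spec$sites, function(s)
      sum(state[sp$type == "receptor" & sp$form == s &
                  sp$status != "u"]), numeric(1)) * fmap$phospho
    cfg <- .dimer_states(.pocket_states(""))
    s1 <- spec$sites[1]
    recs <- sp$type == "receptor" & sp$form == s1
    xl <- sum(state[recs][cfg$active[match(sp$config[recs], cfg$label)]]) *
      fmap$crosslinked
    ligand <- state[sp$name == "IGF1"] * fmap$ligand
  } else {
    di <- network$dimer_info
    recs <- sp$type == "receptor"
    bound <- if (length(spec$partners))
      as.numeric(state[recs] %*% di$bound_count) else numeric(0)
    names(bound) <- spec$partners
    phospho <- as.numeric(state[recs] %*% di$phospho_count)
    names(phospho) <- spec$sites
    xl <- sum(state[recs][di$active])
    ligand <- state[sp$name == "IGF1"]
  }
  list(bound = bound, phospho = phospho, crosslinked = xl,
       ligand = unname(ligand))
}

#' Export a network as a plain-text reaction list
#'
#' Writes a species table (name, initial concentration) and a reaction
#' table (reactants, products, rate constant) separated by blank lines.
#'
#' @param network a `reaction_network`.
#' @param path output file.
#' @export
write_network <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s formulation: %d species, %d reactions",
                     network$formulation, nrow(network$species),
                     nrow(network$reactions)), con)
  writeLines("begin species", con)
  writeLines(sprintf("%s\t%.17g", network$species$name, network$init), con)
  writeLines("end species", con)
  writeLines("begin reactions", con)
  nm <- network$species$name
  rx <- network$reactions
  lhs <- ifelse(rx[, "r2"] > 0, paste(nm[rx[, "r1"]], nm[rx[, "r2"]],
                                      sep = " + "), nm[rx[, "r1"]])
  rhs <- ifelse(rx[, "p2"] > 0, paste(nm[rx[, "p1"]], nm[rx[, "p2"]],
                                      sep = " + "), nm[rx[, "p1"]])
  writeLines(sprintf("%s -> %s\t%.17g", lhs, rhs, rx[, "k"]), con)
  writeLines("end reactions", con)
  invisible(path)
}
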