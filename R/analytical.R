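## Analytical single-occupancy equilibrium approximation of competitive
## recruitment: each active receptor is assumed to bind at most one
## partner at a time, which closes the equilibrium into one scalar
## balance equation for the free active receptor concentration.

#' Inputs of the analytical recruitment approximation
#'
#' @param R_tot total active receptor concentration, molar.
#' @param X_tot named vector of total partner concentrations, molar.
#' @param K named vector of apparent per-partner dissociation
#'   constants, molar (same names as `X_tot`).
#' @return an `analytical_inputs` object.
#' @export
analytical_inputs <- function(R_tot, X_tot, K) {
  stopifnot(R_tot >= 0, all(X_tot >= 0), all(K > 0),
            identical(sort(names(X_tot)), sort(names(K))))
  K <- K[names(X_tot)]
  structure(list(R_tot = R_tot, X_tot = X_tot, K = K),
            class = "analytical_inputs")
}

#' Solve the free active receptor balance
#'
#' Finds the unique nonnegative root `R` of
#' `R * (1 + sum_i X_i_tot / (K_i + R)) = R_tot`. The left-hand side is
#' strictly increasing in `R`, is 0 at `R = 0` and at least `R_tot` at
#' `R = R_tot`, so the root is bracketed in `[0, R_tot]`; it is located
#' by bisection-based root finding and polished with one Newton step.
#'
#' @param inputs an [analytical_inputs()] object.
#' @param tol relative tolerance of the root.
#' @return free active receptor concentration `R_free`, molar.
#' @export
solve_free_active_receptor <- function(inputs, tol = 1e-12) {
  stopifnot(inherits(inputs, "analytical_inputs"))
  R_tot <- inputs$R_tot
  if (R_tot == 0) return(0)
  if (length(inputs$X_tot) == 0) return(R_tot)
  f <- function(R) R * (1 + sum(inputs$X_tot / (inputs$K + R))) - R_tot
  root <- stats::uniroot(f, c(0, R_tot), tol = R_tot * tol)$root
  ## one Newton polish
  fp <- function(R) 1 + sum(inputs$X_tot * inputs$K / (inputs$K + R)^2)
  polished <- root - f(root) / fp(root)
  if (polished > 0 && polished <= R_tot &&
      abs(f(polished)) < abs(f(root))) polished else root
}

#' Analytical bound-partner estimates and ranking
#'
#' Evaluates `X_i_bound = R_free * X_i_tot / (K_i + R_free)` per
#' partner. Together with the balance equation this satisfies
#' `R_free + sum_i X_i_bound = R_tot` identically. The ranking orders
#' partners by descending bound concentration, ties broken
#' alphabetically.
#'
#' @param R_free output of [solve_free_active_receptor()].
#' @param inputs the matching [analytical_inputs()].
#' @return an `analytical_result`: `R_free`, named `X_bound`, and a
#'   data frame `ranking` (protein, bound, rank).
#' @export
bound_estimates <- function(R_free, inputs) {
  stopifnot(inherits(inputs, "analytical_inputs"), R_free >= 0)
  xb <- R_free * inputs$X_tot / (inputs$K + R_free)
  ord <- order(-xb, names(xb))
  ranking <- data.frame(protein = names(xb)[ord], bound = xb[ord],
                        rank = seq_along(xb), row.names = NULL)
  structure(list(R_free = R_free, X_bound = xb, ranking = ranking,
                 inputs = inputs),
            class = "analytical_result")
}

#' @export
print.analytical_result <- function(x, ...) {
  cat(sprintf("analytical_result: R_free = %.3g M, %d partners\n",
              x$R_free, length(x$X_bound)))
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Derive analytical inputs from a cell model
#'
#' Maps a mechanistic cell model onto the single-occupancy analytical
#' approximation at a given IGF1 dose. The total active receptor is the
#' crosslinked-receptor concentration (monomer units, both kinase
#' domains of a crosslinked dimer being active), scaled by the
#' phospho-availability factor `kp / (kp + kdp)` — the equilibrium
#' probability that an active site is phosphorylated and able to accept
#' a partner. A partner with edges to several sites receives one
#' apparent constant by harmonic aggregation, `1/K_i = sum_e 1/K_e`,
#' the parallel-binding combination of its site affinities. Both
#' choices are recorded in the result's metadata.
#'
#' @param model a [build_cell_model()] object.
#' @param dose IGF1 dose in nanomolar.
#' @return an [analytical_inputs()] object with attribute
#'   `"aggregation"`.
#' @export
effective_inputs_from_model <- function(model, dose) {
  stopifnot(inherits(model, "cell_model"), dose >= 0)
  dose_M <- dose * 1e-9
  f_active <- if (dose_M > 0) crosslinked_fraction(model$params, dose_M) else 0
  monomer_conc <- 2 * model$receptor_dimer_conc
  phospho_avail <- model$params$kp / (model$params$kp + model$params$kdp)
  R_tot <- f_active * monomer_conc * phospho_avail
  K <- vapply(model$partners, function(j) {
    kds <- model$map$KD[model$map$protein == j]
    1 / sum(1 / kds)
  }, numeric(1))
  out <- analytical_inputs(R_tot, X_tot = model$partner_conc, K = K)
  attr(out, "aggregation") <- list(K = "harmonic over edges",
                                   R_tot = "crosslinked monomers x kp/(kp+kdp)")
  out
}

#' One-call analytical recruitment prediction
#'
#' @inheritParams effective_inputs_from_model
#' @return an `analytical_result` whose `X_bound` is also expressed as
#'   copies per cell in `bound_copies`.
#' @export
analytical_recruitment <- function(model, dose) {
  inputs <- effective_inputs_from_model(model, dose)
  res <- bound_estimates(solve_free_active_receptor(inputs), inputs)
  res$bound_copies <- molar_to_copies(res$X_bound, model$volume)
  res
}

#' Export an analytical result as CSV
#'
#' Columns: protein, K (molar), X_tot (molar), X_bound (molar), rank.
#'
#' @param result an `analytical_result`.
#' @param path output file.
#' @export
write_analytical_result <- function(result, path) {
  stopifnot(inherits(result, "analytical_result"))
  ins <- result$inputs
  out <- data.frame(protein = names(result$X_bound),
                    K = as.numeric(ins$K),
                    X_tot = as.numeric(ins$X_tot),
                    X_bound = as.numeric(result$X_bound))
  out$rank <- result$ranking$rank[match(out$protein, result$ranking$protein)]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
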