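#' Rate constants of the cyclic IGF1-IGF1R binding scheme
#'
#' IGF1 engages a binding pocket of the preformed IGF1R dimer at one of
#' two dissimilar sites (S1 or S2) and then crosslinks the pocket by
#' engaging the remaining site, giving a cyclic four-state scheme per
#' pocket with eight rate constants: second-order association rates
#' `a1`, `a2` (per molar per second), first-order crosslinking rates
#' `a1p` (crosslinks S1 from the S2-bound state) and `a2p` (crosslinks
#' S2 from the S1-bound state), and the corresponding dissociation rates
#' `d1`, `d2`, `d1p`, `d2p` (per second). Because the cycle is driven by
#' thermal fluctuations only, the rate constants must satisfy detailed
#' balance:
#'
#'   (a1/d1) * (a2p/d2p) == (a1p/d1p) * (a2/d2)
#'
#' so only seven of the eight are free. `kp` and `kdp` are the
#' pseudo-first-order phosphorylation and dephosphorylation rate
#' constants (per second) applied uniformly to all receptor tyrosines.
#'
#' @param a1,a2 association rate constants, 1/(M s).
#' @param d1,d2,d1p,d2p dissociation rate constants, 1/s.
#' @param a1p,a2p crosslinking rate constants, 1/s. `a2p` may be `NULL`,
#'   in which case it is completed from the other seven by detailed
#'   balance (see [complete_detailed_balance()]).
#' @param kp,kdp phosphorylation / dephosphorylation rates, 1/s.
#' @param balanced if `TRUE`, require the relative detailed-balance
#'   residual to be below `tol`.
#' @param tol tolerance used when `balanced = TRUE`.
#' @return an object of class `ligand_params` (a named list of rates).
#' @seealso [table1_params()] for the published best-fit estimates.
#' @export
ligand_params <- function(a1, d1, a2, d2, a1p, d1p, a2p = NULL, d2p,
                          kp = 0.5, kdp = 0.1,
                          balanced = FALSE, tol = 1e-8) {
  if (is.null(a2p)) {
    a2p <- complete_detailed_balance(a1, d1, a2, d2, a1p, d1p, d2p)
    balanced <- TRUE
  }
  p <- list(a1 = a1, d1 = d1, a2 = a2, d2 = d2,
            a1p = a1p, d1p = d1p, a2p = a2p, d2p = d2p,
            kp = kp, kdp = kdp)
  rates <- unlist(p)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants must be finite and strictly positive")
  class(p) <- "ligand_params"
  if (balanced) {
    res <- detailed_balance_residual(p)
    if (res > tol)
      stop(sprintf("parameter set violates detailed balance (residual %.3g > %.3g)",
                   res, tol))
    attr(p, "balanced") <- TRUE
  }
  p
}

#' @export
print.ligand_params <- function(x, ...) {
  cat("IGF1-IGF1R cyclic binding scheme rate constants\n")
  cat(sprintf("  a1  = %.3g 1/(M s)   d1  = %.3g 1/s\n", x$a1, x$d1))
  cat(sprintf("  a2  = %.3g 1/(M s)   d2  = %.3g 1/s\n", x$a2, x$d2))
  cat(sprintf("  a'1 = %.3g 1/s       d'1 = %.3g 1/s\n", x$a1p, x$d1p))
  cat(sprintf("  a'2 = %.3g 1/s       d'2 = %.3g 1/s\n", x$a2p, x$d2p))
  cat(sprintf("  kp = %.3g 1/s, kdp = %.3g 1/s, detailed-balance residual = %.3g\n",
              x$kp, x$kdp, detailed_balance_residual(x)))
  invisible(x)
}

#' Published best-fit rate constants for IGF1-IGF1R binding
#'
#' The best-fit estimates for the cyclic binding scheme obtained by
#' fitting to equilibrium competition and washout dissociation data.
#' By default `a2p` is recomputed from the other seven constants so the
#' returned set satisfies detailed balance exactly (the printed value,
#' 52/s, is rounded; exact arithmetic on the printed seven gives about
#' 54/s).
#'
#' @param balance if `TRUE` (default) complete `a2p` by detailed
#'   balance; if `FALSE` use the printed rounded value 52/s.
#' @return a [ligand_params()] object.
#' @export
table1_params <- function(balance = TRUE) {
  if (balance) {
    ligand_params(a1 = 2.8e5, d1 = 5.0e-2, a2 = 1.5e4, d2 = 1.9e-4,
                  a1p = 5.6e-3, d1p = 1.9e-5, a2p = NULL, d2p = 1.3e-2)
  } else {
    ligand_params(a1 = 2.8e5, d1 = 5.0e-2, a2 = 1.5e4, d2 = 1.9e-4,
                  a1p = 5.6e-3, d1p = 1.9e-5, a2p = 52, d2p = 1.3e-2)
  }
}

#' Complete the cyclic scheme by detailed balance
#'
#' Returns the unique value of the crosslinking rate `a2p` that closes
#' the thermodynamic cycle, `a2p = d2p * (a1p/d1p) * (a2/d2) / (a1/d1)`.
#'
#' @inheritParams ligand_params
#' @return `a2p` in 1/s.
#' @export
complete_detailed_balance <- function(a1, d1, a2, d2, a1p, d1p, d2p) {
  v <- c(a1 = a1, d1 = d1, a2 = a2, d2 = d2, a1p = a1p, d1p = d1p, d2p = d2p)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all seven rate constants must be finite and strictly positive")
  d2p * (a1p / d1p) * (a2 / d2) / (a1 / d1)
}

#' Relative detailed-balance residual of a parameter set
#'
#' The cycle condition equates the two products of equilibrium ratios
#' around the binding cycle. This returns
#' `|(a1/d1)(a2p/d2p) - (a1p/d1p)(a2/d2)|` divided by the mean of the
#' two products, a dimensionless measure of thermodynamic inconsistency
#' (0 for a balanced set).
#'
#' @param params a [ligand_params()] object.
#' @return nonnegative dimensionless residual.
#' @export
detailed_balance_residual <- function(params) {
  stopifnot(inherits(params, "ligand_params"))
  p1 <- (params$a1 / params$d1) * (params$a2p / params$d2p)
  p2 <- (params$a1p / params$d1p) * (params$a2 / params$d2)
  abs(p1 - p2) / mean(c(p1, p2))
}

#' Site-specific equilibrium dissociation constants
#'
#' The two single-site ligand dissociation constants of the binding
#' pocket, `d1/a1` and `d2/a2`, returned sorted ascending. The
#' assignment of the labels S1/S2 to the high- and low-affinity site is
#' arbitrary (the scheme is symmetric under swapping the two paths).
#'
#' @param params a [ligand_params()] object.
#' @return numeric vector of length 2 (molar), sorted ascending.
#' @export
site_dissociation_constants <- function(params) {
  stopifnot(inherits(params, "ligand_params"))
  sort(c(params$d1 / params$a1, params$d2 / params$a2))
}

#' Swap the two paths of the cyclic binding scheme
#'
#' Exchanges (a1, d1, a1p, d1p) with (a2, d2, a2p, d2p). All observable
#' kinetics are invariant under this relabeling of S1 and S2.
#'
#' @param params a [ligand_params()] object.
#' @return a [ligand_params()] object with the paths exchanged.
#' @export
swap_paths <- function(params) {
  stopifnot(inherits(params, "ligand_params"))
  out <- params
  out$a1 <- params$a2;  out$a2 <- params$a1
  out$d1 <- params$d2;  out$d2 <- params$d1
  out$a1p <- params$a2p; out$a2p <- params$a1p
  out$d1p <- params$d2p; out$d2p <- params$d1p
  out
}

#' Read / write binding rate constants as a key-value config file
#'
#' The config is a plain-text file of `key: value` lines keyed by the
#' symbols a1, d1, a2, d2, a1p, d1p, a2p, d2p, kp, kdp. Units: a1 and a2
#' in 1/(M s), all others in 1/s.
#'
#' @param path file path.
#' @return for `read_ligand_params`, a [ligand_params()] object.
#' @export
read_ligand_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- vapply(kv, function(x) as.numeric(trimws(x[2])), numeric(1))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  need <- c("a1", "d1", "a2", "d2", "a1p", "d1p", "a2p", "d2p")
  if (!all(need %in% names(vals)))
    stop("config must define: ", paste(setdiff(need, names(vals)), collapse = ", "))
  ligand_params(a1 = vals[["a1"]], d1 = vals[["d1"]],
                a2 = vals[["a2"]], d2 = vals[["d2"]],
                a1p = vals[["a1p"]], d1p = vals[["d1p"]],
                a2p = vals[["a2p"]], d2p = vals[["d2p"]],
                kp = if ("kp" %in% names(vals)) vals[["kp"]] else 0.5,
                kdp = if ("kdp" %in% names(vals)) vals[["kdp"]] else 0.1)
}

#' @rdname read_ligand_params
#' @param params a [ligand_params()] object.
#' @export
write_ligand_params <- function(params, path) {
  stopifnot(inherits(params, "ligand_params"))
  keys <- c("a1", "d1", "a2", "d2", "a1p", "d1p", "a2p", "d2p", "kp", "kdp")
  writeLines(sprintf("%s: %.17g", keys,
                     vapply(keys, function(k) params[[k]], numeric(1))),
             path)
  invisible(path)
}
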