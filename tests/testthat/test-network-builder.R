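p_ref <- table1_params()

toy_spec <- function(map, partner_conc, sites, ligand = 1e-9,
                     mode = "clamped", receptor = 1e-8)
  model_spec(map, p_ref, receptor, ligand, partner_conc, sites = sites,
             ligand_mode = mode)

test_that("restructuring halves a1/a2 and doubles the abundances", {
  spec <- toy_spec(toy_map_1s1p(), c(SHC1 = 2e-7), "Y980")
  rs <- restructure(spec)
  expect_equal(rs$params$a1, spec$params$a1 / 2)
  expect_equal(rs$params$a2, spec$params$a2 / 2)
  expect_equal(rs$receptor_dimers, 2 * spec$receptor_dimers)
  expect_equal(rs$ligand_conc, 2 * spec$ligand_conc)
  expect_true(rs$restructured)
  expect_identical(restructure(rs), rs)  # idempotent
})

test_that("restructured species enumeration follows the counting formula", {
  ## toy: 1 site, 1 partner -> 9 x (2 + 1) + ligand + partner = 29
  spec <- toy_spec(toy_map_1s1p(), c(SHC1 = 2e-7), "Y980")
  net <- generate_network(restructure(spec))
  expect_equal(nrow(net$species), 29)
  ## random synthetic maps: N = F + 9 * sum_i (2 + n_i)
  for (seed in 1:3) {
    sp <- synthetic_spec(seed = seed, n_proteins = 6, n_sites = 4,
                         edge_density = 0.5)
    map <- generate_interaction_map(sp)
    partners <- sort(unique(map$protein))
    conc <- stats::setNames(rep(1e-7, length(partners)), partners)
    spec <- toy_spec(map, conc, IGF1R_SITES[1:4])
    net <- generate_network(restructure(spec))
    n_i <- vapply(IGF1R_SITES[1:4], function(s) sum(map$site == s), numeric(1))
    expect_equal(nrow(net$species),
                 1 + length(partners) + 9 * sum(2 + n_i))
  }
})

test_that("removing an edge removes exactly 9 species", {
  map <- toy_map_2s2p()
  partners <- c(SHC1 = 1e-7, STAT1 = 1e-7)
  full <- generate_network(restructure(toy_spec(map, partners,
                                                c("Y980", "Y1161"))))
  ## drop STAT1@Y980 (STAT1 keeps its Y1161 edge, so only one site
  ## status disappears from one form)
  drop <- which(map$protein == "STAT1" & map$site == "Y980")
  map2 <- interaction_map(as.data.frame(map)[-drop, c("protein", "site", "KD")])
  less <- generate_network(restructure(toy_spec(map2, partners,
                                                c("Y980", "Y1161"))))
  expect_equal(nrow(full$species) - nrow(less$species), 9)
})

test_that("species count is invariant under partner relabeling", {
  map_a <- interaction_map(data.frame(
    protein = c("SHC1", "STAT1"), site = c("Y980", "Y980"),
    KD = c(1e-6, 2e-6)))
  map_b <- interaction_map(data.frame(
    protein = c("CRKL", "ABL2"), site = c("Y980", "Y980"),
    KD = c(1e-6, 2e-6)))
  n_a <- nrow(generate_network(restructure(toy_spec(
    map_a, c(SHC1 = 1e-7, STAT1 = 1e-7), "Y980")))$species)
  n_b <- nrow(generate_network(restructure(toy_spec(
    map_b, c(CRKL = 1e-7, ABL2 = 1e-7), "Y980")))$species)
  expect_equal(n_a, n_b)
})

test_that("mass-action right-hand side respects the rate law", {
  spec <- toy_spec(toy_map_1s1p(), c(SHC1 = 2e-7), "Y980")
  net <- generate_network(restructure(spec))
  ## zero state -> zero derivative
  expect_equal(mass_action_rhs(net, numeric(nrow(net$species))),
               numeric(nrow(net$species)))
  ## conservation residual at random states is machine-zero
  set.seed(7)
  C <- net$conservation
  for (i in 1:5) {
    st <- stats::runif(nrow(net$species)) * 1e-8
    expect_lt(max(abs(C %*% mass_action_rhs(net, st))), 1e-18)
  }
  expect_error(mass_action_rhs(net, 1:3), "length")
})

test_that("a single reversible binding step matches the hand-written law", {
  ## the partner-recruitment reaction pair on one species: flux
  ## ka*[R_p][X] - kd*[R_b]
  map <- toy_map_1s1p(KD = 1e-6)
  spec <- toy_spec(map, c(SHC1 = 2e-7), "Y980")
  net <- generate_network(restructure(spec))
  st <- net$init
  sp <- net$species
  ip <- which(sp$form == "Y980" & sp$config == "EMPTY+EMPTY" & sp$status == "p")
  ib <- which(sp$form == "Y980" & sp$config == "EMPTY+EMPTY" & sp$status == "b:SHC1")
  ix <- which(sp$name == "SHC1")
  st[] <- 0
  st[ip] <- 3e-9; st[ib] <- 1e-9; st[ix] <- 2e-7
  dx <- mass_action_rhs(net, st)
  ka <- 1e6; kd <- ka * 1e-6
  ## with only these species populated, the b-state balance is purely
  ## the binding pair (the p-state also phosph/dephosphorylates)
  expect_equal(dx[ib], ka * st[ip] * st[ix] - kd * st[ib], tolerance = 1e-12)
})

test_that("the natural formulation refuses oversized instances", {
  fx <- hela_like_fixture()
  partners <- fx$profile$copies[setdiff(names(fx$profile$copies), "IGF1R")]
  spec <- model_spec(fx$map, p_ref, 1e-8, 1e-9,
                     copies_to_molar(partners[partners > 0]))
  expect_error(generate_natural_network(spec), "cap")
})

test_that("restructured and natural formulations agree on toy models", {
  t_grid <- c(0, 1, 10, 100, 1000)
  ## 1 site, 1 partner, clamped ligand
  spec <- toy_spec(toy_map_1s1p(), c(SHC1 = 2e-7), "Y980")
  rn <- generate_network(restructure(spec))
  nn <- generate_natural_network(spec)
  sr <- simulate_network(rn, t_grid)
  sn <- simulate_network(nn, t_grid)
  expect_obs_equal(rn, sr, nn, sn, seq_along(t_grid), tol = 1e-6)

  ## 2 sites, 2 partners with one shared partner (shared-pool coupling)
  spec2 <- toy_spec(toy_map_2s2p(), c(SHC1 = 1e-7, STAT1 = 5e-8),
                    c("Y980", "Y1161"))
  rn2 <- generate_network(restructure(spec2))
  nn2 <- generate_natural_network(spec2)
  sr2 <- simulate_network(rn2, t_grid)
  sn2 <- simulate_network(nn2, t_grid)
  expect_obs_equal(rn2, sr2, nn2, sn2, seq_along(t_grid), tol = 1e-6)
})

test_that("scaling stays exact with a depleting ligand pool (one form)", {
  t_grid <- c(0, 10, 100, 1000)
  spec <- toy_spec(toy_map_1s1p(), c(SHC1 = 2e-7), "Y980",
                   ligand = 2e-9, mode = "depleting")
  rn <- generate_network(restructure(spec))
  nn <- generate_natural_network(spec)
  sr <- simulate_network(rn, t_grid)
  sn <- simulate_network(nn, t_grid)
  expect_obs_equal(rn, sr, nn, sn, seq_along(t_grid), tol = 1e-6)
  ## ligand conservation in both formulations
  Cn <- nn$conservation
  lig_law <- Cn["ligand", ]
  tot <- as.numeric(as.matrix(sn[, -1]) %*% lig_law)
  expect_equal(tot, rep(tot[1], length(tot)), tolerance = 1e-8)
})

test_that("network text export lists every species and reaction", {
  spec <- toy_spec(toy_map_1s1p(), c(SHC1 = 2e-7), "Y980")
  net <- generate_network(restructure(spec))
  f <- tempfile(fileext = ".txt")
  write_network(net, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("->", lines, fixed = TRUE)), nrow(net$reactions))
  expect_true(any(grepl("R[Y980][EMPTY+EMPTY][u]", lines, fixed = TRUE)))
})
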