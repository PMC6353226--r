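test_that("profile generation is seeded, masked and range-respecting", {
  sp <- synthetic_spec(seed = 4, n_proteins = 10)
  p1 <- generate_cell_profile(sp)
  p2 <- generate_cell_profile(sp)
  expect_identical(p1$copies, p2$copies)
  pm <- generate_cell_profile(sp, mask = c("ITK", "ZAP70", "SRC"))
  expect_equal(unname(pm$copies[intersect(c("ITK", "ZAP70", "SRC"),
                                          names(pm$copies))]),
               rep(0, sum(c("ITK", "ZAP70", "SRC") %in% names(pm$copies))))
  ## distribution check over many draws: log-uniform over the range
  draws <- unlist(lapply(1:500, function(s)
    generate_cell_profile(synthetic_spec(seed = s, n_proteins = 18))$copies))
  expect_gte(min(draws), 1e2)
  expect_lte(max(draws), 1e7)
  lg <- log10(draws)
  ## quartiles of a uniform(2, 7) distribution
  expect_equal(unname(stats::quantile(lg, c(0.25, 0.5, 0.75))),
               c(3.25, 4.5, 5.75), tolerance = 0.05)
})

test_that("interaction map generation is seeded with full site coverage", {
  sp <- synthetic_spec(seed = 8, n_proteins = 12, edge_density = 0.4)
  m1 <- generate_interaction_map(sp)
  m2 <- generate_interaction_map(sp)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_setequal(unique(m1$site), IGF1R_SITES)
  expect_true(all(m1$KD >= 1e-7 & m1$KD <= 1e-5))
  ## density 1: complete bipartite, n_proteins x n_sites edges
  mf <- generate_interaction_map(synthetic_spec(seed = 1, n_proteins = 9,
                                                edge_density = 1))
  expect_equal(nrow(mf), 9 * 6)
})

test_that("a full-scale 50-edge map implies the 577-species network", {
  sp <- synthetic_spec(seed = 2, n_proteins = 18, n_edges = 50)
  map <- generate_interaction_map(sp)
  expect_equal(nrow(map), 50)
  partners <- sort(unique(IGF1R_PARTNERS))
  conc <- stats::setNames(rep(1e-7, length(partners)), partners)
  spec <- model_spec(map, table1_params(), 1e-8, 1e-9, conc)
  net <- generate_network(restructure(spec))
  n_i <- vapply(IGF1R_SITES, function(s) sum(map$site == s), numeric(1))
  expect_equal(nrow(net$species), 19 + 9 * sum(2 + n_i))
  expect_equal(nrow(net$species), 577)
})

test_that("the HeLa-like fixture encodes the stated qualitative facts", {
  fx <- hela_like_fixture()
  cp <- fx$profile$copies
  ## 18 candidate partners; ITK and ZAP70 silent; 50 edges in total
  expect_setequal(setdiff(names(cp), "IGF1R"), IGF1R_PARTNERS)
  expect_equal(unname(cp[c("ITK", "ZAP70")]), c(0, 0))
  expect_equal(nrow(fx$map), 50)
  ## SHC1 binds only Y980; two orders over IRS1; 20-fold stronger
  expect_equal(fx$map$site[fx$map$protein == "SHC1"], "Y980")
  expect_equal(unname(cp["SHC1"] / cp["IRS1"]), 100)
  kd980 <- function(p) fx$map$KD[fx$map$protein == p & fx$map$site == "Y980"]
  expect_equal(kd980("IRS1") / kd980("SHC1"), 20)
  ## ABL2 ~40-fold stronger than CRKL at Y973
  kd973 <- function(p) fx$map$KD[fx$map$protein == p & fx$map$site == "Y973"]
  expect_equal(kd973("CRKL") / kd973("ABL2"), 40)
  ## the nine pY1161 partners include the named seven
  y1161 <- fx$map$protein[fx$map$site == "Y1161"]
  expect_length(y1161, 9)
  expect_true(all(c("STAT1", "PIK3R3", "SRC", "YES1", "SYK", "BLK", "VAV2")
                  %in% y1161))
  ## STAT1 and VAV2 bind only pY1161 at similar affinity
  expect_equal(fx$map$site[fx$map$protein == "STAT1"], "Y1161")
  expect_equal(fx$map$site[fx$map$protein == "VAV2"], "Y1161")
  ## CRKL at Y973 and Y1166; PIK3R2 at Y1346
  expect_setequal(fx$map$site[fx$map$protein == "CRKL"], c("Y973", "Y1166"))
  expect_true("Y1346" %in% fx$map$site[fx$map$protein == "PIK3R2"])
})

test_that("the fixture reproduces the stated recruitment orderings", {
  fx <- hela_like_fixture()
  mod <- build_cell_model(fx$profile, fx$map)
  r <- simulate_to_steady_state(mod, 1)
  expect_gt(r$bound[["SHC1"]], r$bound[["IRS1"]])
  ## ABL2 outranks CRKL in pY973 occupancy (40-fold affinity edge)
  y973 <- igfrec:::.algebraic_steady(mod, 1e-9)
  expect_gt(y973$bound["Y973", "ABL2"], y973$bound["Y973", "CRKL"])
})

test_that("interaction-map invariants: duplicate domains and IRS1 rule", {
  ## duplicate (protein, site) rows collapse to the minimum KD
  m <- interaction_map(data.frame(
    protein = c("PIK3R2", "PIK3R2"), site = c("Y1346", "Y1346"),
    KD = c(2e-6, 6e-7)))
  expect_equal(nrow(m), 1)
  expect_equal(m$KD, 6e-7)
  ## IRS1 with unmeasured affinity inherits 20 x SHC1 at Y980
  m2 <- interaction_map(data.frame(
    protein = c("SHC1", "IRS1"), site = "Y980", KD = c(5e-7, NA)))
  expect_equal(m2$KD[m2$protein == "IRS1"], 1e-5)
  expect_error(interaction_map(data.frame(protein = "IRS1", site = "Y980",
                                          KD = NA)), "SHC1")
  expect_error(interaction_map(data.frame(protein = "A", site = "Y999",
                                          KD = 1e-6)), "unknown site")
})

test_that("supplementary-style tables round-trip and report unknowns", {
  fx <- hela_like_fixture()
  d <- tempfile(); dir.create(d)
  pf <- file.path(d, "profiles.tsv")
  mf <- file.path(d, "map.tsv")
  panel <- synthetic_cell_panel(3, seed = 6)
  write_cell_profiles(panel, pf)
  write_interaction_map(fx$map, mf)
  back <- read_supplementary_tables(pf, mf)
  expect_equal(length(back$profiles), 3)
  for (nm in names(panel))
    expect_equal(back$profiles[[nm]]$copies[names(panel[[nm]]$copies)],
                 panel[[nm]]$copies)
  expect_equal(as.data.frame(back$map), as.data.frame(fx$map),
               tolerance = 1e-12)
  ## unknown symbols are excluded with a warning and counted
  tab <- utils::read.delim(pf)
  tab <- rbind(tab, c("NOTAPROTEIN", rep(5, ncol(tab) - 1)))
  pf2 <- file.path(d, "profiles2.tsv")
  utils::write.table(tab, pf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(out <- read_cell_profiles(pf2), "NOTAPROTEIN")
  expect_equal(attr(out, "parse_report")$n_dropped, 1)
})

test_that("panel generation is deterministic and rescaling-ready", {
  p1 <- synthetic_cell_panel(5, seed = 10)
  p2 <- synthetic_cell_panel(5, seed = 10)
  expect_identical(lapply(p1, `[[`, "copies"), lapply(p2, `[[`, "copies"))
  expect_true(all(vapply(p1, function(p) p$copies[["IGF1R"]] > 0,
                         logical(1))))
})

test_that("injected correlation structure survives the full pipeline", {
  ## a constructed two-competitor map must come out negative, and an
  ## injected dominant competitor must couple its victims positively
  map2 <- interaction_map(data.frame(protein = c("STAT1", "VAV2"),
                                     site = "Y1161", KD = c(2e-7, 2e-7)))
  prof2 <- cell_profile("inj2", c(IGF1R = 2e4, STAT1 = 1e5, VAV2 = 1e5))
  pc2 <- population_correlations(
    population_spec(prof2, n_cells = 300, sigma = 0.2, dose = 1, seed = 33),
    map2)
  expect_lt(pc2$pearson["STAT1", "VAV2"], 0)
  map3 <- interaction_map(data.frame(
    protein = c("SRC", "STAT1", "VAV2"), site = "Y1161",
    KD = c(2e-7, 2e-7, 2e-7)))
  prof3 <- cell_profile("inj3", c(IGF1R = 2e4, SRC = 1e7, STAT1 = 1e3,
                                  VAV2 = 1e3))
  pc3 <- population_correlations(
    population_spec(prof3, n_cells = 300, sigma = 0.2, dose = 1, seed = 34),
    map3)
  expect_gt(pc3$pearson["STAT1", "VAV2"], 0)
})
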