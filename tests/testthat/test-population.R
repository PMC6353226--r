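fx <- hela_like_fixture()

test_that("population sampling is lognormal, seeded and mask-preserving", {
  spec <- population_spec(fx$profile, n_cells = 5000, sigma = 0.2, seed = 9)
  cells <- sample_population(spec)
  expect_equal(dim(cells), c(5000, length(fx$profile$copies)))
  ## zero-copy proteins stay zero in every cell
  expect_true(all(cells[, "ITK"] == 0))
  expect_true(all(cells[, "ZAP70"] == 0))
  ## the log-mean equals the log of the base copy number (mu = ln mean)
  lx <- log(cells[, "SHC1"])
  expect_equal(mean(lx), log(fx$profile$copies[["SHC1"]]),
               tolerance = 3 * 0.2 / sqrt(5000) / log(1e5))
  expect_equal(stats::sd(lx), 0.2, tolerance = 0.05)
  ## bit-identical regeneration under the same seed
  expect_identical(cells, sample_population(spec))
  ## sigma 0 reproduces the base profile in every cell
  cells0 <- sample_population(population_spec(fx$profile, n_cells = 10,
                                              sigma = 0, seed = 1))
  expect_true(all(apply(cells0, 2, function(v) all(v == v[1]))))
  expect_equal(unname(cells0[1, ]), unname(fx$profile$copies))
})

test_that("population recruitment reduces to the single-cell result", {
  spec <- population_spec(fx$profile, n_cells = 2, sigma = 0, dose = 1,
                          seed = 1)
  cells <- sample_population(spec)
  Y <- population_recruitment(cells, fx$map, dose = 1)
  single <- simulate_to_steady_state(build_cell_model(fx$profile, fx$map), 1)
  expect_equal(unname(Y[1, ]), unname(single$bound[colnames(Y)]),
               tolerance = 1e-6)
  expect_equal(Y[1, ], Y[2, ])  # identical cells, zero variance
})

test_that("population column means are consistent with the base profile", {
  spec <- population_spec(fx$profile, n_cells = 300, sigma = 0.2, dose = 1,
                          seed = 17)
  Y <- population_recruitment(sample_population(spec), fx$map, dose = 1)
  base <- simulate_to_steady_state(build_cell_model(fx$profile, fx$map), 1)
  for (pr in c("SHC1", "STAT1", "CRKL")) {
    se <- stats::sd(Y[, pr]) / sqrt(nrow(Y))
    ## lognormal mean exceeds the median slightly; allow 3 SE + 3%
    expect_lt(abs(mean(Y[, pr]) - base$bound[[pr]]),
              3 * se + 0.03 * base$bound[[pr]])
  }
})

test_that("pairwise correlations have Pearson structure", {
  set.seed(5)
  Y <- cbind(a = stats::rnorm(5000), b = stats::rnorm(5000))
  Y <- cbind(Y, dup = Y[, "a"])
  pc <- pairwise_correlations(Y)
  expect_equal(pc$pearson["a", "dup"], 1, tolerance = 1e-12)
  expect_lt(abs(pc$pearson["a", "b"]), 0.05)
  expect_equal(pc$pearson, t(pc$pearson))
  expect_true(all(abs(pc$pearson) <= 1 + 1e-12))
  expect_error(pairwise_correlations(Y[1, , drop = FALSE]), "two cells")
  ## zero-variance columns are flagged, not silently correlated
  Yz <- cbind(Y, const = 1)
  pcz <- pairwise_correlations(Yz)
  expect_equal(pcz$degenerate, "const")
  expect_true(all(is.na(pcz$pearson["const", ])))
})

test_that("direct competitors are negatively correlated", {
  ## two comparable partners contending for a single site
  map <- interaction_map(data.frame(protein = c("STAT1", "VAV2"),
                                    site = "Y1161", KD = c(2e-7, 2e-7)))
  prof <- cell_profile("duo", c(IGF1R = 2e4, STAT1 = 1e5, VAV2 = 1e5))
  spec <- population_spec(prof, n_cells = 400, sigma = 0.2, dose = 1,
                          seed = 21)
  pc <- population_correlations(spec, map)
  expect_lt(pc$pearson["STAT1", "VAV2"], -0.1)
})

test_that("a dominant mutual competitor induces positive correlation", {
  ## SRC at very high abundance crowds out two small partners of the
  ## same site: their fluctuations become positively coupled
  map <- interaction_map(data.frame(
    protein = c("SRC", "STAT1", "VAV2"), site = "Y1161",
    KD = c(2e-7, 2e-7, 2e-7)))
  prof <- cell_profile("trio", c(IGF1R = 2e4, SRC = 1e7,
                                 STAT1 = 1e3, VAV2 = 1e3))
  spec <- population_spec(prof, n_cells = 400, sigma = 0.2, dose = 1,
                          seed = 22)
  pc <- population_correlations(spec, map)
  expect_gt(pc$pearson["STAT1", "VAV2"], 0.1)
  expect_lt(pc$pearson["SRC", "STAT1"], 0)
  expect_lt(pc$pearson["SRC", "VAV2"], 0)
})

test_that("correlation estimates are stable across seeds", {
  map <- interaction_map(data.frame(protein = c("STAT1", "VAV2"),
                                    site = "Y1161", KD = c(2e-7, 2e-7)))
  prof <- cell_profile("duo", c(IGF1R = 2e4, STAT1 = 1e5, VAV2 = 1e5))
  n <- 400
  r <- vapply(c(31, 32), function(s) {
    pc <- population_correlations(
      population_spec(prof, n_cells = n, sigma = 0.2, dose = 1, seed = s),
      map)
    pc$pearson["STAT1", "VAV2"]
  }, numeric(1))
  expect_lt(abs(r[1] - r[2]), 2 / sqrt(n) * 2)
})

test_that("population exports write the documented files", {
  map <- interaction_map(data.frame(protein = c("STAT1", "VAV2"),
                                    site = "Y1161", KD = c(2e-7, 2e-7)))
  prof <- cell_profile("duo", c(IGF1R = 2e4, STAT1 = 1e5, VAV2 = 1e5))
  spec <- population_spec(prof, n_cells = 20, sigma = 0.2, dose = 1, seed = 2)
  pc <- population_correlations(spec, map)
  d <- tempfile()
  write_population_result(pc, d, prefix = "duo")
  expect_true(file.exists(file.path(d, "duo_bound.csv")))
  expect_true(file.exists(file.path(d, "duo_pearson.csv")))
  expect_true(file.exists(file.path(d, "duo_spec.json")))
})
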