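fx <- hela_like_fixture()
mod <- build_cell_model(fx$profile, fx$map)

test_that("ranking metrics order partners as documented", {
  ## abundance metric: SHC1 (1e5) above IRS1 (1e3)
  rc <- rank_partners(mod, "copy_number")
  expect_lt(rc$rank[rc$protein == "SHC1"], rc$rank[rc$protein == "IRS1"])
  ## affinity metric equals ascending minimum-KD order
  rk <- rank_partners(mod, "kd")
  mk <- tapply(mod$map$KD, mod$map$protein, min)
  ## re-sort oracle: ascending minimum KD, ties alphabetical
  ord <- order(mk[rk$protein[order(rk$rank)]])
  expect_equal(unname(mk[rk$protein]), unname(sort(mk)))
  expect_true(all(diff(rk$value) >= 0))
  ## copy/KD metric
  rr <- rank_partners(mod, "copy_over_kd")
  ratio <- mod$partner_copies[rr$protein] / mk[rr$protein]
  expect_true(all(diff(ratio) <= 0))
  ## ranks are a permutation, unexpressed proteins listed separately
  for (r in list(rc, rk, rr)) {
    expect_setequal(r$rank, seq_len(nrow(r)))
    expect_setequal(attr(r, "unexpressed"), c("ITK", "ZAP70"))
  }
})

test_that("all metrics agree on a single-partner model", {
  map <- toy_map_1s1p()
  prof <- cell_profile("solo", c(IGF1R = 2e4, SHC1 = 1e5))
  m1 <- build_cell_model(prof, map)
  for (metric in c("simulation", "analytical", "copy_number", "kd",
                   "copy_over_kd")) {
    r <- rank_partners(m1, metric)
    expect_equal(r$protein, "SHC1")
    expect_equal(r$rank, 1L)
  }
})

test_that("rankings are invariant under uniform rescaling", {
  rc1 <- rank_partners(mod, "copy_number")
  prof10 <- cell_profile("x10", fx$profile$copies * 10)
  rc2 <- rank_partners(build_cell_model(prof10, fx$map), "copy_number")
  expect_equal(rc1$protein, rc2$protein)
  rk1 <- rank_partners(mod, "kd")
  ed <- as.data.frame(fx$map)[, c("protein", "site", "KD")]
  ed$KD <- ed$KD * 5
  rk2 <- rank_partners(build_cell_model(fx$profile, interaction_map(ed)),
                       "kd")
  expect_equal(rk1$protein, rk2$protein)
})

test_that("rank deviations behave like signed permutation differences", {
  r_sim <- rank_partners(mod, "copy_number")
  expect_equal(rank_deviation(r_sim, r_sim)$deviation,
               rep(0L, nrow(r_sim)))
  ## swapping two neighbours yields deviations +1 / -1
  r_alt <- r_sim
  r_alt$protein[1:2] <- r_alt$protein[2:1]
  d <- rank_deviation(r_sim, r_alt)
  swapped <- r_sim$protein[1:2]
  expect_setequal(d$deviation[d$protein %in% swapped], c(1L, -1L))
  expect_equal(sum(d$deviation), 0)
  ## random permutations: zero-sum and antisymmetric
  set.seed(11)
  for (i in 1:5) {
    r_rand <- r_sim
    perm <- sample(nrow(r_sim))
    r_rand$protein <- r_sim$protein[perm]
    d1 <- rank_deviation(r_sim, r_rand)
    d2 <- rank_deviation(r_rand, r_sim)
    expect_equal(sum(d1$deviation), 0)
    expect_equal(d1$deviation, -d2$deviation)
  }
  r_other <- rank_partners(build_cell_model(
    cell_profile("solo", c(IGF1R = 2e4, SHC1 = 1e5)), toy_map_1s1p()),
    "copy_number")
  expect_error(rank_deviation(r_sim, r_other), "different partner sets")
})

test_that("cross-cell summaries aggregate expressed-only ranks", {
  r1 <- rank_partners(mod, "copy_number")
  cs1 <- cross_cell_summary(list(A = r1))
  expect_equal(cs1$mean_rank, r1$rank[match(cs1$protein, r1$protein)])
  expect_equal(cs1$sd_rank, rep(0, nrow(cs1)))
  expect_equal(cs1$n_expressed, rep(1L, nrow(cs1)))
  expect_equal(sum(cs1$top1), 1)
  ## a protein missing from one line is averaged over the rest only
  prof_no_shc1 <- fx$profile$copies
  prof_no_shc1["SHC1"] <- 0
  r2 <- rank_partners(build_cell_model(cell_profile("B", prof_no_shc1),
                                       fx$map), "copy_number")
  cs2 <- cross_cell_summary(list(A = r1, B = r2))
  expect_equal(cs2$n_expressed[cs2$protein == "SHC1"], 1L)
  expect_equal(cs2$mean_rank[cs2$protein == "SHC1"],
               r1$rank[r1$protein == "SHC1"])
})

test_that("numerical vs analytical comparison returns a correlation", {
  cmp <- compare_numerical_vs_analytical(mod, 1)
  expect_true(is.finite(cmp$r) && abs(cmp$r) <= 1)
  expect_gt(cmp$r, 0.8)  # strong positive agreement
  expect_lt(cmp$p_value, 1e-4)
  expect_equal(nrow(cmp$table), length(mod$partners))
  solo <- build_cell_model(cell_profile("solo", c(IGF1R = 2e4, SHC1 = 1e5)),
                           toy_map_1s1p())
  expect_error(compare_numerical_vs_analytical(solo), "three partners")
})

test_that("Ward clustering groups identical and similar profiles", {
  ## two identical rows merge first at height 0
  m <- rbind(a = c(1, 1, 1), b = c(1, 1, 1), c = c(5, 5, 5),
             d = c(5.1, 5, 5))
  cl <- cluster_cell_lines(m)
  h <- cl$row_hclust
  first <- sort(rownames(m)[-h$merge[1, ]])
  expect_equal(first, c("a", "b"))
  expect_equal(h$height[1], 0)
  ## three rows with one outlier: the outlier joins last
  m2 <- rbind(x = c(0, 0), y = c(0, 0.1), z = c(10, 10))
  cl2 <- cluster_cell_lines(m2)
  expect_equal(cl2$row_hclust$merge[1, ], c(-1, -2))
  ## merge heights invariant under row permutation
  perm <- c(3, 1, 2)
  cl2p <- cluster_cell_lines(m2[perm, ])
  expect_equal(cl2p$row_hclust$height, cl2$row_hclust$height)
  expect_error(cluster_cell_lines(rbind(c(1, NA), c(0, 1))), "missing")
})

test_that("duplicate profiles of a cell line co-cluster", {
  ## the same biological line measured by two 'studies' (slightly
  ## perturbed copies) ends up in one terminal pair
  set.seed(13)
  panel <- synthetic_cell_panel(6, seed = 3)
  dup <- panel[[1]]
  dup$copies[dup$copies > 0] <-
    dup$copies[dup$copies > 0] * exp(stats::rnorm(sum(dup$copies > 0), 0, 0.05))
  profiles <- c(panel, list(DUP = cell_profile("DUP", dup$copies)))
  mat <- recruitment_matrix(profiles, fx$map, dose = 1)
  cl <- cluster_cell_lines(mat)
  h <- cl$row_hclust
  i1 <- match(panel[[1]]$name, h$labels)
  i2 <- match("DUP", h$labels)
  expect_true(any(apply(h$merge, 1, function(r)
    setequal(r, c(-i1, -i2)))))
})
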