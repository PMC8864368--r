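test_that("the configuration grid and its feasible subset count correctly", {
  one <- enumerate_configs(metrics = "mpd", algorithms = "tip_shuffle",
                           pools = "global", trait_subsets = "all")
  expect_equal(nrow(one), 1)
  expect_true(one$feasible)

  grid <- enumerate_configs()
  expect_equal(attr(grid, "n_full"), 36)
  expect_equal(attr(grid, "n_feasible"), 33)
  excluded <- grid[!grid$feasible, ]
  expect_equal(nrow(excluded), 3)
  expect_true(all(excluded$metric == "mntd"))
  expect_true(all(excluded$algorithm == "tip_shuffle"))
  expect_true(all(excluded$trait_subset == "diet"))

  no_rules <- enumerate_configs(exclusions = NULL)
  expect_equal(attr(no_rules, "n_feasible"), 36)
})

test_that("a site holding the whole pool is infeasible under tip shuffle", {
  tab <- random_traits(6, seed = 51)
  occ <- matrix(1L, 3, 6, dimnames = list(c("s1", "s2", "s3"), tab$species))
  occ[2, 5:6] <- 0L; occ[3, c(1, 6)] <- 0L
  cm <- community_matrix(occ, data.frame(
    site = rownames(occ), ocean = "Atlantic", margin = "east",
    latitude = c(40, 45, 50)))
  scoped <- scope_pool(cm, "global")
  D <- gower_dist(tab, "all")
  res <- withr::with_seed(51,
    ses_for_site("s1", scoped, D, metric = "mpd", algorithm = "tip_shuffle",
                 n_perm = 99))
  expect_false(res$feasible)
  expect_true(is.na(res$ses))
  res2 <- withr::with_seed(51,
    ses_for_site("s2", scoped, D, metric = "mpd", algorithm = "tip_shuffle",
                 n_perm = 99))
  expect_true(res2$feasible)
})

test_that("SES sign tracks whether the observed metric exceeds the null mean", {
  tab <- random_traits(12, seed = 52)
  occ <- random_occurrence(8, 12, seed = 52)
  colnames(occ) <- tab$species
  cm <- community_matrix(occ, data.frame(
    site = rownames(occ), ocean = "Atlantic", margin = "east",
    latitude = seq(35, 56, 3)))
  ses <- trait_dispersion(cm, tab,
                          enumerate_configs(metrics = "mntd",
                                            algorithms = "tip_shuffle",
                                            pools = "global",
                                            trait_subsets = "all"),
                          n_perm = 199, seed = 52)
  f <- ses[ses$feasible, ]
  expect_true(all((f$ses > 0) == (f$observed > f$null_mean)))
  expect_true(all(f$quantile > 0 & f$quantile < 1))
  expect_true(all(f$null_sd > 0))
})

test_that("SES is invariant under affine rescaling of the distance matrix", {
  tab <- random_traits(10, seed = 53)
  occ <- random_occurrence(6, 10, seed = 53)
  colnames(occ) <- tab$species
  meta <- data.frame(site = rownames(occ), ocean = "Atlantic",
                     margin = "east", latitude = seq(35, 50, 3))
  cm <- community_matrix(occ, meta)
  scoped <- scope_pool(cm, "global")
  D <- gower_dist(tab, "all")
  D2 <- D
  off <- row(D2) != col(D2)
  D2[off] <- 0.35 * D2[off] + 0.2   # affine map of all off-diagonal distances

  for (alg in c("independent_swap", "tip_shuffle")) {
    r1 <- withr::with_seed(53, traitdisp:::ses_grid_config(
      scoped, D, "mpd", alg, n_perm = 99, n_swaps = 200))
    r2 <- withr::with_seed(53, traitdisp:::ses_grid_config(
      scoped, D2, "mpd", alg, n_perm = 99, n_swaps = 200))
    expect_equal(r1$ses, r2$ses, tolerance = 1e-9)
  }
})

test_that("swap-generated communities score near zero against the swap null", {
  # self-consistency: observed matrices drawn from the null ensemble
  base <- random_occurrence(100, 30, fill = 0.3, seed = 54)
  tab <- random_traits(30, seed = 54)
  colnames(base) <- tab$species
  D <- gower_dist(tab, "all")
  meta <- data.frame(site = rownames(base), ocean = "Atlantic",
                     margin = "east", latitude = seq(30, 60, length.out = 100))
  withr::local_seed(54)
  obs <- independent_swap(base, n_swaps = 3000)
  cm <- community_matrix(obs, meta)
  scoped <- scope_pool(cm, "global")
  res <- traitdisp:::ses_grid_config(scoped, D, "mpd", "independent_swap",
                                     n_perm = 199, n_swaps = 1000)
  expect_lt(abs(mean(res$ses[res$feasible])), 0.1)
})

test_that("the SES grid is reproducible and covers sites x feasible configs", {
  sc <- tiny_scenario()
  out1 <- simulate_ses(sc, seed = 55,
                       configs = enumerate_configs(
                         metrics = c("mpd", "mntd"),
                         algorithms = c("independent_swap", "tip_shuffle"),
                         pools = "global", trait_subsets = c("all", "diet")),
                       n_perm = 49)
  expect_equal(nrow(out1$ses),
               nrow(out1$community$occurrence) * 7)  # 8 cells - 1 excluded
  expect_false(any(out1$ses$metric == "mntd" &
                     out1$ses$algorithm == "tip_shuffle" &
                     out1$ses$trait_subset == "diet"))
  out2 <- simulate_ses(sc, seed = 55,
                       configs = enumerate_configs(
                         metrics = c("mpd", "mntd"),
                         algorithms = c("independent_swap", "tip_shuffle"),
                         pools = "global", trait_subsets = c("all", "diet")),
                       n_perm = 49)
  expect_identical(as.data.frame(out1$ses), as.data.frame(out2$ses))
})

test_that("ocean pools restrict both sites and species before permuting", {
  sc <- tiny_scenario()
  ds <- simulate(sc, seed = 56)
  agg <- aggregate_sites(ds$plots, ds$tethers)
  env <- ds$environment
  cm <- community_matrix(agg$abundance,
                         env[match(rownames(agg$abundance), env$site), ])
  sc_atl <- scope_pool(cm, "Atlantic")
  expect_true(all(sc_atl$sites$ocean == "Atlantic"))
  expect_true(all(colSums(sc_atl$occurrence) >= 1))
  atl_sp <- ds$membership$species[ds$membership$Atlantic]
  expect_true(all(sc_atl$species %in% atl_sp))
  expect_error(scope_pool(cm, "Arctic"), "no sites")
})
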