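test_that("pool structure follows the scenario's ocean membership", {
  sc <- zen_scenario(n_species = c(Atlantic = 20, Pacific = 25), n_shared = 0)
  pool <- gen_pool(sc, seed = 91)
  expect_equal(sum(pool$membership$Atlantic & pool$membership$Pacific), 0)
  expect_equal(sum(pool$membership$Atlantic), 20)
  expect_equal(sum(pool$membership$Pacific), 25)

  def <- gen_pool(zen_scenario(), seed = 91)
  expect_equal(nrow(def$traits), 105)
  expect_equal(sum(def$membership$Atlantic), 55)
  expect_equal(sum(def$membership$Pacific), 60)
  expect_equal(sum(def$membership$Atlantic & def$membership$Pacific), 10)
  expect_error(zen_scenario(n_shared = 70), "exceeds")
})

test_that("generated trait values conform to the schema over many draws", {
  sc <- zen_scenario(n_species = c(Atlantic = 5100, Pacific = 5100),
                     n_shared = 200)
  pool <- gen_pool(sc, seed = 92)
  expect_equal(nrow(pool$traits), 10000)
  expect_true(all(pool$traits$max_length >= 2 & pool$traits$max_length <= 50))
  rep <- validate_trait_table(pool$traits)
  expect_true(rep$ok)
})

test_that("missing-diet blocks only affect diet traits", {
  sc <- zen_scenario(n_missing_diet = 8)
  pool <- gen_pool(sc, seed = 93)
  diet <- trait_subset_names(default_trait_schema(), "diet")
  other <- setdiff(names(pool$traits), c("species", diet))
  expect_equal(sum(rowSums(is.na(pool$traits[, diet])) > 0), 8)
  expect_false(anyNA(pool$traits[, other]))
})

test_that("predation tracks latitude as steered by the gradient slope", {
  flat <- zen_scenario(predation_b = 0, predation_a = 0.5,
                       n_sites = list(Atlantic = c(east = 25, west = 25),
                                      Pacific = c(east = 25, west = 25)))
  env0 <- gen_environment(flat, seed = 94)
  expect_lt(abs(cor(env0$predation, env0$latitude)), 0.2)

  steep <- zen_scenario(predation_b = 0.4, predation_a = 18,
                        predation_noise = 0.01)
  env1 <- gen_environment(steep, seed = 94)
  expect_lt(cor(env1$predation, env1$latitude, method = "spearman"), -0.9)

  env2 <- gen_environment(zen_scenario(predation_noise = 0.5), seed = 95)
  expect_true(all(env2$predation >= 0 & env2$predation <= 1))
})

test_that("neutral assembly selects species uniformly", {
  tab <- random_traits(10, seed = 96)
  D <- unclass(gower_dist(tab, "all"))
  tn <- setNames(seq(0, 1, length.out = 10), tab$species)
  withr::local_seed(96)
  n_rep <- 10000; k <- 3
  tallies <- table(factor(unlist(
    replicate(n_rep, assemble_community(k, 0.5, 0, 0, tn, D), simplify = FALSE)),
    levels = tab$species))
  p <- k / 10
  se <- sqrt(p * (1 - p) * n_rep)
  expect_true(all(abs(tallies - n_rep * p) < 3 * se))
})

test_that("assembly guards reject impossible settings", {
  tab <- random_traits(5, seed = 97)
  D <- unclass(gower_dist(tab, "all"))
  tn <- setNames(seq(0, 1, length.out = 5), tab$species)
  expect_error(assemble_community(6, 0.5, 0, 0, tn, D), "exceeds pool")
  expect_error(assemble_community(3, 0.5, 0, 0, tn, D, sigma = 0),
               "sigma")
  expect_error(zen_scenario(sigma = -1), "sigma")
  expect_error(zen_scenario(tau_filter = -2), "non-negative")
})

test_that("strong filtering packs, strong repulsion spreads, trait space", {
  # direct effect on the assemblage's trait dispersion, before any SES:
  # filtering is judged on the filtered trait's own distances (where the
  # packing acts), repulsion on the full Gower space it operates in
  tab <- random_traits(40, seed = 98)
  D <- unclass(gower_dist(tab, "all"))
  D_len <- unclass(gower_dist(tab, "max_length"))
  r <- rank(tab$max_length)
  tn <- setNames((r - 1) / (length(r) - 1), tab$species)
  withr::local_seed(98)
  len_neutral <- mean(replicate(
    200, mntd(assemble_community(8, 0.5, 0, 0, tn, D), D_len)))
  len_filter <- mean(replicate(
    200, mntd(assemble_community(8, 0.5, 30, 0, tn, D), D_len)))
  expect_lt(len_filter, len_neutral)
  all_neutral <- mean(replicate(
    200, mntd(assemble_community(8, 0.5, 0, 0, tn, D), D)))
  all_limit <- mean(replicate(
    200, mntd(assemble_community(8, 0.5, 0, 8, tn, D), D)))
  expect_gt(all_limit, all_neutral)
})

test_that("the default design yields 42 sites of 20 plots", {
  ds <- simulate(zen_scenario(), seed = 99)
  expect_equal(nrow(ds$environment), 42)
  expect_equal(nrow(unique(ds$plots[, c("site", "plot")])), 42 * 20)
  expect_equal(nrow(ds$tethers), 42 * 20 * 3)
  # every selected species appears with positive counts
  expect_true(all(rowSums(ds$communities) > 0))
  expect_true(all(ds$plots$count >= 0))
  expect_true(all(ds$plots$ag_biomass_g > 0))
})

test_that("dataset bundles are byte-identical under the same seed", {
  sc <- tiny_scenario()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_dataset(sc, d1, seed = 100)
  gen_dataset(sc, d2, seed = 100)
  for (f in c("traits.csv", "plots.csv", "tethers.csv", "environment.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_error(gen_dataset(sc, d1, seed = 100), "exist")
  expect_silent(gen_dataset(sc, d1, seed = 100, overwrite = TRUE))
})
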