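test_that("AICc penalty behaves as the closed form requires", {
  # strictly increasing in k at fixed rss, and AICc - AIC vanishes as n grows
  a <- vapply(2:8, function(k) aicc(10, 42, k), 0)
  expect_true(all(diff(a) > 0))
  aic <- function(rss, n, k) n * log(2 * pi * rss / n) + n + 2 * k
  expect_lt(abs(aicc(10, 1e6, 4) - aic(10, 1e6, 4)), 1e-4)
  expect_error(aicc(10, 6, 5), "undefined")
  expect_error(aicc(-1, 30, 2), "positive")
})

test_that("AICc matches a from-scratch Gaussian likelihood oracle", {
  withr::local_seed(71)
  x <- rnorm(10)
  y <- 1 + 2 * x + rnorm(10, 0, 0.5)
  fit <- lm(y ~ x)
  expect_equal(traitdisp:::aicc_lm(fit), oracle_aicc(y, cbind(x)),
               tolerance = 1e-10)
})

test_that("habitat PCA recovers known structure deterministically", {
  withr::local_seed(72)
  n <- 30
  latent <- rnorm(n)
  hab <- data.frame(shoot_density = latent + rnorm(n, 0, 0.05),
                    sheath_width = -latent + rnorm(n, 0, 0.05),
                    sheath_length = rnorm(n),
                    longest_leaf = rnorm(n),
                    ag_biomass = rnorm(n))
  p <- pca_habitat(hab)
  # the correlated pair dominates PC1
  expect_gt(p$explained[1], 0.35)
  expect_lt(abs(sum(p$scores[, 1] * p$scores[, 2])), 1e-10)
  # deterministic sign convention: largest loading positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)

  # scores match an independent eigendecomposition of the correlation matrix
  X <- scale(as.matrix(hab))
  eig <- eigen(crossprod(X) / (n - 1))
  sc_or <- X %*% eig$vectors[, 1:2]
  for (j in 1:2) {
    cmp <- sc_or[, j] * sign(sum(sc_or[, j] * p$scores[, j]))
    expect_equal(unname(p$scores[, j]), unname(cmp), tolerance = 1e-8)
  }
  hab$sheath_width <- 1
  expect_error(pca_habitat(hab), "constant")
})

test_that("predictor transformations follow the registry's named forms", {
  env <- random_env(12, seed = 73)
  env$predation[1] <- 0; env$predation[2] <- 1
  env$macroalgal_biomass[3] <- 0
  pt <- transform_predictors(env)
  expect_equal(pt$arcsin_predation[1], 0)
  expect_equal(pt$arcsin_predation[2], pi / 2)
  expect_equal(pt$log_macroalgae[3], 0)
  expect_equal(pt$log_epiphyte, log(env$epiphyte_load))
  expect_equal(levels(pt$ocean)[1], "Atlantic")
  expect_equal(levels(pt$margin)[1], "east")
  # variance-stabilizing option
  pt2 <- transform_predictors(env, arcsin_sqrt = TRUE)
  expect_equal(pt2$arcsin_predation[2], asin(1))
  expect_equal(pt2$arcsin_predation, asin(sqrt(env$predation)))

  env$epiphyte_load[5] <- 0
  expect_error(transform_predictors(env), "site05")
  env2 <- random_env(12, seed = 74)
  env2$predation[4] <- 1.2
  expect_error(transform_predictors(env2), "predation")
})

test_that("the registry holds the sixteen named a priori models", {
  reg <- default_model_registry()
  expect_length(reg, 16)
  expect_setequal(
    names(reg),
    c(paste0("biogeography_", 1:5), "abiotic_environment",
      paste0("temperature_regime_", 1:3), "community", "total_biodiversity",
      "peracarid_biodiversity", "habitat", "predation",
      "resource_1", "resource_2"))
  expect_equal(reg$predation$terms, "arcsin_predation")
  expect_equal(reg$biogeography_5$terms,
               c("latitude", "margin", "ocean", "latitude:margin",
                 "latitude:ocean"))
  interactions <- unlist(lapply(reg, function(m)
    grep(":", m$terms, value = TRUE)))
  expect_setequal(unique(interactions),
                  c("latitude:margin", "latitude:ocean", "sst_mean:sst_range"))
})

test_that("every registry model is fitted and ranked on a noise response", {
  env <- random_env(42, seed = 75)
  pt <- transform_predictors(env)
  y <- withr::with_seed(75, rnorm(42))
  rk <- rank_registry(y, pt)
  expect_equal(nrow(rk), 16)
  expect_equal(rk$delta_aicc[1], 0)
  expect_true(all(diff(rk$aicc) >= 0))
  expect_true(all(rk$k >= 3))
})

test_that("AICc ranking is invariant to adding a constant to the response", {
  env <- random_env(42, seed = 76)
  pt <- transform_predictors(env)
  y <- withr::with_seed(76, rnorm(42))
  r1 <- rank_registry(y, pt)
  r2 <- rank_registry(y + 100, pt)
  expect_equal(r1$model, r2$model)
  expect_equal(r1$aicc, r2$aicc, tolerance = 1e-8)
})

test_that("a predation-driven response puts the predation model first", {
  env <- random_env(42, seed = 77)
  pt <- transform_predictors(env)
  signal <- 2 * pt$arcsin_predation
  hits <- withr::with_seed(77, {
    sum(vapply(1:100, function(i) {
      y <- signal + rnorm(42, 0, sd(signal) / 2)
      rank_registry(y, pt)$model[1] == "predation"
    }, TRUE))
  })
  expect_gte(hits, 90)
})

test_that("VIF equals one for orthogonal predictors and flags collinear copies", {
  # orthogonal polynomial columns: mutually orthogonal AND mean-zero, so
  # each auxiliary regression (which includes an intercept) has R^2 = 0
  X <- stats::poly(1:40, 3)
  df <- data.frame(a = X[, 1], b = X[, 2], c = X[, 3])
  v <- vif_terms(c("a", "b", "c"), df)
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-10)

  df$d <- df$a   # exact copy
  v2 <- vif_terms(c("a", "b", "d"), df)
  expect_true(v2[["a"]] > 1e6 && v2[["d"]] > 1e6)
  expect_equal(v2[["b"]], 1, tolerance = 1e-10)
})

test_that("vif_terms agrees with car::vif on a numeric design", {
  env <- random_env(42, seed = 79)
  pt <- transform_predictors(env)
  terms <- c("latitude", "arcsin_predation", "log_epiphyte", "sst_mean")
  y <- withr::with_seed(79, rnorm(42))
  fit <- lm(reformulate(terms, "y"), data = cbind(y = y, pt))
  expect_equal(unname(vif_terms(terms, pt)), unname(car::vif(fit)),
               tolerance = 1e-8)
})

test_that("composite selection unions the top three models and screens VIF", {
  # custom registry with three disjoint single-predictor models
  reg <- structure(list(
    m1 = list(name = "m1", terms = "x1"),
    m2 = list(name = "m2", terms = "x2"),
    m3 = list(name = "m3", terms = "x3"),
    m4 = list(name = "m4", terms = "x4")), class = "model_registry")
  withr::local_seed(80)
  n <- 42
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                   x4 = rnorm(n, 0, 1e-2))
  y <- df$x1 + 0.8 * df$x2 + 0.6 * df$x3 + rnorm(n, 0, 0.4)
  sel <- select_drivers(y, df, registry = reg)
  expect_length(sel$composite_terms, 3)
  expect_setequal(sel$composite_terms, c("x1", "x2", "x3"))
  expect_setequal(sel$final_terms, c("x1", "x2", "x3"))

  # collinear duplicate of x1 under another name is removed by the VIF rule
  reg2 <- structure(c(unclass(reg)[c("m1", "m2")],
                      list(m5 = list(name = "m5", terms = "x5"))),
                    class = "model_registry")
  df$x5 <- df$x1 + rnorm(n, 0, 1e-8)
  sel2 <- select_drivers(y, df, registry = reg2)
  expect_length(sel2$vif_removed, 1)
  expect_true(sel2$vif_removed %in% c("x1", "x5"))
})

test_that("backward elimination never worsens AICc and recovers two drivers", {
  env <- random_env(42, seed = 81)
  pt <- transform_predictors(env)
  # predation carries the larger standardized share so its one-term model
  # outranks the nested latitude models and reaches the composite pool
  signal <- 2.5 * pt$arcsin_predation - 0.05 * pt$latitude
  hits <- withr::with_seed(81, {
    vapply(1:100, function(i) {
      y <- signal + rnorm(42, 0, sd(signal) / 2)
      sel <- select_drivers(y, pt)
      start <- sel$audit$aicc[sel$audit$step == "composite"]
      # the elimination path itself never worsens AICc (the parsimony rule
      # may then prefer a smaller model within its AICc window)
      expect_lte(min(sel$audit$aicc), start + 1e-10)
      all(c("arcsin_predation", "latitude") %in% sel$final_terms)
    }, TRUE)
  })
  expect_gte(sum(hits), 80)
})

test_that("Welch statistics match the textbook formula oracle", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6, 19.0, 21.7, 21.4)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.1, 22.9, 30.5, 24.2)
  ses <- data.frame(ses = c(x, y), ocean = rep(c("Atlantic", "Pacific"),
                                               each = 15))
  out <- ses_t_tests(ses)
  two <- out[out$test == "two-sample", ]
  orac <- oracle_welch(x, y)
  expect_equal(two$t, orac$t, tolerance = 1e-10)
  expect_equal(two$df, orac$df, tolerance = 1e-10)

  sym <- data.frame(ses = c(-2, -1, 1, 2, -1.5, 1.5), ocean = "Atlantic")
  o2 <- ses_t_tests(sym)
  expect_equal(o2$t[o2$group == "overall"], 0)
  degen <- data.frame(ses = rep(0, 5), ocean = "Atlantic")
  expect_error(ses_t_tests(degen), "zero variance")
})
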