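#' Synthetic study scenario for a two-ocean eelgrass survey
#'
#' Describes a hierarchical sampling design (two oceans, each with two
#' continental margins, each margin with several sites of 20 plots), a
#' latitudinal predation gradient, and a community-assembly regime with
#' tunable environmental-filtering and limiting-similarity strength. The
#' defaults mirror the scale of the field study the package is designed
#' around: 42 sites, 840 plots, a pool of 105 species of which 10 occur in
#' both oceans, and predation declining from nearly complete removal at
#' 30 deg N to roughly 20% at 60 deg N.
#'
#' Assembly is sequential: species are drawn without replacement with weight
#' proportional to `exp(-tau_filter * (t_i - theta)^2) *
#' (1 - exp(-d_NN / sigma))^tau_limit`, where `t_i` is the species' value of
#' the designated filtering trait (normalized adult length by default),
#' `theta` the site optimum (tied to scaled latitude), and `d_NN` the
#' candidate's Gower nearest-neighbour distance to the species already
#' selected. With both strengths zero, assembly is uniform.
#'
#' @param n_species named vector: pool sizes per ocean.
#' @param n_shared number of species present in both ocean pools.
#' @param n_sites nested list: sites per ocean and margin (each 6--14).
#' @param plots_per_site plots per site (default 20).
#' @param latitude_range site latitudes are uniform in this range (deg N).
#' @param predation_a,predation_b inverse-logit intercept/slope of the
#'   predation--latitude gradient (`b > 0` means predation declines
#'   poleward); `predation_noise` is additive Gaussian noise (then clipped
#'   to \[0, 1\]).
#' @param tethers_per_plot tethered prey per plot; `moult_prob` the chance a
#'   tether is lost to moulting (excluded from the predation denominator).
#' @param richness_mean,richness_sd site richness is drawn from a
#'   discretized normal with this mean and sd, clipped to \[2, pool size\].
#' @param tau_filter,tau_limit baseline filtering / limiting-similarity
#'   strengths (>= 0; both 0 gives uniform random assembly).
#' @param tau_filter_latitude additional filtering strength per unit scaled
#'   latitude; `tau_limit_predation` additional limiting-similarity strength
#'   per unit predation (links assembly to the gradient).
#' @param sigma length scale (> 0) of the nearest-neighbour repulsion in
#'   Gower distance units.
#' @param filter_trait trait the environmental filter acts on.
#' @param n_missing_diet number of species given partially missing diet
#'   traits (0 disables; use to exercise feasibility rules).
#' @return an object of class `zen_scenario`.
#' @export
zen_scenario <- function(n_species = c(Atlantic = 55, Pacific = 60),
                         n_shared = 10,
                         n_sites = list(Atlantic = c(east = 11, west = 10),
                                        Pacific = c(east = 7, west = 14)),
                         plots_per_site = 20,
                         latitude_range = c(30, 60),
                         predation_a = 8.4, predation_b = 0.163,
                         predation_noise = 0.05,
                         tethers_per_plot = 3, moult_prob = 0.05,
                         richness_mean = 13, richness_sd = 2,
                         tau_filter = 0, tau_limit = 0,
                         tau_filter_latitude = 0, tau_limit_predation = 0,
                         sigma = 0.15, filter_trait = "max_length",
                         n_missing_diet = 0) {
  if (n_shared > min(n_species))
    stopf("shared-species count (%d) exceeds an ocean pool size", n_shared)
  if (sigma <= 0) stopf("sigma must be positive")
  if (tau_filter < 0 || tau_limit < 0)
    stopf("assembly strengths must be non-negative")
  structure(list(n_species = n_species, n_shared = n_shared,
                 n_sites = n_sites, plots_per_site = plots_per_site,
                 latitude_range = latitude_range, predation_a = predation_a,
                 predation_b = predation_b, predation_noise = predation_noise,
                 tethers_per_plot = tethers_per_plot, moult_prob = moult_prob,
                 richness_mean = richness_mean, richness_sd = richness_sd,
                 tau_filter = tau_filter,
                 tau_limit = tau_limit,
                 tau_filter_latitude = tau_filter_latitude,
                 tau_limit_predation = tau_limit_predation,
                 sigma = sigma, filter_trait = filter_trait,
                 n_missing_diet = n_missing_diet),
            class = "zen_scenario")
}

#' @export
print.zen_scenario <- function(x, ...) {
  ns <- sum(unlist(x$n_sites))
  cat(sprintf("Synthetic scenario: %d sites x %d plots, %d species (%d shared)\n",
              ns, x$plots_per_site, sum(x$n_species) - x$n_shared, x$n_shared))
  cat(sprintf("Assembly: tau_filter = %g (+%g/lat), tau_limit = %g (+%g/predation), sigma = %g\n",
              x$tau_filter, x$tau_filter_latitude, x$tau_limit,
              x$tau_limit_predation, x$sigma))
  invisible(x)
}

#' Generate a species pool with traits and ocean membership
#'
#' Species get lognormal adult lengths clipped to the schema range, brood
#' sizes binned into the ordered fecundity categories, categorical shape /
#' habit / motility, and Bernoulli diet flags with mild positive association
#' between macroalgae and live-seagrass feeding, detritivory and
#' seagrass-detritus feeding, and suspension feeding and bioturbation.
#' Optionally a block of species gets partially missing diet traits.
#'
#' @param scenario a `zen_scenario`.
#' @param seed RNG seed.
#' @return list with `traits` (species-by-trait data.frame) and `membership`
#'   (data.frame: species, Atlantic, Pacific).
#' @export
gen_pool <- function(scenario, seed = 1L) {
  with_seed(seed, {
    n_tot <- sum(scenario$n_species) - scenario$n_shared
    sp <- sprintf("sp%03d", seq_len(n_tot))
    n_shared <- scenario$n_shared
    n_atl_only <- scenario$n_species[["Atlantic"]] - n_shared
    membership <- data.frame(
      species = sp,
      Atlantic = seq_len(n_tot) <= n_shared + n_atl_only,
      Pacific = seq_len(n_tot) <= n_shared |
        seq_len(n_tot) > n_shared + n_atl_only,
      stringsAsFactors = FALSE)

    len <- pmin(50, pmax(2, stats::rlnorm(n_tot, log(10), 0.45)))
    eggs <- round(stats::rlnorm(n_tot, log(40), 0.9))
    bioturb <- stats::rbinom(n_tot, 1, 0.3)
    suspension <- stats::rbinom(n_tot, 1, ifelse(bioturb == 1, 0.6, 0.2))
    macro <- stats::rbinom(n_tot, 1, 0.5)
    seagrass <- stats::rbinom(n_tot, 1, ifelse(macro == 1, 0.4, 0.1))
    detrit <- stats::rbinom(n_tot, 1, 0.5)
    sg_detrit <- stats::rbinom(n_tot, 1, ifelse(detrit == 1, 0.6, 0.15))
    traits <- data.frame(
      species = sp,
      max_fecundity = bin_fecundity(eggs),
      max_length = round(len, 1),
      body_shape = sample(c("laterally_compressed", "dorsoventrally_compressed",
                            "vermiform"), n_tot, TRUE, prob = c(0.6, 0.25, 0.15)),
      living_habit = sample(c("free", "parasite_commensal", "tube_burrow"),
                            n_tot, TRUE, prob = c(0.55, 0.1, 0.35)),
      motility = sample(c("swimmer", "crawler"), n_tot, TRUE),
      bioturbator = bioturb,
      feeds_microalgae = stats::rbinom(n_tot, 1, 0.85),
      feeds_macroalgae = macro,
      feeds_seagrass = seagrass,
      feeds_seagrass_detritus = sg_detrit,
      suspension_feeder = suspension,
      detritivore = detrit,
      carnivore = stats::rbinom(n_tot, 1, 0.2),
      stringsAsFactors = FALSE)

    if (scenario$n_missing_diet > 0) {
      diet_cols <- trait_subset_names(default_trait_schema(), "diet")
      idx <- sample.int(n_tot, min(scenario$n_missing_diet, n_tot))
      for (i in idx) {
        gone <- sample(diet_cols, sample(3:6, 1))
        traits[i, gone] <- NA
      }
    }
    list(traits = traits, membership = membership)
  })
}

#' Generate site-level environment along a latitudinal gradient
#'
#' Latitudes are uniform within the scenario range on each coast; predation
#' follows an inverse-logit decline with latitude plus noise, clipped to
#' \[0, 1\]; epiphyte load is lognormal; temperature variables decline with
#' latitude; habitat-structure and resource variables are drawn from
#' lognormal or Gaussian distributions with mild latitude trends.
#'
#' @param scenario a `zen_scenario`.
#' @param seed RNG seed.
#' @return data.frame with one row per site: site, ocean, margin, latitude,
#'   predation (latent site-level rate), plus abiotic, habitat and resource
#'   columns matching [transform_predictors()] (richness and abundance
#'   columns are filled in when communities are assembled).
#' @export
gen_environment <- function(scenario, seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (ocean in names(scenario$n_sites)) {
      for (margin in names(scenario$n_sites[[ocean]])) {
        n <- scenario$n_sites[[ocean]][[margin]]
        code <- paste0(toupper(substr(ocean, 1, 1)), toupper(substr(margin, 1, 1)))
        rows[[paste(ocean, margin)]] <- data.frame(
          site = sprintf("%s%02d", code, seq_len(n)),
          ocean = ocean, margin = margin,
          latitude = stats::runif(n, scenario$latitude_range[1],
                                  scenario$latitude_range[2]),
          stringsAsFactors = FALSE)
      }
    }
    env <- do.call(rbind, rows)
    rownames(env) <- NULL
    n <- nrow(env)
    lat <- env$latitude
    env$predation <- pmin(1, pmax(0,
      stats::plogis(scenario$predation_a - scenario$predation_b * lat) +
        stats::rnorm(n, 0, scenario$predation_noise)))
    env$temp_insitu <- 28 - 0.35 * lat + stats::rnorm(n, 0, 1.5)
    env$salinity <- stats::rnorm(n, 28, 4)
    env$sst_mean <- 26 - 0.33 * lat + stats::rnorm(n, 0, 1.2)
    env$sst_range <- stats::rlnorm(n, log(8), 0.4)
    env$shoot_density <- stats::rlnorm(n, log(300) + 0.01 * (lat - 45), 0.5)
    env$sheath_width <- pmax(1, stats::rnorm(n, 4, 1))
    env$sheath_length <- pmax(2, stats::rnorm(n, 8, 2))
    env$longest_leaf <- pmax(10, stats::rnorm(n, 50, 15))
    env$ag_biomass <- stats::rlnorm(n, log(80), 0.5)
    env$macroalgal_biomass <- stats::rbinom(n, 1, 0.8) *
      stats::rlnorm(n, log(5), 1)
    env$epiphyte_load <- stats::rlnorm(n, log(1), 0.6)
    env$chla <- stats::rlnorm(n, log(2), 0.5)
    env$no2 <- stats::rlnorm(n, log(0.3), 0.7)
    env$par <- pmax(5, stats::rnorm(n, 40 - 0.3 * (lat - 45), 6))
    env$leaf_n <- pmax(0.5, stats::rnorm(n, 2.5, 0.4))
    env
  })
}

#' Assemble one site's community under filtering and limiting similarity
#'
#' Sequential weighted sampling without replacement from the pool. The
#' candidate weight is `exp(-tau_filter * (t_i - theta)^2) *
#' (1 - exp(-d_NN / sigma))^tau_limit`; the first species is drawn by the
#' filtering factor alone. Species counts are then scattered over plots
#' multinomially with lognormal plot weights.
#'
#' @param richness number of species to select (<= pool size).
#' @param theta site optimum of the filtering trait, on \[0, 1\].
#' @param tau_filter,tau_limit assembly strengths for this site.
#' @param trait_norm named vector: pool species' filtering-trait values
#'   normalized to \[0, 1\].
#' @param D Gower distance matrix over the pool (all traits).
#' @param sigma repulsion length scale (> 0).
#' @return character vector of selected species.
#' @export
assemble_community <- function(richness, theta, tau_filter, tau_limit,
                               trait_norm, D, sigma = 0.15) {
  if (sigma <= 0) stopf("sigma must be positive")
  pool <- names(trait_norm)
  if (richness > length(pool)) stopf("site richness exceeds pool size")
  tau_filter <- max(0, tau_filter); tau_limit <- max(0, tau_limit)
  filt <- exp(-tau_filter * (trait_norm - theta)^2)
  selected <- character(0)
  remaining <- pool
  for (s in seq_len(richness)) {
    w <- filt[remaining]
    if (length(selected) && tau_limit > 0) {
      dnn <- apply(D[remaining, selected, drop = FALSE], 1L,
                   function(r) min(r, na.rm = TRUE))
      w <- w * (1 - exp(-dnn / sigma))^tau_limit
    }
    if (!any(w > 0) || anyNA(w)) w <- rep(1, length(remaining))
    pick <- remaining[sample.int(length(remaining), 1L, prob = w)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

# Scatter a site's individuals over plots and species.
scatter_plots <- function(site, species, n_plots, plots_prefix = "p") {
  total <- max(length(species), round(stats::rlnorm(1, log(300), 0.5)))
  rel <- stats::rgamma(length(species), 1)   # broken-stick-like abundances
  counts <- pmax(1L, stats::rmultinom(1, total - length(species), rel)[, 1] + 1L)
  plot_w <- stats::rlnorm(n_plots, 0, 0.6)   # lognormal plot totals
  plot_ids <- sprintf("%s%02d", plots_prefix, seq_len(n_plots))
  biomass <- stats::rlnorm(n_plots, log(5), 0.4)
  rows <- lapply(seq_along(species), function(i) {
    per_plot <- stats::rmultinom(1, counts[i], plot_w)[, 1]
    data.frame(site = site, plot = plot_ids, species = species[i],
               count = per_plot, ag_biomass_g = biomass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a full synthetic dataset from a scenario
#'
#' Generates the species pool, site environments, assembled communities,
#' plot-level abundance records (with per-plot eelgrass biomass) and tether
#' outcomes. Richness and abundance predictors in the environment table are
#' filled from the realized communities.
#'
#' @param object a `zen_scenario`.
#' @param nsim number of datasets (a list is returned when > 1).
#' @param seed master seed; all randomness derives from it.
#' @param ... unused.
#' @return a list of class `zen_dataset` with elements `traits`,
#'   `membership`, `environment`, `plots`, `tethers`, `communities`
#'   (site-by-species count matrix), `scenario`, `seed`.
#' @export
simulate.zen_scenario <- function(object, nsim = 1, seed = 1L, ...) {
  if (nsim > 1)
    return(lapply(seq_len(nsim), function(i)
      simulate.zen_scenario(object, 1, child_seed(seed, i))))
  scenario <- object
  pool <- gen_pool(scenario, child_seed(seed, 1))
  env <- gen_environment(scenario, child_seed(seed, 2))

  schema <- default_trait_schema()
  D <- gower_dist(pool$traits, "all", schema)
  # Filter on the quantile scale of the trait, so the species pool is
  # uniformly dense along the filter axis and a site optimum anywhere on
  # [0, 1] packs the same number of candidates around it.
  len <- pool$traits[[scenario$filter_trait]]
  r <- rank(len, ties.method = "average", na.last = "keep")
  trait_norm <- setNames((r - 1) / (sum(!is.na(r)) - 1), pool$traits$species)
  lat_scaled <- (env$latitude - scenario$latitude_range[1]) /
    diff(scenario$latitude_range)

  plots <- list(); tethers <- list(); comm <- list()
  with_seed(child_seed(seed, 3), {
    for (i in seq_len(nrow(env))) {
      ocean_sp <- pool$membership$species[pool$membership[[env$ocean[i]]]]
      k <- min(length(ocean_sp),
               max(2L, round(stats::rnorm(1, scenario$richness_mean,
                                          scenario$richness_sd))))
      tau_f <- scenario$tau_filter + scenario$tau_filter_latitude * lat_scaled[i]
      tau_l <- scenario$tau_limit +
        scenario$tau_limit_predation * env$predation[i]
      sel <- assemble_community(k, lat_scaled[i], tau_f, tau_l,
                                trait_norm[ocean_sp],
                                unclass(D)[ocean_sp, ocean_sp],
                                scenario$sigma)
      plots[[i]] <- scatter_plots(env$site[i], sel, scenario$plots_per_site)
      n_teth <- scenario$plots_per_site * scenario$tethers_per_plot
      moulted <- stats::rbinom(n_teth, 1, scenario$moult_prob) == 1
      eaten <- stats::rbinom(n_teth, 1, env$predation[i]) == 1
      tethers[[i]] <- data.frame(
        site = env$site[i],
        plot = rep(sprintf("p%02d", seq_len(scenario$plots_per_site)),
                   each = scenario$tethers_per_plot),
        tether_id = sprintf("t%03d", seq_len(n_teth)),
        outcome = ifelse(moulted, "moulted", ifelse(eaten, "eaten", "uneaten")),
        stringsAsFactors = FALSE)
      comm[[i]] <- sel
    }
  })
  plots <- do.call(rbind, plots)
  tethers <- do.call(rbind, tethers)

  all_sp <- pool$traits$species
  cm <- matrix(0L, nrow(env), length(all_sp),
               dimnames = list(env$site, all_sp))
  agg <- tapply(plots$count, list(plots$site, plots$species), sum, default = 0)
  cm[rownames(agg), colnames(agg)] <- agg

  env$peracarid_richness <- rowSums(cm > 0)[env$site]
  dens <- tapply(plots$count / plots$ag_biomass_g, plots$site, sum)
  env$crustacean_abundance <- as.numeric(dens[env$site])
  env$crustacean_size <- vapply(env$site, function(s) {
    sp <- colnames(cm)[cm[s, ] > 0]
    stats::median(pool$traits$max_length[match(sp, pool$traits$species)])
  }, 0)
  env <- with_seed(child_seed(seed, 4), {
    env$epifaunal_richness <- env$peracarid_richness +
      stats::rpois(nrow(env), 15)
    env
  })

  structure(list(traits = pool$traits, membership = pool$membership,
                 environment = env, plots = plots, tethers = tethers,
                 communities = cm, scenario = scenario, seed = seed),
            class = "zen_dataset")
}

#' @export
print.zen_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d sites, %d plot records, %d species, seed %d\n",
              nrow(x$environment), nrow(x$plots), nrow(x$traits), x$seed))
  invisible(x)
}

#' Write a synthetic dataset as a CSV bundle
#'
#' Writes `traits.csv`, `plots.csv`, `tethers.csv`, `environment.csv` and a
#' `manifest.yaml` recording the scenario parameters, seed and package
#' version.
#'
#' @param scenario a `zen_scenario`.
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param overwrite overwrite existing files (error otherwise).
#' @return (invisibly) the `zen_dataset`, with an attribute `paths`.
#' @export
gen_dataset <- function(scenario, dir, seed = 1L, overwrite = FALSE) {
  ds <- simulate.zen_scenario(scenario, 1, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c(traits = "traits.csv", plots = "plots.csv",
                            tethers = "tethers.csv",
                            environment = "environment.csv",
                            manifest = "manifest.yaml"))
  names(paths) <- c("traits", "plots", "tethers", "environment", "manifest")
  clash <- paths[file.exists(paths)]
  if (length(clash) && !overwrite)
    stopf("output file(s) exist (use overwrite = TRUE): %s",
          paste(basename(clash), collapse = ", "))
  write_trait_table(ds$traits, paths["traits"])
  utils::write.csv(ds$plots, paths["plots"], row.names = FALSE)
  utils::write.csv(ds$tethers, paths["tethers"], row.names = FALSE)
  utils::write.csv(ds$environment, paths["environment"], row.names = FALSE)
  yaml::write_yaml(list(
    generator = "traitdisp",
    version = as.character(utils::packageVersion("traitdisp")),
    seed = seed,
    scenario = unclass(ds$scenario)), paths["manifest"])
  attr(ds, "paths") <- paths
  invisible(ds)
}

#' Canned scenarios: filtering-, repulsion- and predation-driven assembly
#'
#' Three ready-made variants of [zen_scenario()] used throughout the
#' package's calibration experiments: `filtering_scenario()` sets a strong
#' environmental filter (`tau_filter = 30`), `limiting_scenario()` strong
#' nearest-neighbour repulsion (`tau_limit = 8`), and
#' `driver_recovery_scenario()` links repulsion strength to the site's
#' predation rate (`tau_limit_predation = 20`) with realistic site-to-site
#' predation scatter (`predation_noise = 0.15`), five tethers per plot and
#' richer sites (`richness_mean = 18`) so the per-site SES signal is stable.
#'
#' @param ... overrides passed on to [zen_scenario()].
#' @return a `zen_scenario`.
#' @export
driver_recovery_scenario <- function(...) {
  args <- list(tau_limit_predation = 20, predation_noise = 0.15,
               tethers_per_plot = 5, richness_mean = 18)
  extra <- list(...)
  do.call(zen_scenario, utils::modifyList(args, extra))
}

#' @rdname driver_recovery_scenario
#' @export
filtering_scenario <- function(...) {
  do.call(zen_scenario, utils::modifyList(list(tau_filter = 30), list(...)))
}

#' @rdname driver_recovery_scenario
#' @export
limiting_scenario <- function(...) {
  do.call(zen_scenario, utils::modifyList(list(tau_limit = 8), list(...)))
}

#' One-call SES computation on a synthetic dataset
#'
#' Simulates a dataset, aggregates plots to sites, and computes the SES grid
#' -- the common spine of the package's calibration experiments.
#'
#' @param scenario a `zen_scenario`.
#' @param seed master seed (dataset and permutations derive from it).
#' @param configs configuration grid (default: MNTD / tip shuffle / global
#'   pool / all traits).
#' @param n_perm permutations per null distribution.
#' @return list with `ses` (the `ses_grid`), `dataset` (the `zen_dataset`),
#'   `community` (the `community_matrix`), `env` (site table with
#'   tether-derived predation).
#' @export
simulate_ses <- function(scenario, seed = 1L,
                         configs = enumerate_configs(
                           metrics = "mntd", algorithms = "tip_shuffle",
                           pools = "global", trait_subsets = "all"),
                         n_perm = 999) {
  ds <- simulate.zen_scenario(scenario, 1, seed)
  agg <- aggregate_sites(ds$plots, ds$tethers)
  env <- ds$environment
  env$predation <- agg$env$predation[match(env$site, agg$env$site)]
  community <- community_matrix(agg$abundance,
                                env[match(rownames(agg$abundance), env$site), ])
  ses <- trait_dispersion(community, ds$traits, configs,
                          n_perm = n_perm, seed = child_seed(seed, 999))
  list(ses = ses, dataset = ds, community = community, env = env)
}
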