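# Shared fixtures, built in code.

# The three-species toy table: A and B differ in length and motility,
# A and C only in microalgae feeding.
toy_traits <- function() {
  data.frame(species = c("A", "B", "C"),
             max_length = c(10, 30, 10),
             motility = c("swimmer", "crawler", "swimmer"),
             feeds_microalgae = c(1, 1, 0),
             stringsAsFactors = FALSE)
}
toy_subset <- c("max_length", "motility", "feeds_microalgae")

# A complete, schema-conformant trait table of n random species.
random_traits <- function(n, missing_rate = 0, seed = 1) {
  withr::with_seed(seed, {
    schema <- default_trait_schema()
    tab <- data.frame(
      species = sprintf("s%02d", seq_len(n)),
      max_fecundity = sample(schema$traits$max_fecundity$levels, n, TRUE),
      max_length = round(runif(n, 2, 50), 1),
      body_shape = sample(schema$traits$body_shape$levels, n, TRUE),
      living_habit = sample(schema$traits$living_habit$levels, n, TRUE),
      motility = sample(schema$traits$motility$levels, n, TRUE),
      bioturbator = rbinom(n, 1, 0.5),
      feeds_microalgae = rbinom(n, 1, 0.7),
      feeds_macroalgae = rbinom(n, 1, 0.5),
      feeds_seagrass = rbinom(n, 1, 0.3),
      feeds_seagrass_detritus = rbinom(n, 1, 0.4),
      suspension_feeder = rbinom(n, 1, 0.3),
      detritivore = rbinom(n, 1, 0.5),
      carnivore = rbinom(n, 1, 0.2),
      stringsAsFactors = FALSE)
    if (missing_rate > 0) {
      for (cn in setdiff(names(tab), "species")) {
        gone <- runif(n) < missing_rate
        tab[gone, cn] <- NA
      }
    }
    tab
  })
}

# Random binary occurrence matrix with no empty rows/columns.
random_occurrence <- function(n_sites, n_species, fill = 0.35, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      m <- matrix(rbinom(n_sites * n_species, 1, fill), n_sites, n_species,
                  dimnames = list(sprintf("site%02d", seq_len(n_sites)),
                                  sprintf("s%02d", seq_len(n_species))))
      if (all(rowSums(m) >= 2) && all(colSums(m) >= 1)) return(m)
    }
  })
}

# Small complete synthetic dataset for pipeline tests.
tiny_scenario <- function(...) {
  zen_scenario(n_species = c(Atlantic = 14, Pacific = 15), n_shared = 4,
               n_sites = list(Atlantic = c(east = 2, west = 2),
                              Pacific = c(east = 2, west = 2)),
               plots_per_site = 4, richness_mean = 6, richness_sd = 1, ...)
}

# Raw site-level environment table with every column the predictor
# transformations expect.
random_env <- function(n, seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      site = sprintf("site%02d", seq_len(n)),
      latitude = runif(n, 30, 60),
      ocean = rep_len(c("Atlantic", "Pacific"), n),
      margin = rep_len(c("east", "east", "west", "west"), n),
      temp_insitu = rnorm(n, 15, 3),
      salinity = rnorm(n, 28, 4),
      sst_mean = rnorm(n, 12, 3),
      sst_range = rlnorm(n, log(8), 0.3),
      crustacean_abundance = rlnorm(n, log(50), 0.8),
      crustacean_size = rlnorm(n, log(8), 0.4),
      epifaunal_richness = rpois(n, 30) + 5,
      peracarid_richness = rpois(n, 12) + 3,
      shoot_density = rlnorm(n, log(300), 0.5),
      sheath_width = rnorm(n, 4, 1),
      sheath_length = rnorm(n, 8, 2),
      longest_leaf = rnorm(n, 50, 10),
      ag_biomass = rlnorm(n, log(80), 0.4),
      macroalgal_biomass = rbinom(n, 1, 0.8) * rlnorm(n, log(5), 1),
      predation = runif(n, 0.05, 0.95),
      epiphyte_load = rlnorm(n, 0, 0.6),
      chla = rlnorm(n, log(2), 0.5),
      no2 = rlnorm(n, log(0.3), 0.6),
      par = rnorm(n, 40, 6),
      leaf_n = rnorm(n, 2.5, 0.4),
      stringsAsFactors = FALSE)
  })
}
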