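#' Habitat-structure principal component analysis
#'
#' PCA of the five eelgrass habitat-structure variables (shoot density, leaf
#' sheath width and length, longest leaf length, aboveground biomass),
#' centred and scaled to unit variance. The sign of each component is fixed
#' so that its largest-magnitude loading is positive, making scores
#' deterministic across platforms.
#'
#' @param structure data.frame of habitat variables (numeric columns only;
#'   at least 3 sites, no missing values).
#' @return list with `scores` (matrix, columns PC1/PC2), `loadings`,
#'   `explained` (proportion of variance per component).
#' @export
pca_habitat <- function(structure) {
  x <- as.matrix(structure)
  if (nrow(x) < 3L) stopf("habitat PCA needs at least 3 sites")
  if (anyNA(x)) stopf("habitat PCA does not accept missing values")
  const <- apply(x, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) stopf("constant habitat column(s): %s",
                        paste(colnames(x)[const], collapse = ", "))
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, 1:2, drop = FALSE], loadings = p$rotation,
       explained = expl)
}

#' Transform raw site variables into the model-registry predictor table
#'
#' Applies the named transformations used by the a priori models:
#' log for abundance, richness, epiphyte load and chlorophyll a;
#' log(x + 1) for macroalgal biomass (tolerates zeros); arcsin for the
#' predation proportion (literal arcsin(p) by default; set
#' `arcsin_sqrt = TRUE` for the variance-stabilizing arcsin(sqrt(p)));
#' habitat PC1/PC2 from [pca_habitat()]. Ocean and margin become factors
#' with alphabetical reference levels (Atlantic, east).
#'
#' @param env data.frame with one row per site and raw columns: `site`,
#'   `latitude`, `ocean`, `margin`, `temp_insitu`, `salinity`, `sst_mean`,
#'   `sst_range`, `crustacean_abundance`, `crustacean_size`,
#'   `epifaunal_richness`, `peracarid_richness`, `shoot_density`,
#'   `sheath_width`, `sheath_length`, `longest_leaf`, `ag_biomass`,
#'   `macroalgal_biomass`, `predation`, `epiphyte_load`, `chla`, `no2`,
#'   `par`, `leaf_n`.
#' @param arcsin_sqrt use arcsin(sqrt(p)) instead of arcsin(p).
#' @return data.frame of transformed predictors, one row per site.
#' @export
transform_predictors <- function(env, arcsin_sqrt = FALSE) {
  need <- c("site", "latitude", "ocean", "margin", "temp_insitu", "salinity",
            "sst_mean", "sst_range", "crustacean_abundance", "crustacean_size",
            "epifaunal_richness", "peracarid_richness", "shoot_density",
            "sheath_width", "sheath_length", "longest_leaf", "ag_biomass",
            "macroalgal_biomass", "predation", "epiphyte_load", "chla",
            "no2", "par", "leaf_n")
  miss <- setdiff(need, names(env))
  if (length(miss)) stopf("site table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  check_domain <- function(v, ok, what) {
    bad <- !is.na(v) & !ok(v)
    if (any(bad)) stopf("%s out of domain for site(s): %s", what,
                        paste(env$site[bad], collapse = ", "))
    if (anyNA(v)) stopf("%s missing for site(s): %s", what,
                        paste(env$site[is.na(v)], collapse = ", "))
  }
  check_domain(env$predation, function(v) v >= 0 & v <= 1, "predation proportion")
  for (cn in c("crustacean_abundance", "epifaunal_richness",
               "peracarid_richness", "epiphyte_load", "chla"))
    check_domain(env[[cn]], function(v) v > 0, cn)
  check_domain(env$macroalgal_biomass, function(v) v >= 0, "macroalgal_biomass")

  hab <- pca_habitat(env[, c("shoot_density", "sheath_width", "sheath_length",
                             "longest_leaf", "ag_biomass")])
  p <- env$predation
  data.frame(
    site = env$site,
    latitude = env$latitude,
    ocean = stats::relevel(factor(env$ocean), ref = sort(unique(env$ocean))[1]),
    margin = stats::relevel(factor(env$margin), ref = sort(unique(env$margin))[1]),
    temp_insitu = env$temp_insitu,
    salinity = env$salinity,
    sst_mean = env$sst_mean,
    sst_range = env$sst_range,
    log_crustacean_abundance = log(env$crustacean_abundance),
    median_crustacean_size = env$crustacean_size,
    log_epifaunal_richness = log(env$epifaunal_richness),
    log_peracarid_richness = log(env$peracarid_richness),
    pc1 = hab$scores[, 1],
    pc2 = hab$scores[, 2],
    log_macroalgae = log1p(env$macroalgal_biomass),
    arcsin_predation = if (arcsin_sqrt) asin(sqrt(p)) else asin(p),
    log_epiphyte = log(env$epiphyte_load),
    log_chla = log(env$chla),
    nitrogen_oxide_surface = env$no2,
    par = env$par,
    leaf_n = env$leaf_n,
    stringsAsFactors = FALSE
  )
}
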