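#' Aggregate plot-level records to a site table
#'
#' Abundances are standardized per plot (count divided by the plot's
#' aboveground eelgrass biomass, in grams dry weight) and then summed across
#' plots within a site, so a site's standardized abundance for a species is
#' the sum over plots of count / biomass. Incidence is standardized
#' abundance > 0. Site-level predation is the proportion of tethered prey
#' eaten, excluding moulted tethers from the denominator; partially consumed
#' prey should already be scored `eaten` at ingest. Plot-level habitat and
#' environment measures are averaged per site.
#'
#' @param plots data.frame: `site`, `plot`, `species`, `count`,
#'   `ag_biomass_g` (per-plot aboveground biomass; repeated across that
#'   plot's species rows).
#' @param tethers optional data.frame: `site`, `plot`, `tether_id`,
#'   `outcome` (one of `eaten`, `uneaten`, `moulted`).
#' @param plot_env optional data.frame: `site`, `plot`, plus numeric
#'   plot-level measures to be averaged per site.
#' @return a list of class `site_table` with `abundance` (site x species
#'   standardized densities), `occurrence`, and `env` (one row per site:
#'   predation plus averaged plot measures; predation `NA` when all tethers
#'   moulted, with a warning).
#' @export
aggregate_sites <- function(plots, tethers = NULL, plot_env = NULL) {
  req <- c("site", "plot", "species", "count", "ag_biomass_g")
  miss <- setdiff(req, names(plots))
  if (length(miss)) stopf("plots table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(plots$count < 0)) stopf("counts must be non-negative")
  if (any(plots$ag_biomass_g <= 0))
    stopf("aboveground biomass must be positive for standardization")

  dens <- plots$count / plots$ag_biomass_g
  ab <- tapply(dens, list(plots$site, plots$species), sum, default = 0)
  ab <- as.matrix(ab)
  occ <- matrix(as.integer(ab > 0), nrow(ab), ncol(ab), dimnames = dimnames(ab))

  env <- data.frame(site = rownames(ab), stringsAsFactors = FALSE)
  if (!is.null(tethers)) {
    bad <- setdiff(unique(tethers$outcome), c("eaten", "uneaten", "moulted"))
    if (length(bad)) stopf("unknown tether outcome(s): %s",
                           paste(bad, collapse = ", "))
    pr <- vapply(env$site, function(s) {
      o <- tethers$outcome[tethers$site == s]
      n_eat <- sum(o == "eaten"); n_un <- sum(o == "uneaten")
      if (n_eat + n_un == 0L) NA_real_ else n_eat / (n_eat + n_un)
    }, 0)
    if (anyNA(pr))
      warnf("site(s) with all tethers moulted: predation missing for %s",
            paste(env$site[is.na(pr)], collapse = ", "))
    env$predation <- pr
  }
  if (!is.null(plot_env)) {
    num_cols <- setdiff(names(plot_env)[vapply(plot_env, is.numeric, TRUE)],
                        c("plot"))
    for (cn in num_cols)
      env[[cn]] <- as.numeric(tapply(plot_env[[cn]], plot_env$site,
                                     mean, na.rm = TRUE)[env$site])
  }
  structure(list(abundance = ab, occurrence = occ, env = env),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("Site table: %d sites x %d species\n",
              nrow(x$abundance), ncol(x$abundance)))
  cat("Environment columns:", paste(names(x$env), collapse = ", "), "\n")
  invisible(x)
}
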