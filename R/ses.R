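#' Enumerate the dispersion configuration grid
#'
#' Builds the cross-product of distance metrics, permutation algorithms,
#' species pools and trait subsets, and flags the feasible subset after
#' applying exclusion rules. The default rule excludes the diet trait subset
#' under MNTD with the tip-shuffle algorithm (incomputable when some species
#' lack diet trait data). With the default grid (2 metrics x 2 algorithms x
#' 3 pools x 3 subsets) this yields 36 configurations of which 33 are
#' feasible.
#'
#' @param metrics character, subset of `c("mpd", "mntd")`.
#' @param algorithms character, subset of `c("independent_swap", "tip_shuffle")`.
#' @param pools character, e.g. `c("global", "Atlantic", "Pacific")`.
#' @param trait_subsets character, e.g. `c("all", "diet", "microhabitat")`.
#' @param exclusions a data.frame of configuration patterns to mark
#'   infeasible (columns among metric/algorithm/pool/trait_subset; `NA`
#'   matches anything), or `NULL` for no exclusions.
#' @return data.frame with columns `metric`, `algorithm`, `pool`,
#'   `trait_subset`, `feasible`; attributes `n_full` and `n_feasible`.
#' @export
#' @examples
#' cfg <- enumerate_configs()
#' attr(cfg, "n_full")      # 36
#' attr(cfg, "n_feasible")  # 33
enumerate_configs <- function(metrics = c("mpd", "mntd"),
                              algorithms = c("independent_swap", "tip_shuffle"),
                              pools = c("global", "Atlantic", "Pacific"),
                              trait_subsets = c("all", "diet", "microhabitat"),
                              exclusions = default_exclusions()) {
  grid <- expand.grid(metric = metrics, algorithm = algorithms, pool = pools,
                      trait_subset = trait_subsets,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$feasible <- TRUE
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      hit <- rep(TRUE, nrow(grid))
      for (col in intersect(names(exclusions), names(grid))) {
        pat <- exclusions[[col]][i]
        if (!is.na(pat)) hit <- hit & grid[[col]] == pat
      }
      grid$feasible[hit] <- FALSE
    }
  }
  structure(grid, n_full = nrow(grid), n_feasible = sum(grid$feasible))
}

#' @rdname enumerate_configs
#' @export
default_exclusions <- function() {
  data.frame(metric = "mntd", algorithm = "tip_shuffle", trait_subset = "diet",
             stringsAsFactors = FALSE)
}

#' Standard effect size of trait dispersion for one site
#'
#' Computes the observed metric (MPD or MNTD) for a site's assemblage and
#' compares it to a null distribution of `n_perm` values generated by the
#' chosen permutation algorithm: `independent_swap` randomizes the
#' pool-scoped incidence matrix (preserving row and column sums) and
#' recomputes the metric on the site's randomized assemblage; `tip_shuffle`
#' permutes species labels on the pool-scoped distance matrix and recomputes
#' the metric on the fixed assemblage. SES = (observed - null mean) / null
#' sd (sample sd, n-1 denominator). A site is infeasible when the observed
#' metric is undefined (fewer than 2 species or undefined distances) or the
#' null sd is zero (e.g. a site containing every pool species under tip
#' shuffle).
#'
#' @param site site identifier (must be a row of the scoped matrix).
#' @param scoped a pool scope from [scope_pool()].
#' @param D trait distance matrix covering the pool species.
#' @param metric `"mpd"` or `"mntd"`.
#' @param algorithm `"independent_swap"` or `"tip_shuffle"`.
#' @param n_perm number of permutations (default 999).
#' @param n_swaps successful swaps per independent-swap randomization.
#' @return one-row data.frame: site, observed, null_mean, null_sd, ses,
#'   quantile, feasible.
#' @export
ses_for_site <- function(site, scoped, D, metric = "mntd",
                         algorithm = "tip_shuffle", n_perm = 999,
                         n_swaps = 1000) {
  occ <- scoped$occurrence
  if (!site %in% rownames(occ)) stopf("site '%s' not in pool scope", site)
  res <- ses_grid_config(scoped, D, metric, algorithm, n_perm, n_swaps)
  res[res$site == site, , drop = FALSE]
}

# SES for every site of a scoped pool under one metric/algorithm config.
ses_grid_config <- function(scoped, D, metric, algorithm, n_perm, n_swaps) {
  occ <- scoped$occurrence
  sp <- colnames(occ)
  Dm <- unclass(D)[sp, sp]
  metric_rows <- if (metric == "mpd") mpd_rows else mntd_rows
  obs <- metric_rows(occ, Dm)

  nulls <- matrix(NA_real_, n_perm, nrow(occ))
  if (algorithm == "independent_swap") {
    can_swap <- has_checkerboard_cpp(occ)
    if (!can_swap)
      warnf("pool matrix has no checkerboard; independent-swap nulls are degenerate")
    for (p in seq_len(n_perm)) {
      rnd <- if (can_swap) independent_swap_cpp(occ, as.integer(n_swaps)) else occ
      nulls[p, ] <- metric_rows(rnd, Dm)
    }
  } else if (algorithm == "tip_shuffle") {
    n <- length(sp)
    for (p in seq_len(n_perm)) {
      perm <- sample.int(n)
      nulls[p, ] <- metric_rows(occ, Dm[perm, perm])
    }
  } else stopf("unknown algorithm '%s'", algorithm)

  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2L, stats::sd)
  # a null distribution that is constant up to floating-point noise (e.g. a
  # site holding every pool species under tip shuffle) counts as degenerate
  degenerate <- is.na(null_sd) |
    null_sd <= 1e-10 * pmax(1, abs(null_mean))
  ses <- ifelse(!degenerate, (obs - null_mean) / null_sd, NA_real_)
  quant <- vapply(seq_along(obs), function(i) {
    if (is.na(obs[i]) || anyNA(nulls[, i])) return(NA_real_)
    (sum(nulls[, i] < obs[i]) + 1) / (n_perm + 1)
  }, 0)
  feasible <- !is.na(obs) & !degenerate & colSums(is.na(nulls)) == 0L
  data.frame(site = rownames(occ), observed = obs, null_mean = null_mean,
             null_sd = null_sd, ses = ses, quantile = quant,
             feasible = feasible, row.names = NULL, stringsAsFactors = FALSE)
}

#' Trait dispersion standard effect sizes over a configuration grid
#'
#' The main estimator: for every feasible configuration (metric x algorithm
#' x pool x trait subset) it scopes the community to the species pool,
#' computes Gower distances over the trait subset within that pool, and
#' derives per-site standard effect sizes against the configured null model.
#'
#' @param community a `community_matrix`.
#' @param traits species-by-trait data.frame covering all community species.
#' @param configs configuration grid from [enumerate_configs()]; infeasible
#'   rows are skipped.
#' @param schema a `trait_schema`.
#' @param n_perm permutations per null distribution (default 999).
#' @param n_swaps successful swaps per independent-swap randomization.
#' @param seed master seed; per-configuration child seeds are derived from
#'   it, so the full grid is reproducible.
#' @return an object of class `ses_grid`: a data.frame with one row per site
#'   x feasible configuration (columns site, metric, algorithm, pool,
#'   trait_subset, observed, null_mean, null_sd, ses, quantile, feasible)
#'   plus site metadata (ocean, margin, latitude).
#' @export
trait_dispersion <- function(community, traits,
                             configs = enumerate_configs(),
                             schema = default_trait_schema(),
                             n_perm = 999, n_swaps = 1000, seed = 1L) {
  stopifnot(inherits(community, "community_matrix"))
  run <- configs[configs$feasible, , drop = FALSE]
  out <- vector("list", nrow(run))
  for (i in seq_len(nrow(run))) {
    cf <- run[i, ]
    scoped <- scope_pool(community, cf$pool)
    if (length(scoped$species) < 2L) {
      warnf("pool '%s' has fewer than 2 species; configuration skipped", cf$pool)
      next
    }
    pool_traits <- traits[match(scoped$species, traits$species), , drop = FALSE]
    D <- gower_dist(pool_traits, subset = cf$trait_subset, schema = schema)
    res <- with_seed(child_seed(seed, i),
                     ses_grid_config(scoped, D, cf$metric, cf$algorithm,
                                     n_perm, n_swaps))
    res <- cbind(res, cf[rep(1L, nrow(res)), c("metric", "algorithm", "pool",
                                               "trait_subset"), drop = FALSE],
                 row.names = NULL)
    meta <- scoped$sites[match(res$site, scoped$sites$site),
                         c("ocean", "margin", "latitude"), drop = FALSE]
    out[[i]] <- cbind(res, meta, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("ses_grid", "data.frame"),
            n_perm = n_perm, n_swaps = n_swaps, seed = seed,
            n_configs_run = nrow(run))
}

#' @export
print.ses_grid <- function(x, ...) {
  cat(sprintf("SES grid: %d rows (%d sites x %d configurations), %d permutations\n",
              nrow(x), length(unique(x$site)), attr(x, "n_configs_run"),
              attr(x, "n_perm")))
  cat(sprintf("Feasible rows: %d/%d; mean SES (feasible): %.3f\n",
              sum(x$feasible), nrow(x), mean(x$ses[x$feasible])))
  invisible(x)
}

#' @export
summary.ses_grid <- function(object, ...) {
  f <- object[object$feasible, , drop = FALSE]
  agg <- stats::aggregate(ses ~ metric + algorithm + pool + trait_subset,
                          data = f, FUN = function(v)
                            c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out <- data.frame(agg[1:4], mean_ses = agg$ses[, "mean"],
                    sd_ses = agg$ses[, "sd"], n_sites = agg$ses[, "n"])
  class(out) <- c("summary.ses_grid", "data.frame")
  out
}

#' @export
print.summary.ses_grid <- function(x, ...) {
  cat("Mean SES by configuration (feasible sites only)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.ses_grid <- function(x, ...) {
  f <- x[x$feasible, , drop = FALSE]
  lab <- interaction(f$metric, f$algorithm, f$pool, f$trait_subset, drop = TRUE)
  graphics::boxplot(f$ses ~ lab, las = 2, ylab = "SES",
                    xlab = "", cex.axis = 0.6, ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Write an SES grid as tidy CSV
#'
#' One row per site x configuration with observed, null mean/sd, SES,
#' rank quantile and feasibility.
#'
#' @param x a `ses_grid`.
#' @param path file path.
#' @export
write_ses_csv <- function(x, path) {
  cols <- c("site", "metric", "algorithm", "pool", "trait_subset", "observed",
            "null_mean", "null_sd", "ses", "quantile", "feasible")
  utils::write.csv(as.data.frame(x)[, cols], path, row.names = FALSE, na = "NA")
  invisible(path)
}
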