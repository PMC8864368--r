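#' Site-by-species community matrix with site metadata
#'
#' Bundles a binary incidence matrix (and optionally abundances) with the
#' site metadata needed for pool scoping: ocean, continental margin and
#' latitude per site.
#'
#' @param abundance sites-by-species matrix of non-negative values (counts or
#'   biomass-standardized densities); incidence is derived as `abundance > 0`.
#'   Alternatively pass a binary matrix.
#' @param sites data.frame with columns `site`, `ocean`, `margin`, `latitude`
#'   (rows aligned with the matrix; matched by `site` against rownames when
#'   present).
#' @return an object of class `community_matrix` with elements `occurrence`,
#'   `abundance`, `sites`.
#' @export
community_matrix <- function(abundance, sites) {
  m <- as.matrix(abundance)
  if (is.null(rownames(m))) rownames(m) <- sites$site
  if (any(m < 0, na.rm = TRUE)) stopf("abundances must be non-negative")
  req <- c("site", "ocean", "margin", "latitude")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stopf("sites metadata lacks column(s): %s",
                          paste(miss, collapse = ", "))
  sites <- sites[match(rownames(m), sites$site), , drop = FALSE]
  if (anyNA(sites$site)) stopf("site metadata missing for some matrix rows")
  occ <- matrix(as.integer(m > 0), nrow(m), ncol(m), dimnames = dimnames(m))
  structure(list(occurrence = occ, abundance = m, sites = sites),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community matrix: %d sites x %d species\n",
              nrow(x$occurrence), ncol(x$occurrence)))
  cat("Oceans:", paste(sprintf("%s (%d)", names(table(x$sites$ocean)),
                               table(x$sites$ocean)), collapse = ", "), "\n")
  cat("Site richness:", paste(range(rowSums(x$occurrence)), collapse = "-"), "\n")
  invisible(x)
}

#' Scope a community matrix to a species pool
#'
#' Restricts sites and species to a pool: `"global"` keeps everything;
#' an ocean name keeps that ocean's sites and the species occurring in at
#' least one of them. Species with no occurrence within the scoped sites are
#' dropped, so every pool member occurs in at least one member site.
#'
#' @param community a `community_matrix`.
#' @param pool `"global"` or an ocean label present in the site metadata.
#' @return a list with `occurrence` (scoped incidence matrix), `sites`,
#'   `species`, `pool`.
#' @export
scope_pool <- function(community, pool = "global") {
  occ <- community$occurrence
  meta <- community$sites
  if (!identical(pool, "global")) {
    keep <- meta$ocean == pool
    if (!any(keep)) stopf("no sites in pool '%s'", pool)
    occ <- occ[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  occ <- occ[, colSums(occ) > 0, drop = FALSE]
  list(occurrence = occ, sites = meta, species = colnames(occ), pool = pool)
}
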