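#' Mean pairwise distance (MPD) of a species assemblage
#'
#' MPD is the average trait distance over all unordered pairs of species
#' present at a site. Undefined (`NA`) when fewer than 2 species are present
#' or any required pairwise entry is undefined.
#'
#' @param present character vector (species names) or logical/integer index
#'   into the rows of `D`.
#' @param D square distance matrix with species dimnames.
#' @return a single dissimilarity value, or `NA` when undefined.
#' @export
mpd <- function(present, D) {
  idx <- resolve_species(present, D)
  s <- length(idx)
  if (s < 2L) return(NA_real_)
  sub <- D[idx, idx]
  mean(sub[upper.tri(sub)])
}

#' Mean nearest taxon distance (MNTD) of a species assemblage
#'
#' MNTD is the average, over species present at a site, of each species'
#' distance to its nearest neighbour in trait space within the site.
#'
#' @inheritParams mpd
#' @return a single dissimilarity value, or `NA` when undefined.
#' @export
mntd <- function(present, D) {
  idx <- resolve_species(present, D)
  s <- length(idx)
  if (s < 2L) return(NA_real_)
  sub <- D[idx, idx]
  diag(sub) <- Inf   # exclude self; genuine NA entries still propagate
  mean(apply(sub, 1L, min))
}

resolve_species <- function(present, D) {
  if (is.character(present)) {
    idx <- match(present, rownames(D))
    if (anyNA(idx))
      stopf("species not in distance matrix: %s",
            paste(present[is.na(idx)], collapse = ", "))
    idx
  } else if (is.logical(present)) which(present) else as.integer(present)
}

# Fast MPD for every row of a binary occurrence matrix (sites x species,
# columns aligned with D). Requires a complete (no-NA) distance matrix.
mpd_rows <- function(occ, D) {
  s <- rowSums(occ)
  tot <- rowSums((occ %*% D) * occ)   # sum over ordered pairs = 2 * pair sum
  out <- tot / (s * (s - 1))
  out[s < 2] <- NA_real_
  out
}

# Fast MNTD for every row of a binary occurrence matrix.
mntd_rows <- function(occ, D) {
  Dna <- D
  diag(Dna) <- Inf
  apply(occ, 1L, function(r) {
    idx <- which(r > 0)
    if (length(idx) < 2L) return(NA_real_)
    sub <- Dna[idx, idx, drop = FALSE]
    mean(apply(sub, 1L, min))
  })
}
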