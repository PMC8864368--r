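#' Independent-swap randomization of a binary community matrix
#'
#' Re-assembles a site-by-species incidence matrix while preserving every
#' site's richness (row sums) and every species' occurrence frequency
#' (column sums), by performing `n_swaps` successful 2x2 checkerboard
#' exchanges (submatrix \[\[1,0\],\[0,1\]\] swapped with \[\[0,1\],\[1,0\]\])
#' at uniformly sampled row/column pairs.
#'
#' If the matrix contains no checkerboard submatrix (for example an all-ones
#' matrix) it is returned unchanged with a warning. Randomness comes from
#' R's RNG, so `set.seed()` makes draws reproducible.
#'
#' @param occ binary matrix (sites x species).
#' @param n_swaps number of successful swaps to perform (default 1000).
#' @return a randomized binary matrix with the same dimnames and margins.
#' @export
independent_swap <- function(occ, n_swaps = 1000) {
  if (nrow(occ) < 2L || ncol(occ) < 2L)
    stopf("independent swap needs a matrix with >= 2 rows and >= 2 columns")
  m <- matrix(as.integer(occ > 0), nrow(occ), ncol(occ), dimnames = dimnames(occ))
  if (!has_checkerboard_cpp(m)) {
    warnf("matrix contains no 2x2 checkerboard; returned unchanged")
    return(m)
  }
  independent_swap_cpp(m, as.integer(n_swaps))
}

#' Tip-shuffle randomization of a trait distance matrix
#'
#' Permutes species labels uniformly at random within a species pool,
#' holding the matrix entries fixed: distances between label pairs change
#' but the multiset of entries does not. Equivalent to moving the tip labels
#' on a trait dendrogram. Species outside the pool keep their labels.
#'
#' @param D square distance matrix with species dimnames.
#' @param pool character vector of pool member species (default: all).
#' @return the relabelled distance matrix (same dimnames ordering as `D`).
#' @export
tip_shuffle <- function(D, pool = rownames(D)) {
  sp <- rownames(D)
  idx <- match(pool, sp)
  if (anyNA(idx))
    stopf("pool species not in distance matrix: %s",
          paste(pool[is.na(idx)], collapse = ", "))
  if (length(idx) < 2L) stopf("tip shuffle needs a pool of at least 2 species")
  perm <- seq_along(sp)
  perm[idx] <- idx[sample.int(length(idx))]
  out <- D[perm, perm]
  dimnames(out) <- dimnames(D)
  attributes(out)[c("subset", "traits", "class")] <-
    attributes(D)[c("subset", "traits", "class")]
  out
}
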