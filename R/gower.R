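#' Gower distance matrix over a trait subset
#'
#' Computes pairwise Gower dissimilarities between species over the traits in
#' a subset, handling mixed trait kinds and missing values. Per-trait
#' dissimilarities are: continuous, absolute difference divided by the trait's
#' observed range over the supplied table; ordered, absolute rank difference
#' divided by (L - 1) with levels mapped to ranks 0..L-1; categorical and
#' binary, simple mismatch (0/1). The pairwise distance is the average of
#' per-trait dissimilarities over traits non-missing for both species; a pair
#' sharing no non-missing trait gets an undefined (`NA`) entry.
#'
#' Because continuous traits are normalised by the range observed in the
#' supplied table, distances depend on the active species pool.
#'
#' @param table species-by-trait data.frame (`species` column + trait columns).
#' @param subset `"all"`, `"diet"`, `"microhabitat"`, or a character vector of
#'   trait names.
#' @param schema a `trait_schema`.
#' @return a symmetric matrix of class `gower_dist` with species as
#'   dimnames, zero diagonal, entries in \[0, 1\] or `NA`; attributes
#'   `subset` (label) and `traits` (names used).
#' @export
#' @examples
#' tab <- data.frame(species = c("A", "B"), max_length = c(10, 30),
#'                   motility = c("swimmer", "crawler"))
#' gower_dist(tab, subset = c("max_length", "motility"))
gower_dist <- function(table, subset = "all", schema = default_trait_schema()) {
  traits <- trait_subset_names(schema, subset)
  traits <- intersect(traits, names(table))
  if (length(traits) == 0L) stopf("trait subset selects no traits present in table")
  sp <- as.character(table$species)
  if (anyDuplicated(sp)) stopf("duplicate species identifiers in trait table")
  n <- length(sp)
  if (n < 2L) stopf("need at least 2 species")

  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (tn in traits) {
    tr <- schema$traits[[tn]]
    v <- table[[tn]]
    x <- switch(tr$kind,
      continuous = as.numeric(v),
      ordered = as.numeric(match(as.character(v), tr$levels)) - 1,
      categorical = as.numeric(match(as.character(v), tr$levels)),
      binary = as.numeric(v))
    obs <- !is.na(x)
    w <- outer(obs, obs, `&`)
    if (tr$kind %in% c("continuous", "ordered")) {
      rng <- if (tr$kind == "ordered") length(tr$levels) - 1 else {
        r <- diff(range(x[obs]))
        if (sum(obs) >= 2 && r == 0) {
          warnf("continuous trait '%s' has zero observed range; contributes 0", tn)
          NA_real_
        } else r
      }
      d <- abs(outer(x, x, `-`))
      d <- if (is.na(rng) || rng == 0) d * 0 else d / rng
    } else {
      d <- 1 * outer(x, x, `!=`)
    }
    d[!w] <- 0
    num <- num + d
    den <- den + w
  }
  D <- ifelse(den > 0, num / den, NA_real_)
  diag(D) <- 0
  dimnames(D) <- list(sp, sp)
  label <- if (length(subset) == 1 && subset %in% c("all", "diet", "microhabitat"))
    subset else "custom"
  structure(D, class = c("gower_dist", "matrix"),
            subset = label, traits = traits)
}

#' @export
print.gower_dist <- function(x, ...) {
  cat(sprintf("Gower distance matrix: %d species, subset '%s' (%d traits)\n",
              nrow(x), attr(x, "subset"), length(attr(x, "traits"))))
  if (anyNA(x)) cat(sum(is.na(x[upper.tri(x)])), "undefined pairwise entries\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], ...)
  invisible(x)
}

#' Write / read a distance matrix as square CSV
#'
#' Square layout with species as header row and first column; undefined
#' entries written as `NA`.
#'
#' @param D a distance matrix with species dimnames.
#' @param path file path.
#' @export
write_dist_csv <- function(D, path) {
  df <- data.frame(species = rownames(D), unclass(D), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_dist_csv
#' @export
read_dist_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
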