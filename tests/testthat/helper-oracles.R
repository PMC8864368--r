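# Independent brute-force oracles, written before the implementation paths
# they check and kept deliberately naive.

# Gower distance by direct per-pair, per-trait summation.
oracle_gower <- function(table, traits, schema) {
  sp <- table$species
  n <- length(sp)
  ranges <- lapply(traits, function(tn) {
    tr <- schema$traits[[tn]]
    if (tr$kind == "continuous") {
      v <- as.numeric(table[[tn]])
      diff(range(v[!is.na(v)]))
    } else NULL
  })
  names(ranges) <- traits
  D <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0; w <- 0
    for (tn in traits) {
      tr <- schema$traits[[tn]]
      vi <- table[[tn]][i]; vj <- table[[tn]][j]
      if (is.na(vi) || is.na(vj)) next
      dk <- switch(tr$kind,
        continuous = if (ranges[[tn]] == 0) 0
                     else abs(as.numeric(vi) - as.numeric(vj)) / ranges[[tn]],
        ordered = abs(match(vi, tr$levels) - match(vj, tr$levels)) /
          (length(tr$levels) - 1),
        categorical = as.numeric(vi != vj),
        binary = as.numeric(vi != vj))
      s <- s + dk; w <- w + 1
    }
    D[i, j] <- if (w == 0) NA_real_ else s / w
  }
  D
}

# MPD / MNTD by exhaustive pair scans.
oracle_mpd <- function(sp, D) {
  tot <- 0; np <- 0
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i < j) { tot <- tot + D[sp[i], sp[j]]; np <- np + 1 }
  }
  tot / np
}
oracle_mntd <- function(sp, D) {
  mins <- vapply(sp, function(a) {
    min(vapply(setdiff(sp, a), function(b) D[a, b], 0))
  }, 0)
  mean(mins)
}

# AICc from an explicit Gaussian log-likelihood with sigma^2 = rss / n.
oracle_aicc <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  p <- ncol(X) + 1
  sigma2 <- rss / n
  loglik <- sum(stats::dnorm(fit$residuals, 0, sqrt(sigma2), log = TRUE))
  k <- p + 1
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Welch two-sample t and Welch-Satterthwaite df from the textbook formulas.
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df)
}

# All permutations of 1..n (n small), for exhaustive tip-shuffle nulls.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1)
  }
  out
}
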