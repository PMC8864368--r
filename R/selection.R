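#' Akaike information criterion corrected for small samples
#'
#' AICc = -2 log L + 2k + 2k(k + 1) / (n - k - 1) with the full Gaussian
#' log-likelihood at the least-squares fit, -2 log L = n log(2 pi rss / n)
#' + n, matching `stats::AIC()` and the mainstream multimodel-inference
#' convention (the additive constant does not affect rankings). `k` counts
#' all estimated parameters including the residual variance, so an ordinary
#' regression with p coefficients (intercept included) has k = p + 1.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of observations.
#' @param k number of estimated parameters.
#' @return the AICc value; the fit is rejected (error) when n - k - 1 < 1.
#' @export
aicc <- function(rss, n, k) {
  if (rss <= 0) stopf("rss must be positive")
  if (n - k - 1 < 1) stopf("AICc undefined: n - k - 1 = %d < 1", n - k - 1)
  n * log(2 * pi * rss / n) + n + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

aicc_lm <- function(fit) {
  k <- length(stats::coef(fit)) + 1  # + residual variance
  aicc(sum(stats::residuals(fit)^2), stats::nobs(fit), k)
}

#' Variance inflation factors of a predictor set
#'
#' VIF of each term is 1 / (1 - R^2) from regressing that term's design
#' column on all the others (intercept included). Two-level factors
#' contribute one column each; multi-column terms get their maximum column
#' VIF.
#'
#' @param terms character vector of main-effect terms.
#' @param predictors predictor data.frame.
#' @return named numeric vector of VIFs.
#' @export
vif_terms <- function(terms, predictors) {
  if (length(terms) < 2L)
    return(setNames(rep(1, length(terms)), terms))
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = " + "))),
    data = predictors)
  asgn <- attr(mm, "assign")
  X <- mm[, asgn > 0, drop = FALSE]
  asgn <- asgn[asgn > 0]
  col_vif <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  vapply(seq_along(terms), function(t) max(col_vif[asgn == t]),
         0, USE.NAMES = FALSE) |> setNames(terms)
}

#' Fit and AICc-rank the a priori model registry
#'
#' Fits every registry model to the per-site SES response by ordinary least
#' squares and ranks them by AICc (ascending). Rank-deficient designs are
#' flagged and excluded from the ranking with a warning.
#'
#' @param ses numeric response vector (one SES value per site) or a
#'   data.frame containing a `ses` column.
#' @param predictors transformed predictor table from
#'   [transform_predictors()], rows aligned with `ses`.
#' @param registry a `model_registry`.
#' @return a data.frame of class `registry_ranking` with columns `model`,
#'   `k`, `aicc`, `delta_aicc`, `r2`, ordered by AICc; attribute `fits`
#'   holds the underlying `lm` objects.
#' @export
rank_registry <- function(ses, predictors, registry = default_model_registry()) {
  if (is.data.frame(ses)) ses <- ses$ses
  if (length(ses) != nrow(predictors))
    stopf("response length (%d) does not match predictor rows (%d)",
          length(ses), nrow(predictors))
  dat <- cbind(ses = ses, predictors)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  rows <- list(); fits <- list()
  for (m in registry) {
    fit <- stats::lm(registry_formula(m$terms), data = dat)
    if (anyNA(stats::coef(fit))) {
      warnf("model '%s' is rank-deficient; excluded from ranking", m$name)
      next
    }
    k <- length(stats::coef(fit)) + 1
    if (stats::nobs(fit) - k - 1 < 1) {
      warnf("model '%s' rejected: too many parameters for n = %d",
            m$name, stats::nobs(fit))
      next
    }
    rows[[m$name]] <- data.frame(model = m$name, k = k, aicc = aicc_lm(fit),
                                 r2 = summary(fit)$r.squared,
                                 stringsAsFactors = FALSE)
    fits[[m$name]] <- fit
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$aicc), , drop = FALSE]
  out$delta_aicc <- out$aicc - out$aicc[1]
  out <- out[, c("model", "k", "aicc", "delta_aicc", "r2")]
  rownames(out) <- NULL
  structure(out, class = c("registry_ranking", "data.frame"),
            fits = fits, data = dat, registry = registry)
}

#' Composite-model construction and backward elimination
#'
#' Pools the union of predictors from the three lowest-AICc registry models,
#' removes collinear predictors by iterated VIF screening (recomputing after
#' each removal, worst first, threshold `vif_threshold`), and applies
#' backward elimination: at each step the term whose removal most lowers
#' AICc is dropped, until no removal lowers it. Interaction terms are kept
#' only while both parents survive, and parents are not droppable while
#' their interaction is retained. Finally, among all models examined along
#' the way whose AICc is within `delta_cut` of the minimum, the model with
#' the fewest parameters is selected (ties broken by lower AICc).
#'
#' @param ranking a `registry_ranking` from [rank_registry()].
#' @param vif_threshold VIF above which a predictor is removed (default 5).
#' @param delta_cut AICc window for the parsimony rule (default 3).
#' @return an object of class `driver_selection`: list with `ranking`,
#'   `composite_terms`, `vif_removed`, `final` (an `lm`), `final_terms`,
#'   `audit` (data.frame of every model examined, with the rule that
#'   selected the final one).
#' @export
composite_select <- function(ranking, vif_threshold = 5, delta_cut = 3) {
  stopifnot(inherits(ranking, "registry_ranking"))
  if (nrow(ranking) < 3L) stopf("need at least 3 ranked models")
  dat <- attr(ranking, "data")
  registry <- attr(ranking, "registry")
  top3 <- ranking$model[1:3]
  pooled <- unique(unlist(lapply(registry[top3], `[[`, "terms")))
  mains <- pooled[!grepl(":", pooled, fixed = TRUE)]
  ints <- setdiff(pooled, mains)

  # iterated VIF screening on main effects
  removed <- character()
  repeat {
    if (length(mains) < 2L) break
    v <- vif_terms(mains, dat)
    if (max(v) <= vif_threshold) break
    worst <- names(v)[which.max(v)]
    removed <- c(removed, worst)
    mains <- setdiff(mains, worst)
  }
  ints <- ints[vapply(strsplit(ints, ":", fixed = TRUE),
                      function(p) all(p %in% mains), TRUE)]
  terms <- c(mains, ints)

  fit0 <- stats::lm(registry_formula(terms), data = dat)
  if (anyNA(stats::coef(fit0))) {
    warnf("composite design rank-deficient after VIF screening; falling back to best a priori model")
    best <- ranking$model[1]
    fit <- attr(ranking, "fits")[[best]]
    audit <- data.frame(step = "fallback", terms = best,
                        k = length(stats::coef(fit)) + 1, aicc = aicc_lm(fit),
                        rule = "rank-deficient composite; best a priori model",
                        stringsAsFactors = FALSE)
    return(structure(list(ranking = ranking, composite_terms = terms,
                          vif_removed = removed, final = fit,
                          final_terms = registry[[best]]$terms, audit = audit),
                     class = "driver_selection"))
  }

  audit <- list()
  note <- function(step, terms, fit, rule = "") {
    audit[[length(audit) + 1L]] <<- data.frame(
      step = step, terms = paste(terms, collapse = " + "),
      k = length(stats::coef(fit)) + 1, aicc = aicc_lm(fit), rule = rule,
      stringsAsFactors = FALSE)
  }
  candidates <- list(list(terms = terms, fit = fit0))
  note("composite", terms, fit0)

  current <- terms; fit <- fit0; cur_aicc <- aicc_lm(fit0)
  repeat {
    if (length(current) == 0L) break
    in_int <- unique(unlist(strsplit(current[grepl(":", current, fixed = TRUE)],
                                     ":", fixed = TRUE)))
    droppable <- current[!(current %in% in_int)]
    if (!length(droppable)) break
    trial <- lapply(droppable, function(tm) {
      tms <- setdiff(current, tm)
      f <- stats::lm(registry_formula(tms), data = dat)
      list(terms = tms, fit = f, aicc = aicc_lm(f), dropped = tm)
    })
    candidates <- c(candidates, trial)
    for (tr in trial) note("elimination-candidate", tr$terms, tr$fit,
                           paste("drop", tr$dropped))
    best <- trial[[which.min(vapply(trial, `[[`, 0, "aicc"))]]
    if (best$aicc < cur_aicc) {
      current <- best$terms; fit <- best$fit; cur_aicc <- best$aicc
      note("eliminated", current, fit, paste("dropped", best$dropped))
    } else break
  }

  aiccs <- vapply(candidates, function(c) aicc_lm(c$fit), 0)
  ks <- vapply(candidates, function(c) length(stats::coef(c$fit)) + 1, 0)
  near <- which(aiccs - min(aiccs) < delta_cut)
  pick <- near[order(ks[near], aiccs[near])][1]
  final <- candidates[[pick]]
  rule <- if (ks[pick] < ks[which.min(aiccs)])
    sprintf("parsimony: fewest parameters within %g AICc of minimum", delta_cut)
  else "lowest AICc"
  note("final", final$terms, final$fit, rule)

  structure(list(ranking = ranking, composite_terms = terms,
                 vif_removed = removed, final = final$fit,
                 final_terms = final$terms, audit = do.call(rbind, audit)),
            class = "driver_selection")
}

#' Select environmental drivers of trait dispersion
#'
#' Convenience wrapper: ranks the a priori registry on a SES response and
#' runs composite construction with VIF screening and backward elimination.
#'
#' @inheritParams rank_registry
#' @inheritParams composite_select
#' @return a `driver_selection` (see [composite_select()]).
#' @export
select_drivers <- function(ses, predictors, registry = default_model_registry(),
                           vif_threshold = 5, delta_cut = 3) {
  composite_select(rank_registry(ses, predictors, registry),
                   vif_threshold = vif_threshold, delta_cut = delta_cut)
}

#' @export
print.driver_selection <- function(x, ...) {
  cat("Driver selection\n")
  cat("Top a priori models:\n")
  print(utils::head(as.data.frame(x$ranking), 3), row.names = FALSE, digits = 4)
  if (length(x$vif_removed))
    cat("Removed by VIF screening:", paste(x$vif_removed, collapse = ", "), "\n")
  cat("Final model: ses ~",
      if (length(x$final_terms)) paste(x$final_terms, collapse = " + ") else "1",
      "\n")
  invisible(x)
}

#' @export
summary.driver_selection <- function(object, ...) {
  list(ranking = object$ranking, audit = object$audit,
       final = summary(object$final))
}

#' @export
coef.driver_selection <- function(object, ...) stats::coef(object$final)

#' Welch t-tests of SES values
#'
#' One-sample two-tailed t-tests of SES against zero, overall and per ocean,
#' and a two-sample unequal-variance (Welch) t-test between oceans with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param ses data.frame with columns `ses` and `ocean` (e.g. one
#'   configuration's rows of a `ses_grid`).
#' @return data.frame with columns `test`, `group`, `mean`, `t`, `df`, `p`.
#' @export
ses_t_tests <- function(ses) {
  groups <- c(list(overall = ses$ses), split(ses$ses, ses$ocean))
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]][!is.na(groups[[g]])]
    if (length(v) < 2L) stopf("group '%s' has fewer than 2 observations", g)
    if (stats::sd(v) == 0) stopf("group '%s' has zero variance", g)
    tt <- stats::t.test(v, mu = 0)
    data.frame(test = "one-sample", group = g, mean = mean(v),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  oceans <- setdiff(names(groups), "overall")
  if (length(oceans) == 2L) {
    tt <- stats::t.test(groups[[oceans[1]]], groups[[oceans[2]]],
                        var.equal = FALSE)
    rows <- c(rows, list(data.frame(
      test = "two-sample", group = paste(oceans, collapse = " vs "),
      mean = mean(groups[[oceans[1]]], na.rm = TRUE) -
        mean(groups[[oceans[2]]], na.rm = TRUE),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
      stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}
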