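#' Load and validate a run configuration
#'
#' A run configuration names the inputs (either CSV paths or a synthetic
#' scenario), the SES grid block, the model-selection block, the master
#' seed and the output directory. Referenced paths must exist at load time.
#'
#' @param config a list or a path to a YAML file with blocks `inputs` (paths
#'   `traits`, `plots`, `tethers`, `environment`) or `scenario`
#'   (arguments to [zen_scenario()]), optional `grid`
#'   (metrics/algorithms/pools/trait_subsets/n_perm/n_swaps), optional
#'   `selection` (response config, vif_threshold, delta_cut), `seed`, `out`.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$inputs) && is.null(config$scenario))
    stopf("config needs either an 'inputs' block or a 'scenario' block")
  if (!is.null(config$inputs)) {
    for (nm in c("traits", "plots", "tethers", "environment")) {
      p <- config$inputs[[nm]]
      if (is.null(p)) stopf("inputs block lacks '%s'", nm)
      if (!file.exists(p)) stopf("input file not found: %s (%s)", p, nm)
    }
  }
  config$seed <- config$seed %||% 1L
  if (config$seed < 0 || config$seed != round(config$seed))
    stopf("seed must be a non-negative integer")
  config$out <- config$out %||% "traitdisp-out"
  structure(config, class = "run_config")
}

# Write a file atomically through a .partial staging name so that aborted
# runs leave only .partial outputs behind.
write_staged <- function(path, writer) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full pipeline: simulate / aggregate / SES grid / model selection
#'
#' Executes the stages in order, writing each declared output CSV and a
#' manifest (package version, seed, configuration hash, infeasible-row
#' count). Any stage failure aborts with a stage-tagged error; outputs
#' written before the failure remain, and the failing stage's partial
#' output keeps a `.partial` suffix.
#'
#' @param config a `run_config`, list, or YAML path (see
#'   [read_run_config()]).
#' @return (invisibly) a list with `ses` (the `ses_grid`), `selection`
#'   (the `driver_selection`), `tests` (Welch t-tests of the response
#'   configuration), `manifest`.
#' @export
run_all <- function(config) {
  config <- read_run_config(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] stage failed: %s", name, conditionMessage(e)))
  }

  # -- simulate (optional) ---------------------------------------------------
  if (is.null(config$inputs)) {
    ds <- stage("simulate", {
      sc <- do.call(zen_scenario, config$scenario %||% list())
      gen_dataset(sc, file.path(config$out, "synthetic"),
                  seed = config$seed, overwrite = isTRUE(config$overwrite))
    })
    traits <- ds$traits; plots <- ds$plots
    tethers <- ds$tethers; environment <- ds$environment
  } else {
    traits <- read_trait_table(config$inputs$traits)
    plots <- utils::read.csv(config$inputs$plots, stringsAsFactors = FALSE)
    tethers <- utils::read.csv(config$inputs$tethers, stringsAsFactors = FALSE)
    environment <- utils::read.csv(config$inputs$environment,
                                   stringsAsFactors = FALSE)
  }

  # -- aggregate -------------------------------------------------------------
  agg <- stage("aggregate", {
    val <- validate_trait_table(traits)
    if (!val$ok) stopf("trait table rejected:\n%s",
                       paste(utils::capture.output(print(val)), collapse = "\n"))
    aggregate_sites(plots, tethers)
  })
  env <- environment[match(rownames(agg$abundance), environment$site), ]
  # measured (tether-based) predation takes precedence over any latent column
  env$predation <- agg$env$predation
  community <- community_matrix(agg$abundance, env)

  # -- SES grid --------------------------------------------------------------
  grid_cfg <- config$grid %||% list()
  configs <- enumerate_configs(
    metrics = grid_cfg$metrics %||% c("mpd", "mntd"),
    algorithms = grid_cfg$algorithms %||% c("independent_swap", "tip_shuffle"),
    pools = grid_cfg$pools %||% c("global", "Atlantic", "Pacific"),
    trait_subsets = grid_cfg$trait_subsets %||% c("all", "diet", "microhabitat"))
  ses <- stage("dispersion", trait_dispersion(
    community, traits, configs,
    n_perm = grid_cfg$n_perm %||% 999,
    n_swaps = grid_cfg$n_swaps %||% 1000,
    seed = config$seed))
  write_staged(file.path(config$out, "ses.csv"),
               function(p) write_ses_csv(ses, p))

  # -- model selection -------------------------------------------------------
  sel_cfg <- config$selection %||% list()
  resp <- sel_cfg$response %||% list(metric = "mntd", algorithm = "tip_shuffle",
                                     pool = "global", trait_subset = "all")
  sub <- ses[ses$metric == resp$metric & ses$algorithm == resp$algorithm &
               ses$pool == resp$pool & ses$trait_subset == resp$trait_subset &
               ses$feasible, , drop = FALSE]
  selection <- stage("select-models", {
    predictors <- transform_predictors(env[match(sub$site, env$site), ])
    sel <- select_drivers(sub$ses, predictors,
                          vif_threshold = sel_cfg$vif_threshold %||% 5,
                          delta_cut = sel_cfg$delta_cut %||% 3)
    write_staged(file.path(config$out, "model_ranking.csv"), function(p)
      utils::write.csv(as.data.frame(sel$ranking), p, row.names = FALSE))
    write_staged(file.path(config$out, "final_coefficients.csv"), function(p)
      utils::write.csv(data.frame(term = names(coef(sel)),
                                  estimate = unname(coef(sel))),
                       p, row.names = FALSE))
    write_staged(file.path(config$out, "selection_audit.csv"), function(p)
      utils::write.csv(sel$audit, p, row.names = FALSE))
    sel
  })
  tests <- stage("select-models", ses_t_tests(sub))

  # -- manifest --------------------------------------------------------------
  cfg_file <- file.path(config$out, "run_config.yaml")
  write_staged(cfg_file, function(p) yaml::write_yaml(unclass(config), p))
  manifest <- list(
    package = "traitdisp",
    version = as.character(utils::packageVersion("traitdisp")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    n_ses_rows = nrow(ses),
    n_infeasible = sum(!ses$feasible),
    outputs = c("ses.csv", "model_ranking.csv", "final_coefficients.csv",
                "selection_audit.csv"))
  write_staged(file.path(config$out, "manifest.yaml"),
               function(p) yaml::write_yaml(manifest, p))

  invisible(list(ses = ses, selection = selection, tests = tests,
                 manifest = manifest))
}
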