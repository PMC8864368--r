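#' The a priori model registry
#'
#' Sixteen named regression models of site-level SES values, each a small
#' hypothesis about what drives trait dispersion: five biogeography models
#' (latitude, continental margin, ocean and their named interactions), an
#' abiotic-environment model, three temperature-regime models, a community
#' model, two biodiversity models, a habitat model, a predation model and
#' two resource models. The registry ships as YAML
#' (`extdata/model_registry.yaml`) and can be overridden by the user.
#'
#' The `resource_2` model's first term is named `nitrogen_oxide_surface`:
#' the source tables label this water-column nitrogen predictor
#' inconsistently (NO2 versus nitrate), so the registry keeps a neutral
#' name rather than resolving it.
#'
#' @param path YAML file; default is the registry shipped with the package.
#' @return a `model_registry`: named list of model specs, each with `name`
#'   and `terms` (character vector; `"a:b"` denotes an interaction).
#' @export
read_model_registry <- function(path = system.file("extdata",
                                                   "model_registry.yaml",
                                                   package = "traitdisp")) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(m) {
    if (is.null(m$name) || is.null(m$terms))
      stopf("every registry entry needs 'name' and 'terms'")
    list(name = m$name, terms = as.character(m$terms))
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs))) stopf("duplicate model names in registry")
  structure(specs, class = "model_registry")
}

#' @rdname read_model_registry
#' @export
default_model_registry <- function() read_model_registry()

#' @export
print.model_registry <- function(x, ...) {
  cat("Model registry with", length(x), "models\n")
  for (m in x)
    cat(sprintf("  %-24s ~ %s\n", m$name, paste(m$terms, collapse = " + ")))
  invisible(x)
}

registry_formula <- function(terms, response = "ses") {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  stats::as.formula(paste(response, "~", rhs))
}
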