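#' Trait schema for eelgrass peracarid communities
#'
#' A trait schema describes the traits scored for each species: the kind of
#' each trait (continuous, ordered, categorical or binary), admissible levels
#' or ranges, units, and the trait group used to build trait subsets
#' (microhabitat, diet, or neither).
#'
#' @param traits a list of trait descriptors, each a list with elements
#'   `name`, `kind` (one of `"continuous"`, `"ordered"`, `"categorical"`,
#'   `"binary"`), `group` (one of `"microhabitat"`, `"diet"`, `"neither"`),
#'   and, depending on kind, `levels` (ordered labels for ordered/categorical
#'   traits), `range` (length-2 numeric for continuous traits) and `units`.
#' @return an object of class `trait_schema`.
#' @seealso [default_trait_schema()]
#' @export
trait_schema <- function(traits) {
  kinds <- c("continuous", "ordered", "categorical", "binary")
  groups <- c("microhabitat", "diet", "neither")
  for (tr in traits) {
    if (is.null(tr$name) || !nzchar(tr$name)) stopf("every trait needs a name")
    if (!tr$kind %in% kinds)
      stopf("trait '%s': unknown kind '%s'", tr$name, tr$kind)
    if (!tr$group %in% groups)
      stopf("trait '%s': unknown group '%s'", tr$name, tr$group)
    if (tr$kind %in% c("ordered", "categorical") && length(tr$levels) < 2)
      stopf("trait '%s': %s traits need at least 2 levels", tr$name, tr$kind)
    if (tr$kind == "continuous") {
      if (is.null(tr$range) || length(tr$range) != 2 || !all(is.finite(tr$range)))
        stopf("trait '%s': continuous traits need a finite length-2 range", tr$name)
      if (is.null(tr$units) || !nzchar(tr$units))
        stopf("trait '%s': continuous traits need units", tr$name)
    }
  }
  nm <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("duplicate trait names in schema")
  names(traits) <- nm
  structure(list(traits = traits), class = "trait_schema")
}

#' Default 13-trait schema for peracarid crustaceans
#'
#' The default schema scores each species for maximum fecundity (an ordered
#' trait binned from brood egg counts), maximum adult length (2--50 mm),
#' body shape, living habit, motility, bioturbation, and seven binary diet
#' components. Five traits form the `microhabitat` group, seven the `diet`
#' group; fecundity belongs to neither.
#'
#' @return a `trait_schema` with 13 traits.
#' @export
default_trait_schema <- function() {
  tr <- function(name, kind, group, levels = NULL, range = NULL, units = NULL)
    list(name = name, kind = kind, group = group, levels = levels,
         range = range, units = units)
  trait_schema(list(
    tr("max_fecundity", "ordered", "neither",
       levels = c("very_low", "low", "medium", "high", "very_high")),
    tr("max_length", "continuous", "microhabitat", range = c(2, 50), units = "mm"),
    tr("body_shape", "categorical", "microhabitat",
       levels = c("laterally_compressed", "dorsoventrally_compressed", "vermiform")),
    tr("living_habit", "categorical", "microhabitat",
       levels = c("free", "parasite_commensal", "tube_burrow")),
    tr("motility", "categorical", "microhabitat", levels = c("swimmer", "crawler")),
    tr("bioturbator", "binary", "microhabitat"),
    tr("feeds_microalgae", "binary", "diet"),
    tr("feeds_macroalgae", "binary", "diet"),
    tr("feeds_seagrass", "binary", "diet"),
    tr("feeds_seagrass_detritus", "binary", "diet"),
    tr("suspension_feeder", "binary", "diet"),
    tr("detritivore", "binary", "diet"),
    tr("carnivore", "binary", "diet")
  ))
}

#' @export
print.trait_schema <- function(x, ...) {
  cat("Trait schema with", length(x$traits), "traits\n")
  for (tr in x$traits) {
    extra <- switch(tr$kind,
      continuous = sprintf(" [%g-%g %s]", tr$range[1], tr$range[2], tr$units),
      ordered = ,
      categorical = paste0(" {", paste(tr$levels, collapse = ", "), "}"),
      "")
    cat(sprintf("  %-24s %-12s %-13s%s\n", tr$name, tr$kind, tr$group, extra))
  }
  invisible(x)
}

#' Names of the traits in a subset of a schema
#'
#' @param schema a `trait_schema`.
#' @param subset `"all"`, `"diet"`, `"microhabitat"`, or a character vector of
#'   trait names (a custom subset).
#' @return character vector of trait names.
#' @export
trait_subset_names <- function(schema, subset = "all") {
  nm <- names(schema$traits)
  if (length(subset) == 1 && subset %in% c("all", "diet", "microhabitat")) {
    if (subset == "all") return(nm)
    grp <- vapply(schema$traits, `[[`, "", "group")
    return(nm[grp == subset])
  }
  unknown <- setdiff(subset, nm)
  if (length(unknown))
    stopf("unknown trait(s) in subset: %s", paste(unknown, collapse = ", "))
  subset
}

#' Bin a brood egg count into the ordered fecundity categories
#'
#' Categories use half-open intervals: very_low \[0, 18), low \[18, 31),
#' medium \[31, 65), high \[65, 135), very_high \[135, Inf). Counts of exactly
#' 135 are assigned to `very_high`, keeping the mapping total.
#'
#' @param egg_count non-negative integer vector of maximum brood sizes.
#' @return character vector of fecundity labels.
#' @export
#' @examples
#' bin_fecundity(c(17, 31, 134, 135))
bin_fecundity <- function(egg_count) {
  if (any(!is.finite(egg_count) | egg_count < 0))
    stopf("egg_count must be non-negative and finite")
  labs <- c("very_low", "low", "medium", "high", "very_high")
  labs[findInterval(egg_count, c(0, 18, 31, 65, 135))]
}

#' Validate a species-by-trait table against a schema
#'
#' Checks species identifiers for duplicates, every non-missing value for
#' conformance with its trait's kind, levels and range, and tallies
#' missingness per trait and per species. Missing values are allowed; the
#' table is accepted iff there are no hard violations.
#'
#' @param table a data.frame with a `species` column and one column per
#'   schema trait; missing values as `NA` (empty CSV cells).
#' @param schema a `trait_schema` (default: [default_trait_schema()]).
#' @return an object of class `trait_validation` with elements `ok`,
#'   `violations` (data.frame: species, trait, problem),
#'   `missing_by_trait`, `missing_by_species`.
#' @export
validate_trait_table <- function(table, schema = default_trait_schema()) {
  if (!is.data.frame(table) || !"species" %in% names(table))
    stopf("trait table must be a data.frame with a 'species' column")
  viol <- list()
  add <- function(species, trait, problem)
    viol[[length(viol) + 1L]] <<- data.frame(
      species = species, trait = trait, problem = problem,
      stringsAsFactors = FALSE)

  sp <- as.character(table$species)
  dup <- unique(sp[duplicated(sp)])
  for (d in dup) add(d, NA_character_, "duplicate species identifier")

  missing_cols <- setdiff(names(schema$traits), names(table))
  for (m in missing_cols) add(NA_character_, m, "trait column absent")

  for (tn in intersect(names(schema$traits), names(table))) {
    tr <- schema$traits[[tn]]
    v <- table[[tn]]
    miss <- is.na(v)
    if (tr$kind == "continuous") {
      num <- suppressWarnings(as.numeric(v))
      bad_kind <- !miss & is.na(num)
      for (s in sp[bad_kind]) add(s, tn, "non-numeric value for continuous trait")
      oob <- !miss & !is.na(num) & (num < tr$range[1] | num > tr$range[2])
      for (s in sp[oob]) add(s, tn, sprintf("value outside [%g, %g] %s",
                                            tr$range[1], tr$range[2], tr$units))
    } else if (tr$kind == "binary") {
      ok <- miss | v %in% c(0, 1, "0", "1", TRUE, FALSE)
      for (s in sp[!ok]) add(s, tn, "binary trait must be 0/1")
    } else {
      ok <- miss | as.character(v) %in% tr$levels
      for (s in sp[!ok & !miss]) add(s, tn, "unknown category label")
    }
  }

  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(species = character(), trait = character(),
               problem = character(), stringsAsFactors = FALSE)
  present <- intersect(names(schema$traits), names(table))
  mbt <- vapply(present, function(tn) sum(is.na(table[[tn]])), 0L)
  mbs <- setNames(rowSums(is.na(table[, present, drop = FALSE])), sp)
  structure(list(ok = nrow(viol) == 0L, violations = viol,
                 missing_by_trait = mbt, missing_by_species = mbs),
            class = "trait_validation")
}

#' @export
print.trait_validation <- function(x, ...) {
  cat(if (x$ok) "Trait table accepted" else "Trait table REJECTED", "\n")
  if (nrow(x$violations)) {
    cat(nrow(x$violations), "violation(s):\n")
    print(x$violations, row.names = FALSE)
  }
  nmiss <- sum(x$missing_by_trait)
  if (nmiss) cat(nmiss, "missing values across",
                 sum(x$missing_by_trait > 0), "trait(s)\n")
  invisible(x)
}

#' Read / write a trait table as CSV
#'
#' CSV layout: first column `species`, one column per trait; missing values
#' as empty cells or `NA`.
#'
#' @param path file path.
#' @param table a trait table data.frame.
#' @return `read_trait_table` returns a data.frame.
#' @export
read_trait_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""), check.names = FALSE)
}

#' @rdname read_trait_table
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a trait schema as YAML
#'
#' @param schema a `trait_schema`.
#' @param path file path.
#' @export
write_trait_schema <- function(schema, path) {
  yaml::write_yaml(lapply(unname(schema$traits), function(tr)
    Filter(Negate(is.null), tr)), path)
  invisible(path)
}

#' @rdname write_trait_schema
#' @export
read_trait_schema <- function(path) {
  trait_schema(yaml::read_yaml(path))
}
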