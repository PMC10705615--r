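# The framework model: the Five Domains hierarchy (domains -> provisions),
# the per-(species, provision) question catalogue and decision trees, the
# per-domain capacities and the risk category bands, parsed from a single
# configuration file.

#' Construct a framework model
#'
#' Usually built by [load_framework()] or [default_framework()]; exposed
#' for programmatic construction (e.g. by the synthetic generators).
#'
#' @param trees Nested named list: `trees[[species]][[provision]]` is a
#'   `welfare_tree` or (for the mutilations provision) a `mutilation_rule`.
#' @param capacities Named list of one `welfare_capacity` per domain.
#' @param bands A `category_bands` object.
#' @param domains Named list mapping domain id to provision ids; defaults
#'   to the canonical [domain_provisions()].
#' @param questions Named list mapping question id to display text
#'   (optional; scoring uses ids only, so translated or re-worded
#'   questionnaires score identically).
#' @param meta Free-form metadata list.
#' @param validate If `TRUE` (default), the model must pass
#'   [validate_framework()] with no errors.
#' @return An object of class `welfare_framework`.
#' @export
welfare_framework <- function(trees, capacities, bands = category_bands(),
                              domains = domain_provisions(),
                              questions = list(), meta = list(),
                              validate = TRUE) {
  model <- structure(
    list(domains = domains, questions = questions, trees = trees,
         capacities = capacities, bands = bands, meta = meta),
    class = "welfare_framework")
  if (validate) {
    rep <- validate_framework(model)
    stop_on_invalid(rep, "framework")
  }
  model
}

# tree (or mutilation rule) for a (species, provision) pair, or NULL
framework_tree <- function(model, species, provision) {
  model$trees[[species]][[provision]]
}

#' @export
print.welfare_framework <- function(x, ...) {
  n_trees <- sum(vapply(x$trees, length, integer(1)))
  cat("Five Domains welfare risk framework\n")
  cat(sprintf("  domains: %s\n", paste(names(x$domains), collapse = ", ")))
  cat(sprintf("  %d provisions, %d (species, provision) trees, %d species\n",
              length(unlist(x$domains)), n_trees, length(x$trees)))
  cat(sprintf("  capacities: %s\n",
              paste(names(x$capacities), collapse = ", ")))
  invisible(x)
}

#' Validate a framework model
#'
#' Structural validation of the whole configuration. Errors: wrong domain
#' set or provision counts, a provision assigned to two domains, missing
#' trees for a (species, provision) pair, invalid trees, capacities or
#' bands, capacity ground sets not matching their domain's provisions.
#' Warnings: any non-mutilation provision whose tree has fewer than two
#' single measures (the framework aims to cover every provision with at
#' least two single indicators per species).
#'
#' @param model A `welfare_framework`.
#' @return A `welfare_validation` report (findings are returned, never
#'   thrown).
#' @export
validate_framework <- function(model) {
  errors <- character()
  warnings <- character()
  canonical <- domain_provisions()

  if (!setequal(names(model$domains), names(canonical))) {
    errors <- c(errors, sprintf(
      "domains must be exactly: %s", paste(names(canonical), collapse = ", ")))
  } else {
    for (d in names(canonical)) {
      if (length(model$domains[[d]]) != length(canonical[[d]])) {
        errors <- c(errors, sprintf(
          "domain %s must have %d provisions, found %d",
          d, length(canonical[[d]]), length(model$domains[[d]])))
      }
    }
  }
  provs <- unlist(model$domains, use.names = FALSE)
  dup <- unique(provs[duplicated(provs)])
  if (length(dup)) {
    errors <- c(errors, paste0("duplicate provision assignment: ",
                               paste(dup, collapse = ", ")))
  }
  missing_prov <- setdiff(provision_levels(), provs)
  if (length(missing_prov)) {
    errors <- c(errors, paste0("missing provision(s): ",
                               paste(missing_prov, collapse = ", ")))
  }

  # tree coverage and per-tree validity
  for (sp in species_levels()) {
    for (p in provision_levels()) {
      node <- framework_tree(model, sp, p)
      if (is.null(node)) {
        errors <- c(errors, sprintf("no tree for (%s, %s)", sp, p))
      } else if (inherits(node, "mutilation_rule")) {
        if (p != "mutilations") {
          errors <- c(errors, sprintf(
            "mutilation rule attached to non-mutilation provision %s", p))
        }
      } else {
        trep <- validate_tree(node)
        if (!is_valid(trep)) {
          errors <- c(errors, sprintf("tree (%s, %s): %s", sp, p,
                                      trep$errors))
        }
        if (length(node$questions) < 2L && p != "mutilations") {
          warnings <- c(warnings, sprintf(
            "provision %s (%s) is covered by fewer than two single indicators",
            p, sp))
        }
      }
    }
  }

  # capacities per domain
  for (d in names(canonical)) {
    cap <- model$capacities[[d]]
    if (is.null(cap)) {
      errors <- c(errors, paste0("missing capacity for domain ", d))
      next
    }
    crep <- validate_capacity(cap)
    if (!is_valid(crep)) {
      errors <- c(errors, sprintf("capacity %s: %s", d, crep$errors))
    }
    if (!setequal(cap$ground_set, model$domains[[d]])) {
      errors <- c(errors, sprintf(
        "capacity %s is defined on {%s}, domain has {%s}",
        d, paste(cap$ground_set, collapse = ", "),
        paste(model$domains[[d]], collapse = ", ")))
    }
  }

  brep <- validate_bands(model$bands)
  errors <- c(errors, brep$errors)

  validation_report(errors = errors, warnings = warnings)
}

# config (plain list from YAML/JSON) -> model ---------------------------

expand_species <- function(species) {
  if (length(species) == 1L && identical(species, "all")) species_levels()
  else {
    bad <- setdiff(species, species_levels())
    if (length(bad)) {
      stop("unknown species in tree entry: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    species
  }
}

framework_from_config <- function(config, source = NA_character_,
                                  validate = TRUE) {
  for (key in c("domains", "trees", "capacities")) {
    if (is.null(config[[key]])) {
      stop("framework configuration is missing top-level key '", key, "'",
           call. = FALSE)
    }
  }
  domains <- lapply(config$domains, unlist)

  trees <- setNames(vector("list", length(species_levels())),
                    species_levels())
  for (entry in config$trees) {
    if (is.null(entry$provision) || is.null(entry$species)) {
      stop("every tree entry needs 'provision' and 'species'", call. = FALSE)
    }
    for (sp in expand_species(unlist(entry$species))) {
      node <- if (identical(entry$type, "mutilation_rule")) {
        mutilation_rule(
          species = sp,
          items = entry$items,
          graded_scores = if (is.null(entry$graded_scores))
            default_graded_scores() else entry$graded_scores)
      } else {
        decision_tree(
          provision = entry$provision,
          species = sp,
          questions = unlist(entry$questions),
          leaves = entry$leaves,
          monotone = !isFALSE(entry$monotone),
          validate = FALSE)  # deferred to validate_framework
      }
      if (!is.null(trees[[sp]][[entry$provision]])) {
        stop("two trees configured for (", sp, ", ", entry$provision, ")",
             call. = FALSE)
      }
      trees[[sp]][[entry$provision]] <- node
    }
  }

  capacities <- lapply(config$capacities, parse_capacity_config)

  bands <- if (is.null(config$bands)) category_bands() else {
    b <- config$bands
    category_bands(lower = vapply(b, `[[`, numeric(1), "lower"),
                   upper = vapply(b, `[[`, numeric(1), "upper"),
                   labels = vapply(b, `[[`, character(1), "label"))
  }

  welfare_framework(
    trees = trees, capacities = capacities, bands = bands,
    domains = domains,
    questions = if (is.null(config$questions)) list() else config$questions,
    meta = c(config$meta, list(source = source)),
    validate = validate)
}

# capacity config: either {ranking: [...], interaction: x} or
# {ground_set: [...], mu: {subset-key: value}, complete: additive?}
parse_capacity_config <- function(cfg) {
  if (inherits(cfg, "welfare_capacity")) return(cfg)
  if (!is.null(cfg$ranking)) {
    capacity_from_ranking(unlist(cfg$ranking),
                          interaction = if (is.null(cfg$interaction)) 0.3
                                        else cfg$interaction)
  } else if (!is.null(cfg$mu)) {
    if (is.null(cfg$ground_set)) {
      stop("explicit capacity config needs 'ground_set'", call. = FALSE)
    }
    capacity(unlist(cfg$ground_set), mu = cfg$mu,
             complete = if (identical(cfg$complete, "additive")) "additive"
                        else "none")
  } else {
    stop("capacity config needs either 'ranking' or 'mu'", call. = FALSE)
  }
}

# model -> config list (inverse of framework_from_config, for round trips)
framework_to_config <- function(model) {
  tree_entries <- list()
  for (sp in names(model$trees)) {
    for (p in names(model$trees[[sp]])) {
      node <- model$trees[[sp]][[p]]
      tree_entries[[length(tree_entries) + 1L]] <-
        if (inherits(node, "mutilation_rule")) {
          list(provision = p, species = sp, type = "mutilation_rule",
               items = as.list(node$items),
               graded_scores = as.list(node$graded_scores))
        } else {
          list(provision = p, species = sp,
               questions = as.list(node$questions),
               leaves = as.list(node$leaves),
               monotone = node$monotone)
        }
    }
  }
  caps <- lapply(model$capacities, function(cap) {
    keys <- all_mask_keys(cap$ground_set)
    list(ground_set = as.list(cap$ground_set),
         mu = setNames(as.list(cap$mu[-1]), keys[-1]))
  })
  list(domains = lapply(model$domains, as.list),
       questions = model$questions,
       trees = tree_entries,
       capacities = caps,
       bands = lapply(seq_len(nrow(model$bands)), function(i)
         list(lower = model$bands$lower[i], upper = model$bands$upper[i],
              label = model$bands$label[i])))
}

#' The packaged default framework
#'
#' Loads the framework configuration shipped in the package's `extdata`:
#' the reference feed decision tree (all species), the per-species
#' mutilation rules, illustrative two-question trees for the remaining
#' provisions (marked as illustrative in the configuration file), ranking
#' default capacities and the standard risk bands. See the package
#' vignette for which parts are reference material and which are
#' illustrative defaults.
#'
#' @return A validated `welfare_framework`.
#' @export
default_framework <- function() {
  load_framework(system.file("extdata", "framework", "default_framework.yaml",
                             package = "fibrewelfare", mustWork = TRUE))
}
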