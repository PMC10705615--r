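# Readers and writers: framework / tree / capacity / answer configuration
# (YAML or JSON), result tables (CSV / JSON) and the packaged fixtures.

# read a structured text file, dispatching on extension
read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(file_ext(path))
  parsed <- switch(ext,
    yaml = ,
    yml = tryCatch(yaml::read_yaml(path), error = function(e)
      stop("YAML parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE)),
    json = tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e)
      stop("JSON parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE)),
    stop("unsupported file extension '", ext, "' (expected .yaml/.yml/.json): ",
         path, call. = FALSE))
  parsed
}

write_structured <- function(x, path) {
  ext <- tolower(file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(x, path, precision = 15L),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported file extension '", ext, "': ", path, call. = FALSE))
  invisible(path)
}

#' Load / write a framework configuration file
#'
#' Framework files are structured text (YAML or JSON, chosen by extension)
#' with top-level keys `domains`, `questions`, `trees`, `capacities`,
#' `bands`; see the schema document shipped at
#' `system.file("extdata", "schemas", "framework.schema.md", package =
#' "fibrewelfare")` and the packaged default configuration for a complete
#' example.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @param validate If `TRUE` (default), the parsed model must validate
#'   with no errors.
#' @return `load_framework()`: a `welfare_framework`.
#' @export
load_framework <- function(path, validate = TRUE) {
  framework_from_config(read_structured(path), source = path,
                        validate = validate)
}

#' @rdname load_framework
#' @param model A `welfare_framework` to serialise.
#' @return `write_framework()`: the path, invisibly. Re-loading the written
#'   file yields a structurally identical model.
#' @export
write_framework <- function(model, path) {
  cfg <- framework_to_config(model)
  cfg$meta <- NULL
  write_structured(cfg, path)
}

#' Load a single decision tree file
#'
#' Tree files carry `provision`, `species`, `questions` (ordered ids) and
#' `leaves` (mapping `"y"/"n"` path strings to scores). The reference feed
#' tree ships as `system.file("extdata", "trees", "feed_generic.yaml",
#' package = "fibrewelfare")`.
#'
#' @param path File path.
#' @return A validated `welfare_tree` (species as listed in the file).
#' @export
load_tree <- function(path) {
  cfg <- read_structured(path)
  decision_tree(provision = cfg$provision,
                species = unlist(cfg$species),
                questions = unlist(cfg$questions),
                leaves = cfg$leaves,
                monotone = !isFALSE(cfg$monotone))
}

#' Load a capacity file
#'
#' Capacity files list subset keys (ids joined by `+`) to measure values;
#' omitted subsets are an error unless the file sets `complete: additive`,
#' in which case non-singleton subsets are completed additively.
#'
#' @param path File path.
#' @return A validated `welfare_capacity`.
#' @export
load_capacity <- function(path) {
  cfg <- read_structured(path)
  parse_capacity_config(cfg)
}

# answers ---------------------------------------------------------------

#' Construct an answer set for one standard
#'
#' @param standard Standard identifier (standards are anonymised by number
#'   in the published assessment; `meta` can attach names locally).
#' @param species One of [species_levels()].
#' @param answers Named list: per provision id, a named list of yes/no
#'   answers keyed by question id.
#' @param mutilations Named list: per mutilation item, a status string
#'   (see [score_mutilations()]), plus `other_mutilations_allowed` (yes/no).
#' @param meta Free-form metadata list.
#' @return An object of class `welfare_answers`.
#' @export
answer_set <- function(standard, species, answers, mutilations = list(),
                       meta = list()) {
  structure(list(standard = as.character(standard),
                 species = match.arg(species, species_levels()),
                 answers = answers, mutilations = mutilations, meta = meta),
            class = "welfare_answers")
}

#' Load an answer file
#'
#' Answer files are structured text with keys `standard`, `species`,
#' `answers` (per provision, per question id, yes/no) and `mutilations`
#' (per item status plus `other_mutilations_allowed`). If a framework is
#' supplied the answers are checked against it and unknown or missing ids
#' raise an error naming them.
#'
#' @param path File path (YAML or JSON).
#' @param framework Optional `welfare_framework` to validate against.
#' @return A `welfare_answers` object.
#' @export
load_answers <- function(path, framework = NULL) {
  cfg <- read_structured(path)
  for (key in c("standard", "species", "answers")) {
    if (is.null(cfg[[key]])) {
      stop("answer file ", path, " is missing key '", key, "'",
           call. = FALSE)
    }
  }
  ans <- answer_set(standard = cfg$standard, species = cfg$species,
                    answers = cfg$answers,
                    mutilations = if (is.null(cfg$mutilations)) list()
                                  else cfg$mutilations,
                    meta = if (is.null(cfg$meta)) list() else cfg$meta)
  if (!is.null(framework)) {
    rep <- validate_answers(ans, framework)
    if (!is_valid(rep)) {
      stop("answer file ", path, ": ", paste(rep$errors, collapse = "; "),
           call. = FALSE)
    }
  }
  ans
}

#' @rdname load_answers
#' @param answers A `welfare_answers` object.
#' @return `validate_answers()`: a `welfare_validation` report listing
#'   unknown provision/question ids and missing answers.
#' @export
validate_answers <- function(answers, framework) {
  errors <- character()
  sp <- answers$species
  unknown_prov <- setdiff(names(answers$answers), provision_levels())
  if (length(unknown_prov)) {
    errors <- c(errors, paste0("unknown provision id: ",
                               paste(unknown_prov, collapse = ", ")))
  }
  for (p in setdiff(provision_levels(), "mutilations")) {
    tree <- framework_tree(framework, sp, p)
    if (is.null(tree)) {
      errors <- c(errors, sprintf("framework has no tree for (%s, %s)", sp, p))
      next
    }
    got <- names(answers$answers[[p]])
    missing <- setdiff(tree$questions, got)
    if (length(missing)) {
      errors <- c(errors, sprintf("%s: missing answer(s) for %s", p,
                                  paste(missing, collapse = ", ")))
    }
    unknown <- setdiff(got, tree$questions)
    if (length(unknown)) {
      errors <- c(errors, sprintf("%s: unknown question id(s): %s", p,
                                  paste(unknown, collapse = ", ")))
    }
  }
  rule <- framework_tree(framework, sp, "mutilations")
  if (inherits(rule, "mutilation_rule")) {
    missing <- setdiff(names(rule$items), names(answers$mutilations))
    if (length(missing)) {
      errors <- c(errors, paste0("mutilations: missing status for ",
                                 paste(missing, collapse = ", ")))
    }
    if (is.null(answers$mutilations$other_mutilations_allowed)) {
      errors <- c(errors,
                  "mutilations: missing other_mutilations_allowed flag")
    }
  }
  validation_report(errors = errors)
}

#' @rdname load_answers
#' @return `write_answers()`: the path, invisibly.
#' @export
write_answers <- function(answers, path) {
  write_structured(list(standard = answers$standard,
                        species = answers$species,
                        answers = answers$answers,
                        mutilations = answers$mutilations,
                        meta = answers$meta),
                   path)
}

# results ---------------------------------------------------------------

# canonical flat column layout shared by the results CSV and the packaged
# reference table: standard, 12 provisions interleaved with their domain
# score (feed, water, nutrition, ...), final score
results_columns <- function() {
  dp <- domain_provisions()
  cols <- "standard"
  for (d in names(dp)) cols <- c(cols, dp[[d]], d)
  c(cols, "final_score")
}

assessment_row <- function(res) {
  row <- c(list(standard = res$standard),
           as.list(res$provision_scores),
           as.list(res$domain_scores),
           list(final_score = res$final_score))
  as.data.frame(row[results_columns()], check.names = FALSE,
                stringsAsFactors = FALSE)
}

#' Turn assessment results into a flat table
#'
#' @param results A `welfare_assessment` or list of them.
#' @return A data.frame, one row per standard, with the 12 provision
#'   columns, the 4 domain columns (each following its provisions) and the
#'   final score — the column layout of the published results table.
#' @export
results_table <- function(results) {
  if (inherits(results, "welfare_assessment")) results <- list(results)
  do.call(rbind, lapply(results, assessment_row))
}

#' Write assessment results
#'
#' CSV output reproduces the published results-table column order with
#' deterministic number formatting (integers without decimals, halves as
#' `.5`). JSON output additionally carries the category labels per domain
#' and overall.
#'
#' @param results A `welfare_assessment` or list of them.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default: from the file extension).
#' @return The path, invisibly.
#' @export
write_results <- function(results, path,
                          format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(file_ext(path)), json = "json", "csv")
  }
  if (inherits(results, "welfare_assessment")) results <- list(results)
  if (format == "csv") {
    df <- results_table(results)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], format_score)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    payload <- lapply(results, function(res) {
      list(standard = res$standard,
           species = res$species,
           provision_scores = as.list(res$provision_scores),
           domain_scores = as.list(res$domain_scores),
           domain_categories = as.list(res$domain_categories),
           final_score = res$final_score,
           category = res$category)
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back a JSON results file
#'
#' Inverse of [write_results()] in JSON format; the write/read round trip
#' is lossless.
#'
#' @param path JSON results file.
#' @return List of `welfare_assessment` objects.
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    structure(
      list(standard = p$standard,
           species = if (is.null(p$species)) NA_character_ else p$species,
           provision_scores = unlist(p$provision_scores),
           domain_scores = unlist(p$domain_scores),
           domain_categories = unlist(p$domain_categories),
           final_score = p$final_score,
           category = p$category),
      class = "welfare_assessment")
  })
}

#' The packaged reference results for 17 anonymised textile standards
#'
#' The published per-standard results: 12 provision scores, 4 domain
#' scores and the final (mental-state) score for each of 17 anonymised
#' textile standards. Used as a regression fixture for the median stage
#' and the categorisation headline.
#'
#' @return A data.frame with columns [results_columns()]; 17 rows,
#'   standards `"1"` to `"17"`.
#' @export
#' @examples
#' t7 <- fixture_table7()
#' stopifnot(nrow(t7) == 17)
fixture_table7 <- function() {
  path <- system.file("extdata", "standards_results.csv",
                      package = "fibrewelfare", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE, colClasses = c(standard = "character"))
  stopifnot(identical(names(df), results_columns()))
  df
}
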