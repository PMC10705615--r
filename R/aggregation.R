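# Final aggregation: domain scores -> mental-state (final) score by median,
# and categorisation of scores into the five welfare risk bands.

#' Welfare risk category bands
#'
#' The five-band legend partitioning the 0-100 score range: 0-19 very poor,
#' 20-39 poor, 40-59 acceptable, 60-79 good, 80-100 excellent. Fractional
#' scores are rounded half-up to the nearest integer before banding, which
#' places a boundary score such as 19.5 in the "poor" band.
#'
#' @param lower Integer lower bounds of the bands (ascending, starting 0).
#' @param upper Integer upper bounds (ending 100); bands must partition
#'   0..100 with no gaps or overlaps.
#' @param labels Band labels, same length.
#' @return A data.frame of class `category_bands` with columns `lower`,
#'   `upper`, `label`.
#' @export
#' @examples
#' category_bands()
category_bands <- function(lower = c(0, 20, 40, 60, 80),
                           upper = c(19, 39, 59, 79, 100),
                           labels = category_labels()) {
  if (length(lower) != length(upper) || length(lower) != length(labels)) {
    stop("lower, upper and labels must have equal length", call. = FALSE)
  }
  bands <- data.frame(lower = as.integer(lower), upper = as.integer(upper),
                      label = as.character(labels),
                      stringsAsFactors = FALSE)
  stop_on_invalid(validate_bands(bands), "category bands")
  class(bands) <- c("category_bands", "data.frame")
  bands
}

validate_bands <- function(bands) {
  errors <- character()
  if (bands$lower[1] != 0L) errors <- c(errors, "bands must start at 0")
  if (bands$upper[nrow(bands)] != 100L) errors <- c(errors, "bands must end at 100")
  if (any(bands$upper < bands$lower)) errors <- c(errors, "band with upper < lower")
  if (nrow(bands) > 1) {
    gaps <- bands$lower[-1] != bands$upper[-nrow(bands)] + 1L
    if (any(gaps)) {
      errors <- c(errors, sprintf("gap or overlap between bands %d and %d",
                                  which(gaps), which(gaps) + 1L))
    }
  }
  validation_report(errors = errors)
}

#' Mental-state (final) score of a standard
#'
#' The four scored domains are assumed to have an equal ability to
#' influence the animal's mental state, so the final score is their median:
#' with four values, the arithmetic mean of the two middle order
#' statistics. Permutation-invariant and bounded by the input range.
#'
#' @param domain_scores Numeric vector or named list of the four domain
#'   scores in \[0, 100\]; if named, names must be the four domain ids.
#' @return The final score.
#' @export
#' @examples
#' mental_state_score(c(46, 48, 19, 49))  # 47
#' mental_state_score(c(28, 6, 4, 9))     # 7.5
mental_state_score <- function(domain_scores) {
  x <- unlist(domain_scores)
  if (!is.null(names(x))) {
    missing <- setdiff(names(domain_provisions()), names(x))
    if (length(missing)) {
      stop("missing domain score(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x <- x[names(domain_provisions())]
  }
  if (length(x) != 4L || anyNA(x <- as.numeric(x))) {
    stop("exactly four non-missing domain scores are required", call. = FALSE)
  }
  if (any(x < 0 | x > 100)) {
    stop("domain scores must lie in [0, 100]", call. = FALSE)
  }
  s <- sort(x)
  (s[2] + s[3]) / 2
}

#' Map a score to its welfare risk category
#'
#' Rounds the score half-up to the nearest integer and returns the label of
#' the band whose integer range contains it. The half-up rule is what
#' places a final score of 19.5 in "Probability for poor animal welfare".
#'
#' @param score Number(s) in \[0, 100\] (vectorised).
#' @param bands A `category_bands` object; defaults to [category_bands()].
#' @return Character vector of band labels.
#' @export
#' @examples
#' categorize(c(47, 19.5, 0, 100))
categorize <- function(score, bands = category_bands()) {
  score <- as.numeric(score)
  if (anyNA(score) || any(score < 0 | score > 100)) {
    stop("score must lie in [0, 100]", call. = FALSE)
  }
  r <- round_half_up(score)
  idx <- vapply(r, function(v) which(v >= bands$lower & v <= bands$upper)[1],
                integer(1))
  bands$label[idx]
}

#' Assess a standard from its 12 provision scores
#'
#' Runs the last two aggregation stages: Choquet integral per domain, then
#' the median into the final mental-state score, then categorisation.
#' Intermediate scores are carried at full precision; rounding happens only
#' in reports.
#'
#' @param provision_scores Named numeric vector or list covering all 12
#'   provisions ([provision_levels()]) with scores in \[0, 100\].
#' @param capacities Named list of one valid `welfare_capacity` per domain
#'   (ground set = that domain's provisions).
#' @param bands A `category_bands` object.
#' @param standard Standard identifier recorded in the result.
#' @param species Optional species recorded in the result.
#' @return An object of class `welfare_assessment`: list with fields
#'   `standard`, `species`, `provision_scores`, `domain_scores`,
#'   `domain_categories`, `final_score`, `category`.
#' @export
assess_from_provisions <- function(provision_scores, capacities,
                                   bands = category_bands(),
                                   standard = NA_character_,
                                   species = NA_character_) {
  scores <- unlist(provision_scores)
  missing <- setdiff(provision_levels(), names(scores))
  if (length(missing)) {
    stop("incomplete provision scores; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(scores), provision_levels())
  if (length(extra)) {
    stop("unknown provision id(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (any(scores < 0 | scores > 100)) {
    stop("provision scores must lie in [0, 100]", call. = FALSE)
  }
  dp <- domain_provisions()
  missing_cap <- setdiff(names(dp), names(capacities))
  if (length(missing_cap)) {
    stop("missing capacity for domain(s): ",
         paste(missing_cap, collapse = ", "), call. = FALSE)
  }
  domain_scores <- vapply(names(dp), function(d) {
    cap <- capacities[[d]]
    if (!setequal(cap$ground_set, dp[[d]])) {
      stop("capacity for ", d, " must be defined on its provisions (",
           paste(dp[[d]], collapse = ", "), ")", call. = FALSE)
    }
    choquet_integral(scores[dp[[d]]], cap)
  }, numeric(1))
  final <- mental_state_score(domain_scores)
  structure(
    list(standard = standard,
         species = species,
         provision_scores = scores[provision_levels()],
         domain_scores = domain_scores,
         domain_categories = setNames(categorize(domain_scores, bands),
                                      names(domain_scores)),
         final_score = final,
         category = categorize(final, bands)),
    class = "welfare_assessment")
}

#' Assess a standard from its yes/no answers
#'
#' Runs the full pipeline: per provision, [evaluate_tree()] (or
#' [score_mutilations()] for the mutilations provision), then
#' [assess_from_provisions()].
#'
#' @param answers A `welfare_answers` object ([load_answers()] or
#'   [answer_set()]).
#' @param framework A `welfare_framework` ([load_framework()] or
#'   [default_framework()]).
#' @return A `welfare_assessment`; see [assess_from_provisions()].
#' @export
assess_from_answers <- function(answers, framework) {
  species <- answers$species
  if (!species %in% species_levels()) {
    stop("unknown species: ", species, call. = FALSE)
  }
  scores <- vapply(provision_levels(), function(p) {
    node <- framework_tree(framework, species, p)
    if (is.null(node)) {
      stop("framework has no tree for (", species, ", ", p, ")",
           call. = FALSE)
    }
    if (inherits(node, "mutilation_rule")) {
      score_mutilations(node, answers$mutilations)
    } else {
      evaluate_tree(node, answers$answers[[p]])
    }
  }, numeric(1))
  assess_from_provisions(scores, framework$capacities, framework$bands,
                         standard = answers$standard, species = species)
}

#' @export
print.welfare_assessment <- function(x, ...) {
  cat(sprintf("Welfare risk assessment: %s%s\n",
              if (is.na(x$standard)) "(unnamed standard)" else x$standard,
              if (is.na(x$species)) "" else paste0(" [", x$species, "]")))
  dp <- domain_provisions()
  for (d in names(dp)) {
    cat(sprintf("  %s: %s (%s)\n", d, format_score(x$domain_scores[[d]]),
                x$domain_categories[[d]]))
    cat(sprintf("    %-26s %s\n", dp[[d]],
                format_score(x$provision_scores[dp[[d]]])), sep = "")
  }
  cat(sprintf("  final (mental state): %s -> %s\n",
              format_score(x$final_score), x$category))
  invisible(x)
}
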