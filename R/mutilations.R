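# The mutilations provision follows its own rule set rather than a fixed
# yes/no tree: one partial score per mutilation item, the worst partial is
# retained, and allowing any mutilation outside the listed items forces the
# provision to 0.

#' Default graded mutilation scores
#'
#' Partial score assigned to a graded mutilation item by its status. The
#' defaults (prohibited = 100; allowed with anaesthesia and analgesia = 35;
#' allowed with partial pain relief = 17; allowed without pain relief = 2)
#' reproduce the score vocabulary observed in the published standard
#' results, but the exact elicited mapping is not public, so the mapping is
#' plain configuration and can be overridden per rule.
#'
#' @return Named numeric vector keyed by status.
#' @export
default_graded_scores <- function() {
  c(prohibited = 100,
    allowed_full_pain_relief = 35,
    allowed_partial_pain_relief = 17,
    allowed_no_pain_relief = 2)
}

#' Construct a mutilation scoring rule
#'
#' @param species One of [species_levels()].
#' @param items Named character vector: mutilation id to scoring mode,
#'   either `"graded"` (the partial score depends on method and use of pain
#'   relief) or `"prohibition_only"` (complete prohibition is needed for
#'   allocation of points: full partial score if prohibited, 0 otherwise).
#' @param graded_scores Named numeric mapping graded statuses to partial
#'   scores in \[0, 100\]; must contain `prohibited`. Defaults to
#'   [default_graded_scores()].
#' @return An object of class `mutilation_rule`.
#' @seealso [score_mutilations()], [default_mutilation_items()]
#' @export
mutilation_rule <- function(species, items,
                            graded_scores = default_graded_scores()) {
  species <- match.arg(species, species_levels())
  items <- unlist(items)
  if (is.null(names(items)) || !all(nzchar(names(items)))) {
    stop("items must be named by mutilation id", call. = FALSE)
  }
  bad <- items[!items %in% c("graded", "prohibition_only")]
  if (length(bad)) {
    stop("unknown scoring mode(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  gv <- unlist(graded_scores)
  graded_scores <- setNames(as.numeric(gv), names(gv))
  if (!"prohibited" %in% names(graded_scores)) {
    stop("graded_scores must map the status 'prohibited'", call. = FALSE)
  }
  if (any(graded_scores < 0 | graded_scores > 100)) {
    stop("graded scores must lie in [0, 100]", call. = FALSE)
  }
  structure(list(species = species, items = items,
                 graded_scores = graded_scores),
            class = "mutilation_rule")
}

#' Per-species mutilation items
#'
#' The published per-species catalogue: alpacas have castration (graded);
#' goats, sheep and cattle have dehorning, tail docking and castration
#' (graded, scored by method and use of pain relief); sheep additionally
#' have mulesing, and waterfowl have live plucking, force feeding and any
#' form of flight restraint, all prohibition-only (complete prohibition
#' needed for allocation of points).
#'
#' @param species One of [species_levels()].
#' @return Named character vector of scoring modes, suitable for
#'   [mutilation_rule()].
#' @export
#' @examples
#' default_mutilation_items("sheep")
default_mutilation_items <- function(species) {
  species <- match.arg(species, species_levels())
  ruminant <- c(dehorning = "graded", tail_docking = "graded",
                castration = "graded")
  switch(species,
    alpaca = c(castration = "graded"),
    goat = ruminant,
    cattle = ruminant,
    sheep = c(ruminant, mulesing = "prohibition_only"),
    waterfowl = c(live_plucking = "prohibition_only",
                  force_feeding = "prohibition_only",
                  flight_restraint = "prohibition_only"))
}

#' Score the mutilations provision
#'
#' Computes one partial score per mutilation item and retains the worst
#' (minimum) of the partials. If the standard allows any mutilation outside
#' the listed items (e.g. ear-notching, biopsies of breeding animals, teeth
#' clipping), the provision immediately scores 0 regardless of the item
#' partials.
#'
#' @param rule A `mutilation_rule`.
#' @param answers A list with one status per item in the rule, plus the
#'   flag `other_mutilations_allowed` (yes/no). Statuses:
#'   prohibition-only items accept `"prohibited"` or `"allowed"`; graded
#'   items accept the names of the rule's `graded_scores`
#'   (e.g. `"prohibited"`, `"allowed_full_pain_relief"`,
#'   `"allowed_partial_pain_relief"`, `"allowed_no_pain_relief"`).
#' @return The provision score in \[0, 100\].
#' @export
#' @examples
#' rule <- mutilation_rule("waterfowl", default_mutilation_items("waterfowl"))
#' score_mutilations(rule, list(live_plucking = "allowed",
#'                              force_feeding = "prohibited",
#'                              flight_restraint = "prohibited",
#'                              other_mutilations_allowed = FALSE))  # 0
score_mutilations <- function(rule, answers) {
  if (is.null(answers$other_mutilations_allowed)) {
    stop("answers must state other_mutilations_allowed (yes/no)",
         call. = FALSE)
  }
  other <- as_yes_no(answers$other_mutilations_allowed,
                     "other_mutilations_allowed")
  missing <- setdiff(names(rule$items), names(answers))
  if (length(missing)) {
    stop("missing status for mutilation item(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  partials <- vapply(names(rule$items), function(id) {
    status <- answers[[id]]
    if (!is.character(status) || length(status) != 1L) {
      stop("status for ", id, " must be a single string", call. = FALSE)
    }
    if (rule$items[[id]] == "prohibition_only") {
      if (!status %in% c("prohibited", "allowed")) {
        stop(id, " is prohibition-only; status must be 'prohibited' or ",
             "'allowed', got '", status, "'", call. = FALSE)
      }
      if (status == "prohibited") rule$graded_scores[["prohibited"]] else 0
    } else {
      if (!status %in% names(rule$graded_scores)) {
        stop("status for graded item ", id, " must be one of: ",
             paste(names(rule$graded_scores), collapse = ", "),
             "; got '", status, "'", call. = FALSE)
      }
      rule$graded_scores[[status]]
    }
  }, numeric(1))
  if (other) return(0)
  min(partials)
}
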