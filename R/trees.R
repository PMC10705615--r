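# Decision trees: ordered yes/no single-measure questions mapped to a
# provision score. A tree of depth k is stored as an explicit table of all
# 2^k answer paths ("y"/"n" strings, first question first) to leaf scores
# in [0, 100] -- the simplest form to validate for completeness and to diff
# against a published tree table.

#' Construct a decision tree for a provision
#'
#' @param provision Provision id the tree scores.
#' @param species Species the tree applies to: a subset of
#'   [species_levels()], or `"all"`.
#' @param questions Ordered character vector of question ids (depth `k`).
#' @param leaves Named numeric: one leaf score in \[0, 100\] for every
#'   complete answer path, named by `k`-character strings of `"y"`/`"n"`
#'   in question order (e.g. `"yny"`).
#' @param monotone If `TRUE`, the tree additionally claims monotonicity:
#'   flipping any single answer from no to yes never decreases the leaf
#'   score; enforced by [validate_tree()].
#' @param validate If `TRUE` (default) the tree must pass [validate_tree()].
#' @return An object of class `welfare_tree`.
#' @seealso [evaluate_tree()], [feed_tree()]
#' @export
#' @examples
#' decision_tree("appropriate_water", "all",
#'               questions = c("water_quality", "unrestricted_water_access"),
#'               leaves = c(yy = 100, yn = 65, ny = 35, nn = 5))
decision_tree <- function(provision, species, questions, leaves,
                          monotone = TRUE, validate = TRUE) {
  lv <- unlist(leaves)
  tree <- structure(
    list(provision = as.character(provision),
         species = as.character(species),
         questions = as.character(questions),
         leaves = setNames(as.numeric(lv), names(lv)),
         monotone = isTRUE(monotone)),
    class = "welfare_tree")
  if (validate) {
    stop_on_invalid(validate_tree(tree, enforce_monotone = tree$monotone),
                    paste0("decision tree for ", provision))
  }
  tree
}

#' @export
print.welfare_tree <- function(x, ...) {
  cat(sprintf("Decision tree: %s (%s), %d questions, %d paths\n",
              x$provision, paste(x$species, collapse = "/"),
              length(x$questions), length(x$leaves)))
  for (q in seq_along(x$questions)) {
    cat(sprintf("  Q%d: %s\n", q, x$questions[q]))
  }
  paths <- sort(names(x$leaves), decreasing = TRUE)
  cat(sprintf("  %s -> %s\n", paths, format_score(x$leaves[paths])), sep = "")
  invisible(x)
}

all_paths <- function(k) {
  if (k == 0L) return("")
  grid <- do.call(expand.grid, rep(list(c("y", "n")), k))
  # column 1 is the first question; expand.grid varies the first factor
  # fastest, which is fine -- we only need the complete set
  apply(grid, 1, paste, collapse = "")
}

#' Validate a decision tree
#'
#' Checks path coverage (exactly `2^k` paths, none missing, none
#' duplicated), leaf range (scores in \[0, 100\]), and optionally
#' monotonicity: every single-answer flip from no to yes must not decrease
#' the leaf score.
#'
#' @param tree A `welfare_tree`.
#' @param enforce_monotone Check the monotonicity property; defaults to the
#'   tree's own `monotone` flag.
#' @return A `welfare_validation` report; monotonicity findings name the
#'   offending path pair.
#' @export
validate_tree <- function(tree, enforce_monotone = tree$monotone) {
  errors <- character()
  k <- length(tree$questions)
  if (k == 0L) {
    return(validation_report(errors = sprintf(
      "tree for %s has no questions", tree$provision)))
  }
  if (anyDuplicated(tree$questions)) {
    errors <- c(errors, "duplicated question ids")
  }
  leaves <- tree$leaves
  paths <- names(leaves)
  expected <- all_paths(k)
  bad_form <- paths[!grepl(sprintf("^[yn]{%d}$", k), paths)]
  if (length(bad_form)) {
    errors <- c(errors, paste0("malformed path label(s): ",
                               paste(bad_form, collapse = ", ")))
  }
  if (anyDuplicated(paths)) {
    errors <- c(errors, paste0("duplicated path(s): ",
                               paste(unique(paths[duplicated(paths)]),
                                     collapse = ", ")))
  }
  if (!setequal(paths, expected) || length(leaves) != 2^k) {
    errors <- c(errors, sprintf("path coverage %d/%d%s",
                                sum(expected %in% paths), 2^k,
                                if (length(setdiff(expected, paths)))
                                  paste0(" (missing: ",
                                         paste(setdiff(expected, paths),
                                               collapse = ", "), ")")
                                else ""))
  }
  if (!is.numeric(leaves) || anyNA(leaves)) {
    errors <- c(errors, "leaf scores must be numeric")
  } else {
    out <- leaves[leaves < 0 | leaves > 100]
    if (length(out)) {
      errors <- c(errors, sprintf("leaf score out of range [0, 100]: %s -> %g",
                                  names(out), out))
    }
  }
  if (length(errors) == 0 && isTRUE(enforce_monotone)) {
    for (p in expected) {
      bits <- strsplit(p, "")[[1]]
      for (i in which(bits == "n")) {
        flipped <- bits
        flipped[i] <- "y"
        q <- paste(flipped, collapse = "")
        if (leaves[[q]] < leaves[[p]]) {
          errors <- c(errors, sprintf(
            "not monotone: flipping %s (question %s: no -> yes) drops %g to %g",
            p, tree$questions[i], leaves[[p]], leaves[[q]]))
        }
      }
    }
  }
  validation_report(errors = errors)
}

#' Evaluate a decision tree on a set of answers
#'
#' Looks up the leaf score of the answer path selected by the yes/no
#' answers. A pure function of the tree and the answers to its own
#' questions: answers to other questions are ignored.
#'
#' @param tree A valid `welfare_tree`.
#' @param answers Named list or vector of yes/no answers (logical, or
#'   `"yes"`/`"no"`); must contain an answer for every question in the tree.
#' @return The leaf score, a number in \[0, 100\] from the tree's leaf set.
#' @export
#' @examples
#' evaluate_tree(feed_tree(), list(ad_libitum_roughage = TRUE,
#'                                 appropriate_feed_quantity = TRUE,
#'                                 bcs_management = TRUE))  # 100
evaluate_tree <- function(tree, answers) {
  if (is.null(names(answers)) && length(answers) == length(tree$questions)) {
    names(answers) <- tree$questions  # positional answers allowed
  }
  missing <- setdiff(tree$questions, names(answers))
  if (length(missing)) {
    stop("missing answer for question(s): ", paste(missing, collapse = ", "),
         " (provision ", tree$provision, ")", call. = FALSE)
  }
  vals <- vapply(tree$questions, function(q)
    as_yes_no(answers[[q]], paste0("answer to ", q)), logical(1))
  path <- paste(ifelse(vals, "y", "n"), collapse = "")
  score <- tree$leaves[[path]]
  if (is.null(score)) {
    stop("tree has no leaf for path ", path, " (provision ",
         tree$provision, ")", call. = FALSE)
  }
  unname(score)
}

#' The reference decision tree for the appropriate feed provision
#'
#' The published feed tree shared by all five species: three single
#' measures (ad libitum access to roughage, appropriate quantity of
#' additional feed, regular Body Condition Score management) and eight leaf
#' scores. This tree is paper-exact; it also ships as the
#' `trees/feed_generic.yaml` file in the package's `extdata`.
#'
#' @return A `welfare_tree` of depth 3 with leaves
#'   `yyy=100, yyn=65, yny=55, ynn=35, nyy=45, nyn=25, nny=35, nnn=5`.
#' @export
feed_tree <- function() {
  decision_tree(
    provision = "appropriate_feed",
    species = "all",
    questions = c("ad_libitum_roughage", "appropriate_feed_quantity",
                  "bcs_management"),
    leaves = c(yyy = 100, yyn = 65, yny = 55, ynn = 35,
               nyy = 45, nyn = 25, nny = 35, nnn = 5),
    monotone = TRUE)
}
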