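# Synthetic generators: random-but-valid frameworks, trees, capacities and
# answer sets, so every aggregation stage and every property is testable
# without any external data. These are testing devices emulating the
# structure of the assessment (yes/no measures, 0-100 leaves on a grid of
# fives, monotone weighting) -- not an elicitation method.

# run expr with a fixed RNG seed, leaving the caller's RNG state untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Configuration for the synthetic generators
#'
#' @param seed Integer seed; identical seeds reproduce identical outputs,
#'   bit-exact.
#' @param n_questions Integer range (length 2) of questions per generated
#'   tree; default 2 to 4.
#' @param monotone_trees If `TRUE` (default), generated trees satisfy the
#'   monotonicity property (no single no-to-yes flip decreases the leaf).
#' @param leaf_grid Allowed leaf scores; default multiples of 5 in
#'   \[0, 100\], the score vocabulary of the published trees and results.
#' @param capacity_scheme `"additive"`, `"ranking"` or `"random_monotone"`.
#' @param interaction Interaction strength for the ranking scheme.
#' @param yes_prob Probability that any single answer is yes (scalar, or
#'   named per provision id); also the probability that each mutilation
#'   item is prohibited, and `1 - yes_prob` is the probability that some
#'   other mutilation is allowed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_questions = c(2L, 4L),
                             monotone_trees = TRUE,
                             leaf_grid = seq(0, 100, by = 5),
                             capacity_scheme = c("random_monotone",
                                                 "additive", "ranking"),
                             interaction = 0.3, yes_prob = 0.5) {
  if (length(leaf_grid) == 0) stop("leaf grid must be non-empty", call. = FALSE)
  if (any(leaf_grid < 0 | leaf_grid > 100)) {
    stop("leaf grid values must lie in [0, 100]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_questions = as.integer(n_questions),
                 monotone_trees = isTRUE(monotone_trees),
                 leaf_grid = sort(unique(leaf_grid)),
                 capacity_scheme = match.arg(capacity_scheme),
                 interaction = interaction,
                 yes_prob = yes_prob),
            class = "generator_config")
}

snap_to_grid <- function(x, grid) {
  grid[vapply(x, function(v) which.min(abs(grid - v)), integer(1))]
}

#' Generate a random decision tree
#'
#' Monotone trees are built from a random base score plus non-negative
#' per-question increments for each yes answer (then snapped to the leaf
#' grid), which guarantees the no-to-yes monotonicity property by
#' construction; non-monotone trees draw leaves independently from the
#' grid.
#'
#' @param cfg A [generator_config()].
#' @param provision Provision id for the generated tree.
#' @param species Species label(s) (default `"all"`).
#' @param seed Seed override; defaults to `cfg$seed`.
#' @return A validated `welfare_tree`.
#' @export
generate_tree <- function(cfg, provision = "appropriate_feed",
                          species = "all", seed = cfg$seed) {
  with_seed(seed, {
    k <- sample(seq(cfg$n_questions[1], cfg$n_questions[2]), 1L)
    questions <- sprintf("%s_q%d", provision, seq_len(k))
    paths <- all_paths(k)
    if (cfg$monotone_trees) {
      base <- runif(1, 0, 25)
      incs <- runif(k, 5, (100 - base) / k)
      raw <- vapply(paths, function(p) {
        yes <- strsplit(p, "")[[1]] == "y"
        base + sum(incs[yes])
      }, numeric(1))
    } else {
      raw <- sample(cfg$leaf_grid, length(paths), replace = TRUE)
    }
    leaves <- setNames(pmin(100, pmax(0, snap_to_grid(raw, cfg$leaf_grid))),
                       paths)
    decision_tree(provision = provision, species = species,
                  questions = questions, leaves = leaves,
                  monotone = cfg$monotone_trees)
  })
}

#' Generate a random valid capacity
#'
#' `"additive"` draws normalised uniform singleton weights;
#' `"ranking"` applies [capacity_from_ranking()] to a random permutation;
#' `"random_monotone"` draws a uniform value per coalition, enforces
#' monotonicity by propagating the running maximum up the subset lattice,
#' and renormalises by the ground-set value — covering both sub- and
#' super-additive coalitions.
#'
#' @param cfg A [generator_config()].
#' @param ground_set Provision ids (2-4).
#' @param seed Seed override; defaults to `cfg$seed`.
#' @return A `welfare_capacity` passing [validate_capacity()].
#' @export
generate_capacity <- function(cfg, ground_set, seed = cfg$seed) {
  ground_set <- as.character(ground_set)
  n <- length(ground_set)
  with_seed(seed, {
    switch(cfg$capacity_scheme,
      additive = {
        w <- runif(n)
        capacity(ground_set, mu = setNames(as.list(w / sum(w)), ground_set),
                 complete = "additive")
      },
      ranking = capacity_from_ranking(sample(ground_set),
                                      interaction = cfg$interaction),
      random_monotone = {
        mu <- numeric(2^n)
        # masks ordered by popcount so covered subsets are already final
        masks <- (1:(2^n - 1L))
        pop <- vapply(masks, function(m)
          sum(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L), integer(1))
        for (m in masks[order(pop)]) {
          below <- 0
          for (i in seq_len(n)) {
            bit <- bitwShiftL(1L, i - 1L)
            if (bitwAnd(m, bit) != 0L) {
              below <- max(below, mu[bitwAnd(m, bitwNot(bit)) + 1L])
            }
          }
          mu[m + 1L] <- max(runif(1), below)
        }
        mu <- mu / mu[2^n]
        structure(list(ground_set = ground_set, mu = mu),
                  class = "welfare_capacity")
      })
  })
}

#' Generate a complete synthetic framework
#'
#' One random tree per provision (shared across species, mirroring the
#' aligned question catalogue of the real framework), the standard
#' per-species mutilation rules, one generated capacity per domain and the
#' standard bands.
#'
#' @param cfg A [generator_config()].
#' @return A validated `welfare_framework`.
#' @export
generate_framework <- function(cfg) {
  with_seed(cfg$seed, {
    trees <- setNames(vector("list", length(species_levels())),
                      species_levels())
    for (p in setdiff(provision_levels(), "mutilations")) {
      tree <- generate_tree(cfg, provision = p, species = "all",
                            seed = NULL)  # inherit the outer stream
      for (sp in species_levels()) trees[[sp]][[p]] <- tree
    }
    for (sp in species_levels()) {
      trees[[sp]][["mutilations"]] <-
        mutilation_rule(sp, default_mutilation_items(sp))
    }
    capacities <- lapply(domain_provisions(), function(gs)
      generate_capacity(cfg, gs, seed = NULL))
    welfare_framework(trees = trees, capacities = capacities,
                      meta = list(synthetic = TRUE, seed = cfg$seed))
  })
}

#' Generate a random answer set for a framework
#'
#' Per question, an independent yes with probability `yes_prob` (looked up
#' per provision if `yes_prob` is named); mutilation items are prohibited
#' with probability `yes_prob` and otherwise get a random allowed status;
#' some other mutilation is allowed with probability `1 - yes_prob`.
#'
#' @param cfg A [generator_config()].
#' @param framework A `welfare_framework`.
#' @param species Species to answer for (default: random).
#' @param standard Standard id recorded in the answer set.
#' @param seed Seed override; defaults to `cfg$seed`.
#' @return A `welfare_answers` object consistent with the framework.
#' @export
generate_answers <- function(cfg, framework, species = NULL,
                             standard = "synthetic-standard",
                             seed = cfg$seed) {
  with_seed(seed, {
    if (is.null(species)) species <- sample(species_levels(), 1L)
    p_yes <- function(prov) {
      if (!is.null(names(cfg$yes_prob)) && prov %in% names(cfg$yes_prob)) {
        cfg$yes_prob[[prov]]
      } else if (is.null(names(cfg$yes_prob))) cfg$yes_prob[[1]] else 0.5
    }
    answers <- list()
    for (p in setdiff(provision_levels(), "mutilations")) {
      tree <- framework_tree(framework, species, p)
      answers[[p]] <- setNames(
        as.list(runif(length(tree$questions)) < p_yes(p)), tree$questions)
    }
    rule <- framework_tree(framework, species, "mutilations")
    pm <- p_yes("mutilations")
    mut <- lapply(rule$items, function(mode) {
      if (runif(1) < pm) "prohibited"
      else if (mode == "prohibition_only") "allowed"
      else sample(setdiff(names(rule$graded_scores), "prohibited"), 1L)
    })
    mut$other_mutilations_allowed <- runif(1) >= pm
    answer_set(standard = standard, species = species, answers = answers,
               mutilations = mut, meta = list(synthetic = TRUE))
  })
}
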