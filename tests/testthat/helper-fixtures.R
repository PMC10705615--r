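# answer-set construction helpers used across test files

# uniform answers: every question answered `yes`; mutilations all
# prohibited and no other mutilation allowed when yes = TRUE, and the
# worst statuses when yes = FALSE
make_uniform_answers <- function(framework, species, yes = TRUE,
                                 standard = "test-standard") {
  answers <- list()
  for (p in setdiff(provision_levels(), "mutilations")) {
    tree <- framework$trees[[species]][[p]]
    answers[[p]] <- setNames(as.list(rep(yes, length(tree$questions))),
                             tree$questions)
  }
  rule <- framework$trees[[species]][["mutilations"]]
  mut <- lapply(rule$items, function(mode) {
    if (yes) "prohibited"
    else if (mode == "prohibition_only") "allowed" else "allowed_no_pain_relief"
  })
  mut$other_mutilations_allowed <- !yes
  answer_set(standard = standard, species = species, answers = answers,
             mutilations = mut)
}

# all single-step improvements of an answer set: each question no -> yes,
# each mutilation status -> prohibited, the other-mutilations flag -> no
improvement_steps <- function(answers, framework) {
  steps <- list()
  for (p in setdiff(provision_levels(), "mutilations")) {
    for (q in names(answers$answers[[p]])) {
      if (!isTRUE(answers$answers[[p]][[q]])) {
        a2 <- answers
        a2$answers[[p]][[q]] <- TRUE
        steps[[length(steps) + 1L]] <- a2
      }
    }
  }
  rule <- framework$trees[[answers$species]][["mutilations"]]
  for (item in names(rule$items)) {
    if (!identical(answers$mutilations[[item]], "prohibited")) {
      a2 <- answers
      a2$mutilations[[item]] <- "prohibited"
      steps[[length(steps) + 1L]] <- a2
    }
  }
  if (isTRUE(answers$mutilations$other_mutilations_allowed)) {
    a2 <- answers
    a2$mutilations$other_mutilations_allowed <- FALSE
    steps[[length(steps) + 1L]] <- a2
  }
  steps
}
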