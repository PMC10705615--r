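test_that("prohibition-only items zero the provision whenever allowed", {
  rule <- mutilation_rule("waterfowl", default_mutilation_items("waterfowl"))
  expect_equal(score_mutilations(rule, list(
    live_plucking = "allowed", force_feeding = "prohibited",
    flight_restraint = "prohibited", other_mutilations_allowed = FALSE)), 0)
  # every waterfowl item is prohibition-only
  expect_true(all(rule$items == "prohibition_only"))
})

test_that("full prohibition with no other mutilations scores 100", {
  rule <- mutilation_rule("sheep", default_mutilation_items("sheep"))
  expect_equal(score_mutilations(rule, list(
    dehorning = "prohibited", tail_docking = "prohibited",
    castration = "prohibited", mulesing = "prohibited",
    other_mutilations_allowed = FALSE)), 100)
})

test_that("the worst partial score is retained", {
  rule <- mutilation_rule("goat", default_mutilation_items("goat"),
                          graded_scores = c(prohibited = 100,
                                            allowed_full_pain_relief = 35,
                                            allowed_partial_pain_relief = 17,
                                            allowed_no_pain_relief = 2))
  # partials (100, 35, 17) -> 17
  expect_equal(score_mutilations(rule, list(
    dehorning = "prohibited", tail_docking = "allowed_full_pain_relief",
    castration = "allowed_partial_pain_relief",
    other_mutilations_allowed = FALSE)), 17)
})

test_that("allowing any other mutilation forces 0 despite perfect items", {
  rule <- mutilation_rule("cattle", default_mutilation_items("cattle"))
  expect_equal(score_mutilations(rule, list(
    dehorning = "prohibited", tail_docking = "prohibited",
    castration = "prohibited", other_mutilations_allowed = TRUE)), 0)
})

test_that("the species item catalogue matches the published rules", {
  expect_identical(names(default_mutilation_items("alpaca")), "castration")
  expect_identical(default_mutilation_items("sheep")[["mulesing"]],
                   "prohibition_only")
  for (sp in c("goat", "sheep", "cattle")) {
    items <- default_mutilation_items(sp)
    expect_identical(unname(items[c("dehorning", "tail_docking", "castration")]),
                     rep("graded", 3), label = sp)
  }
  expect_setequal(names(default_mutilation_items("waterfowl")),
                  c("live_plucking", "force_feeding", "flight_restraint"))
})

test_that("status errors are informative", {
  rule <- mutilation_rule("sheep", default_mutilation_items("sheep"))
  full <- list(dehorning = "prohibited", tail_docking = "prohibited",
               castration = "prohibited", mulesing = "prohibited",
               other_mutilations_allowed = FALSE)
  expect_error(score_mutilations(rule, full[-2]), "tail_docking")
  bad <- full
  bad$mulesing <- "allowed_full_pain_relief"  # graded qualifier on prohibition-only
  expect_error(score_mutilations(rule, bad), "prohibition-only")
  bad2 <- full
  bad2$castration <- "allowed"  # graded item needs a pain-relief qualifier
  expect_error(score_mutilations(rule, bad2), "graded")
  expect_error(score_mutilations(rule, full[1:4]), "other_mutilations_allowed")
})

test_that("dominance properties hold on randomised answers", {
  set.seed(7)
  for (i in 1:200) {
    sp <- sample(species_levels(), 1)
    rule <- mutilation_rule(sp, default_mutilation_items(sp))
    statuses <- lapply(rule$items, function(mode) {
      if (mode == "prohibition_only") sample(c("prohibited", "allowed"), 1)
      else sample(names(rule$graded_scores), 1)
    })
    partials <- vapply(names(rule$items), function(id) {
      if (rule$items[[id]] == "prohibition_only") {
        if (statuses[[id]] == "prohibited") 100 else 0
      } else rule$graded_scores[[statuses[[id]]]]
    }, numeric(1))
    s_clean <- score_mutilations(rule, c(statuses,
                                         other_mutilations_allowed = FALSE))
    expect_lte(s_clean, min(partials))
    expect_equal(s_clean, min(partials))
    # the any-other-mutilation override always forces 0
    s_other <- score_mutilations(rule, c(statuses,
                                         other_mutilations_allowed = TRUE))
    expect_identical(s_other, 0)
  }
})
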