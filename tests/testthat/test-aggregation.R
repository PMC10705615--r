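test_that("the mental-state score is the median of the four domains", {
  expect_equal(mental_state_score(c(46, 48, 19, 49)), 47)
  expect_equal(mental_state_score(c(28, 6, 4, 9)), 7.5)
  expect_equal(mental_state_score(c(31, 29, 7, 10)), 19.5)
  expect_equal(mental_state_score(rep(62, 4)), 62)
  # named input is accepted in any order
  expect_equal(mental_state_score(c(health = 19, nutrition = 46,
                                    behavioural_interactions = 49,
                                    physical_environment = 48)), 47)
  expect_error(mental_state_score(c(health = 19, nutrition = 46,
                                    physical_environment = 48)),
               "behavioural_interactions")
  expect_error(mental_state_score(c(1, 2, 3)), "four")
  # agreement with the standard even-n median and permutation invariance
  set.seed(3)
  for (i in 1:100) {
    x <- runif(4, 0, 100)
    expect_equal(mental_state_score(x), stats::median(x))
    expect_equal(mental_state_score(sample(x)), mental_state_score(x))
    expect_gte(mental_state_score(x), min(x))
    expect_lte(mental_state_score(x), max(x))
  }
})

test_that("categorisation applies the five bands with half-up rounding", {
  expect_equal(categorize(47), "Probability for acceptable animal welfare")
  expect_equal(categorize(19.5), "Probability for poor animal welfare")
  expect_equal(categorize(19.49), "Probability for very poor animal welfare")
  expect_equal(categorize(0), "Probability for very poor animal welfare")
  expect_equal(categorize(100), "Probability for excellent animal welfare")
  expect_equal(categorize(c(39.5, 59.5, 79.5)),
               paste("Probability for", c("acceptable", "good", "excellent"),
                     "animal welfare"))
  expect_error(categorize(101), "\\[0, 100\\]")
  # bands must partition 0-100
  expect_error(category_bands(lower = c(0, 25), upper = c(19, 100),
                              labels = c("a", "b")), "gap")
})

test_that("assessment from provisions records all intermediates", {
  fw <- default_framework()
  all100 <- setNames(rep(100, 12), provision_levels())
  res <- assess_from_provisions(all100, fw$capacities, fw$bands,
                                standard = "perfect")
  expect_s3_class(res, "welfare_assessment")
  expect_equal(unname(res$domain_scores), rep(100, 4))
  expect_equal(res$final_score, 100)
  expect_equal(res$category, "Probability for excellent animal welfare")

  res0 <- assess_from_provisions(setNames(rep(0, 12), provision_levels()),
                                 fw$capacities, fw$bands)
  expect_equal(res0$final_score, 0)
  expect_equal(res0$category, "Probability for very poor animal welfare")

  expect_error(assess_from_provisions(all100[-3], fw$capacities, fw$bands),
               names(all100)[3])
})

test_that("the median stage is exact whatever capacities produced the domains", {
  # domain scores (5, 5, 3, 9) -> final 5, category very poor
  expect_equal(mental_state_score(c(5, 5, 3, 9)), 5)
  expect_equal(categorize(5), "Probability for very poor animal welfare")
})

test_that("full-pipeline extremes behave monotonically", {
  fw <- default_framework()
  for (sp in c("sheep", "waterfowl")) {
    best <- assess_from_answers(make_uniform_answers(fw, sp, yes = TRUE), fw)
    expect_equal(best$final_score, 100)
    expect_equal(unname(best$provision_scores), rep(100, 12))
    worst <- assess_from_answers(make_uniform_answers(fw, sp, yes = FALSE), fw)
    expect_equal(unname(worst$provision_scores["mutilations"]), 0)
    expect_lte(worst$final_score, 5)
  }
})

test_that("assessment is invariant to answer key ordering", {
  fw <- default_framework()
  cfg <- generator_config(seed = 505)
  set.seed(505)
  for (i in 1:100) {
    ans <- generate_answers(cfg, fw, standard = paste0("s", i),
                            seed = 505 + i)
    ref <- assess_from_answers(ans, fw)
    shuffled <- ans
    shuffled$answers <- shuffled$answers[sample(names(shuffled$answers))]
    for (p in names(shuffled$answers)) {
      shuffled$answers[[p]] <-
        shuffled$answers[[p]][sample(names(shuffled$answers[[p]]))]
    }
    shuffled$mutilations <-
      shuffled$mutilations[sample(names(shuffled$mutilations))]
    res <- assess_from_answers(shuffled, fw)
    expect_identical(res$provision_scores, ref$provision_scores)
    expect_identical(res$final_score, ref$final_score)
  }
})
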