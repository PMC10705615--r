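test_that("the reference feed tree reproduces its published leaf table", {
  tree <- feed_tree()
  expected <- c(yyy = 100, yyn = 65, yny = 55, ynn = 35,
                nyy = 45, nyn = 25, nny = 35, nnn = 5)
  for (p in names(expected)) {
    ans <- setNames(as.list(strsplit(p, "")[[1]] == "y"), tree$questions)
    expect_identical(evaluate_tree(tree, ans), unname(expected[[p]]),
                     label = paste("path", p))
  }
  # the shipped file is the same tree
  shipped <- load_tree(system.file("extdata", "trees", "feed_generic.yaml",
                                   package = "fibrewelfare"))
  expect_identical(shipped$questions, tree$questions)
  expect_identical(shipped$leaves[names(expected)], expected)
})

test_that("single-question trees evaluate as identity", {
  tree <- decision_tree("fitness", "all", "q1", c(y = 100, n = 0))
  expect_equal(evaluate_tree(tree, list(q1 = TRUE)), 100)
  expect_equal(evaluate_tree(tree, list(q1 = "no")), 0)
})

test_that("evaluation errors name the offending question", {
  tree <- feed_tree()
  expect_error(evaluate_tree(tree, list(ad_libitum_roughage = TRUE)),
               "appropriate_feed_quantity")
  expect_error(evaluate_tree(tree, list(ad_libitum_roughage = "maybe",
                                        appropriate_feed_quantity = TRUE,
                                        bcs_management = TRUE)),
               "yes/no")
})

test_that("evaluation is a pure function of the tree's own questions", {
  tree <- feed_tree()
  base <- list(ad_libitum_roughage = TRUE, appropriate_feed_quantity = FALSE,
               bcs_management = TRUE)
  ref <- evaluate_tree(tree, base)
  set.seed(42)
  for (i in 1:25) {
    shuffled <- base[sample(names(base))]
    shuffled[[sprintf("unrelated_%d", i)]] <- runif(1) < 0.5
    expect_identical(evaluate_tree(tree, shuffled), ref)
  }
})

test_that("tree validation catches coverage, range and monotonicity defects", {
  # valid monotone reference tree: no findings, confirmed by brute force
  expect_length(validate_tree(feed_tree())$errors, 0)
  expect_identical(count_decreasing_flips(feed_tree()$leaves), 0L)

  incomplete <- decision_tree("fitness", "all", c("a", "b"),
                              c(yy = 100, yn = 50, nn = 0),
                              validate = FALSE)
  expect_match(validate_tree(incomplete)$errors, "path coverage 3/4",
               all = FALSE)

  out_of_range <- decision_tree("fitness", "all", c("a", "b"),
                                c(yy = 105, yn = 50, ny = 20, nn = 0),
                                validate = FALSE)
  expect_match(validate_tree(out_of_range)$errors, "out of range",
               all = FALSE)

  non_mono <- decision_tree("fitness", "all", c("a", "b"),
                            c(yy = 10, yn = 50, ny = 20, nn = 0),
                            validate = FALSE)
  rep <- validate_tree(non_mono, enforce_monotone = TRUE)
  expect_match(rep$errors, "not monotone", all = FALSE)
  # brute force agrees on the number of decreasing flips
  expect_length(rep$errors, count_decreasing_flips(non_mono$leaves))
  # without the flag the same tree passes
  expect_length(validate_tree(non_mono, enforce_monotone = FALSE)$errors, 0)
})
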