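quad_capacity <- function(ids) {
  # mu(S) = (|S|/n)^2: sub-additive for small coalitions
  n <- length(ids)
  mu <- vapply(0:(2^n - 1), function(m)
    (sum(bitwAnd(m, 2^(0:(n - 1))) != 0) / n)^2, numeric(1))
  structure(list(ground_set = ids, mu = mu), class = "welfare_capacity")
}

test_that("the integral matches hand-checkable cases", {
  cap <- capacity(c("feed", "water"),
                  mu = c(feed = 0.8, water = 0.2), complete = "additive")
  # additive capacity reduces to the weighted mean
  expect_equal(choquet_integral(c(feed = 45, water = 55), cap), 47)
  # idempotence
  expect_equal(choquet_integral(c(feed = 62.5, water = 62.5), cap), 62.5)
  # sub-additive quadratic capacity on four scores, value frozen from the
  # Moebius-sum oracle
  capq <- quad_capacity(c("a", "b", "c", "d"))
  x <- c(a = 100, b = 35, c = 0, d = 55)
  expect_equal(oracle_choquet(x, capq), 27.5)
  expect_equal(choquet_integral(x, capq), 27.5)
  # unanimity capacity gives the minimum
  cap_min <- capacity_from_ranking(c("a", "b", "c"), interaction = 1)
  expect_equal(choquet_integral(c(a = 80, b = 20, c = 50), cap_min), 20)
})

test_that("capacity validation reports normalisation and monotonicity", {
  ok <- capacity(c("a", "b", "c"),
                 mu = c(a = 0.5, b = 0.3, c = 0.2), complete = "additive")
  expect_length(validate_capacity(ok)$errors, 0)

  bad_empty <- ok
  bad_empty$mu[1] <- 0.1
  expect_match(validate_capacity(bad_empty)$errors, "empty set", all = FALSE)

  bad_mono <- ok
  bad_mono$mu[2] <- 0.6                       # mu({a}) = 0.6
  bad_mono$mu[4] <- 0.5                       # mu({a,b}) = 0.5
  rep <- validate_capacity(bad_mono)
  expect_match(rep$errors, "mu\\(\\{a\\}\\) = 0.6 > mu\\(\\{a\\+b\\}\\) = 0.5",
               all = FALSE)

  expect_error(capacity(c("a", "b"), mu = c(a = 0.5)), "omits")
  expect_error(choquet_integral(c(a = 1, b = 2, c = 3), bad_mono),
               "invalid capacity")
  expect_error(choquet_integral(c(a = 1, x = 2), ok), "ground set")
})

test_that("Moebius and capacity forms are mutual inverses", {
  w <- c(a = 0.2, b = 0.5, c = 0.3)
  add <- capacity(names(w), mu = w, complete = "additive")
  m <- moebius_from_capacity(add)
  # additive capacity: masses sit on singletons only
  singles <- vapply(1:3, function(i) m$m[2^(i - 1) + 1], numeric(1))
  expect_equal(singles, unname(w))
  expect_equal(sum(abs(m$m[-c(2, 3, 5)])), 0)
  expect_equal(capacity_from_moebius(m)$mu, add$mu)

  # round trip on a non-additive capacity
  capq <- quad_capacity(c("p", "q", "r", "s"))
  expect_equal(capacity_from_moebius(moebius_from_capacity(capq))$mu, capq$mu)
  # masses always sum to 1
  expect_equal(sum(moebius_from_capacity(capq)$m), 1)

  # non-monotone induced set function is rejected: mu({a}) = 1.5 > mu({a,b})
  expect_error(capacity_from_moebius(list(ground_set = c("a", "b"),
                                          m = c("a" = 1.5, "b" = 0.5,
                                                "a+b" = -1))),
               "invalid capacity")
})

test_that("ranking-built capacities behave as documented", {
  cap0 <- capacity_from_ranking(c("first", "second"), interaction = 0)
  expect_equal(unname(cap0$mu[2:3]), c(2 / 3, 1 / 3))
  # interaction 0: Choquet equals the rank-sum weighted mean
  x <- c(first = 80, second = 20)
  expect_equal(choquet_integral(x, cap0), 2 / 3 * 80 + 1 / 3 * 20)
  # interaction 1: unanimity capacity, integral is the minimum
  cap1 <- capacity_from_ranking(c("first", "second", "third"),
                                interaction = 1)
  expect_equal(max(abs(cap1$mu[-2^3])), 0)
  expect_equal(choquet_integral(c(first = 10, second = 90, third = 40), cap1),
               10)
  # intermediate interaction: valid and below the additive mean
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:4, 1)
    lambda <- runif(1)
    cap <- capacity_from_ranking(sprintf("p%d", 1:n), interaction = lambda)
    expect_length(validate_capacity(cap)$errors, 0)
    x <- setNames(runif(n, 0, 100), cap$ground_set)
    w <- rev(seq_len(n)) / sum(seq_len(n))
    expect_lte(choquet_integral(x, cap), sum(w * x) + 1e-9)
  }
  expect_error(capacity_from_ranking(c("a", "a")), "permutation")
})

test_that("integral properties hold against the oracle on random capacities", {
  set.seed(101)
  cfg <- generator_config(seed = 101)
  for (i in 1:400) {
    n <- sample(2:4, 1)
    ids <- sprintf("p%d", seq_len(n))
    cap <- generate_capacity(cfg, ids, seed = NULL)
    expect_length(validate_capacity(cap)$errors, 0)
    x <- setNames(runif(n, 0, 100), ids)
    v <- choquet_integral(x, cap)
    # agreement with the Moebius-sum oracle
    expect_equal(v, oracle_choquet(x, cap), tolerance = 1e-9)
    # boundedness
    expect_gte(v, min(x) - 1e-9)
    expect_lte(v, max(x) + 1e-9)
    # monotonicity in each coordinate
    j <- sample(n, 1)
    x2 <- x
    x2[j] <- min(100, x2[j] + runif(1, 0, 30))
    expect_gte(choquet_integral(x2, cap), v - 1e-9)
    # comonotonic additivity and positive homogeneity
    ord <- order(runif(n))
    a <- setNames(sort(runif(n, 0, 50))[order(ord)], ids)
    b <- setNames(sort(runif(n, 0, 50))[order(ord)], ids)
    expect_equal(choquet_integral(a + b, cap),
                 choquet_integral(a, cap) + choquet_integral(b, cap),
                 tolerance = 1e-9)
    lambda <- runif(1)
    expect_equal(choquet_integral(lambda * x, cap), lambda * v,
                 tolerance = 1e-9)
  }
})
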