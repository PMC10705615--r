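# Capacities (fuzzy measures) over a domain's provisions and the discrete
# Choquet integral that aggregates provision scores into a domain score.
#
# A capacity on a ground set N is stored densely: mu is a numeric vector of
# length 2^n indexed by bitmask + 1, where bit i of the mask marks the
# presence of ground_set[i + 1]. Ground sets here are small (2-4 provisions
# per domain) so dense subset enumeration is exact and cheap.

# subset-key helpers ----------------------------------------------------

# human-readable key for a subset mask: ids joined by "+", "" for the empty set
mask_key <- function(mask, ground_set) {
  paste(ground_set[bitwAnd(mask, bitwShiftL(1L, seq_along(ground_set) - 1L)) != 0L],
        collapse = "+")
}

mask_of <- function(ids, ground_set) {
  pos <- match(ids, ground_set)
  if (anyNA(pos)) {
    stop("unknown ids for this ground set: ",
         paste(ids[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(pos)) stop("duplicated ids in subset", call. = FALSE)
  sum(bitwShiftL(1L, pos - 1L))
}

all_mask_keys <- function(ground_set) {
  vapply(0:(2^length(ground_set) - 1L), mask_key, character(1),
         ground_set = ground_set)
}

#' Construct a capacity (fuzzy measure)
#'
#' A capacity assigns a weight in \[0, 1\] to every coalition (subset) of a
#' domain's provisions, with `mu(empty) = 0`, `mu(full set) = 1`, and
#' monotonicity under set inclusion. It encodes both the importance of
#' individual provisions and the interaction of provision coalitions, and
#' drives the Choquet integral used for domain aggregation.
#'
#' @param ground_set Character vector of provision ids (2 to 4 elements).
#' @param mu Named numeric vector or list giving the measure of subsets.
#'   Subset names are ids joined by `"+"` (order-free); the empty set may be
#'   written `""` and defaults to 0; the full set must equal 1.
#' @param complete Either `"none"` (every subset must be listed; omission is
#'   an error) or `"additive"` (only singletons are required; every other
#'   subset is completed additively as the sum of its singletons).
#' @param validate If `TRUE` (default) the resulting capacity must pass
#'   [validate_capacity()].
#'
#' @return An object of class `welfare_capacity`.
#' @seealso [choquet_integral()], [capacity_from_ranking()],
#'   [capacity_from_moebius()]
#' @export
#' @examples
#' capacity(c("appropriate_feed", "appropriate_water"),
#'          mu = c(appropriate_feed = 0.8, appropriate_water = 0.2),
#'          complete = "additive")
capacity <- function(ground_set, mu, complete = c("none", "additive"),
                     validate = TRUE) {
  complete <- match.arg(complete)
  ground_set <- as.character(ground_set)
  n <- length(ground_set)
  if (n < 1L || n > 8L) stop("ground set must have 1-8 elements", call. = FALSE)
  if (anyDuplicated(ground_set)) stop("duplicated provision ids", call. = FALSE)

  mu_in <- unlist(mu)
  # normalise user keys: ids may be listed in any order within a key
  keys <- names(mu_in)
  if (is.null(keys) && length(mu_in) == n) keys <- ground_set  # bare singleton weights
  if (is.null(keys)) stop("mu must be named by subset", call. = FALSE)
  canon <- vapply(keys, function(k) {
    ids <- strsplit(k, "+", fixed = TRUE)[[1]]
    ids <- ids[nzchar(ids)]
    if (length(ids) == 0) "" else mask_key(mask_of(ids, ground_set), ground_set)
  }, character(1))
  if (anyDuplicated(canon)) {
    stop("subset listed twice: ", canon[duplicated(canon)][1], call. = FALSE)
  }

  vals <- rep(NA_real_, 2^n)
  names(vals) <- all_mask_keys(ground_set)
  vals[canon] <- as.numeric(mu_in)
  if (is.na(vals[1])) vals[1] <- 0  # empty set defaults to 0

  if (anyNA(vals)) {
    if (complete == "additive") {
      singles <- vals[vapply(seq_len(n), function(i)
        mask_key(bitwShiftL(1L, i - 1L), ground_set), character(1))]
      if (anyNA(singles)) {
        stop("additive completion needs every singleton measure", call. = FALSE)
      }
      for (m in which(is.na(vals)) - 1L) {
        members <- bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L
        vals[m + 1L] <- sum(singles[members])
      }
    } else {
      stop("capacity omits subsets (set complete = \"additive\" to fill in): ",
           paste(names(vals)[is.na(vals)], collapse = ", "), call. = FALSE)
    }
  }

  cap <- structure(list(ground_set = ground_set, mu = unname(vals)),
                   class = "welfare_capacity")
  if (validate) stop_on_invalid(validate_capacity(cap), "capacity")
  cap
}

#' @export
print.welfare_capacity <- function(x, ...) {
  cat("Capacity on {", paste(x$ground_set, collapse = ", "), "}\n", sep = "")
  keys <- all_mask_keys(x$ground_set)
  keys[1] <- "(empty)"
  cat(sprintf("  mu(%s) = %g\n", keys, x$mu), sep = "")
  invisible(x)
}

# measure of an arbitrary subset (by ids)
capacity_mu <- function(cap, ids) {
  cap$mu[mask_of(ids, cap$ground_set) + 1L]
}

#' Validate a capacity
#'
#' Checks normalisation (`mu(empty) = 0`, `mu(full) = 1`) and monotonicity
#' (`A` a subset of `B` implies `mu(A) <= mu(B)`), to an absolute tolerance
#' of `1e-9`. Findings are returned, not thrown.
#'
#' @param cap A `welfare_capacity` (fields `ground_set`, `mu`).
#' @param tol Absolute numerical tolerance.
#' @return A `welfare_validation` report; each monotonicity violation names
#'   the offending subset pair.
#' @export
validate_capacity <- function(cap, tol = 1e-9) {
  errors <- character()
  n <- length(cap$ground_set)
  mu <- cap$mu
  if (length(mu) != 2^n || anyNA(mu)) {
    return(validation_report(errors = sprintf(
      "capacity must assign a value to all %d subsets", 2^n)))
  }
  keys <- all_mask_keys(cap$ground_set)
  if (abs(mu[1]) > tol) {
    errors <- c(errors, sprintf("mu(empty set) = %g, expected 0", mu[1]))
  }
  if (abs(mu[2^n] - 1) > tol) {
    errors <- c(errors, sprintf("mu(ground set) = %g, expected 1", mu[2^n]))
  }
  # covering pairs suffice: A subset of B with |B \ A| = 1
  for (m in 1:(2^n - 1L)) {
    for (i in seq_len(n)) {
      bit <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(m, bit) != 0L) {
        sub <- bitwAnd(m, bitwNot(bit))
        if (mu[sub + 1L] > mu[m + 1L] + tol) {
          errors <- c(errors, sprintf(
            "monotonicity violated: mu({%s}) = %g > mu({%s}) = %g",
            keys[sub + 1L], mu[sub + 1L], keys[m + 1L], mu[m + 1L]))
        }
      }
    }
  }
  validation_report(errors = errors)
}

#' Discrete Choquet integral of provision scores
#'
#' Aggregates a domain's provision scores into a single domain score with
#' respect to a capacity. With scores sorted ascending,
#' `x_(1) <= ... <= x_(n)` and `x_(0) = 0`, the integral is
#' `sum_i (x_(i) - x_(i-1)) * mu(A_(i))` where `A_(i)` is the coalition of
#' provisions scoring at least `x_(i)`. For an additive capacity this is the
#' weighted mean; for sub-additive coalitions it drops the aggregate below
#' the weighted mean, so a low-scoring important provision cannot be
#' compensated away. The result always lies between `min(scores)` and
#' `max(scores)`.
#'
#' @param scores Named numeric vector (or list) of scores in \[0, 100\];
#'   names must be exactly the capacity's ground set.
#' @param cap A valid `welfare_capacity`.
#' @return The domain score, a number in `[min(scores), max(scores)]`.
#' @export
#' @examples
#' cap <- capacity(c("appropriate_feed", "appropriate_water"),
#'                 mu = c(appropriate_feed = 0.8, appropriate_water = 0.2),
#'                 complete = "additive")
#' choquet_integral(c(appropriate_feed = 45, appropriate_water = 55), cap)  # 47
choquet_integral <- function(scores, cap) {
  scores <- unlist(scores)
  if (is.null(names(scores)) || !setequal(names(scores), cap$ground_set) ||
      length(scores) != length(cap$ground_set)) {
    stop("scores must be named by exactly the capacity's ground set (",
         paste(cap$ground_set, collapse = ", "), ")", call. = FALSE)
  }
  stop_on_invalid(validate_capacity(cap), "capacity")
  x <- as.numeric(scores[cap$ground_set])
  if (anyNA(x)) stop("scores contain NA", call. = FALSE)
  n <- length(x)
  ord <- order(x)                 # ascending; ties in stable positions
  total <- 0
  prev <- 0
  # mask of provisions with score >= x_(i): start with everything, peel off
  mask <- 2^n - 1L
  for (i in seq_len(n)) {
    xi <- x[ord[i]]
    total <- total + (xi - prev) * cap$mu[mask + 1L]
    prev <- xi
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, ord[i] - 1L)))
  }
  total
}

# Moebius representation ------------------------------------------------

#' Möbius representation of a capacity
#'
#' The Möbius transform re-expresses a capacity as signed masses on
#' coalitions: `m(A) = sum over B within A of (-1)^|A - B| mu(B)`, with the
#' inverse `mu(A) = sum over B within A of m(B)`. Masses sum to 1. In this
#' form the Choquet integral is `sum_B m(B) * min over i in B of x_i`, which
#' serves as an interchange/oracle form.
#'
#' @param cap A valid `welfare_capacity`.
#' @return An object of class `welfare_moebius` with fields `ground_set` and
#'   `m` (numeric, indexed like the capacity's `mu`).
#' @export
moebius_from_capacity <- function(cap) {
  stop_on_invalid(validate_capacity(cap), "capacity")
  n <- length(cap$ground_set)
  m <- numeric(2^n)
  for (a in 0:(2^n - 1L)) {
    acc <- 0
    for (b in 0:a) {
      if (bitwAnd(a, b) == b) {
        extra <- sum(bitwAnd(bitwXor(a, b), bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
        acc <- acc + (-1)^extra * cap$mu[b + 1L]
      }
    }
    m[a + 1L] <- acc
  }
  structure(list(ground_set = cap$ground_set, m = m),
            class = "welfare_moebius")
}

#' @rdname moebius_from_capacity
#' @param moebius A `welfare_moebius` object (or a list with `ground_set`
#'   and named masses `m`, keyed like [capacity()] subsets).
#' @return `capacity_from_moebius()` returns the induced `welfare_capacity`;
#'   an error is thrown if the induced set function is not a valid capacity
#'   (non-monotone or unnormalised).
#' @export
capacity_from_moebius <- function(moebius) {
  gs <- moebius$ground_set
  n <- length(gs)
  m <- moebius$m
  if (!is.null(names(m))) {
    dense <- numeric(2^n)
    names(dense) <- all_mask_keys(gs)
    for (k in names(m)) {
      ids <- strsplit(k, "+", fixed = TRUE)[[1]]
      ids <- ids[nzchar(ids)]
      key <- if (length(ids) == 0) "" else mask_key(mask_of(ids, gs), gs)
      dense[key] <- dense[key] + m[[k]]
    }
    m <- unname(dense)
  }
  if (length(m) != 2^n) stop("m must cover all subsets", call. = FALSE)
  mu <- numeric(2^n)
  for (a in 0:(2^n - 1L)) {
    b <- 0:a
    mu[a + 1L] <- sum(m[b[bitwAnd(a, b) == b] + 1L])
  }
  cap <- structure(list(ground_set = gs, mu = mu), class = "welfare_capacity")
  rep <- validate_capacity(cap)
  if (!is_valid(rep)) {
    stop("Möbius masses induce an invalid capacity: ",
         paste(rep$errors, collapse = "; "), call. = FALSE)
  }
  cap
}

#' Build a capacity from an importance ranking
#'
#' A documented default construction for domains whose expert-elicited
#' capacity is not available as configuration. Singleton measures follow
#' rank-sum weights (`n` provisions ranked most to least important get raw
#' weights `n, n-1, ..., 1`, normalised to sum 1). Every proper coalition
#' `A` is then shrunk below additivity:
#' `mu(A) = (1 - interaction) * sum of its singleton weights`, with
#' `mu(full set) = 1`. `interaction = 0` recovers the additive capacity
#' (Choquet = weighted mean); `interaction = 1` gives the unanimity capacity
#' (Choquet = min); intermediate values drop the aggregate below the
#' weighted mean, penalising unbalanced provision profiles.
#'
#' @param ranking Character vector: provision ids ordered most to least
#'   important; must be a permutation of the domain's provisions.
#' @param interaction Number in \[0, 1\]; strength of the sub-additive
#'   interaction (default 0.3).
#' @return A valid `welfare_capacity` on `ranking`'s elements (ground set in
#'   the given order).
#' @export
#' @examples
#' capacity_from_ranking(c("appropriate_feed", "appropriate_water"),
#'                       interaction = 0)  # mu(feed) = 2/3, mu(water) = 1/3
capacity_from_ranking <- function(ranking, interaction = 0.3) {
  ranking <- as.character(ranking)
  n <- length(ranking)
  if (n < 1L || anyDuplicated(ranking)) {
    stop("ranking must be a permutation of the domain's provisions",
         call. = FALSE)
  }
  if (!is.numeric(interaction) || length(interaction) != 1L ||
      is.na(interaction) || interaction < 0 || interaction > 1) {
    stop("interaction must be a number in [0, 1]", call. = FALSE)
  }
  w <- rev(seq_len(n)) / sum(seq_len(n))  # rank-sum weights, most important first
  mu <- numeric(2^n)
  for (a in 1:(2^n - 1L)) {
    members <- bitwAnd(a, bitwShiftL(1L, seq_len(n) - 1L)) != 0L
    mu[a + 1L] <- (1 - interaction) * sum(w[members])
  }
  mu[2^n] <- 1
  structure(list(ground_set = ranking, mu = mu), class = "welfare_capacity")
}
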