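# Independent oracles, deliberately implemented with different machinery
# than the package (combn-based subset enumeration instead of bitmasks).

# measure of a subset given by member positions (integer vector) in the
# capacity's ground set
oracle_mu <- function(cap, positions) {
  cap$mu[sum(2^(positions - 1)) + 1]
}

# Möbius mass of the coalition at `positions`, by direct inclusion-exclusion
# over every sub-coalition (enumerated via a logical grid)
oracle_moebius_mass <- function(cap, positions) {
  size <- length(positions)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), size))
  m <- 0
  for (r in seq_len(nrow(grid))) {
    S <- positions[unlist(grid[r, ])]
    m <- m + (-1)^(size - length(S)) * oracle_mu(cap, S)
  }
  m
}

# Choquet integral in Möbius form: sum over coalitions of mass * min score
oracle_choquet <- function(scores, cap) {
  gs <- cap$ground_set
  n <- length(gs)
  total <- 0
  for (size in seq_len(n)) {
    for (B in asplit(utils::combn(n, size), 2)) {
      total <- total + oracle_moebius_mass(cap, B) * min(scores[gs[B]])
    }
  }
  total
}

# brute-force monotonicity check of a tree: every single no->yes flip
count_decreasing_flips <- function(leaves) {
  bad <- 0L
  for (p in names(leaves)) {
    bits <- strsplit(p, "")[[1]]
    for (i in which(bits == "n")) {
      q <- bits
      q[i] <- "y"
      if (leaves[[paste(q, collapse = "")]] < leaves[[p]]) bad <- bad + 1L
    }
  }
  bad
}
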