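# Independent oracles, deliberately written without the package's encoding
# or walk code paths: genotypes are treated as integers 0..2^L-1 and all
# subset products are computed with bit arithmetic.

# Walsh-Hadamard transform of cell means by direct subset enumeration.
# `means` is named by genotype label in lexicographic order (binary counting).
# Returns coefficients named "" (intercept) then by subset of site indices
# ("1", "1,3", ...): theta_T = 2^-L * sum_g y_g * prod_{i in T} u_i(g).
brute_wht <- function(means) {
  L <- nchar(names(means)[1L])
  n <- 2L^L
  stopifnot(length(means) == n)
  # bit i (1-based, leftmost character) of genotype g
  bit <- function(g, i) bitwAnd(bitwShiftR(g, L - i), 1L)
  subsets <- list(integer(0))
  for (i in seq_len(L)) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, i)))
  }
  lex <- vapply(subsets, function(s)
    paste(formatC(s, width = 2, flag = "0"), collapse = ","), character(1L))
  subsets <- subsets[order(lengths(subsets), lex)]
  out <- vapply(subsets, function(T) {
    total <- 0
    for (g in 0:(n - 1L)) {
      prod_u <- 1
      for (i in T) prod_u <- prod_u * (2 * bit(g, i) - 1)
      total <- total + means[[g + 1L]] * prod_u
    }
    total / n
  }, numeric(1L))
  names(out) <- vapply(subsets, paste, character(1L), collapse = ",")
  out
}

# Exhaustive local-optimum enumeration by direct neighbor comparison.
brute_optima <- function(means) {
  L <- nchar(names(means)[1L])
  n <- 2L^L
  labels <- names(means)
  opt <- character(0)
  for (g in 0:(n - 1L)) {
    is_opt <- TRUE
    for (i in seq_len(L)) {
      nb <- bitwXor(g, bitwShiftL(1L, L - i))
      if (means[[nb + 1L]] >= means[[g + 1L]]) { is_opt <- FALSE; break }
    }
    if (is_opt) opt <- c(opt, labels[g + 1L])
  }
  opt
}

# A complete one-environment landscape with the given cell means and
# `reps` identical replicates (noiseless: spans are points).
means_landscape <- function(means, environment = "env", reps = 1L) {
  gs <- names(means)
  landscape_table(data.frame(
    genotype = rep(gs, each = reps),
    environment = environment,
    replicate = rep(seq_len(reps), times = length(gs)),
    activity = rep(unname(means), each = reps),
    stringsAsFactors = FALSE))
}

# Random positive noiseless landscape over L sites (activities span orders
# of magnitude, as in the assays this emulates).
random_means <- function(L) {
  gs <- all_genotypes(L)
  stats::setNames(10^stats::rnorm(length(gs), 1, 1), gs)
}

# The L=2 worked example: activities (00,10,01,11) = (0,1,1,4).
toy_l2 <- function() {
  landscape_table(data.frame(
    genotype = c("00", "10", "01", "11"),
    environment = "env", replicate = 1L,
    activity = c(0, 1, 1, 4), stringsAsFactors = FALSE))
}
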