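test_that("genotype encoding uses -1/+1 coordinates with product interactions", {
  expect_equal(unname(encode_genotype("00000", max_order = 1)), rep(-1, 5))
  e2 <- encode_genotype("11000", max_order = 2)
  expect_equal(e2[["72"]], 1)
  expect_equal(e2[["193"]], 1)
  expect_equal(e2[["72x193"]], 1)
  expect_equal(e2[["72x258"]], -1)
  expect_equal(e2[["193x258"]], -1)
  # full-order encoding of all genotypes at L=2 has orthogonal columns
  M <- t(sapply(all_genotypes(2), function(g) encode_genotype(g, 2)))
  M <- cbind(intercept = 1, M)
  expect_equal(crossprod(M), diag(4) * 4, ignore_attr = TRUE)
  expect_error(encode_genotype("11", max_order = 3), "max_order")
})

test_that("Hadamard environment coordinates have the stated geometry", {
  co <- encode_environments(metal_environments())
  expect_equal(dim(co), c(8, 7))
  expect_equal(unname(co["Ca", ]), rep(1, 7))  # first label: all ones
  G <- co %*% t(co)
  expect_equal(unname(diag(G)), rep(7, 8))
  expect_equal(unname(G[upper.tri(G)]), rep(-1, 28))
  expect_equal(unname(colSums(co)), rep(0, 7))
  # E=2 degenerates to the +/-1 genetic coding
  c2 <- encode_environments(c("a", "b"))
  expect_equal(unname(c2[, 1]), c(1, -1))
  # non-power-of-two falls back to sum-to-zero contrasts
  c3 <- encode_environments(c("a", "b", "c"))
  expect_equal(dim(c3), c(3, 2))
  expect_equal(unname(colSums(c3)), c(0, 0))
})

test_that("design matrices have the documented shape and orthogonality", {
  sim <- generate_study_mimic(seed = 3)
  tab <- sim$table
  d1 <- build_design(tab, design_spec(max_genetic_order = 1,
                                      include_environment = TRUE))
  expect_equal(ncol(d1$X), 1 + 5 + 7)
  d2 <- build_design(tab, design_spec(max_genetic_order = 2), environment = "Zn")
  expect_equal(ncol(d2$X), 1 + 5 + 10)
  d5 <- build_design(tab, design_spec(max_genetic_order = 5), environment = "Zn",
                     aggregate = "means")
  expect_equal(dim(d5$X), c(32, 32))
  # complete balanced factorial: orthogonal columns, zero-sum genetic columns
  ip <- crossprod(d5$X)
  expect_equal(unname(ip), diag(32) * 32, ignore_attr = TRUE)
  expect_equal(unname(colSums(d5$X[, -1])), rep(0, 31))
  # GxE columns appear for every (site, dimension) pair
  dg <- build_design(tab, design_spec(max_genetic_order = 1,
                                      include_environment = TRUE, gxe_order = 1))
  expect_equal(ncol(dg$X), 1 + 5 + 7 + 35)
  expect_true("72xE1" %in% colnames(dg$X))
  expect_true(all(dg$X[, -1] %in% c(-1, 1)))
})

test_that("the L=2 worked example is solved exactly", {
  fit <- fit_ols(build_design(toy_l2(),
                              design_spec(max_genetic_order = 2,
                                          transform = "identity")))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["intercept"]], 1.5)
  expect_equal(est[["s1"]], 1.0)
  expect_equal(est[["s2"]], 1.0)
  expect_equal(est[["s1xs2"]], 0.5)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$zero_residual)
})

test_that("full-order coefficients equal the brute-force Walsh transform", {
  withr::local_seed(11)
  for (L in 2:4) {
    means <- random_means(L)
    tab <- means_landscape(means)
    fit <- fit_ols(build_design(tab, design_spec(max_genetic_order = L,
                                                 transform = "identity"),
                                aggregate = "means"))
    oracle <- brute_wht(means)
    expect_equal(unname(fit$coefficients$estimate), unname(oracle),
                 tolerance = 1e-12)
  }
})

test_that("degenerate fits follow the stated conventions", {
  # additive noiseless landscape: all order>=2 coefficients are zero
  spec <- synthetic_spec(L = 3, environments = "e", replicates = 1,
                         genetic = c(s1 = 0.3, s2 = -0.2, s3 = 0.1),
                         site_labels = paste0("s", 1:3))
  sim <- generate_landscape(spec, seed = 1)
  fit <- fit_ols(build_design(sim$table, design_spec(max_genetic_order = 3)))
  cf <- fit$coefficients
  expect_equal(max(abs(cf$estimate[cf$order >= 2])), 0, tolerance = 1e-12)

  # constant response: R^2 defined as 0, non-intercept coefficients 0
  const <- means_landscape(setNames(rep(2, 4), all_genotypes(2)), reps = 2)
  fitc <- fit_ols(build_design(const, design_spec(max_genetic_order = 1,
                                                  transform = "identity")))
  expect_equal(fitc$r_squared, 0)
  expect_equal(max(abs(fitc$coefficients$estimate[-1])), 0)

  # rank deficiency (missing cell) names collinear terms
  missing <- means_landscape(random_means(2), reps = 2)
  missing <- landscape_table(missing[missing$genotype != "10", ])
  expect_error(fit_ols(build_design(missing, design_spec(max_genetic_order = 2,
                                                         transform = "identity"))),
               "collinear")
  expect_error(fit_ols(matrix(1, 2, 3), c(1, 2)), "underdetermined")
})

test_that("the intercept equals the grand mean on a balanced design", {
  sim <- generate_study_mimic(seed = 5)
  d <- build_design(sim$table, design_spec(max_genetic_order = 2), environment = "Co")
  fit <- fit_ols(d)
  expect_equal(fit$coefficients$estimate[1], mean(d$y))
})

test_that("nested comparison computes dRadj, LRT and flags exact fits", {
  tab <- means_landscape(random_means(3), reps = 3)
  f1 <- fit_ols(build_design(tab, design_spec(max_genetic_order = 1)))
  f2 <- fit_ols(build_design(tab, design_spec(max_genetic_order = 2)))
  cmp <- compare_nested(f1, f2)
  expect_equal(cmp$df, 3)
  expect_equal(cmp$lrt, 2 * (f2$log_likelihood - f1$log_likelihood))
  expect_equal(cmp$p_value, pchisq(cmp$lrt, 3, lower.tail = FALSE))
  expect_error(compare_nested(f2, f1), "not nested")
  expect_error(compare_nested(f1, f1), "not strictly nested")

  # zero-residual richer model: Inf sentinel with flag, not a bare number
  toy <- toy_l2()
  g1 <- fit_ols(build_design(toy, design_spec(max_genetic_order = 1,
                                              transform = "identity")))
  g2 <- fit_ols(build_design(toy, design_spec(max_genetic_order = 2,
                                              transform = "identity")))
  cz <- compare_nested(g1, g2)
  expect_true(cz$zero_residual)
  expect_identical(cz$lrt, Inf)
  expect_equal(cz$p_value, 0)
})

test_that("the order-2 LRT detects a clearly planted pairwise interaction", {
  withr::local_seed(42)
  sigma <- 0.2
  n <- 96
  planted <- 2 * 3 * sigma / sqrt(n)  # twice the detectability threshold
  hits <- 0
  n_seeds <- 150
  for (s in seq_len(n_seeds)) {
    spec <- synthetic_spec(L = 5, environments = "e", replicates = 3,
                           genetic = c("72" = 0.3, "258" = 0.4,
                                       "72x258" = planted),
                           noise_sigma = sigma)
    tab <- generate_landscape(spec, seed = 5000 + s)$table
    f1 <- fit_ols(build_design(tab, design_spec(max_genetic_order = 1)))
    f2 <- fit_ols(build_design(tab, design_spec(max_genetic_order = 2)))
    if (compare_nested(f1, f2)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("variance partition increments are orthogonal and order-stable", {
  # pure pairwise landscape: all variance lands at order 2
  spec <- synthetic_spec(L = 3, environments = "e", replicates = 1,
                         genetic = c("s1xs2" = 0.4),
                         site_labels = paste0("s", 1:3))
  tab <- generate_landscape(spec, seed = 1)$table
  vp <- variance_partition(tab, "e")
  expect_equal(vp$increment_pct, c(0, 100, 0), tolerance = 1e-9)
  expect_equal(vp$epistatic_total_pct, 100, tolerance = 1e-9)

  # additive landscape: everything at order 1
  spec <- synthetic_spec(L = 3, environments = "e", replicates = 1,
                         genetic = c(s1 = 0.3, s3 = 0.2),
                         site_labels = paste0("s", 1:3))
  tab <- generate_landscape(spec, seed = 1)$table
  vp <- variance_partition(tab, "e")
  expect_equal(vp$increment_pct, c(100, 0, 0), tolerance = 1e-9)

  # increments sum to the full-order cumulative R^2
  sim <- generate_study_mimic(seed = 9)
  vp <- variance_partition(sim$table, "Mg")
  expect_equal(sum(vp$increment_pct), vp$cumulative_pct[5], tolerance = 1e-10)
  expect_true(all(vp$increment_pct > -1e-10))

  # site relabeling permutes same-order terms but leaves the partition alone
  perm <- sim$table
  attr(perm, "site_labels") <- rev(landscape_sites(sim$table))
  vp_perm <- variance_partition(perm, "Mg")
  expect_equal(vp_perm$increment_pct, vp$increment_pct, tolerance = 1e-10)

  expect_error(variance_partition(landscape_table(
    sim$table[sim$table$genotype != "00011", ]), "Mg"), "missing")
})

test_that("environment effect magnitudes recover planted offsets", {
  offsets <- c(Ca = 0.5, Cd = -0.4, Co = 0.1, Cu = 0, Mg = 0.3,
               Mn = -0.2, Ni = -0.6, Zn = 0.9)
  spec <- synthetic_spec(L = 2, environments = names(offsets), replicates = 1,
                         genetic = c(s1 = 0.2), env_offsets = offsets,
                         site_labels = c("s1", "s2"))
  tab <- generate_landscape(spec, seed = 1)$table
  fit <- fit_ols(build_design(tab, design_spec(max_genetic_order = 0,
                                               include_environment = TRUE)))
  mags <- vapply(names(offsets), function(e)
    environment_effect_magnitude(fit, e), numeric(1))
  expect_equal(unname(mags), unname(offsets - mean(offsets)), tolerance = 1e-9)
  expect_equal(sum(mags), 0, tolerance = 1e-9)
  expect_error(environment_effect_magnitude(fit, "Pb"), "unknown environment")
})

test_that("adding pure noise columns does not inflate adjusted R^2 on average", {
  withr::local_seed(99)
  deltas <- replicate(300, {
    n <- 40
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    X1 <- cbind(intercept = 1, x = x)
    X2 <- cbind(X1, junk = rnorm(n))
    fit_ols(X2, y)$adj_r_squared - fit_ols(X1, y)$adj_r_squared
  })
  expect_lt(mean(deltas), 0.005)
})

test_that("coefficient RMSE scales as sigma/sqrt(n)", {
  withr::local_seed(123)
  sigma <- 0.2
  planted <- c("72" = 0.3, "193" = -0.2, "258" = 0.4, "258x271" = 0.15)
  for (reps in c(3L, 12L)) {
    n <- 32 * reps
    errs <- c()
    for (s in 1:40) {
      spec <- synthetic_spec(L = 5, environments = "e", replicates = reps,
                             genetic = planted, noise_sigma = sigma)
      tab <- generate_landscape(spec, seed = 300 + s)$table
      fit <- fit_ols(build_design(tab, design_spec(max_genetic_order = 5)))
      cf <- fit$coefficients
      theta <- setNames(rep(0, 31), cf$term[-1])
      theta[names(planted)] <- planted
      errs <- c(errs, cf$estimate[-1] - unname(theta))
    }
    rmse <- sqrt(mean(errs^2))
    expect_gt(rmse / (sigma / sqrt(n)), 0.8)
    expect_lt(rmse / (sigma / sqrt(n)), 1.2)
  }
})
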