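test_that("a perfect single-gene predictor dominates PLS1", {
  # few noise genes relative to regions: chance correlations contribute
  # about (p - 1)/n to the unexplained share, so keep p/n small
  sph <- make_parcel_sphere(200, seed = 1)
  set.seed(2)
  expr <- matrix(runif(200 * 8), 200, 8,
                 dimnames = list(sph$region_id, sprintf("g%02d", 1:8)))
  y <- setNames(scale(expr[, "g05"])[, 1], rownames(expr))
  fit <- pls_fit(expr, y, 3)
  expect_equal(which.max(abs(fit$weights[, 1])), 5L, ignore_attr = TRUE)
  expect_gt(fit$variance_explained[1], 0.95)
  expect_gt(cor(fit$region_scores[, 1], y), 0)   # sign convention
})

test_that("duplicated gene columns split PLS1 weight symmetrically", {
  sph <- make_parcel_sphere(40, seed = 3)
  set.seed(4)
  expr <- matrix(runif(40 * 6), 40, 6,
                 dimnames = list(sph$region_id, sprintf("g%02d", 1:6)))
  expr[, 6] <- expr[, 1]
  y <- setNames(rnorm(40), rownames(expr))
  fit <- pls_fit(expr, y, 2)
  expect_lt(abs(fit$weights[1, 1] - fit$weights[6, 1]), 1e-10)
})

test_that("variance explained is non-increasing and the fit deterministic", {
  sph <- make_parcel_sphere(50, seed = 5)
  set.seed(6)
  expr <- matrix(runif(50 * 20), 50, 20,
                 dimnames = list(sph$region_id, sprintf("g%02d", 1:20)))
  y <- setNames(rnorm(50), rownames(expr))
  fit <- pls_fit(expr, y, 4)
  expect_gte(fit$variance_explained[1], max(fit$variance_explained[-1]))
  expect_true(all(fit$variance_explained >= 0 & fit$variance_explained <= 1))
  expect_identical(pls_fit(expr, y, 4)$weights, fit$weights)
  expect_error(pls_fit(expr, y, 25), "rank")
})

test_that("PLS1 weights agree with the cross-covariance singular-vector oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    sph <- make_parcel_sphere(20, seed = seed)
    expr <- matrix(runif(20 * 10), 20, 10,
                   dimnames = list(sph$region_id, sprintf("g%02d", 1:10)))
    y <- setNames(rnorm(20), rownames(expr))
    fit <- pls_fit(expr, y, 1)
    # oracle: leading singular vector of the cross-covariance between the
    # standardised predictors and response (direction is invariant to the
    # sample-vs-population SD convention, which rescales all columns alike)
    sv <- svd(crossprod(scale(expr), scale(y[rownames(expr)])))
    expect_gt(abs(cor(fit$weights[, 1], sv$u[, 1])), 0.999)
  }
})

test_that("component significance hits the permutation bound for planted signal", {
  # moderate smoothness: for near-linear maps, rotations about the map's
  # own axis leave it invariant, and such spins tie with the observed fit
  sph <- make_parcel_sphere(120, seed = 7)
  spins <- build_spins(sph, 400, seed = 8)
  tmap <- make_smooth_map(sph, 0.5, seed = 9)
  expr <- make_expression(sph, 40,
                          planted = list(hub = list(map = tmap, effect = 1)),
                          seed = 10)
  fit <- pls_fit(expr, tmap, 2)
  res <- pls_component_significance(fit, expr, tmap, spins)
  expect_equal(res$p, 1 / 401)
  expect_gte(res$p, 1 / (spins$n_permutations + 1))
  expect_length(res$null, 400)
})

test_that("sign-flipping the response flips weights but not their magnitudes", {
  sph <- make_parcel_sphere(60, seed = 11)
  spins <- build_spins(sph, 200, seed = 12)
  tmap <- make_smooth_map(sph, 0.8, seed = 13)
  expr <- make_expression(sph, 25, seed = 14)
  gw_pos <- gene_weight_significance(expr, tmap, spins)
  gw_neg <- gene_weight_significance(expr, -tmap, spins)
  expect_equal(gw_neg$weight, -gw_pos$weight, tolerance = 1e-12)
  expect_equal(gw_neg$p, gw_pos$p)
  expect_equal(gw_neg$q, gw_pos$q)
})

test_that("hypergeometric overlap matches a brute-force combinatorial oracle", {
  brute_tail <- function(N, nA, nB, ov) {
    ks <- ov:min(nA, nB)
    sum(choose(nA, ks) * choose(N - nA, nB - ks)) / choose(N, nB)
  }
  universe <- sprintf("t%02d", 1:20)
  for (seed in 1:20) {
    set.seed(seed)
    nA <- sample(1:15, 1); nB <- sample(1:15, 1)
    A <- sample(universe, nA); B <- sample(universe, nB)
    got <- term_overlap(A, B, universe)
    expect_equal(got$p, brute_tail(20, nA, nB, got$overlap), tolerance = 1e-12)
  }
  # identities
  expect_equal(term_overlap(universe, universe, universe)$p, 1)
  expect_equal(term_overlap(universe[1:5], universe[6:10], universe)$p, 1)
  expect_error(term_overlap(c("x"), universe[1:3], universe), "subsets")
})

test_that("rank similarity follows hand-computed Spearman on shared labels", {
  expect_equal(rank_similarity(c("x", "y", "z"), c("x", "y", "z")), 1)
  expect_equal(rank_similarity(c("x", "y", "z"), c("z", "y", "x")), -1)
  expect_equal(rank_similarity(c("x", "y", "z"), c("x", "z", "y")), 0.5)
  # restriction to the intersection
  expect_equal(rank_similarity(c("x", "y", "z", "w"), c("q", "x", "y", "z")), 1)
  expect_error(rank_similarity(c("x", "y"), c("x", "y")), "3 shared")
})
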