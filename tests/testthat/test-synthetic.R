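test_that("parcel sphere is a deterministic mirrored unit-sphere lattice", {
  sph <- make_parcel_sphere(4, seed = 1)
  expect_equal(nrow(sph), 4)
  expect_equal(table(sph$hemisphere)[["L"]], 2)

  sph <- make_parcel_sphere(200, seed = 5)
  r <- sqrt(sph$x^2 + sph$y^2 + sph$z^2)
  expect_lt(max(abs(r - 1)), 1e-12)
  left <- sph[sph$hemisphere == "L", ]
  right <- sph[sph$hemisphere == "R", ]
  expect_equal(right$x, -left$x)
  expect_equal(right$y, left$y)
  expect_equal(right$z, left$z)

  expect_identical(make_parcel_sphere(200, seed = 5), sph)
  expect_false(identical(make_parcel_sphere(200, seed = 6)$x, sph$x))
  expect_error(make_parcel_sphere(7, seed = 1), "even")
})

test_that("templates respect modality constraints and the kernel decays", {
  st <- make_template(40, "structural", seed = 2)
  v <- st$matrix$values
  expect_true(all(v >= 0))
  expect_true(all(diag(v) == 0))
  expect_identical(v, t(v))

  ft <- make_template(40, "functional", seed = 2)
  fv <- ft$matrix$values
  expect_true(all(fv >= -1 & fv <= 1))
  expect_true(all(diag(fv) == 1))

  # noise-free kernel: nearly equal latent coords beat maximally distant ones
  lat <- st$latent
  K <- latent_kernel(lat)
  near <- order(abs(outer(lat, lat, "-")) + diag(Inf, length(lat)))[1]
  far <- which.max(abs(outer(lat, lat, "-")))
  expect_gt(K[near], K[far])
  # monotone decay overall
  expect_equal(K[which.min(abs(outer(lat, lat, "-")) + diag(Inf, length(lat)))],
               max(K - diag(1, length(lat))))
})

test_that("effect_spec enforces the regime invariants", {
  expect_error(effect_spec("expansion", gamma = 0.9), "gamma > 1")
  expect_error(effect_spec("contraction", gamma = 1.2), "gamma < 1")
  expect_error(effect_spec("reorganisation", reorg_fraction = 0), "reorg_fraction")
  expect_error(effect_spec("reorganisation", reorg_fraction = 0.2, gamma = 1.1),
               "gamma = 1")
  expect_equal(effect_spec("expansion")$gamma, 1.3)
  expect_equal(effect_spec("contraction")$gamma, 0.8)
})

test_that("noise-free identity regime reproduces the template kernel mean", {
  st <- make_template(30, "structural", seed = 4)
  eff <- effect_spec("none", noise_sd = 0, latent_jitter = 0)
  sub <- make_subject(st, eff, seed = 9)
  expect_equal(attr(sub, "latent"), st$latent)
  # same latent => identical expected (kernel) weights
  expect_identical(latent_kernel(attr(sub, "latent")), latent_kernel(st$latent))
})

test_that("reorganisation permutes exactly the requested number of regions", {
  st <- make_template(50, "structural", seed = 4)
  eff <- effect_spec("reorganisation", reorg_fraction = 0.2,
                     noise_sd = 0, latent_jitter = 0)
  sub <- make_subject(st, eff, seed = 11)
  moved <- sum(attr(sub, "latent") != st$latent)
  expect_equal(moved, ceiling(0.2 * 50))
})

test_that("expansion increases the spread of the recovered first gradient", {
  st <- make_template(100, "structural", seed = 6)
  cfg <- quick_config()
  spread1 <- function(eff, seeds) {
    vapply(seeds, function(s) {
      g <- subject_gradients(make_subject(st, eff, seed = s), cfg)
      sd(g$scores[, "G1"])
    }, numeric(1))
  }
  base <- spread1(effect_spec("none"), 1:25)
  wide <- spread1(effect_spec("expansion", gamma = 1.3), 1:25)
  narrow <- spread1(effect_spec("contraction", gamma = 0.7), 1:25)
  expect_gt(mean(wide), mean(base))
  expect_lt(mean(narrow), mean(base))
})

test_that("cohorts at the study sizes are reproducible and correctly coupled", {
  sim <- make_cohort(seed = 12, n_regions = 24,
                     group_sizes = c(HC = 23, "PD-NC" = 46, LBD = 62))
  expect_equal(nrow(sim$cohort), 131)
  expect_equal(as.vector(table(sim$cohort$group)), c(23, 46, 62))
  expect_equal(length(sim$matrices), 131)

  # byte-identical cohort table for the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_cohort(sim$cohort, f1)
  write_cohort(make_cohort(seed = 12, n_regions = 24,
                           group_sizes = c(HC = 23, "PD-NC" = 46, LBD = 62))$cohort,
               f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(make_cohort(group_sizes = c(HC = 0, LBD = 5)), "empty group")
})

test_that("zero coupling yields near-zero empirical rank correlation", {
  # the 95% sampling band for a single Spearman estimate at n = 62 is wide
  # (about +/- 0.25 around 0), so the check is on the average over replicates
  rhos <- vapply(1:20, function(s) {
    sim <- make_cohort(group_sizes = c(LBD = 62),
                       effects = list(LBD = effect_spec("expansion")),
                       coupling_rho = 0, seed = 100 + s, n_regions = 24)
    cor(sim$cohort$cognitive_score, sim$cohort$planted_deviation,
        method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.2)
})

test_that("smooth maps are z-scored, decorrelate as smoothness vanishes, and are independent across seeds", {
  sph <- make_parcel_sphere(200, seed = 3)
  m <- make_smooth_map(sph, 0.6, seed = 21)
  expect_lt(abs(mean(m)), 1e-12)
  expect_lt(abs(sd(m) - 1), 1e-12)

  # neighbour correlation: smooth maps similar at nearby parcels, rough not
  # (neighbours taken within hemisphere: the two hemispheres live on
  # separate registration spheres)
  X <- as.matrix(sph[, c("x", "y", "z")])
  gd <- acos(pmin(pmax(tcrossprod(X), -1), 1))
  gd[outer(sph$hemisphere, sph$hemisphere, "!=")] <- Inf
  diag(gd) <- Inf
  nb <- apply(gd, 1, which.min)
  nbcor_smooth <- mean(vapply(1:15, function(s) {
    v <- make_smooth_map(sph, 0.6, seed = s); cor(v, v[nb])
  }, numeric(1)))
  nbcor_rough <- mean(vapply(1:15, function(s) {
    v <- make_smooth_map(sph, 1e-4, seed = s, homotopic = FALSE)
    cor(v, v[nb])
  }, numeric(1)))
  expect_gt(nbcor_smooth, 0.5)
  expect_lt(abs(nbcor_rough), 0.15)

  # independent seeds give uncorrelated maps on average
  rhos <- vapply(1:15, function(s)
    cor(make_smooth_map(sph, 0.6, seed = s),
        make_smooth_map(sph, 0.6, seed = 1000 + s), method = "spearman"),
    numeric(1))
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("expression tables stay in [0,1] and honour planted effects", {
  sph <- make_parcel_sphere(200, seed = 3)
  target <- make_smooth_map(sph, 0.6, seed = 40)
  expr <- make_expression(sph, 30,
                          planted = list(RORB = list(map = target, effect = 1)),
                          seed = 41)
  expect_true(all(expr >= 0 & expr <= 1))
  expect_equal(colnames(expr)[1], "RORB")
  # effect 1: gene column is a monotone transform of the target
  expect_equal(cor(expr[, "RORB"], target[rownames(expr)], method = "spearman"), 1)

  # effect 0: no systematic association with the target
  expr0 <- make_expression(sph, 200,
                           planted = list(g = list(map = target, effect = 0)),
                           seed = 42)
  rhos <- abs(apply(expr0, 2, cor, y = target[rownames(expr0)],
                    method = "spearman"))
  expect_lt(median(rhos), 0.1)
  expect_error(make_expression(sph, 1,
                               planted = list(a = list(map = target, effect = 1),
                                              b = list(map = target, effect = 1))),
               "planted")
})
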