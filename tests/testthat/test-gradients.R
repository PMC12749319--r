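test_that("row sparsification zeroes the smallest entries with a stable tie rule", {
  m <- matrix(c(5, 1, 4, 2, 3,
                1, 2, 3, 4, 5,
                2, 2, 2, 2, 2), 3, 5, byrow = TRUE)
  expect_identical(sparsify_rows(m, 0), m)
  out <- sparsify_rows(m, 0.6)   # floor(0.6 * 5) = 3 dropped per row
  expect_equal(out[1, ], c(5, 0, 4, 0, 0))
  expect_equal(out[2, ], c(0, 0, 0, 4, 5))
  # all-tied row at sparsity 0.8: exactly one survivor, the largest column
  out2 <- sparsify_rows(m, 0.8)
  expect_equal(which(out2[3, ] != 0), 5L)
  expect_error(sparsify_rows(m, 1), "sparsity")
})

test_that("normalised angle returns 1 / 0.5 / 0 for identical / orthogonal / antiparallel rows", {
  m <- rbind(c(1, 2, 0, 0),
             c(2, 4, 0, 0),    # parallel to row 1
             c(0, 0, 3, 0),    # orthogonal to rows 1-2
             c(-1, -2, 0, 0))  # antiparallel to row 1
  A <- normalized_angle(m)
  expect_equal(A[1, 2], 1, tolerance = 1e-12)
  expect_equal(A[1, 3], 0.5, tolerance = 1e-12)
  expect_equal(A[1, 4], 0, tolerance = 1e-12)
  expect_true(all(diag(A) == 1))
  expect_identical(A, t(A))
  expect_error(normalized_angle(rbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("diffusion embedding separates blocks and matches the dense Markov oracle", {
  # two-block affinity: within 1, between epsilon
  n <- 20
  A <- matrix(1e-3, n, n)
  A[1:10, 1:10] <- 1
  A[11:20, 11:20] <- 1
  g <- diffusion_embed(A, 3)
  s1 <- sign(g$scores[1:10, 1])
  s2 <- sign(g$scores[11:20, 1])
  expect_true(all(s1 == s1[1]))
  expect_true(all(s2 == s2[1]))
  expect_true(s1[1] != s2[1])

  # oracle equivalence on random affinities
  for (seed in 1:5) {
    A <- random_affinity(30, seed)
    g <- diffusion_embed(A, 5)
    orc <- dense_markov_oracle(A, 5)
    expect_equal(g$eigenvalues, orc$values, tolerance = 1e-8)
    for (k in 1:5)
      expect_gt(abs(cor(g$scores[, k], orc$vectors[, k])), 1 - 1e-8)
  }
})

test_that("embedding is equivariant under region relabelling and flags disconnection", {
  A <- random_affinity(25, 7)
  g <- diffusion_embed(A, 4)
  set.seed(8)
  perm <- sample(25)
  gp <- diffusion_embed(A[perm, perm], 4)
  expect_equal(gp$scores, g$scores[perm, ], tolerance = 1e-8,
               ignore_attr = TRUE)

  # trivial (discarded) eigenvalue is 1 within 1e-10
  expect_lt(abs(g$lambda0 - 1), 1e-10)

  disc <- matrix(0, 10, 10)
  disc[1:5, 1:5] <- 1; disc[6:10, 6:10] <- 1
  expect_error(diffusion_embed(disc, 2), "disconnected")
})

test_that("eigenvalues are non-increasing and the sign convention is deterministic", {
  A <- random_affinity(30, 11)
  g <- diffusion_embed(A, 6)
  expect_true(all(diff(g$eigenvalues) <= 1e-12))
  for (k in seq_len(ncol(g$scores)))
    expect_gt(g$scores[which.max(abs(g$scores[, k])), k], 0)
  expect_identical(diffusion_embed(A, 6)$scores, g$scores)
})

test_that("Procrustes alignment recovers rotated templates and preserves norms", {
  A <- random_affinity(30, 13)
  tmpl <- diffusion_embed(A, 5)
  expect_equal(procrustes_align(tmpl, tmpl)$scores, tmpl$scores,
               tolerance = 1e-10)
  set.seed(14)
  for (i in 1:10) {
    R0 <- random_orthogonal(5)
    rotated <- tmpl
    rotated$scores <- tmpl$scores %*% R0
    aligned <- procrustes_align(rotated, tmpl)
    expect_lt(max(abs(aligned$scores - tmpl$scores)), 1e-8)
    expect_true(aligned$aligned)
    expect_equal(norm(aligned$scores, "F"), norm(rotated$scores, "F"),
                 tolerance = 1e-12)
  }
  bad <- tmpl; bad$scores <- bad$scores[, 1:3]
  expect_error(procrustes_align(bad, tmpl), "dimension mismatch")
})

test_that("fusion concatenates norm-matched blocks and leaves cosine geometry intact", {
  st <- make_template(20, "structural", seed = 15)
  ft <- make_template(20, "functional", seed = 16)
  ft$matrix$region_ids <- st$matrix$region_ids
  fused <- fuse(st$matrix, ft$matrix)
  expect_equal(ncol(fused$values), 40)
  expect_equal(fused$modality, "fused")
  n1 <- norm(fused$values[, 1:20], "F")
  n2 <- norm(fused$values[, 21:40], "F")
  expect_equal(n1 / n2, 1, tolerance = 1e-12)

  # fusing a matrix with itself does not change the normalised-angle kernel
  self_fused <- fuse(st$matrix, st$matrix)
  expect_equal(normalized_angle(self_fused), normalized_angle(st$matrix),
               tolerance = 1e-12)
  other <- make_template(20, "functional", seed = 1)$matrix
  other$region_ids <- paste0("x", other$region_ids)
  expect_error(fuse(st$matrix, other), "region_id mismatch")
})

test_that("group templates average controls and track the planted latent axis", {
  st <- make_template(40, "structural", seed = 17)
  cfg <- quick_config()
  single <- group_template(list(st$matrix), cfg)
  expect_equal(single$scores, subject_gradients(st$matrix, cfg)$scores)
  dup <- group_template(list(st$matrix, st$matrix, st$matrix), cfg)
  expect_equal(dup$scores, single$scores)

  # 23 simulated controls: template G1 recovers the planted latent gradient
  # (100 regions: at much smaller parcellations the top two eigenvalues
  # come close to degenerate and the latent axis can land on G2)
  st2 <- make_template(100, "structural", seed = 18)
  controls <- lapply(1:23, function(s)
    make_subject(st2, effect_spec("none", noise_sd = 0.05, latent_jitter = 0.05),
                 seed = s))
  tmpl <- group_template(controls, cfg)
  expect_gt(abs(cor(tmpl$scores[, "G1"], st2$latent, method = "spearman")), 0.9)
})

test_that("the full pipeline is deterministic given input and config", {
  st <- make_template(30, "structural", seed = 19)
  cfg <- quick_config()
  expect_identical(subject_gradients(st$matrix, cfg)$scores,
                   subject_gradients(st$matrix, cfg)$scores)
})
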