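test_that("farthest-point sampling is greedy max-min with seeded start", {
  pts <- cbind(0:9, 0, 0)
  g2 <- farthest_point_sample(pts, 2, seed = 1)
  # brute force: whatever the start, the second point maximizes min-dist
  d <- abs(pts[, 1] - pts[g2$indices[1], 1])
  expect_equal(g2$indices[2], which.max(d))
  expect_setequal(farthest_point_sample(pts, 10, seed = 3)$indices, 1:10)
  expect_identical(farthest_point_sample(pts, 4, seed = 5)$indices,
                   farthest_point_sample(pts, 4, seed = 5)$indices)
  expect_error(farthest_point_sample(pts, 11),
               class = "defectometer_shape_error")
  # colinear 0..9 starting at the left end selects the right end
  set.seed(1)
  starts <- vapply(1:20, function(s) {
    farthest_point_sample(pts, 2, seed = s)$indices[1]
  }, integer(1))
  expect_gt(length(unique(starts)), 1)     # the start really is random
})

test_that("KDE at the mode of a standard 3-D Gaussian is near analytic", {
  set.seed(10)
  X <- matrix(rnorm(10000 * 3), 10000, 3)
  grid <- farthest_point_sample(X, 400, seed = 0)
  dens <- kde_density(X, grid)
  expect_true(all(is.finite(dens) & dens > 0))
  peak <- (2 * pi)^(-3 / 2)
  expect_lt(abs(max(dens) - peak) / peak, 0.2)
})

test_that("KDE respects mirror symmetry of the dataset", {
  set.seed(3)
  half <- matrix(rnorm(2000 * 3), 2000, 3)
  X <- rbind(half, half * cbind(rep(-1, 2000), 1, 1))   # mirror in x
  gp <- rbind(c(0.7, 0.2, -0.1), c(-0.7, 0.2, -0.1),
              c(1.4, -0.5, 0.3), c(-1.4, -0.5, 0.3))
  dens <- kde_density(X, gp)
  expect_equal(dens[1], dens[2], tolerance = 0.02)
  expect_equal(dens[3], dens[4], tolerance = 0.02)
})

test_that("mode seeking finds the planted number of density maxima", {
  # unimodal
  b1 <- gaussian_blobs(matrix(0, 1, 3), 1500, seed = 21)
  cp1 <- cluster_pass_public(b1$points, 150, seed = 1)
  expect_equal(max(cp1$grid_labels), 1)

  # two blobs, 10 sigma apart
  b2 <- gaussian_blobs(rbind(c(0, 0, 0), c(10, 0, 0)), 800, seed = 22)
  cp2 <- cluster_pass_public(b2$points, 160, seed = 1)
  expect_equal(max(cp2$grid_labels), 2)
  modes_xyz <- cp2$grid$points[cp2$modes, , drop = FALSE]
  expect_equal(sort(round(modes_xyz[, 1] / 10)), c(0, 1))  # near the means

  # three blobs
  b3 <- gaussian_blobs(rbind(c(0, 0, 0), c(12, 0, 0), c(0, 12, 0)),
                       600, seed = 23)
  cp3 <- cluster_pass_public(b3$points, 180, seed = 1)
  expect_equal(max(cp3$grid_labels), 3)
  expect_true(all(cp3$grid_labels %in% 1:3))   # labels partition the grid
})

test_that("point assignment recovers planted mixtures and is equivariant", {
  b <- gaussian_blobs(rbind(c(0, 0, 0), c(10, 0, 0)), 800, seed = 31)
  cp <- cluster_pass_public(b$points, 160, seed = 2)
  expect_gte(adjusted_rand(cp$point_labels, b$labels), 0.9)
  # a grid point inherits its own label
  gi <- cp$grid$indices[5]
  expect_equal(cp$point_labels[gi], cp$grid_labels[5])
  # permuting dataset rows permutes labels identically
  perm <- sample(nrow(b$points))
  lab_perm <- assign_microstates(b$points[perm, ], cp$grid, cp$grid_labels)
  expect_identical(lab_perm, cp$point_labels[perm])
})

test_that("bootstrap stability separates well-separated blobs", {
  b <- gaussian_blobs(rbind(c(0, 0, 0), c(10, 0, 0)), 600, seed = 41)
  cp <- cluster_pass_public(b$points, 120, seed = 3)
  expect_equal(max(cp$grid_labels), 2)
  bs <- bootstrap_stability(b$points, cp$point_labels, 120, n_boot = 15,
                            seed = 3)
  expect_equal(diag(bs$stability), c(1, 1), ignore_attr = TRUE)
  expect_lt(max(bs$stability[upper.tri(bs$stability)]), 0.05)
  expect_true(isSymmetric(bs$stability))
  bs2 <- bootstrap_stability(b$points, cp$point_labels, 120, n_boot = 15,
                             seed = 3)
  expect_identical(bs$stability, bs2$stability)   # seeded determinism
})

test_that("macrocluster cuts are deterministic and cover edge cases", {
  b <- gaussian_blobs(rbind(c(0, 0, 0), c(12, 0, 0), c(0, 12, 0)),
                      500, seed = 51)
  fit <- pamm(b$points, n_grid = 150, K = 3, n_boot = 10, seed = 4)
  C <- fit$n_micro
  expect_identical(cut_macroclusters(fit$merge_tree, C), seq_len(C))
  expect_equal(unique(cut_macroclusters(fit$merge_tree, 1)), 1L)
  expect_error(cut_macroclusters(fit$merge_tree, C + 1),
               class = "defectometer_shape_error")
  expect_gte(adjusted_rand(fit$point_macro, b$labels), 0.9)
})

test_that("clustering is invariant under row shuffling up to relabelling", {
  b <- gaussian_blobs(rbind(c(0, 0, 0), c(12, 0, 0), c(0, 12, 0)),
                      400, seed = 61)
  f1 <- pamm(b$points, n_grid = 120, n_boot = 0, seed = 5)
  set.seed(62)
  perm <- sample(nrow(b$points))
  f2 <- pamm(b$points[perm, ], n_grid = 120, n_boot = 0, seed = 5)
  expect_equal(adjusted_rand(f2$point_labels, f1$point_labels[perm]), 1)
})

test_that("pamm fit exposes tidy accessors and settings", {
  b <- gaussian_blobs(rbind(c(0, 0, 0), c(10, 0, 0)), 300, seed = 71)
  fit <- pamm(b$points, n_grid = 100, K = 2, n_boot = 8, seed = 6)
  td <- tidy(fit)
  expect_equal(nrow(td), 600)
  expect_true(all(td$macro %in% 1:2))
  gl <- glance(fit)
  expect_equal(gl$n_points, 600)
  expect_equal(gl$n_boot, 8)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_micro_newick(fit, f)
  phy <- ape::read.tree(f)
  expect_equal(length(phy$tip.label), fit$n_micro)
})
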