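test_that("extended XYZ frames parse with box, time and unit conversion", {
  txt <- c("4",
           'Lattice="100 0 0 0 100 0 0 0 120" Time=0.0 pbc="T T T"',
           "CG 1.0 2.0 3.0", "CG 4.0 5.0 6.0",
           "CG 7.0 8.0 9.0", "CG 1.5 2.5 3.5",
           "4",
           'Lattice="100 0 0 0 100 0 0 0 120" Time=1.0 pbc="T T T"',
           "CG 1.1 2.1 3.1", "CG 4.1 5.1 6.1",
           "CG 7.1 8.1 9.1", "CG 1.6 2.6 3.6")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(txt, f)
  traj <- read_trajectory(f)               # default unit: Angstrom
  expect_equal(dim(traj), c(4L, 3L, 2L))
  expect_equal(traj$box$lengths, c(10, 10, 12))   # converted to nm
  expect_equal(traj$coords[1, , 1], c(0.1, 0.2, 0.3))
  expect_equal(traj$times, c(0, 1))
})

test_that("malformed XYZ input fails with informative errors", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", 'Lattice="10 0 0 0 10 0 0 0 10"',
               "CG 0 0 0", "CG 1 1 1",
               "3", 'Lattice="10 0 0 0 10 0 0 0 10"',
               "CG 0 0 0", "CG 1 1 1", "CG 2 2 2"), f)
  expect_error(read_trajectory(f), class = "defectometer_shape_error")

  writeLines(c("1", "no lattice here", "CG 0 0 0"), f)
  expect_error(read_trajectory(f), class = "defectometer_format_error")

  writeLines(c("1", 'Lattice="10 1 0 0 10 0 0 0 10"', "CG 0 0 0"), f)
  expect_error(read_trajectory(f), class = "defectometer_format_error")

  writeLines(c("1", 'Lattice="10 0 0 0 10 0 0 0 10"', "CG 0 zzz 0"), f)
  expect_error(read_trajectory(f), class = "defectometer_parse_error")
})

test_that("write/read round trip preserves coordinates and box", {
  set.seed(3)
  coords <- array(runif(5 * 3 * 4, 0, 8), dim = c(5, 3, 4))
  traj <- cg_trajectory(coords, cg_box(c(8.123456, 9, 10)),
                        system_id = "rt", sampling_interval = 0.5)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, f, unit = "nm")
  back <- read_trajectory(f, unit = "nm")
  expect_lt(max(abs(back$coords - traj$coords)), 1e-6)
  expect_equal(back$box$lengths, round(traj$box$lengths, 6))
  expect_equal(dim(back)[3], 4L)

  g <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(traj, g)
  back2 <- read_trajectory(g)
  expect_lt(max(abs(back2$coords - traj$coords)), 5e-4 + 1e-12)
  expect_equal(back2$box$lengths, traj$box$lengths, tolerance = 1e-6)
})

test_that("trajectory invariants are enforced at construction", {
  expect_error(cg_trajectory(array(1, c(0, 3, 1)), big_box()),
               class = "defectometer_shape_error")
  expect_error(cg_trajectory(array(Inf, c(2, 3, 1)), big_box()),
               class = "defectometer_shape_error")
  expect_error(cg_trajectory(array(1, c(2, 3, 2)), big_box(),
                             times = c(1, 0)),
               class = "defectometer_shape_error")
  expect_error(cg_box(c(-1, 2, 3)), class = "defectometer_box_error")
})

test_that("minimum-image components lie in (-L/2, L/2] on periodic axes", {
  box <- cg_box(c(10, 7, 4), periodic = c(TRUE, TRUE, FALSE))
  set.seed(11)
  d <- matrix(runif(300, -40, 40), 100, 3)
  m <- minimum_image(d, box)
  for (ax in 1:2) {
    L <- box$lengths[ax]
    expect_true(all(m[, ax] > -L / 2 & m[, ax] <= L / 2))
    # same point modulo the box
    expect_equal((m[, ax] - d[, ax]) %% L, rep(0, 100), tolerance = 1e-9)
  }
  expect_equal(m[, 3], d[, 3])             # non-periodic axis untouched
})

test_that("centers of geometry unwrap across the periodic boundary", {
  box <- cg_box(c(10, 10, 10))
  raw <- rbind(c(5, 5, 9.9), c(5, 5, 0.1))
  ctr <- compute_centers(raw, box, list(c(1, 2)))
  expect_equal(ctr[1, 3], 0, tolerance = 1e-9)   # 10.0 wraps to 0.0

  raw2 <- rbind(c(1, 1, 0), c(1, 1, 1), c(1, 1, 2))
  expect_equal(compute_centers(raw2, box, list(1:3))[1, ], c(1, 1, 1))
  # single-bead group: the bead itself
  expect_equal(compute_centers(raw2, box, list(2))[1, ], c(1, 1, 1))
})

test_that("center computation is translation-equivariant modulo the box", {
  box <- cg_box(c(10, 10, 10))
  set.seed(5)
  raw <- matrix(runif(18, 0, 3), 6, 3)
  sel <- list(1:3, 4:6)
  v <- c(4.7, 8.9, 2.2)
  c0 <- compute_centers(raw, box, sel)
  c1 <- compute_centers(sweep(raw, 2, v, "+") %% 10, box, sel)
  expect_equal((c1 - c0 - rep(v, each = 2)) %% 10, matrix(0, 2, 3),
               tolerance = 1e-9)
})

test_that("invalid selections are rejected", {
  box <- cg_box(c(10, 10, 10))
  raw <- matrix(runif(9), 3, 3)
  expect_error(compute_centers(raw, box, list(c(1, 5))),
               class = "defectometer_selection_error")
  expect_error(compute_centers(raw, box, list(1:2, 2:3)),
               class = "defectometer_selection_error")
  wide <- rbind(c(0, 0, 0), c(4.9, 4.9, 4.9))
  expect_error(compute_centers(wide, box, list(1:2)),
               class = "defectometer_ambiguity_error")
})
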