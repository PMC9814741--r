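test_that("a noiseless defect-free fiber is a perfect stack", {
  spec <- synthetic_spec("fiber", n_monomers = 40, n_frames = 2,
                         state_fractions = c(1, 0, 0), thermal_noise = 0,
                         seed = 1)
  asm <- gen_fiber(spec)
  z <- asm$trajectory$coords[, 3, 1]
  dz <- diff(z)
  expect_equal(dz, rep(spec$geometry$spacing, 39), tolerance = 1e-12)
  # stack crosses the periodic boundary: wrap-around gap equals spacing too
  Lz <- asm$trajectory$box$lengths[3]
  expect_equal(Lz - z[40] + z[1], spec$geometry$spacing, tolerance = 1e-12)
  expect_true(all(asm$labels == 1L))
})

test_that("planted fractions apportion by largest remainder", {
  spec <- synthetic_spec("fiber", n_monomers = 100, n_frames = 1,
                         state_fractions = c(0.6, 0.3, 0.1), seed = 3)
  asm <- gen_fiber(spec)
  expect_equal(as.vector(table(factor(asm$labels[, 1], levels = 1:3))),
               c(60, 30, 10))
  # odd splits round deterministically
  expect_equal(defectometer:::largest_remainder(c(0.85, 0.10, 0.05), 201),
               c(171L, 20L, 10L))
})

test_that("noiseless planar lattices have the exact lattice constant", {
  spec <- synthetic_spec("planar", n_monomers = 64, n_frames = 1,
                         thermal_noise = 0, seed = 2)
  asm <- gen_planar(spec)
  n <- dim(asm$trajectory)[1]
  expect_equal(n, 64L)                      # nx * ny exactly
  xy <- asm$trajectory$coords[, 1:2, 1]
  box <- asm$trajectory$box
  d2 <- sapply(seq_len(n), function(i) {
    d <- minimum_image(cbind(sweep(xy, 2, xy[i, ]), 0), box)
    r <- sqrt(rowSums(d^2)); min(r[r > 0])
  })
  expect_equal(d2, rep(spec$geometry$lattice, n), tolerance = 1e-9)
})

test_that("shell radii and counts are exact without jitter", {
  spec <- synthetic_spec("shell", n_monomers = 150, n_frames = 2,
                         thermal_noise = 0, diffusion = 0, seed = 4)
  asm <- gen_shell(spec)
  ctr <- asm$trajectory$box$lengths / 2
  r <- sqrt(rowSums(sweep(asm$trajectory$coords[, , 1], 2, ctr)^2))
  expect_equal(r, rep(spec$geometry$radius, 150), tolerance = 1e-12)
  expect_equal(dim(asm$trajectory)[1], 150)
})

test_that("droplet surface fractions follow the shell-volume law", {
  spec <- synthetic_spec("ball", n_monomers = 2048, n_frames = 1, seed = 5)
  asm <- gen_ball(spec)
  R <- spec$geometry$radius; t <- spec$geometry$thickness
  expected <- 1 - (1 - t / R)^3
  got <- mean(asm$labels[, 1] == 1L)
  expect_lt(abs(got - expected), 3 * sqrt(expected * (1 - expected) / 2048))
  ctr <- asm$trajectory$box$lengths / 2
  r <- sqrt(rowSums(sweep(asm$trajectory$coords[, , 1], 2, ctr)^2))
  expect_true(all(r <= R + 6 * spec$thermal_noise))

  # at fixed absolute thickness, bigger droplets have more bulk
  bulk_frac <- vapply(c(128, 512, 2048), function(n) {
    # radius grows with n at constant number density
    Rn <- R * (n / 2048)^(1 / 3)
    s <- synthetic_spec("ball", n_monomers = n, n_frames = 1,
                        geometry = list(radius = Rn), seed = 6)
    mean(gen_ball(s)$labels[, 1] == 2L)
  }, numeric(1))
  expect_true(all(diff(bulk_frac) > 0))
})

test_that("generators are bit-reproducible under a fixed seed", {
  for (kind in c("fiber", "planar", "shell", "ball")) {
    s <- synthetic_spec(kind, n_monomers = 50, n_frames = 3,
                        state_fractions = switch(kind,
                          fiber = c(0.8, 0.1, 0.1),
                          planar = c(0.5, 0.5), NULL),
                        seed = 17)
    a1 <- generate_assembly(s)
    a2 <- generate_assembly(s)
    expect_identical(a1$trajectory$coords, a2$trajectory$coords)
    expect_identical(a1$labels, a2$labels)
  }
})

test_that("synthetic trajectories round-trip through the XYZ writer", {
  s <- synthetic_spec("fiber", n_monomers = 30, n_frames = 3,
                      state_fractions = c(0.8, 0.1, 0.1), seed = 8)
  asm <- gen_fiber(s)
  pre <- withr::local_tempfile()
  paths <- write_assembly(asm, pre)
  expect_true(all(file.exists(paths)))
  back <- read_trajectory(paths[1])
  expect_lt(max(abs(back$coords - asm$trajectory$coords)), 1e-6)
  lab <- utils::read.csv(paths[2])
  expect_equal(nrow(lab), 30 * 3)
  expect_equal(matrix(lab$state, 30, 3), unclass(asm$labels),
               ignore_attr = TRUE)
})

test_that("planted transition dynamics are recovered from the labels", {
  P <- rbind(c(0.95, 0.04, 0.01),
             c(0.15, 0.80, 0.05),
             c(0.05, 0.05, 0.90))
  s <- synthetic_spec("fiber", n_monomers = 100, n_frames = 1000,
                      state_fractions = c(0.85, 0.10, 0.05),
                      planted_P = P, seed = 12)
  asm <- gen_fiber(s)
  tm <- transition_matrix(asm$labels)
  expect_lt(max(abs(tm$P - P)), 0.02)     # M*T = 1e5 observations
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec("fiber", state_fractions = c(0.5, 0.2, 0.2)),
               class = "defectometer_params_error")
  expect_error(synthetic_spec("fiber", geometry = list(spacing = -1)),
               class = "defectometer_params_error")
  expect_error(synthetic_spec("ball", planted_P = rbind(c(0.5, 0.4),
                                                        c(0.5, 0.5))),
               class = "defectometer_params_error")
  expect_error(gen_fiber(synthetic_spec("shell")))
})

test_that("gel replicates are closer to each other than to the liquid phase", {
  mk <- function(fracs, seed) {
    s <- synthetic_spec("planar", n_monomers = 49, n_frames = 6,
                        state_fractions = fracs, seed = seed)
    asm <- gen_planar(s)
    sr <- soap_trajectory(asm$trajectory, soap_params(rcut = 0.8),
                          per_center = FALSE)
    sr$simulation_average
  }
  gelA <- mk(c(1, 0), 1)
  gelB <- mk(c(1, 0), 2)
  liq <- mk(c(0, 1), 3)
  expect_lt(soap_distance(gelA, gelB), soap_distance(gelA, liq))
  expect_lt(soap_distance(gelA, gelB), soap_distance(gelB, liq))
})
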