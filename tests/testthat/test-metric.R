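make_coeffs <- function(coords, p) soap_coefficients(coords, big_box(), p)

test_that("frame average is the spectrum of averaged coefficients", {
  p <- soap_params(nmax = 4, lmax = 4)
  # heterogeneous 2-center frame: a tight pair and a lone center
  coords <- rbind(c(25, 25, 25), c(25, 25, 25.35), c(30, 30, 30))
  cf <- make_coeffs(coords, p)

  fa <- frame_average(cf, p)
  # oracle: average the complex coefficients by hand, then form Eq. 2
  cbar <- array(0 + 0i, dim = c(1, dim(cf)[2], dim(cf)[3]))
  for (i in seq_len(dim(cf)[1])) cbar[1, , ] <- cbar[1, , ] + cf[i, , ]
  cbar <- cbar / dim(cf)[1]
  expect_equal(as.numeric(fa), as.numeric(power_spectrum(cbar, p)),
               tolerance = 1e-12)

  # ... and differs from the (wrong) mean of the per-center spectra
  outer_avg <- colMeans(power_spectrum(cf, p))
  expect_gt(max(abs(as.numeric(fa) - outer_avg)),
            1e-3 * max(abs(outer_avg)))
})

test_that("single-center and homogeneous frames collapse to one spectrum", {
  p <- soap_params(nmax = 4, lmax = 4)
  lone <- make_coeffs(matrix(c(25, 25, 25), 1, 3), p)
  expect_equal(as.numeric(frame_average(lone, p)),
               as.numeric(power_spectrum(lone, p)), tolerance = 1e-12)

  n <- 10; spacing <- 0.3
  stack <- cbind(3, 3, (seq_len(n) - 1) * spacing)
  cf <- soap_coefficients(stack, cg_box(c(6, 6, n * spacing)),
                          soap_params(nmax = 4, lmax = 4))
  fa <- frame_average(cf)
  one <- power_spectrum(cf)[1, ]
  expect_lt(max(abs(as.numeric(fa) - one)) / max(abs(one)), 1e-8)
})

test_that("simulation average is the componentwise frame mean", {
  a <- c(1, 2, 3); b <- c(3, 2, 1)
  m <- rbind(a, b)
  expect_equal(as.numeric(simulation_average(m)), (a + b) / 2)
  expect_equal(as.numeric(simulation_average(rbind(a))), a)   # T = 1
  expect_equal(as.numeric(simulation_average(rbind(a, a, a))), a)
  expect_error(simulation_average(list()),
               class = "defectometer_shape_error")
})

test_that("kernel normalization: identity, orthogonality, scale freedom", {
  a <- c(1, 0, 2, 0.5)
  expect_equal(soap_kernel(a, a), 1)
  expect_equal(soap_kernel(a, 3 * a), 1)
  expect_equal(soap_kernel(c(1, 0), c(0, 1)), 0)
  expect_error(soap_kernel(a, rep(0, 4)),
               class = "defectometer_numeric_error")
  expect_error(soap_kernel(a, c(1, 2)), class = "defectometer_shape_error")
})

test_that("kernel distance closed forms hold", {
  a <- c(1, 0); b <- c(0, 1)                 # K = 0
  expect_equal(soap_distance(a, b), sqrt(2))
  expect_equal(soap_distance(a, a), 0)
  # K = 0.5: unit vectors at 60 degrees
  c1 <- c(1, 0); c2 <- c(cos(pi / 3), sin(pi / 3))
  expect_equal(soap_kernel(c1, c2), 0.5, tolerance = 1e-12)
  expect_equal(soap_distance(c1, c2), 1, tolerance = 1e-12)
})

test_that("metric axioms hold on random positive vectors", {
  set.seed(19)
  V <- matrix(runif(60 * 12), 60, 12)
  ok_triangle <- TRUE; ok_bound <- TRUE; ok_sym <- TRUE
  for (i in 1:1000) {
    idx <- sample(60, 3)
    dab <- soap_distance(V[idx[1], ], V[idx[2], ])
    dbc <- soap_distance(V[idx[2], ], V[idx[3], ])
    dac <- soap_distance(V[idx[1], ], V[idx[3], ])
    ok_triangle <- ok_triangle && (dac <= dab + dbc + 1e-12)
    ok_bound <- ok_bound && dab <= sqrt(2) + 1e-12 && dab >= 0
    ok_sym <- ok_sym &&
      abs(dab - soap_distance(V[idx[2], ], V[idx[1], ])) < 1e-12
  }
  expect_true(ok_triangle)
  expect_true(ok_bound)
  expect_true(ok_sym)
  # invariance under common rescaling
  expect_equal(soap_distance(V[1, ], V[2, ]),
               soap_distance(10 * V[1, ], 0.1 * V[2, ]))
})

test_that("distance matrices are consistent with pairwise recomputation", {
  set.seed(4)
  avgs <- lapply(1:4, function(i) {
    structure(runif(10), system_id = paste0("sys", i), class = "soap_avg")
  })
  avgs[[4]] <- structure(as.numeric(avgs[[1]]), system_id = "dup",
                         class = "soap_avg")
  dm <- soap_distance_matrix(avgs)
  expect_equal(unclass(dm), t(unclass(dm)), ignore_attr = TRUE)
  expect_equal(diag(dm), rep(0, 4), ignore_attr = TRUE)
  expect_lt(dm["sys1", "dup"], 1e-7)        # duplicate system
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(dm[i, j], soap_distance(avgs[[i]], avgs[[j]]))
    }
  }
  td <- tidy(dm)
  expect_equal(nrow(td), 6)
  expect_true(all(td$d_soap >= 0 & td$d_soap <= sqrt(2)))
})
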