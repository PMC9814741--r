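test_that("smooth cutoff has the plateau, zero and cosine midpoint", {
  expect_equal(smooth_cutoff(0, 0.8, 0.2), 1)
  expect_equal(smooth_cutoff(0.6, 0.8, 0.2), 1)
  expect_equal(smooth_cutoff(0.8, 0.8, 0.2), 0)
  expect_equal(smooth_cutoff(0.95, 0.8, 0.2), 0)
  expect_equal(smooth_cutoff(0.7, 0.8, 0.2), 0.5)      # cosine midpoint
  r <- seq(0, 1, by = 1e-3)
  w <- smooth_cutoff(r, 0.8, 0.2)
  expect_true(all(diff(w) <= 1e-12))                   # monotone
  expect_true(all(w >= 0 & w <= 1))
})

test_that("descriptor dimension follows nmax(nmax+1)/2 (lmax+1)", {
  for (nmax in c(1, 3, 8)) {
    for (lmax in c(0, 2, 8)) {
      p <- soap_params(nmax = nmax, lmax = lmax)
      expect_identical(soap_dim(p),
                       as.integer(nmax * (nmax + 1) / 2 * (lmax + 1)))
      expect_length(soap_component_names(p), soap_dim(p))
    }
  }
})

test_that("radial bases are orthonormal on [0, rcut] with r^2 weight", {
  for (basis in c("poly", "gaussian")) {
    p <- soap_params(nmax = 6, lmax = 2, radial_basis = basis)
    gl <- pracma::gaussLegendre(400, 0, p$rcut)
    R <- eval_radial_basis(gl$x, p)
    G <- t(R * (gl$w * gl$x^2)) %*% R
    # the gaussian primitive family is strongly correlated, so its
    # orthonormalization carries more conditioning error than "poly"
    tol <- if (basis == "poly") 1e-8 else 1e-6
    expect_equal(G, diag(6), tolerance = tol, ignore_attr = TRUE)
  }
})

test_that("a center with no neighbors has zero coefficients", {
  p <- soap_params(nmax = 4, lmax = 3, include_self = FALSE)
  coords <- rbind(c(25, 25, 25), c(30, 30, 30))
  cf <- soap_coefficients(coords, big_box(), p)
  expect_equal(max(abs(cf)), 0)
})

test_that("a single neighbor on +z leaves only m = 0 channels", {
  p <- soap_params(nmax = 4, lmax = 4, include_self = FALSE)
  coords <- rbind(c(25, 25, 25), c(25, 25, 25.4))
  cf <- soap_coefficients(coords, big_box(), p)
  for (l in 0:4) {
    for (m in setdiff(-l:l, 0)) {
      expect_lt(max(abs(cf[1, , l^2 + l + m + 1])), 1e-12)
    }
    expect_gt(max(abs(cf[1, , l^2 + l + 1])), 0)
  }
})

test_that("coefficients obey the real-density conjugation symmetry", {
  p <- soap_params(nmax = 3, lmax = 4)
  coords <- random_cluster_coords(6, seed = 2)
  cf <- soap_coefficients(coords, big_box(), p)
  for (l in 1:4) {
    for (m in 1:l) {
      expect_equal(cf[, , l^2 + l - m + 1],
                   (-1)^m * Conj(cf[, , l^2 + l + m + 1]),
                   tolerance = 1e-12)
    }
  }
})

test_that("coefficients match the dense 3-D quadrature oracle", {
  p <- soap_params(nmax = 8, lmax = 8)
  coords <- random_cluster_coords(6, seed = 7)
  cf <- soap_coefficients(coords, big_box(), p)
  o <- oracle_soap_coefficients(coords, 1, p)
  expect_lt(max(abs(cf[1, , ] - o)) / max(abs(o)), 1e-6)

  # and with the alternative radial family
  p2 <- soap_params(nmax = 5, lmax = 4, radial_basis = "gaussian")
  cf2 <- soap_coefficients(coords, big_box(), p2)
  o2 <- oracle_soap_coefficients(coords, 1, p2)
  expect_lt(max(abs(cf2[1, , ] - o2)) / max(abs(o2)), 1e-6)
})

test_that("spectra are invariant under rotation, translation, permutation", {
  p <- soap_params(nmax = 4, lmax = 4)
  box <- big_box()
  set.seed(42)
  for (rep in 1:5) {
    coords <- random_cluster_coords(7)
    ps0 <- power_spectrum(soap_coefficients(coords, box, p), p)
    scale0 <- max(abs(ps0))

    ctr <- colMeans(coords)
    R <- random_rotation()
    rot <- sweep(sweep(coords, 2, ctr) %*% t(R), 2, ctr, "+")
    ps_rot <- power_spectrum(soap_coefficients(rot, box, p), p)
    expect_lt(max(abs(ps_rot - ps0)) / scale0, 1e-8)

    tra <- sweep(coords, 2, c(3.1, -2.2, 7.9), "+")
    ps_tra <- power_spectrum(soap_coefficients(tra, box, p), p)
    expect_lt(max(abs(ps_tra - ps0)) / scale0, 1e-8)

    perm <- sample(nrow(coords))
    ps_perm <- power_spectrum(soap_coefficients(coords[perm, ], box, p), p)
    expect_lt(max(abs(ps_perm - ps0[perm, ])) / scale0, 1e-8)
  }
})

test_that("all sites of a perfect periodic stack share one spectrum", {
  p <- soap_params(rcut = 0.8)
  n <- 12; spacing <- 0.3
  coords <- cbind(3, 3, (seq_len(n) - 1) * spacing)
  box <- cg_box(c(6, 6, n * spacing))
  sf <- soap_frame(coords, box, p)
  expect_equal(nrow(sf$spectra), n)
  expect_length(sf$spectra[1, ], 324)
  ref <- sf$spectra[1, ]
  for (i in 2:n) {
    expect_lt(max(abs(sf$spectra[i, ] - ref)) / max(abs(ref)), 1e-8)
  }
})

test_that("single-center frames and zero coefficients behave", {
  p <- soap_params(nmax = 3, lmax = 2)
  sf <- soap_frame(matrix(c(25, 25, 25), 1, 3), big_box(), p)
  expect_equal(dim(sf$spectra), c(1L, soap_dim(p)))
  z <- array(0 + 0i, dim = c(2, 3, 9))
  expect_equal(power_spectrum(z, p), matrix(0, 2, soap_dim(p)),
               ignore_attr = TRUE)
})

test_that("rcut beyond the half-box is rejected", {
  p <- soap_params(rcut = 3)
  expect_error(soap_coefficients(matrix(1, 1, 3), cg_box(c(4, 4, 4)), p),
               class = "defectometer_params_error")
})
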