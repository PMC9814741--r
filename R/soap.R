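#' SOAP descriptor parameters
#'
#' Parameter set for the Smooth Overlap of Atomic Positions descriptor of a
#' single-species system: the neighbor density around each monomer center is
#' a sum of Gaussians of width `sigma`, smoothly truncated at `rcut`, and is
#' expanded on `nmax` orthonormal radial functions times spherical harmonics
#' up to `lmax`. The rotationally invariant power spectrum then has
#' `D = nmax (nmax + 1) / 2 * (lmax + 1)` components (324 at the default
#' `nmax = lmax = 8`).
#'
#' @param nmax radial basis size (>= 1).
#' @param lmax maximum angular momentum (>= 0); angular channels run l = 0..lmax.
#' @param rcut cutoff radius in nm. Typical choices for Martini-resolution
#'   centers are 0.8, 1.6 or 3.0 nm.
#' @param sigma Gaussian smearing width in nm.
#' @param w_switch width (nm) of the cosine switching region of the cutoff;
#'   must satisfy `0 < w_switch < rcut`.
#' @param include_self should a center's own Gaussian contribute to its
#'   density (default `TRUE`).
#' @param radial_basis `"poly"` (Gram-Schmidt-orthonormalized polynomial
#'   family `(rcut - r)^(k+2)` on `[0, rcut]`, the default) or `"gaussian"`
#'   (orthonormalized Gaussians of staggered widths, selectable for
#'   cross-checks).
#' @return An object of class `soap_params`.
#' @examples
#' p <- soap_params()
#' soap_dim(p)  # 324
#' @export
soap_params <- function(nmax = 8, lmax = 8, rcut = 0.8, sigma = 0.1,
                        w_switch = 0.05, include_self = TRUE,
                        radial_basis = c("poly", "gaussian")) {
  radial_basis <- match.arg(radial_basis)
  if (nmax < 1 || nmax != round(nmax)) {
    rlang::abort("`nmax` must be a positive integer.",
                 class = "defectometer_params_error")
  }
  if (lmax < 0 || lmax != round(lmax)) {
    rlang::abort("`lmax` must be a non-negative integer.",
                 class = "defectometer_params_error")
  }
  if (!(rcut > 0) || !(sigma > 0) || !(w_switch > 0) || !(w_switch < rcut)) {
    rlang::abort("need rcut > 0, sigma > 0 and 0 < w_switch < rcut.",
                 class = "defectometer_params_error")
  }
  structure(list(nmax = as.integer(nmax), lmax = as.integer(lmax),
                 rcut = rcut, sigma = sigma, w_switch = w_switch,
                 include_self = isTRUE(include_self),
                 radial_basis = radial_basis),
            class = "soap_params")
}

#' @export
print.soap_params <- function(x, ...) {
  cat(sprintf(paste0("<soap_params> nmax=%d lmax=%d rcut=%g nm sigma=%g nm ",
                     "w_switch=%g nm self=%s basis=%s (D=%d)\n"),
              x$nmax, x$lmax, x$rcut, x$sigma, x$w_switch,
              x$include_self, x$radial_basis, soap_dim(x)))
  invisible(x)
}

#' @rdname soap_params
#' @param params a `soap_params` object.
#' @export
soap_dim <- function(params) {
  as.integer(params$nmax * (params$nmax + 1) / 2 * (params$lmax + 1))
}

#' Names of the power-spectrum components
#'
#' `"n<n>_n<n'>_l<l>"` labels in the canonical component order (`l` outer
#' `0..lmax`, then pairs `n' >= n` lexicographic) used by every exported
#' spectrum.
#'
#' @param params a [soap_params()].
#' @return Character vector of length `soap_dim(params)`.
#' @export
soap_component_names <- function(params) {
  out <- character(0)
  for (l in 0:params$lmax) {
    for (n in 1:params$nmax) {
      for (np in n:params$nmax) {
        out <- c(out, sprintf("n%d_n%d_l%d", n, np, l))
      }
    }
  }
  out
}

#' Smooth radial cutoff function
#'
#' Unity for `r <= rcut - w_switch`, zero for `r >= rcut`, cosine
#' half-switch in between; continuously differentiable at both joins.
#'
#' @param r distance(s), nm, `>= 0`.
#' @param rcut cutoff radius (nm).
#' @param w_switch switching width (nm).
#' @return Weight(s) in `[0, 1]`.
#' @export
smooth_cutoff <- function(r, rcut, w_switch) {
  w <- numeric(length(r))
  w[r <= rcut - w_switch] <- 1
  mid <- r > rcut - w_switch & r < rcut
  w[mid] <- 0.5 * (1 + cos(pi * (r[mid] - rcut + w_switch) / w_switch))
  w
}

# ---- radial basis -----------------------------------------------------------

# Gram-Schmidt coefficients: lower-triangular beta with R_n = sum_k
# beta[n,k] phi_k, orthonormal wrt integral f g r^2 dr on [0, rcut].
radial_basis_coefs <- function(params) {
  n <- params$nmax; rc <- params$rcut
  if (params$radial_basis == "poly") {
    # phi_k(r) = (rc - r)^(k+2), k = 0..n-1; Gram has closed form
    S <- matrix(0, n, n)
    for (k in 1:n) {
      for (kp in 1:n) {
        a <- (k - 1) + (kp - 1) + 4
        S[k, kp] <- rc^(a + 3) * (1 / (a + 1) - 2 / (a + 2) + 1 / (a + 3))
      }
    }
  } else {
    # phi_k(r) = exp(-r^2 / (2 s_k^2)), s_k staggered; numeric Gram
    gl <- gauss_legendre_nodes(400, 0, rc)
    P <- gaussian_primitives(gl$x, params)
    S <- t(P * (gl$w * gl$x^2)) %*% P
  }
  U <- chol(S)                       # S = t(U) %*% U
  beta <- solve(t(U))                # beta %*% S %*% t(beta) = I
  # the primitive Gram is ill-conditioned (kappa ~ 1e10 at nmax = 8); one
  # re-orthonormalization pass against the numerically evaluated Gram of
  # the first-pass basis removes the resulting ~1e-6 residual
  gl <- gauss_legendre_nodes(400, 0, rc)
  R1 <- eval_radial_basis(gl$x, params, beta)
  G <- t(R1 * (gl$w * gl$x^2)) %*% R1
  beta <- solve(t(chol(G))) %*% beta
  beta
}

gaussian_primitive_widths <- function(params) {
  params$rcut * seq_len(params$nmax) / (params$nmax + 1) / sqrt(2)
}

gaussian_primitives <- function(r, params) {
  s <- gaussian_primitive_widths(params)
  vapply(s, function(si) exp(-r^2 / (2 * si^2)), numeric(length(r)))
}

#' Evaluate the orthonormal radial basis functions
#'
#' @param r distances in `[0, rcut]` (nm).
#' @param params a [soap_params()].
#' @param beta optional precomputed Gram-Schmidt coefficient matrix.
#' @return `length(r) x nmax` matrix of `R_n(r)` values.
#' @export
eval_radial_basis <- function(r, params, beta = radial_basis_coefs(params)) {
  if (params$radial_basis == "poly") {
    P <- vapply(seq_len(params$nmax),
                function(k) (params$rcut - r)^(k + 1),  # exponent (k-1)+2
                numeric(length(r)))
  } else {
    P <- gaussian_primitives(r, params)
  }
  P %*% t(beta)
}

# ---- spherical harmonics ----------------------------------------------------

# Complex spherical harmonics Y_lm for all l = 0..lmax, m = -l..l at unit
# vectors `u` (N x 3). Condon-Shortley phase (inherited from
# pracma::legendre). Column index: l^2 + l + m + 1.
sph_harm_table <- function(u, lmax) {
  n <- nrow(u)
  ct <- pmin(1, pmax(-1, u[, 3]))
  phi <- atan2(u[, 2], u[, 1])
  Y <- matrix(0 + 0i, n, (lmax + 1)^2)
  for (l in 0:lmax) {
    P <- pracma::legendre(l, ct)             # (l+1) x n, m = 0..l
    if (l == 0) P <- matrix(P, 1, n)
    for (m in 0:l) {
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      ylm <- N * P[m + 1, ] * exp(1i * m * phi)
      Y[, l^2 + l + m + 1] <- ylm
      if (m > 0) Y[, l^2 + l - m + 1] <- (-1)^m * Conj(ylm)
    }
  }
  Y
}

gauss_legendre_nodes <- function(n, a, b) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(x = gl$x, w = gl$w)
}

# scaled modified spherical Bessel: i_l(x) * exp(-x), stable for large x
sbessel_scaled <- function(l, x) {
  out <- numeric(length(x))
  tiny <- x < 1e-12
  if (any(!tiny)) {
    xt <- x[!tiny]
    out[!tiny] <- sqrt(pi / (2 * xt)) * besselI(xt, l + 0.5,
                                                expon.scaled = TRUE)
  }
  if (any(tiny)) out[tiny] <- if (l == 0) exp(-x[tiny]) else 0
  out
}

# ---- expansion coefficients -------------------------------------------------

# Neighbor pair list of one frame under minimum image: for each center, all
# others (and optionally itself) within rcut. Returns tibble-free list of
# vectors to stay lean.
neighbor_pairs <- function(coords, box, params) {
  M <- nrow(coords)
  if (any(box$lengths[box$periodic] < 2 * params$rcut)) {
    rlang::abort(paste0("rcut must not exceed half the box on periodic axes ",
                        "(single minimum image convention)."),
                 class = "defectometer_params_error")
  }
  ci <- integer(0); rj <- numeric(0); ux <- uy <- uz <- numeric(0)
  for (i in seq_len(M)) {
    d <- minimum_image(sweep(coords, 2, coords[i, ]), box)
    r <- sqrt(rowSums(d^2))
    keep <- r <= params$rcut
    keep[i] <- params$include_self
    idx <- which(keep)
    nr <- r[idx]
    un <- d[idx, , drop = FALSE]
    pos <- nr > 0
    un[pos, ] <- un[pos, ] / nr[pos]
    un[!pos, ] <- rep(c(0, 0, 1), each = sum(!pos))
    ci <- c(ci, rep.int(i, length(idx)))
    rj <- c(rj, nr); ux <- c(ux, un[, 1]); uy <- c(uy, un[, 2])
    uz <- c(uz, un[, 3])
  }
  list(center = ci, r = rj, u = cbind(ux, uy, uz))
}

#' SOAP expansion coefficients of every center of a frame
#'
#' Expands the Gaussian-smeared, cutoff-weighted neighbor density around
#' each monomer center on the orthonormal radial basis times spherical
#' harmonics. Each neighbor within `rcut` (minimum image) contributes a
#' unit-normalized 3-D Gaussian of width `sigma`, weighted by the smooth
#' cutoff evaluated at the neighbor distance. The angular integral is done
#' analytically (modified spherical Bessel expansion of the displaced
#' Gaussian); the radial integral by Gauss-Legendre quadrature on the
#' +-6 sigma window of each neighbor.
#'
#' @param coords `M x 3` matrix of center coordinates (nm).
#' @param box a [cg_box()].
#' @param params a [soap_params()].
#' @param n_quad radial quadrature nodes per neighbor window.
#' @return Complex array `M x nmax x (lmax+1)^2`; the last index is the
#'   flattened `(l, m)` channel `l^2 + l + m + 1`. Carries `params` as an
#'   attribute. Coefficients obey the real-density conjugation symmetry
#'   `c_{n,l,-m} = (-1)^m Conj(c_{n,l,m})`.
#' @export
soap_coefficients <- function(coords, box, params, n_quad = 40) {
  stopifnot(inherits(params, "soap_params"))
  if (!is.matrix(coords) || ncol(coords) != 3 || any(!is.finite(coords))) {
    rlang::abort("`coords` must be a finite M x 3 matrix.",
                 class = "defectometer_shape_error")
  }
  M <- nrow(coords)
  nmax <- params$nmax; lmax <- params$lmax
  nlm <- (lmax + 1)^2
  cf <- array(0 + 0i, dim = c(M, nmax, nlm))
  attr(cf, "params") <- params
  pr <- neighbor_pairs(coords, box, params)
  P <- length(pr$center)
  if (P == 0) return(cf)
  beta <- radial_basis_coefs(params)
  sig <- params$sigma
  pref <- (2 * pi * sig^2)^(-1.5) * 4 * pi
  wj <- smooth_cutoff(pr$r, params$rcut, params$w_switch)
  wj[pr$r == 0] <- 1
  gl <- gauss_legendre_nodes(n_quad, -1, 1)

  # per-pair quadrature window [lo, hi] within [0, rcut]
  lo <- pmax(0, pr$r - 6 * sig)
  hi <- pmin(params$rcut, pr$r + 6 * sig)
  half <- (hi - lo) / 2; mid <- (hi + lo) / 2
  # nodes X, weights W: P x n_quad
  X <- outer(half, gl$x) + mid
  W <- outer(half, gl$w)
  Rj <- matrix(pr$r, P, n_quad)
  # radial basis at all nodes
  Rn <- eval_radial_basis(as.vector(X), params, beta)   # (P*nq) x nmax
  gaussf <- exp(-(X - Rj)^2 / (2 * sig^2))
  Wx2 <- W * X^2

  Y <- sph_harm_table(pr$u, lmax)
  grp <- pr$center
  for (l in 0:lmax) {
    A <- gaussf * matrix(sbessel_scaled(l, as.vector(X * Rj / sig^2)),
                         P, n_quad)
    # radial integrals I[p, n] = sum_q W x^2 gauss sbessel R_n
    G <- Rn * as.vector(A * Wx2)
    I_l <- rowsum(G, group = rep(seq_len(P), times = n_quad),
                  reorder = TRUE)                       # P x nmax
    T1 <- I_l * (wj * pref)
    for (m in -l:l) {
      col <- l^2 + l + m + 1
      ym <- Conj(Y[, col])
      re <- rowsum(T1 * Re(ym), grp, reorder = FALSE)
      im <- rowsum(T1 * Im(ym), grp, reorder = FALSE)
      centers <- as.integer(rownames(re))
      cf[centers, , col] <- cf[centers, , col] + (re + 1i * im)
    }
  }
  cf
}

#' SOAP power spectrum from expansion coefficients
#'
#' Contracts the complex expansion coefficients over the magnetic index:
#' `gamma_nn'l = 1/sqrt(2l+1) * sum_m Conj(c_nlm) c_n'lm` for `n' >= n`,
#' assembled in canonical order (l outer 0..lmax, then pairs `n' >= n`).
#' The result is rotation, translation and neighbor-permutation invariant.
#'
#' @param coeffs a coefficient array from [soap_coefficients()] (all
#'   centers), or a single-center `nmax x (lmax+1)^2` complex matrix.
#' @param params a [soap_params()]; defaults to the array's attribute.
#' @param tol maximum tolerated imaginary residue (relative to the largest
#'   component) before a numerical-consistency error is raised.
#' @return `M x D` numeric matrix of power spectra (or a length-`D` vector
#'   for single-center input), columns named `n<n>_n<n'>_l<l>`.
#' @export
power_spectrum <- function(coeffs, params = attr(coeffs, "params"),
                           tol = 1e-10) {
  stopifnot(inherits(params, "soap_params"))
  single <- is.matrix(coeffs)
  if (single) coeffs <- array(coeffs, dim = c(1, dim(coeffs)))
  M <- dim(coeffs)[1]
  nmax <- params$nmax; lmax <- params$lmax
  p <- matrix(0, M, soap_dim(params))
  scale_ref <- max(abs(coeffs))^2
  col <- 0L
  for (l in 0:lmax) {
    lmcols <- (l^2 + 1):((l + 1)^2)
    nm_l <- 2 * l + 1
    cl <- coeffs[, , lmcols, drop = FALSE]     # M x nmax x (2l+1)
    for (n in 1:nmax) {
      an <- Conj(matrix(cl[, n, ], M, nm_l))
      for (np in n:nmax) {
        col <- col + 1L
        s <- rowSums(an * matrix(cl[, np, ], M, nm_l))
        if (scale_ref > 0 && max(abs(Im(s))) > tol * max(scale_ref, 1e-300)) {
          rlang::abort("imaginary residue above tolerance in power spectrum.",
                       class = "defectometer_numeric_error")
        }
        p[, col] <- Re(s) / sqrt(2 * l + 1)
      }
    }
  }
  colnames(p) <- soap_component_names(params)
  if (single) p[1, ] else p
}

#' Per-center SOAP spectra of a frame
#'
#' Convenience wrapper: expansion coefficients plus power spectra for every
#' center of one frame.
#'
#' @inheritParams soap_coefficients
#' @return List with `spectra` (`M x D` matrix) and `coefficients` (the
#'   complex array, retained for frame averaging).
#' @export
soap_frame <- function(coords, box, params, n_quad = 40) {
  cf <- soap_coefficients(coords, box, params, n_quad = n_quad)
  list(spectra = power_spectrum(cf, params), coefficients = cf)
}
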