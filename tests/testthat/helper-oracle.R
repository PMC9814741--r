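# Independent oracles and small fixture builders used across the suite.

# Direct 3-D product-quadrature projection of the smeared neighbor density
# on the radial x spherical-harmonic basis: radial Gauss-Legendre grid,
# Gauss-Legendre in cos(theta), uniform trapezoid in phi. Everything except
# the radial-basis evaluation is computed from scratch, independently of
# the analytic Bessel-expansion path in the package.
oracle_soap_coefficients <- function(coords, i, p, nr = 320, nt = 28,
                                     nph = 56) {
  ctr <- coords[i, ]
  d <- sweep(coords, 2, ctr)
  r_j <- sqrt(rowSums(d^2))
  keep <- r_j <= p$rcut
  keep[i] <- p$include_self
  d <- d[keep, , drop = FALSE]; r_j <- r_j[keep]
  w_j <- smooth_cutoff(r_j, p$rcut, p$w_switch); w_j[r_j == 0] <- 1
  glr <- pracma::gaussLegendre(nr, 0, p$rcut)
  glt <- pracma::gaussLegendre(nt, -1, 1)
  phis <- 2 * pi * (seq_len(nph) - 1) / nph
  grid <- expand.grid(q = seq_len(nr), t = seq_len(nt), f = seq_len(nph))
  r <- glr$x[grid$q]; ct <- glt$x[grid$t]; ph <- phis[grid$f]
  st <- sqrt(1 - ct^2)
  pts <- cbind(r * st * cos(ph), r * st * sin(ph), r * ct)
  rho <- numeric(nrow(pts))
  for (j in seq_along(r_j)) {
    dd <- sweep(pts, 2, d[j, ])
    rho <- rho + w_j[j] * (2 * pi * p$sigma^2)^(-1.5) *
      exp(-rowSums(dd^2) / (2 * p$sigma^2))
  }
  wq <- glr$w[grid$q] * glt$w[grid$t] * (2 * pi / nph) * r^2
  Rn <- eval_radial_basis(r, p)
  cf <- matrix(0 + 0i, p$nmax, (p$lmax + 1)^2)
  for (l in 0:p$lmax) {
    P <- pracma::legendre(l, ct)
    if (l == 0) P <- matrix(P, 1, length(ct))
    for (m in 0:l) {
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  factorial(l - m) / factorial(l + m))
      Y <- N * P[m + 1, ] * exp(1i * m * ph)
      cf[, l^2 + l + m + 1] <- as.vector(t(Rn) %*% (rho * wq * Conj(Y)))
      if (m > 0) {
        Ym <- (-1)^m * Conj(Y)
        cf[, l^2 + l - m + 1] <- as.vector(t(Rn) %*% (rho * wq * Conj(Ym)))
      }
    }
  }
  cf
}

# random 3-D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# a small open (non-periodic-contact) configuration in a big box
random_cluster_coords <- function(n, spread = 0.4, center = c(25, 25, 25),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sweep(matrix(stats::runif(3 * n, -spread, spread), n, 3), 2, center, "+")
}

big_box <- function(L = 50) cg_box(c(L, L, L))

# isotropic Gaussian blobs with planted component labels
gaussian_blobs <- function(centers, n_each, sd = 1, seed = 1) {
  set.seed(seed)
  k <- ncol(centers)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(stats::rnorm(n_each * k, sd = sd), n_each, k) +
      matrix(centers[i, ], n_each, k, byrow = TRUE)
  }))
  list(points = pts, labels = rep(seq_len(nrow(centers)), each = n_each))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# map recovered labels onto planted ones by majority matching, then return
# the relabelled vector (for population comparisons)
match_labels <- function(found, truth, K) {
  tab <- table(factor(found, levels = seq_len(K)),
               factor(truth, levels = seq_len(K)))
  # greedy assignment, largest overlap first
  mapping <- integer(K)
  used <- logical(K)
  for (r in order(-apply(tab, 1, max))) {
    best <- order(-tab[r, ])
    best <- best[!used[best]][1]
    mapping[r] <- best
    used[best] <- TRUE
  }
  mapping[found]
}

# internal clustering pass (grid + density + modes + point labels)
cluster_pass_public <- defectometer:::cluster_pass
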