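#' Farthest-point sampling of a KDE grid
#'
#' Greedy max-min subset selection: the first grid point is a seeded
#' uniform draw, every subsequent point maximizes the minimum distance to
#' the points already selected (ties broken by lowest row index). The
#' resulting grid covers the data support quasi-uniformly and is where the
#' probability density is estimated.
#'
#' @param points numeric `N x k` matrix.
#' @param n_grid number of grid points (`<= N`).
#' @param seed integer seed for the first draw.
#' @return List with `indices` (row indices into `points`) and `points`
#'   (`n_grid x k` coordinates).
#' @export
farthest_point_sample <- function(points, n_grid, seed = 0) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (n_grid > N) {
    rlang::abort("n_grid cannot exceed the number of points.",
                 class = "defectometer_shape_error")
  }
  sel <- integer(n_grid)
  sel[1] <- local_seed(seed, sample.int(N, 1))
  d2min <- rowSums(sweep(points, 2, points[sel[1], ])^2)
  if (n_grid > 1) {
    for (i in 2:n_grid) {
      nxt <- which.max(d2min)              # ties -> lowest index
      sel[i] <- nxt
      d2 <- rowSums(sweep(points, 2, points[nxt, ])^2)
      d2min <- pmin(d2min, d2)
    }
  }
  list(indices = sel, points = points[sel, , drop = FALSE])
}

silverman_factor <- function(N, k) {
  (4 / (N * (k + 2)))^(2 / (k + 4))    # squared bandwidth scale
}

#' Anisotropic kernel density estimate on a grid
#'
#' At each grid point the density of the dataset is estimated with a
#' multivariate Gaussian kernel whose bandwidth matrix is the covariance
#' of the `n_localization` nearest dataset points, scaled by the global
#' Silverman factor. A singular local covariance is ridge-regularized by
#' `ridge * trace / k` on the diagonal.
#'
#' @param points numeric `N x k` dataset.
#' @param grid a grid from [farthest_point_sample()] (or an `n_grid x k`
#'   matrix).
#' @param n_localization neighbors defining the local bandwidth; default
#'   `ceiling(N / 5)`.
#' @param ridge regularization strength for degenerate local covariances.
#' @return Numeric vector of `n_grid` strictly positive densities.
#' @export
kde_density <- function(points, grid, n_localization = NULL, ridge = 1e-8) {
  points <- as.matrix(points)
  gp <- if (is.list(grid)) grid$points else as.matrix(grid)
  N <- nrow(points); k <- ncol(points)
  if (N < k + 1) {
    rlang::abort("need at least k + 1 points for a k-dimensional KDE.",
                 class = "defectometer_shape_error")
  }
  n_loc <- n_localization %||% ceiling(N / 5)
  n_loc <- max(k + 1, min(N, n_loc))
  silv2 <- silverman_factor(N, k)
  dens <- numeric(nrow(gp))
  for (g in seq_len(nrow(gp))) {
    d <- sweep(points, 2, gp[g, ])
    d2 <- rowSums(d^2)
    thr <- sort(d2, partial = n_loc)[n_loc]
    nn <- which(d2 <= thr)
    if (length(nn) > n_loc) nn <- nn[order(d2[nn])][seq_len(n_loc)]
    S <- stats::cov(points[nn, , drop = FALSE]) * silv2
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps))) {
      tr <- sum(diag(S))
      eps <- ridge * (if (tr > 0) tr / k else 1)
      S <- S + diag(eps, k)
      ch <- tryCatch(chol(S), error = function(e) chol(diag(eps, k)))
    }
    z <- d %*% backsolve(ch, diag(k))      # whitened displacements
    logdet <- sum(log(diag(ch)))
    dens[g] <- mean(exp(-0.5 * rowSums(z^2))) *
      exp(-logdet) * (2 * pi)^(-k / 2)
  }
  pmax(dens, .Machine$double.xmin)         # strictly positive
}

#' Quick-shift mode-seeking clustering of the grid
#'
#' Each grid point links to its nearest grid point of strictly higher
#' density (density ties broken by lower index) within
#' `lambda_qs * median nearest-grid-neighbor distance`; link-free points
#' are the modes (local density maxima) and each ascent tree is one
#' microcluster.
#'
#' @param grid a grid from [farthest_point_sample()] (or a matrix).
#' @param density densities at the grid points.
#' @param lambda_qs link radius in units of the typical grid spacing.
#' @return List with `grid_labels` (microcluster id per grid point, 1-based)
#'   and `modes` (one grid index per microcluster, the density maximum).
#' @export
mode_cluster <- function(grid, density, lambda_qs = 3) {
  gp <- if (is.list(grid)) grid$points else as.matrix(grid)
  G <- nrow(gp)
  if (length(density) != G || any(density <= 0)) {
    rlang::abort("densities must be positive, one per grid point.",
                 class = "defectometer_shape_error")
  }
  if (G == 1) return(list(grid_labels = 1L, modes = 1L))
  D2 <- as.matrix(stats::dist(gp))^2
  diag(D2) <- Inf
  nn_dist <- sqrt(apply(D2, 1, min))
  radius2 <- (lambda_qs * stats::median(nn_dist))^2
  # rank: higher density wins; ties -> lower index counts as higher
  rk <- rank(-density, ties.method = "first")  # 1 = highest
  parent <- integer(G)
  for (i in seq_len(G)) {
    cand <- which(rk < rk[i] & D2[i, ] <= radius2)
    parent[i] <- if (length(cand)) cand[which.min(D2[i, cand])] else 0L
  }
  modes <- which(parent == 0L)
  root <- seq_len(G)
  for (i in seq_len(G)) {
    j <- i
    while (parent[j] != 0L) j <- parent[j]
    root[i] <- j
  }
  labels <- match(root, modes)
  list(grid_labels = labels, modes = modes)
}

#' Assign dataset points to microclusters
#'
#' Every dataset vector inherits the microcluster label of its nearest
#' grid point (Euclidean; ties broken by lower grid index).
#'
#' @param points numeric `N x k` dataset.
#' @param grid a grid from [farthest_point_sample()] (or matrix).
#' @param grid_labels microcluster ids of the grid points.
#' @param chunk points per block (memory control).
#' @return Integer vector of `N` microcluster labels.
#' @export
assign_microstates <- function(points, grid, grid_labels, chunk = 4096L) {
  points <- as.matrix(points)
  gp <- if (is.list(grid)) grid$points else as.matrix(grid)
  N <- nrow(points)
  out <- integer(N)
  g2 <- rowSums(gp^2)
  for (s in seq(1, N, by = chunk)) {
    e <- min(N, s + chunk - 1L)
    X <- points[s:e, , drop = FALSE]
    # squared distance via expansion; argmin ties -> lower index
    cross <- X %*% t(gp)
    d2 <- sweep(-2 * cross, 2, g2, "+")
    out[s:e] <- grid_labels[max.col(-d2, ties.method = "first")]
  }
  out
}

# one full clustering pass: fps -> kde -> quick-shift -> point labels
cluster_pass <- function(points, n_grid, seed, n_localization = NULL,
                         lambda_qs = 3, ridge = 1e-8) {
  grid <- farthest_point_sample(points, n_grid, seed = seed)
  dens <- kde_density(points, grid, n_localization = n_localization,
                      ridge = ridge)
  mc <- mode_cluster(grid, dens, lambda_qs = lambda_qs)
  point_labels <- assign_microstates(points, grid, mc$grid_labels)
  list(grid = grid, density = dens, grid_labels = mc$grid_labels,
       modes = mc$modes, point_labels = point_labels)
}

#' Bootstrap stability of the microclusters
#'
#' Re-runs the full clustering pass on `n_boot` bootstrap resamples of the
#' dataset (with replacement, size `N`) and measures, per pair of
#' reference microclusters, the normalized co-assignment probability: how
#' often a random point of cluster a and a random point of cluster b end
#' up in the same resampled cluster, normalized so the diagonal is exactly
#' one. Well-separated clusters score near zero off-diagonal; clusters
#' that the resampling merges or confuses score near one. A degenerate
#' resample that collapses to a single cluster counts as merging all
#' pairs; such resamples are tallied in `n_degenerate`.
#'
#' @param points numeric `N x k` dataset.
#' @param ref_labels reference microcluster labels of the `N` points.
#' @param n_grid grid size per resample pass.
#' @param n_boot number of bootstrap resamples (default 73).
#' @param seed integer seed; resample b uses stream `seed + b`.
#' @param n_localization,lambda_qs,ridge forwarded to the clustering pass.
#' @return List with `stability` (`C x C`, in `[0, 1]`, unit diagonal),
#'   `merge_tree` (average-linkage `hclust` on `1 - stability`, `NULL` for
#'   a single cluster) and `n_degenerate`.
#' @export
bootstrap_stability <- function(points, ref_labels, n_grid, n_boot = 73,
                                seed = 0, n_localization = NULL,
                                lambda_qs = 3, ridge = 1e-8) {
  points <- as.matrix(points)
  N <- nrow(points)
  C <- max(ref_labels)
  acc <- matrix(0, C, C)
  n_degen <- 0L
  for (b in seq_len(n_boot)) {
    idx <- local_seed(seed + b, sample.int(N, N, replace = TRUE))
    cp <- cluster_pass(points[idx, , drop = FALSE], n_grid,
                       seed = seed + b, n_localization = n_localization,
                       lambda_qs = lambda_qs, ridge = ridge)
    lab_b <- assign_microstates(points, cp$grid, cp$grid_labels)
    if (length(unique(lab_b)) == 1L) n_degen <- n_degen + 1L
    # P[a, c] = fraction of reference cluster a in resampled cluster c
    tab <- table(factor(ref_labels, levels = seq_len(C)), lab_b)
    P <- tab / pmax(1, rowSums(tab))
    Craw <- P %*% t(P)
    norm <- sqrt(pmax(diag(Craw), .Machine$double.eps))
    acc <- acc + Craw / outer(norm, norm)
  }
  stability <- acc / n_boot
  stability <- (stability + t(stability)) / 2
  diag(stability) <- 1
  dimnames(stability) <- NULL
  tree <- if (C > 1) {
    stats::hclust(stats::as.dist(1 - stability), method = "average")
  } else NULL
  list(stability = stability, merge_tree = tree, n_degenerate = n_degen)
}

#' Condense microclusters into macroclusters
#'
#' Cuts the bootstrap-stability dendrogram at the height yielding exactly
#' `K` groups (deterministic, via [stats::cutree()]).
#'
#' @param merge_tree an `hclust` merge tree from [bootstrap_stability()].
#' @param K target macrocluster count, `1 <= K <= C`.
#' @return Integer vector `micro_to_macro` of length `C` (values `1..K`).
#' @export
cut_macroclusters <- function(merge_tree, K) {
  if (is.null(merge_tree)) {
    if (K != 1) {
      rlang::abort("a single microcluster can only map to K = 1.",
                   class = "defectometer_shape_error")
    }
    return(1L)
  }
  C <- length(merge_tree$order)
  if (K < 1 || K > C) {
    rlang::abort(sprintf("K must be in 1..%d.", C),
                 class = "defectometer_shape_error")
  }
  as.integer(stats::cutree(merge_tree, k = K))
}

#' PAMM-style density-based clustering of projected SOAP vectors
#'
#' Full stack: farthest-point-sampled grid, anisotropic Gaussian KDE,
#' quick-shift association of density maxima to microclusters, assignment
#' of every dataset vector, bootstrap stability of the microclusters and
#' the micro-to-macro dendrogram cut at `K` groups.
#'
#' @param points numeric `N x k` matrix (typically 3 principal components).
#' @param n_grid grid size; default `min(2000, ceiling(N / 5))`.
#' @param K macrocluster count (`NULL` to skip the macro step).
#' @param n_boot bootstrap resamples for the stability matrix (73 by
#'   default; 0 skips bootstrap, leaving micro = macro).
#' @param seed integer master seed.
#' @param n_localization,lambda_qs,ridge see [kde_density()] and
#'   [mode_cluster()].
#' @return A `pamm_fit` object.
#' @export
pamm <- function(points, n_grid = NULL, K = NULL, n_boot = 73, seed = 0,
                 n_localization = NULL, lambda_qs = 3, ridge = 1e-8) {
  points <- as.matrix(points)
  N <- nrow(points)
  n_grid <- n_grid %||% min(2000L, ceiling(N / 5))
  cp <- cluster_pass(points, n_grid, seed = seed,
                     n_localization = n_localization,
                     lambda_qs = lambda_qs, ridge = ridge)
  C <- max(cp$grid_labels)
  bs <- NULL
  micro_to_macro <- seq_len(C)
  point_macro <- cp$point_labels
  if (n_boot > 0 && C > 1) {
    bs <- bootstrap_stability(points, cp$point_labels, n_grid,
                              n_boot = n_boot, seed = seed,
                              n_localization = n_localization,
                              lambda_qs = lambda_qs, ridge = ridge)
    if (!is.null(K)) {
      micro_to_macro <- cut_macroclusters(bs$merge_tree, K)
      point_macro <- micro_to_macro[cp$point_labels]
    }
  } else if (!is.null(K) && K != C) {
    rlang::abort("macrocluster cut requires the bootstrap merge tree.",
                 class = "defectometer_shape_error")
  }
  structure(list(grid = cp$grid, density = cp$density,
                 grid_labels = cp$grid_labels, modes = cp$modes,
                 point_labels = cp$point_labels,
                 stability = bs$stability, merge_tree = bs$merge_tree,
                 n_degenerate = bs$n_degenerate %||% 0L,
                 micro_to_macro = micro_to_macro,
                 point_macro = point_macro,
                 K = K %||% C, n_micro = C,
                 settings = list(n_grid = n_grid, n_boot = n_boot,
                                 seed = seed, lambda_qs = lambda_qs,
                                 n_localization = n_localization,
                                 ridge = ridge)),
            class = "pamm_fit")
}

#' @export
print.pamm_fit <- function(x, ...) {
  cat(sprintf("<pamm_fit> %d microclusters -> %d macroclusters (N = %d, grid = %d)\n",
              x$n_micro, x$K, length(x$point_labels),
              nrow(x$grid$points)))
  invisible(x)
}

#' @rdname pamm
#' @param x,object a `pamm_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.pamm_fit <- function(x, ...) {
  tibble::tibble(point = seq_along(x$point_labels),
                 micro = x$point_labels,
                 macro = x$point_macro)
}

#' @rdname pamm
#' @exportS3Method generics::glance
#' @export
glance.pamm_fit <- function(x, ...) {
  tibble::tibble(n_points = length(x$point_labels),
                 n_grid = nrow(x$grid$points),
                 n_micro = x$n_micro, n_macro = x$K,
                 n_boot = x$settings$n_boot,
                 n_degenerate = x$n_degenerate)
}

#' @rdname pamm
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.pamm_fit <- function(object, ...) {
  df <- tibble::tibble(PC1 = object$grid$points[, 1],
                       PC2 = object$grid$points[, 2],
                       macro = factor(object$micro_to_macro[object$grid_labels]),
                       density = object$density)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$macro,
                                   size = .data$density)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(0.3, 2.5)) +
    ggplot2::labs(colour = "macrostate", size = "density") +
    ggplot2::theme_minimal()
}

#' Export the microcluster dendrogram as Newick text
#'
#' @param fit a `pamm_fit` with a bootstrap merge tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_micro_newick <- function(fit, path) {
  if (is.null(fit$merge_tree)) {
    rlang::abort("fit has no merge tree (run with n_boot > 0).",
                 class = "defectometer_shape_error")
  }
  phy <- ape::as.phylo(fit$merge_tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
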