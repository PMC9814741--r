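# run code under a temporary RNG seed, restoring the caller's stream
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Balanced pooling of per-system SOAP datasets
#'
#' Draws exactly `n_per_system` vectors uniformly at random (without
#' replacement, seeded) from each system's dataset and concatenates them.
#' A shared, balanced pool is what the principal-component projection is
#' trained on, so that no system dominates the variance.
#'
#' @param datasets list of [spectra_dataset()] objects, one per system
#'   (or a single multi-system dataset, split internally on `system`).
#' @param n_per_system vectors to draw from each system.
#' @param seed integer seed for the draw.
#' @return A pooled [spectra_dataset()].
#' @export
pool_balanced <- function(datasets, n_per_system, seed = 0) {
  if (inherits(datasets, "spectra_dataset")) {
    sys <- unique(datasets$meta$system)
    datasets <- lapply(sys, function(s) {
      keep <- datasets$meta$system == s
      spectra_dataset(datasets$vectors[keep, , drop = FALSE],
                      datasets$meta[keep, ], datasets$params)
    })
  }
  sizes <- vapply(datasets, function(d) nrow(d$vectors), integer(1))
  small <- which(sizes < n_per_system)
  if (length(small)) {
    rlang::abort(sprintf(
      "system '%s' has only %d vectors; %d requested per system.",
      datasets[[small[1]]]$meta$system[1], sizes[small[1]], n_per_system),
      class = "defectometer_insufficient_data_error")
  }
  picked <- local_seed(seed, {
    lapply(datasets, function(d) sort(sample.int(nrow(d$vectors),
                                                 n_per_system)))
  })
  parts <- purrr::map2(datasets, picked, function(d, idx) {
    spectra_dataset(d$vectors[idx, , drop = FALSE], d$meta[idx, ], d$params)
  })
  bind_datasets(parts)
}

#' Fit the principal-component projection of a SOAP dataset
#'
#' Mean-centered PCA (no rescaling of components) with a deterministic sign
#' convention: the largest-magnitude loading of every component is made
#' positive, so projections are reproducible across platforms. Three
#' components are kept by default; with equilibrium SOAP data they
#' typically retain well over 90 percent of the total variance.
#'
#' @param pooled a [spectra_dataset()] (typically from [pool_balanced()]).
#' @param n_components number of principal axes to keep.
#' @return A `soap_projection` object: `mean` (D-vector), `components`
#'   (`k x D` orthonormal rows), `explained_ratio` (length `k`),
#'   `scores` (`N x k` training scores), `meta`, `total_variance`.
#' @export
fit_projection <- function(pooled, n_components = 3) {
  X <- pooled$vectors
  if (nrow(X) <= n_components) {
    rlang::abort("need more vectors than components.",
                 class = "defectometer_shape_error")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  total <- sum(var_all)
  rank_eff <- sum(pc$sdev > pc$sdev[1] * 1e-9)
  k <- n_components
  if (rank_eff < n_components) {
    rlang::warn(sprintf("data rank %d < %d requested components; reducing.",
                        rank_eff, n_components))
    k <- rank_eff
  }
  comp <- t(pc$rotation[, seq_len(k), drop = FALSE])     # k x D
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(comp[j, ]))
    if (comp[j, i_max] < 0) {
      comp[j, ] <- -comp[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(NULL, paste0("PC", seq_len(k)))
  structure(list(mean = pc$center, components = comp,
                 explained_ratio = var_all[seq_len(k)] / total,
                 scores = scores, meta = pooled$meta,
                 total_variance = total, variances = var_all,
                 params = pooled$params),
            class = "soap_projection")
}

#' @export
print.soap_projection <- function(x, ...) {
  cat(sprintf("<soap_projection> %d components, cumulative variance %.1f%%\n",
              nrow(x$components), 100 * sum(x$explained_ratio)))
  invisible(x)
}

#' Project SOAP vectors onto fitted principal axes
#'
#' @param model a `soap_projection` from [fit_projection()].
#' @param vectors `N x D` matrix (or a [spectra_dataset()]).
#' @return `N x k` matrix of scores.
#' @export
project <- function(model, vectors) {
  if (inherits(vectors, "spectra_dataset")) vectors <- vectors$vectors
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (ncol(vectors) != length(model$mean)) {
    rlang::abort("vector dimension does not match the fitted projection.",
                 class = "defectometer_shape_error")
  }
  out <- sweep(vectors, 2, model$mean) %*% t(model$components)
  colnames(out) <- paste0("PC", seq_len(nrow(model$components)))
  out
}

#' @rdname fit_projection
#' @param x a `soap_projection`.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.soap_projection <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$explained_ratio)),
                 std_dev = sqrt(x$variances[seq_along(x$explained_ratio)]),
                 explained_ratio = x$explained_ratio,
                 cumulative = cumsum(x$explained_ratio))
}

#' @rdname fit_projection
#' @exportS3Method generics::glance
#' @export
glance.soap_projection <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$components),
                 n_train = nrow(x$scores),
                 cumulative_variance = sum(x$explained_ratio),
                 total_variance = x$total_variance)
}

#' @rdname fit_projection
#' @exportS3Method generics::augment
#' @export
augment.soap_projection <- function(x, ...) {
  dplyr::bind_cols(x$meta, tibble::as_tibble(x$scores))
}

#' Scatter of the training scores on the first two principal components
#'
#' @param object a `soap_projection`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.soap_projection <- function(object, ...) {
  df <- augment.soap_projection(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$system)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * object$explained_ratio[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * object$explained_ratio[2]),
                  colour = "system") +
    ggplot2::theme_minimal()
}
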