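#' Frame-average SOAP fingerprint
#'
#' Averages the complex expansion coefficients over all `M` centers of a
#' frame and forms the power spectrum of the averaged coefficients. This is
#' the fingerprint of the average density, not the average of the
#' per-center spectra (the two differ whenever environments differ).
#'
#' @param coeffs complex `M x nmax x (lmax+1)^2` array from
#'   [soap_coefficients()].
#' @param params a [soap_params()]; defaults to the array's attribute.
#' @return A `soap_avg` object: the length-`D` fingerprint with attributes
#'   `level = "frame"` and `params`.
#' @export
frame_average <- function(coeffs, params = attr(coeffs, "params")) {
  stopifnot(inherits(params, "soap_params"))
  if (!is.array(coeffs) || length(dim(coeffs)) != 3 || dim(coeffs)[1] < 1) {
    rlang::abort("`coeffs` must be a non-empty M x nmax x (lmax+1)^2 array.",
                 class = "defectometer_shape_error")
  }
  if (dim(coeffs)[2] != params$nmax ||
      dim(coeffs)[3] != (params$lmax + 1)^2) {
    rlang::abort("coefficient array does not match `params`.",
                 class = "defectometer_params_error")
  }
  cbar <- array(colMeans(coeffs), dim = c(1, dim(coeffs)[2], dim(coeffs)[3]))
  p <- power_spectrum(cbar, params)
  structure(as.numeric(p), names = colnames(p), level = "frame",
            params = params, class = "soap_avg")
}

#' Simulation-average SOAP fingerprint
#'
#' Componentwise arithmetic mean of `T` frame-average fingerprints: the
#' compact global fingerprint of the equilibrium structure of one system.
#'
#' @param frame_avgs a list of frame-level `soap_avg` vectors, or a
#'   `T x D` matrix of frame averages (rows = frames).
#' @param system_id label attached to the result.
#' @return A `soap_avg` object with `level = "simulation"`.
#' @export
simulation_average <- function(frame_avgs, system_id = "system") {
  if (is.list(frame_avgs) && !is.matrix(frame_avgs)) {
    if (length(frame_avgs) == 0) {
      rlang::abort("need at least one frame average.",
                   class = "defectometer_shape_error")
    }
    params <- attr(frame_avgs[[1]], "params")
    m <- do.call(rbind, lapply(frame_avgs, as.numeric))
  } else {
    m <- frame_avgs
    params <- attr(frame_avgs, "params")
    if (is.null(dim(m)) || nrow(m) < 1) {
      rlang::abort("need at least one frame average.",
                   class = "defectometer_shape_error")
    }
  }
  structure(colMeans(m), level = "simulation", params = params,
            system_id = system_id, class = "soap_avg")
}

#' @export
print.soap_avg <- function(x, ...) {
  cat(sprintf("<soap_avg> %s-level fingerprint, D = %d, |p| = %.4g\n",
              attr(x, "level"), length(x), sqrt(sum(as.numeric(x)^2))))
  invisible(x)
}

#' Normalized linear SOAP kernel
#'
#' `K(a, b) = (a / |a|) . (b / |b|)`: 1 for identical environments, 0 for
#' non-overlapping ones. Any common rescaling of the inputs cancels.
#'
#' @param a,b SOAP spectra or averaged fingerprints of equal dimension.
#' @return Kernel value in `[-1, 1]` (non-negative for power spectra).
#' @export
soap_kernel <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    rlang::abort("kernel inputs must have equal dimension.",
                 class = "defectometer_shape_error")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    rlang::abort("cannot normalize a zero SOAP vector.",
                 class = "defectometer_numeric_error")
  }
  sum(a * b) / (na * nb)
}

#' SOAP kernel distance
#'
#' The metric induced by the normalized linear kernel:
#' `d = sqrt(K(a,a) + K(b,b) - 2 K(a,b)) = sqrt(2 - 2 K(a,b))`.
#' Zero for identical average environments, `sqrt(2)` for orthogonal ones.
#'
#' @inheritParams soap_kernel
#' @return Distance in `[0, sqrt(2)]`.
#' @export
soap_distance <- function(a, b) {
  sqrt(max(0, 2 - 2 * soap_kernel(a, b)))
}

#' Pairwise SOAP distance matrix between systems
#'
#' @param avgs list of simulation-average `soap_avg` fingerprints (or any
#'   equal-length numeric vectors), one per system.
#' @param labels system labels; default taken from the fingerprints' ids or
#'   list names.
#' @return A `soap_dist` object: symmetric zero-diagonal `S x S` matrix
#'   with `labels` and the shared `params` as attributes.
#' @export
soap_distance_matrix <- function(avgs, labels = NULL) {
  S <- length(avgs)
  if (S < 2) {
    rlang::abort("need at least two systems.",
                 class = "defectometer_shape_error")
  }
  if (is.null(labels)) {
    labels <- purrr::map_chr(seq_len(S), function(i) {
      id <- attr(avgs[[i]], "system_id")
      if (is.null(id)) names(avgs)[i] %||% sprintf("system%d", i) else id
    })
  }
  d <- matrix(0, S, S, dimnames = list(labels, labels))
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      d[i, j] <- d[j, i] <- soap_distance(avgs[[i]], avgs[[j]])
    }
  }
  structure(d, labels = labels, params = attr(avgs[[1]], "params"),
            class = c("soap_dist", "matrix"))
}

#' @export
print.soap_dist <- function(x, ...) {
  cat(sprintf("<soap_dist> %d systems\n", nrow(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Tidy a SOAP distance matrix into a long tibble
#'
#' @param x a `soap_dist` matrix.
#' @param ... unused.
#' @return Tibble with columns `from`, `to`, `d_soap` (upper triangle).
#' @exportS3Method generics::tidy
#' @export
tidy.soap_dist <- function(x, ...) {
  lab <- attr(x, "labels")
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(from = lab[idx[, 1]], to = lab[idx[, 2]],
                 d_soap = unclass(x)[idx])
}
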