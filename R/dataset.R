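#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||%
NULL

#' SOAP spectra dataset
#'
#' Container pairing an `N x D` matrix of per-center SOAP vectors with a
#' provenance tibble (`system`, `frame`, `center`, one row per vector).
#'
#' @param vectors numeric `N x D` matrix.
#' @param meta tibble with columns `system`, `frame`, `center` and `N` rows.
#' @param params the shared [soap_params()].
#' @return An object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(vectors, meta, params = NULL) {
  stopifnot(is.matrix(vectors))
  if (!all(c("system", "frame", "center") %in% names(meta)) ||
      nrow(meta) != nrow(vectors)) {
    rlang::abort("`meta` must have system/frame/center columns, one row per vector.",
                 class = "defectometer_shape_error")
  }
  if (any(!is.finite(vectors))) {
    rlang::abort("spectra must be finite.", class = "defectometer_numeric_error")
  }
  structure(list(vectors = vectors, meta = tibble::as_tibble(meta),
                 params = params),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d vectors x %d components, %d system(s)\n",
              nrow(x$vectors), ncol(x$vectors),
              length(unique(x$meta$system))))
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$vectors)

#' Concatenate spectra datasets
#'
#' @param ... `spectra_dataset` objects with equal dimension.
#' @return A single `spectra_dataset`.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1 && is.list(ds[[1]]) &&
      !inherits(ds[[1]], "spectra_dataset")) ds <- ds[[1]]
  D <- unique(vapply(ds, function(d) ncol(d$vectors), integer(1)))
  if (length(D) != 1) {
    rlang::abort("datasets have mismatched descriptor dimensions.",
                 class = "defectometer_shape_error")
  }
  spectra_dataset(do.call(rbind, lapply(ds, function(d) d$vectors)),
                  dplyr::bind_rows(lapply(ds, function(d) d$meta)),
                  params = ds[[1]]$params)
}

#' SOAP analysis of a whole trajectory
#'
#' Computes, frame by frame, the per-center SOAP power spectra, the
#' frame-average fingerprints (power spectrum of the center-averaged
#' expansion coefficients) and the simulation-average fingerprint.
#'
#' @param traj a [cg_trajectory()].
#' @param params a [soap_params()].
#' @param per_center keep per-center spectra (`TRUE`) or only the global
#'   fingerprints (`FALSE`, cheaper in memory).
#' @param n_quad radial quadrature nodes per neighbor.
#' @return A `soap_result` list: `dataset` (a [spectra_dataset()] or
#'   `NULL`), `frame_average` (`T x D` matrix), `simulation_average`
#'   (a `soap_avg`), `params`, `system_id`.
#' @export
soap_trajectory <- function(traj, params = soap_params(), per_center = TRUE,
                            n_quad = 40) {
  stopifnot(inherits(traj, "cg_trajectory"), inherits(params, "soap_params"))
  M <- n_monomers(traj); Tn <- n_frames(traj)
  D <- soap_dim(params)
  fa <- matrix(0, Tn, D)
  spectra <- if (per_center) matrix(0, M * Tn, D) else NULL
  for (t in seq_len(Tn)) {
    cf <- soap_coefficients(frame_coords(traj, t), traj$box, params,
                            n_quad = n_quad)
    fa[t, ] <- as.numeric(frame_average(cf, params))
    if (per_center) {
      spectra[((t - 1) * M + 1):(t * M), ] <- power_spectrum(cf, params)
    }
  }
  colnames(fa) <- soap_component_names(params)
  dataset <- NULL
  if (per_center) {
    colnames(spectra) <- colnames(fa)
    meta <- tibble::tibble(system = traj$system_id,
                           frame = rep(seq_len(Tn), each = M),
                           center = rep(seq_len(M), times = Tn))
    dataset <- spectra_dataset(spectra, meta, params)
  }
  structure(list(dataset = dataset, frame_average = fa,
                 simulation_average = simulation_average(
                   structure(fa, params = params), traj$system_id),
                 params = params, system_id = traj$system_id),
            class = "soap_result")
}

#' @export
print.soap_result <- function(x, ...) {
  cat(sprintf("<soap_result> '%s': %d frame fingerprints (D = %d)%s\n",
              x$system_id, nrow(x$frame_average), ncol(x$frame_average),
              if (is.null(x$dataset)) "" else
                sprintf(", %d per-center spectra", nrow(x$dataset$vectors))))
  invisible(x)
}

#' Write spectra (or any labelled SOAP vectors) to CSV
#'
#' Header row names the `(n, n', l)` triples; provenance columns precede
#' the components. The parameter block is written alongside as
#' `<path>.params` flat key-value text.
#'
#' @param ds a [spectra_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path) {
  df <- dplyr::bind_cols(ds$meta, tibble::as_tibble(ds$vectors))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(ds$params)) {
    write_params_block(ds$params, paste0(path, ".params"))
  }
  invisible(path)
}

write_params_block <- function(params, path) {
  writeLines(sprintf("%s: %s", names(unclass(params)),
                     vapply(unclass(params), format, character(1))), path)
  invisible(path)
}
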