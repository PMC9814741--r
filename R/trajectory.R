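#' Orthorhombic periodic box
#'
#' Container for the simulation cell of a coarse-grained frame. Only
#' orthorhombic (rectangular, no tilt) cells are supported; triclinic input
#' is rejected where it is encountered by the readers.
#'
#' @param lengths numeric length-3 vector of positive box edge lengths (nm).
#' @param periodic logical length-3 vector; which axes are periodic.
#' @return An object of class `cg_box`.
#' @examples
#' cg_box(c(10, 10, 12))
#' @export
cg_box <- function(lengths, periodic = c(TRUE, TRUE, TRUE)) {
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3 || anyNA(lengths) || any(!is.finite(lengths)) ||
      any(lengths <= 0)) {
    rlang::abort("`lengths` must be 3 positive finite numbers (nm).",
                 class = "defectometer_box_error")
  }
  periodic <- as.logical(periodic)
  if (length(periodic) != 3 || anyNA(periodic)) {
    rlang::abort("`periodic` must be 3 logicals.",
                 class = "defectometer_box_error")
  }
  structure(list(lengths = lengths, periodic = periodic), class = "cg_box")
}

#' @export
print.cg_box <- function(x, ...) {
  cat(sprintf("<cg_box> %.4f x %.4f x %.4f nm (periodic: %s)\n",
              x$lengths[1], x$lengths[2], x$lengths[3],
              paste(ifelse(x$periodic, "T", "F"), collapse = " ")))
  invisible(x)
}

#' Coarse-grained monomer-center trajectory
#'
#' Ordered frames of `M` monomer-center coordinates (nm) in an orthorhombic
#' periodic box. `M` is constant across frames and times are monotone
#' non-decreasing.
#'
#' @param coords numeric array `M x 3 x T` of coordinates in nm, or an
#'   `M x 3` matrix for a single frame.
#' @param box a [cg_box()] shared by all frames.
#' @param times numeric length-`T` frame times (ns). Defaults to
#'   `0:(T-1) * sampling_interval`.
#' @param system_id character label for the system.
#' @param sampling_interval numeric, time between frames (ns).
#' @return An object of class `cg_trajectory` with elements `coords`
#'   (`M x 3 x T` array), `box`, `times`, `system_id`, `sampling_interval`.
#' @export
cg_trajectory <- function(coords, box, times = NULL, system_id = "system",
                          sampling_interval = 1) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    rlang::abort("`coords` must be an M x 3 x T array.",
                 class = "defectometer_shape_error")
  }
  if (dim(coords)[1] < 1 || dim(coords)[3] < 1) {
    rlang::abort("trajectory needs at least one monomer and one frame.",
                 class = "defectometer_shape_error")
  }
  if (any(!is.finite(coords))) {
    rlang::abort("coordinates must be finite.",
                 class = "defectometer_shape_error")
  }
  stopifnot(inherits(box, "cg_box"))
  tt <- dim(coords)[3]
  if (is.null(times)) times <- (seq_len(tt) - 1) * sampling_interval
  if (length(times) != tt || is.unsorted(times)) {
    rlang::abort("`times` must be length T and non-decreasing.",
                 class = "defectometer_shape_error")
  }
  structure(list(coords = coords, box = box, times = as.numeric(times),
                 system_id = system_id,
                 sampling_interval = sampling_interval),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<cg_trajectory> '%s': %d monomers x %d frames, dt = %g ns\n",
              x$system_id, d[1], d[3], x$sampling_interval))
  print(x$box)
  invisible(x)
}

#' @export
dim.cg_trajectory <- function(x) dim(x$coords)

n_monomers <- function(traj) dim(traj$coords)[1]
n_frames <- function(traj) dim(traj$coords)[3]

frame_coords <- function(traj, t) traj$coords[, , t, drop = FALSE][, , 1]

#' Minimum-image displacement
#'
#' Wraps displacement vectors into the primary image of an orthorhombic
#' periodic box: each component of the result lies in `(-L/2, L/2]` for
#' periodic axes, and is untouched for non-periodic axes.
#'
#' @param d numeric `N x 3` matrix (or length-3 vector) of displacements (nm).
#' @param box a [cg_box()].
#' @return Displacements of the same shape, minimum-imaged.
#' @export
minimum_image <- function(d, box) {
  vec <- is.null(dim(d))
  if (vec) d <- matrix(d, ncol = 3)
  for (ax in 1:3) {
    if (!box$periodic[ax]) next
    L <- box$lengths[ax]
    d[, ax] <- d[, ax] - L * round(d[, ax] / L)
    low <- d[, ax] <= -L / 2          # push -L/2 to +L/2: component in (-L/2, L/2]
    d[low, ax] <- d[low, ax] + L
  }
  if (vec) d[1, ] else d
}

#' Monomer centers from bead groups
#'
#' Computes one center of geometry per monomer from the raw bead
#' coordinates of a frame. Each group of bead indices defines one monomer;
#' beads are minimum-image unwrapped relative to the group's first bead
#' (the molecule is assumed whole, i.e. no bead farther than half the
#' smallest box length from that reference), averaged, and the center is
#' wrapped back into `[0, L)` on periodic axes.
#'
#' @param raw_coords numeric `N x 3` matrix of bead coordinates (nm).
#' @param box a [cg_box()].
#' @param selection list of integer vectors of bead indices, one per
#'   monomer; groups must be non-empty, disjoint and in range.
#' @return `M x 3` matrix of monomer-center coordinates, `M = length(selection)`.
#' @export
compute_centers <- function(raw_coords, box, selection) {
  stopifnot(is.matrix(raw_coords), ncol(raw_coords) == 3)
  if (!is.list(selection) || length(selection) == 0) {
    rlang::abort("`selection` must be a non-empty list of index vectors.",
                 class = "defectometer_selection_error")
  }
  idx_all <- unlist(selection)
  if (length(idx_all) == 0 || any(idx_all < 1) ||
      any(idx_all > nrow(raw_coords)) || anyDuplicated(idx_all)) {
    rlang::abort("selection indices must be in range, non-empty and disjoint.",
                 class = "defectometer_selection_error")
  }
  half_min <- min(box$lengths[box$periodic], Inf) / 2
  centers <- matrix(NA_real_, length(selection), 3)
  for (g in seq_along(selection)) {
    idx <- selection[[g]]
    ref <- raw_coords[idx[1], ]
    disp <- minimum_image(sweep(raw_coords[idx, , drop = FALSE], 2, ref), box)
    if (max(sqrt(rowSums(disp^2))) > half_min) {
      rlang::abort(sprintf(
        "group %d spans more than half the box; molecule not whole.", g),
        class = "defectometer_ambiguity_error")
    }
    ctr <- ref + colMeans(disp)
    for (ax in 1:3) {
      if (box$periodic[ax]) ctr[ax] <- ctr[ax] %% box$lengths[ax]
    }
    centers[g, ] <- ctr
  }
  centers
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, xyz = "xyz", exyz = "xyz", gro = "gro",
         rlang::abort(sprintf("cannot guess trajectory format from '%s'.", path),
                      class = "defectometer_format_error"))
}

#' Read a coordinate trajectory
#'
#' Reads an extended-XYZ file (comment line carrying
#' `Lattice="ax 0 0 0 by 0 0 0 cz"` and optionally `Time=<ns>` and
#' `pbc="T T T"`) or a concatenated GRO frame sequence. Coordinates are
#' stored internally in nm; XYZ files default to Angstrom on disk and are
#' converted, GRO files are already in nm.
#'
#' @param path file path.
#' @param format `"xyz"`, `"gro"`, or `"auto"` (guess from extension).
#' @param unit on-disk length unit for XYZ input: `"angstrom"` (default) or
#'   `"nm"`. Ignored for GRO.
#' @param system_id label for the trajectory; defaults to the file stem.
#' @return A [cg_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "gro"),
                            unit = NULL, system_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file '%s' does not exist.", path),
                 class = "defectometer_io_error")
  }
  if (format == "auto") format <- guess_format(path)
  if (is.null(system_id)) {
    system_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path)
  if (format == "xyz") {
    if (is.null(unit)) unit <- "angstrom"
    read_xyz_lines(lines, unit = unit, system_id = system_id)
  } else {
    read_gro_lines(lines, system_id = system_id)
  }
}

parse_xyz_comment <- function(comment, lineno) {
  # key="..." or key=value tokens
  lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (length(lat) == 0) {
    rlang::abort(sprintf("line %d: missing Lattice field.", lineno),
                 class = "defectometer_format_error")
  }
  vals <- suppressWarnings(as.numeric(strsplit(
    trimws(sub('Lattice="([^"]*)"', "\\1", lat)), "\\s+")[[1]]))
  if (length(vals) != 9 || anyNA(vals)) {
    rlang::abort(sprintf("line %d: Lattice must hold 9 numbers.", lineno),
                 class = "defectometer_parse_error")
  }
  M <- matrix(vals, 3, 3, byrow = TRUE)
  if (any(abs(M[upper.tri(M) | lower.tri(M)]) > 1e-10)) {
    rlang::abort(sprintf("line %d: triclinic cells are unsupported.", lineno),
                 class = "defectometer_format_error")
  }
  tm <- regmatches(comment, regexpr('Time=[-0-9.eE+]+', comment))
  time <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else NA_real_
  pb <- regmatches(comment, regexpr('pbc="[^"]*"', comment))
  periodic <- if (length(pb)) {
    toupper(strsplit(trimws(sub('pbc="([^"]*)"', "\\1", pb)), "\\s+")[[1]]) == "T"
  } else c(TRUE, TRUE, TRUE)
  list(lengths = diag(M), time = time, periodic = periodic)
}

read_xyz_lines <- function(lines, unit, system_id) {
  scale <- switch(unit, angstrom = 0.1, nm = 1,
                  rlang::abort("`unit` must be 'angstrom' or 'nm'.",
                               class = "defectometer_format_error"))
  frames <- list(); times <- numeric(); boxinfo <- NULL
  i <- 1L; M0 <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    M <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(M) || M < 1) {
      rlang::abort(sprintf("line %d: expected particle count, got '%s'.",
                           i, lines[i]), class = "defectometer_parse_error")
    }
    if (is.na(M0)) M0 <- M
    if (M != M0) {
      rlang::abort(sprintf("line %d: frame has %d particles, expected %d.",
                           i, M, M0), class = "defectometer_shape_error")
    }
    if (i + 1L + M > length(lines)) {
      rlang::abort(sprintf("line %d: truncated frame.", i),
                   class = "defectometer_parse_error")
    }
    hdr <- parse_xyz_comment(lines[i + 1L], i + 1L)
    boxinfo <- hdr
    rows <- lines[(i + 2L):(i + 1L + M)]
    fields <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(fields) < 4)
    if (length(bad)) {
      rlang::abort(sprintf("line %d: malformed coordinate record.",
                           i + 1L + bad[1]),
                   class = "defectometer_parse_error")
    }
    xyz <- suppressWarnings(
      t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3))))
    if (anyNA(xyz)) {
      rlang::abort(sprintf("line %d: non-numeric coordinate.", i + 2L),
                   class = "defectometer_parse_error")
    }
    frames[[length(frames) + 1L]] <- xyz * scale
    times <- c(times, hdr$time)
    i <- i + 2L + M
  }
  if (!length(frames)) {
    rlang::abort("no frames found.", class = "defectometer_parse_error")
  }
  if (anyNA(times)) times <- seq_along(frames) - 1
  coords <- array(unlist(frames), dim = c(M0, 3, length(frames)))
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  cg_trajectory(coords, cg_box(boxinfo$lengths * scale, boxinfo$periodic),
                times = times, system_id = system_id,
                sampling_interval = dt)
}

read_gro_lines <- function(lines, system_id) {
  frames <- list(); times <- numeric(); box <- NULL
  i <- 1L; M0 <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
    M <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(M) || M < 1) {
      rlang::abort(sprintf("line %d: expected particle count.", i + 1L),
                   class = "defectometer_parse_error")
    }
    if (is.na(M0)) M0 <- M
    if (M != M0) {
      rlang::abort(sprintf("line %d: frame has %d particles, expected %d.",
                           i + 1L, M, M0), class = "defectometer_shape_error")
    }
    if (i + 2L + M > length(lines)) {
      rlang::abort(sprintf("line %d: truncated frame (missing box line?).", i),
                   class = "defectometer_format_error")
    }
    rows <- lines[(i + 2L):(i + 1L + M)]
    xyz <- t(vapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(c(substr(r, 21, 28), substr(r, 29, 36),
                                         substr(r, 37, 44))))
      v
    }, numeric(3), USE.NAMES = FALSE))
    if (anyNA(xyz)) {
      rlang::abort(sprintf("near line %d: malformed GRO coordinate record.",
                           i + 2L), class = "defectometer_parse_error")
    }
    bv <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + M]),
                                               "\\s+")[[1]]))
    if (length(bv) < 3 || anyNA(bv[1:3])) {
      rlang::abort(sprintf("line %d: missing or malformed box line.",
                           i + 2L + M), class = "defectometer_format_error")
    }
    if (length(bv) > 3 && any(abs(bv[-(1:3)]) > 1e-10)) {
      rlang::abort(sprintf("line %d: triclinic cells are unsupported.",
                           i + 2L + M), class = "defectometer_format_error")
    }
    box <- bv[1:3]
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, time)
    i <- i + 3L + M
  }
  if (!length(frames)) {
    rlang::abort("no frames found.", class = "defectometer_parse_error")
  }
  if (anyNA(times)) times <- seq_along(frames) - 1
  coords <- array(unlist(frames), dim = c(M0, 3, length(frames)))
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  cg_trajectory(coords, cg_box(box), times = times, system_id = system_id,
                sampling_interval = dt)
}

#' Write a coordinate trajectory
#'
#' Writes the dialects read by [read_trajectory()]: extended XYZ (Lattice,
#' Time and pbc fields on the comment line; coordinates printed with 8
#' decimals, box with 6) or a GRO frame sequence (fixed-width records, nm).
#'
#' @param traj a [cg_trajectory()].
#' @param path output file path.
#' @param format `"xyz"`, `"gro"` or `"auto"` (from extension).
#' @param unit on-disk unit for XYZ output (`"angstrom"` default, `"nm"`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "xyz", "gro"),
                             unit = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  M <- n_monomers(traj); Tn <- n_frames(traj)
  out <- character(0)
  if (format == "xyz") {
    if (is.null(unit)) unit <- "angstrom"
    scale <- switch(unit, angstrom = 10, nm = 1)
    L <- traj$box$lengths * scale
    lat <- sprintf('Lattice="%.6f 0 0 0 %.6f 0 0 0 %.6f"', L[1], L[2], L[3])
    pbc <- sprintf('pbc="%s"',
                   paste(ifelse(traj$box$periodic, "T", "F"), collapse = " "))
    for (t in seq_len(Tn)) {
      xyz <- frame_coords(traj, t) * scale
      out <- c(out, as.character(M),
               sprintf("%s Time=%.6f %s", lat, traj$times[t], pbc),
               sprintf("CG %.8f %.8f %.8f", xyz[, 1], xyz[, 2], xyz[, 3]))
    }
  } else {
    L <- traj$box$lengths
    for (t in seq_len(Tn)) {
      xyz <- frame_coords(traj, t)
      out <- c(out,
               sprintf("%s t= %.6f", traj$system_id, traj$times[t]),
               sprintf("%5d", M),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       seq_len(M) %% 100000L, "MON", "CG",
                       seq_len(M) %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]),
               sprintf("%10.6f%10.6f%10.6f", L[1], L[2], L[3]))
    }
  }
  tryCatch(writeLines(out, path),
           error = function(e) rlang::abort(
             sprintf("cannot write '%s': %s", path, conditionMessage(e)),
             class = "defectometer_io_error"))
  invisible(path)
}
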