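#' Specification of a synthetic assembly trajectory
#'
#' Desk-scale generators emulating the assembly classes on which the
#' defect-detection workflow operates: a 1-D stack crossing the periodic
#' boundary (`fiber`), a 2-D triangular lattice in gel- or liquid-like
#' regimes (`planar`), a spherical micellar shell (`shell`) and a filled
#' droplet with surface and bulk monomers (`ball`). Every generator
#' returns monomer-center coordinates plus planted ground-truth state
#' labels, and is bit-reproducible under a fixed seed.
#'
#' @param kind one of `"fiber"`, `"planar"`, `"shell"`, `"ball"`.
#' @param n_monomers number of monomers.
#' @param n_frames number of frames.
#' @param geometry named list of kind-specific lengths (nm), merged over
#'   defaults: fiber takes `spacing`, `defect_offset`, `adsorbed_radius`,
#'   `width`; planar takes `lattice`, `nx`; shell takes `radius`; ball
#'   takes `radius`, `thickness`.
#' @param state_fractions planted state fractions (must sum to 1):
#'   ordered/defect/adsorbed for fibers, gel/liquid for planar, surface
#'   only for shells, surface/bulk implied by geometry for balls.
#' @param planted_P optional row-stochastic matrix driving per-frame state
#'   switching (fiber: 3 states; ball: surface/bulk). `NULL` keeps the
#'   planted labels static.
#' @param thermal_noise positional jitter sigma (nm) applied every frame.
#' @param diffusion per-frame in-surface random-walk step (nm) for
#'   adsorbed/liquid/surface monomers.
#' @param run_length fiber only: planted non-ordered states occur in
#'   contiguous runs of up to this many monomers (cooperative, domain-like
#'   defects); 1 scatters them independently.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("fiber", "planar", "shell", "ball"),
                           n_monomers = 200, n_frames = 50,
                           geometry = list(), state_fractions = NULL,
                           planted_P = NULL, thermal_noise = NULL,
                           diffusion = NULL, run_length = 10, seed = 0) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    fiber = list(geometry = list(spacing = 0.3, defect_offset = 0.35,
                                 adsorbed_radius = 1.0, width = 6),
                 state_fractions = c(ordered = 1, defect = 0, adsorbed = 0),
                 thermal_noise = 0.03, diffusion = 0.05),
    planar = list(geometry = list(lattice = 0.5, nx = NULL),
                  state_fractions = c(gel = 1, liquid = 0),
                  thermal_noise = 0.02, diffusion = 0.05),
    shell = list(geometry = list(radius = 2.5),
                 state_fractions = c(surface = 1),
                 thermal_noise = 0.05, diffusion = 0.05),
    ball = list(geometry = list(radius = 2, thickness = 0.5),
                state_fractions = NULL,
                thermal_noise = 0.05, diffusion = 0.05))
  geometry <- utils::modifyList(defaults$geometry, geometry)
  state_fractions <- state_fractions %||% defaults$state_fractions
  thermal_noise <- thermal_noise %||% defaults$thermal_noise
  diffusion <- diffusion %||% defaults$diffusion
  if (!is.null(state_fractions)) {
    if (any(state_fractions < 0) ||
        abs(sum(state_fractions) - 1) > 1e-8) {
      rlang::abort("state fractions must be non-negative and sum to 1.",
                   class = "defectometer_params_error")
    }
  }
  if (!is.null(planted_P)) {
    if (any(planted_P < 0) || any(abs(rowSums(planted_P) - 1) > 1e-8)) {
      rlang::abort("planted_P must be row-stochastic.",
                   class = "defectometer_params_error")
    }
  }
  lens <- unlist(geometry[!vapply(geometry, is.null, logical(1))])
  if (any(lens <= 0)) {
    rlang::abort("geometry lengths must be positive.",
                 class = "defectometer_params_error")
  }
  if (n_monomers < 1 || n_frames < 1) {
    rlang::abort("need at least one monomer and one frame.",
                 class = "defectometer_params_error")
  }
  structure(list(kind = kind, n_monomers = as.integer(n_monomers),
                 n_frames = as.integer(n_frames), geometry = geometry,
                 state_fractions = state_fractions, planted_P = planted_P,
                 thermal_noise = thermal_noise, diffusion = diffusion,
                 run_length = as.integer(max(1, run_length)),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %s: %d monomers x %d frames (seed %d)\n",
              x$kind, x$n_monomers, x$n_frames, x$seed))
  invisible(x)
}

# largest-remainder apportionment of n among fractions (ties: lower index)
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(-(raw - counts), seq_along(raw))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

# planted initial labels: seeded random placement of the state counts;
# with run_length > 1, states 2.. are laid down in contiguous runs
planted_labels <- function(fractions, n, seed, run_length = 1) {
  counts <- largest_remainder(fractions, n)
  if (run_length <= 1) {
    lab <- rep(seq_along(counts), times = counts)
    return(local_seed(seed, sample(lab)))
  }
  units <- list()
  for (s in seq_along(counts)[-1]) {
    left <- counts[s]
    while (left > 0) {
      take <- min(run_length, left)
      units <- c(units, list(rep(s, take)))
      left <- left - take
    }
  }
  units <- c(units, as.list(rep(1L, counts[1])))
  local_seed(seed, unlist(units[sample.int(length(units))]))
}

# state label matrix M x T: static, or evolved under planted_P
evolve_states <- function(init, planted_P, n_frames, seed) {
  if (is.null(planted_P) || n_frames == 1) {
    matrix(init, length(init), n_frames)
  } else {
    simulate_markov_states(planted_P, init, n_frames, seed = seed)
  }
}

synthetic_result <- function(coords, box, labels, spec, state_names) {
  traj <- cg_trajectory(coords, box, system_id = sprintf("%s_seed%d",
                                                         spec$kind,
                                                         spec$seed),
                        sampling_interval = 1)
  structure(list(trajectory = traj, labels = labels, spec = spec,
                 state_names = state_names),
            class = "synthetic_assembly")
}

#' @export
print.synthetic_assembly <- function(x, ...) {
  print(x$spec)
  print(x$trajectory)
  invisible(x)
}

#' Ground-truth labels of a synthetic assembly as a tibble
#'
#' @param x a `synthetic_assembly`.
#' @param ... unused.
#' @return Tibble with columns `frame`, `center`, `state`, `state_name`.
#' @exportS3Method generics::tidy
#' @export
tidy.synthetic_assembly <- function(x, ...) {
  M <- nrow(x$labels); Tn <- ncol(x$labels)
  tibble::tibble(frame = rep(seq_len(Tn), each = M),
                 center = rep(seq_len(M), times = Tn),
                 state = as.vector(x$labels),
                 state_name = x$state_names[as.vector(x$labels)])
}

#' Generate a 1-D stack (supramolecular fiber) with planted defects
#'
#' Monomers occupy sites of a 1-D stack along z that crosses the periodic
#' boundary. Ordered monomers sit on the stack axis at the given spacing.
#' A defect monomer stays at its site but is displaced laterally by
#' `defect_offset` (one stack radius), which detaches it from the tight
#' stacking contacts and reduces its coordination. Adsorbed monomers leave
#' the stack (their site becomes a vacancy) for a cylindrical surface of
#' radius `adsorbed_radius` around the axis, where they perform a seeded
#' random walk. All monomers receive Gaussian thermal jitter each frame.
#' With `planted_P` set, states switch from frame to frame and monomers
#' adopt the placement rule of their current state.
#'
#' @param spec a [synthetic_spec()] with `kind = "fiber"` and
#'   `state_fractions` of length 3 (ordered, defect, adsorbed).
#' @return A `synthetic_assembly`: `trajectory` ([cg_trajectory()]),
#'   `labels` (`M x T` planted states), `spec`, `state_names`.
#' @export
gen_fiber <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "fiber")
  g <- spec$geometry
  n <- spec$n_monomers; Tn <- spec$n_frames
  fr <- spec$state_fractions
  if (length(fr) != 3) {
    rlang::abort("fiber needs 3 state fractions (ordered, defect, adsorbed).",
                 class = "defectometer_params_error")
  }
  init <- planted_labels(fr, n, spec$seed, run_length = spec$run_length)
  labels <- evolve_states(init, spec$planted_P, Tn, spec$seed + 1)
  z_site <- (seq_len(n) - 1) * g$spacing
  Lz <- n * g$spacing                     # stack crosses the PBC along z
  cx <- g$width / 2
  box <- cg_box(c(g$width, g$width, Lz))
  coords <- array(NA_real_, dim = c(n, 3, Tn))
  local_seed(spec$seed + 2, {
    azim <- stats::runif(n, 0, 2 * pi)    # per-monomer lateral direction
    ads_phi <- stats::runif(n, 0, 2 * pi)
    ads_z <- stats::runif(n, 0, Lz)
    for (t in seq_len(Tn)) {
      st <- labels[, t]
      x <- rep(cx, n); y <- rep(cx, n); z <- z_site
      d <- st == 2
      x[d] <- cx + g$defect_offset * cos(azim[d])
      y[d] <- cx + g$defect_offset * sin(azim[d])
      a <- st == 3
      if (any(a)) {
        x[a] <- cx + g$adsorbed_radius * cos(ads_phi[a])
        y[a] <- cx + g$adsorbed_radius * sin(ads_phi[a])
        z[a] <- ads_z[a]
      }
      xyz <- cbind(x, y, z) +
        matrix(stats::rnorm(3 * n, sd = spec$thermal_noise), n, 3)
      xyz[, 3] <- xyz[, 3] %% Lz
      coords[, , t] <- xyz
      # adsorbed monomers random-walk on the cylinder surface
      ads_phi <- ads_phi + stats::rnorm(n, sd = spec$diffusion /
                                          g$adsorbed_radius)
      ads_z <- (ads_z + stats::rnorm(n, sd = spec$diffusion)) %% Lz
    }
  })
  synthetic_result(coords, box, labels, spec,
                   c("ordered", "defect", "adsorbed"))
}

#' Generate a planar (bilayer-like) triangular lattice
#'
#' Head-center monomers on an `nx x ny` triangular lattice in a periodic
#' x-y box. Gel-state monomers only jitter thermally; liquid-state
#' monomers additionally diffuse by a seeded 2-D random walk, melting the
#' local order. A mixed regime plants the gel/liquid labels in contiguous
#' stripes along x.
#'
#' @param spec a [synthetic_spec()] with `kind = "planar"` and
#'   `state_fractions` of length 2 (gel, liquid). `geometry$nx` fixes the
#'   lattice columns (default: near-square).
#' @return A `synthetic_assembly`; `n_monomers` is rounded to `nx * ny`.
#' @export
gen_planar <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "planar")
  g <- spec$geometry
  fr <- spec$state_fractions
  if (length(fr) != 2) {
    rlang::abort("planar needs 2 state fractions (gel, liquid).",
                 class = "defectometer_params_error")
  }
  a <- g$lattice
  nx <- g$nx %||% max(2L, round(sqrt(spec$n_monomers)))
  ny <- max(2L, round(spec$n_monomers / nx))
  n <- as.integer(nx * ny); Tn <- spec$n_frames
  # triangular lattice: rows offset by a/2, vertical pitch a*sqrt(3)/2
  ix <- rep(seq_len(nx) - 1, times = ny)
  iy <- rep(seq_len(ny) - 1, each = nx)
  x0 <- ix * a + (iy %% 2) * a / 2
  y0 <- iy * a * sqrt(3) / 2
  Lx <- nx * a; Ly <- ny * a * sqrt(3) / 2
  Lz <- 6
  box <- cg_box(c(Lx, Ly, Lz))
  # contiguous stripes along x for the planted states
  n_gel <- largest_remainder(fr, n)[1]
  init <- ifelse(rank(ix * 1e6 + iy, ties.method = "first") <= n_gel, 1L, 2L)
  labels <- matrix(init, n, Tn)
  coords <- array(NA_real_, dim = c(n, 3, Tn))
  local_seed(spec$seed + 2, {
    wx <- x0; wy <- y0
    for (t in seq_len(Tn)) {
      xyz <- cbind(wx %% Lx, wy %% Ly, Lz / 2) +
        matrix(stats::rnorm(3 * n, sd = spec$thermal_noise), n, 3)
      xyz[, 3] <- pmin(pmax(xyz[, 3], 0), Lz)
      coords[, , t] <- xyz
      liq <- init == 2
      if (any(liq)) {
        wx[liq] <- wx[liq] + stats::rnorm(sum(liq), sd = spec$diffusion)
        wy[liq] <- wy[liq] + stats::rnorm(sum(liq), sd = spec$diffusion)
      }
    }
  })
  synthetic_result(coords, box, labels, spec, c("gel", "liquid"))
}

# quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  ct <- 1 - 2 * i / n
  st <- sqrt(pmax(0, 1 - ct^2))
  cbind(st * cos(phi), st * sin(phi), ct)
}

#' Generate a spherical micellar shell
#'
#' Monomers quasi-uniform on a sphere (Fibonacci lattice) with radial and
#' tangential thermal jitter and a seeded random walk on the surface.
#' All monomers carry the single planted state `surface`.
#'
#' @param spec a [synthetic_spec()] with `kind = "shell"`;
#'   `geometry$radius` is the shell radius (nm).
#' @return A `synthetic_assembly`.
#' @export
gen_shell <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "shell")
  R <- spec$geometry$radius
  n <- spec$n_monomers; Tn <- spec$n_frames
  L <- 2 * R + 4
  box <- cg_box(c(L, L, L))
  u <- fibonacci_sphere(n)
  labels <- matrix(1L, n, Tn)
  coords <- array(NA_real_, dim = c(n, 3, Tn))
  local_seed(spec$seed + 2, {
    for (t in seq_len(Tn)) {
      pos <- u * R + matrix(stats::rnorm(3 * n, sd = spec$thermal_noise),
                            n, 3)
      coords[, , t] <- sweep(pos, 2, c(L, L, L) / 2, "+")
      # tangential surface diffusion: random step, re-projected
      step <- matrix(stats::rnorm(3 * n, sd = spec$diffusion / R), n, 3)
      step <- step - u * rowSums(step * u)   # remove radial part
      u <- u + step
      u <- u / sqrt(rowSums(u^2))
    }
  })
  synthetic_result(coords, box, labels, spec, "surface")
}

#' Generate a filled spherical droplet with surface and bulk monomers
#'
#' Monomers uniform in a sphere of radius `R` (inverse-CDF radial
#' sampling on the Fibonacci directions), with thermal jitter. The
#' planted ground truth labels a monomer `surface` when its home radius
#' exceeds `R - thickness`, `bulk` otherwise; the expected surface
#' fraction is `1 - (1 - thickness/R)^3`. An optional 2x2 `planted_P`
#' drives surface/bulk exchange by resampling the home position in the
#' destination region.
#'
#' @param spec a [synthetic_spec()] with `kind = "ball"`.
#' @return A `synthetic_assembly` with states `surface` (1), `bulk` (2).
#' @export
gen_ball <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "ball")
  R <- spec$geometry$radius; thick <- spec$geometry$thickness
  if (thick >= R) {
    rlang::abort("shell thickness must be below the radius.",
                 class = "defectometer_params_error")
  }
  n <- spec$n_monomers; Tn <- spec$n_frames
  L <- 2 * R + 4
  box <- cg_box(c(L, L, L))
  rin <- R - thick
  coords <- array(NA_real_, dim = c(n, 3, Tn))
  labels <- matrix(NA_integer_, n, Tn)
  local_seed(spec$seed + 2, {
    u <- fibonacci_sphere(n)[sample.int(n), , drop = FALSE]
    r <- R * stats::runif(n)^(1 / 3)      # uniform-in-volume radii
    state <- ifelse(r > rin, 1L, 2L)
    for (t in seq_len(Tn)) {
      if (!is.null(spec$planted_P) && t > 1) {
        u_sw <- stats::runif(n)
        thr <- spec$planted_P[cbind(state, state)]
        switch_me <- u_sw > thr           # leave current state
        if (any(switch_me)) {
          state[switch_me] <- 3L - state[switch_me]
          to_surf <- switch_me & state == 1L
          to_bulk <- switch_me & state == 2L
          r[to_surf] <- rin + (R - rin) *
            stats::runif(sum(to_surf))^(1 / 3)
          r[to_bulk] <- rin * stats::runif(sum(to_bulk))^(1 / 3)
        }
      }
      labels[, t] <- state
      pos <- u * r + matrix(stats::rnorm(3 * n, sd = spec$thermal_noise),
                            n, 3)
      coords[, , t] <- sweep(pos, 2, c(L, L, L) / 2, "+")
      # slow tangential drift so frames decorrelate
      step <- matrix(stats::rnorm(3 * n, sd = spec$diffusion /
                                    pmax(r, 0.1)), n, 3)
      step <- step - u * rowSums(step * u)
      u <- u + step
      u <- u / sqrt(rowSums(u^2))
    }
  })
  synthetic_result(coords, box, labels, spec, c("surface", "bulk"))
}

#' Generate any synthetic assembly from its spec
#'
#' @param spec a [synthetic_spec()].
#' @return A `synthetic_assembly`.
#' @export
generate_assembly <- function(spec) {
  switch(spec$kind,
         fiber = gen_fiber(spec), planar = gen_planar(spec),
         shell = gen_shell(spec), ball = gen_ball(spec))
}

#' Write a synthetic assembly to disk
#'
#' Emits the extended-XYZ trajectory, a labels CSV (`frame`, `center`,
#' `state`, `state_name`) and the generator settings as a flat key-value
#' sidecar.
#'
#' @param x a `synthetic_assembly`.
#' @param prefix path prefix; writes `<prefix>.xyz`, `<prefix>_labels.csv`,
#'   `<prefix>_spec.txt`.
#' @return The three paths, invisibly.
#' @export
write_assembly <- function(x, prefix) {
  p1 <- paste0(prefix, ".xyz")
  p2 <- paste0(prefix, "_labels.csv")
  p3 <- paste0(prefix, "_spec.txt")
  write_trajectory(x$trajectory, p1, format = "xyz")
  utils::write.csv(tidy.synthetic_assembly(x), p2, row.names = FALSE)
  s <- x$spec
  flat <- c(kind = s$kind, n_monomers = s$n_monomers,
            n_frames = s$n_frames,
            stats::setNames(unlist(s$geometry),
                            paste0("geometry.", names(unlist(s$geometry)))),
            stats::setNames(s$state_fractions,
                            paste0("fraction.",
                                   names(s$state_fractions) %||%
                                     seq_along(s$state_fractions))),
            thermal_noise = s$thermal_noise, diffusion = s$diffusion,
            seed = s$seed)
  writeLines(sprintf("%s: %s", names(flat), as.character(flat)), p3)
  invisible(c(p1, p2, p3))
}
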