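#' Per-monomer state sequences
#'
#' Reassembles flat per-(frame, center) macrostate labels into an `M x T`
#' matrix of per-monomer state sequences, preserving center identity
#' across frames.
#'
#' @param labels integer state labels, or a tibble/data.frame with columns
#'   `frame`, `center` and `state` (records may arrive in any order).
#' @param M,T monomer and frame counts (required for flat `labels`; taken
#'   from the records otherwise).
#' @param sampling_interval time between frames (ns).
#' @return A `state_trajectory` object: `labels` (`M x T` integer matrix),
#'   `sampling_interval`.
#' @export
state_trajectories <- function(labels, M = NULL, T = NULL,
                               sampling_interval = 1) {
  if (is.data.frame(labels)) {
    need <- c("frame", "center", "state")
    if (!all(need %in% names(labels))) {
      rlang::abort("records need columns frame, center, state.",
                   class = "defectometer_index_error")
    }
    M <- M %||% max(labels$center)
    T <- T %||% max(labels$frame)
    if (nrow(labels) != M * T ||
        anyDuplicated(labels[c("frame", "center")]) ||
        any(labels$frame < 1 | labels$frame > T) ||
        any(labels$center < 1 | labels$center > M)) {
      rlang::abort("records must cover every (frame, center) pair exactly once.",
                   class = "defectometer_index_error")
    }
    lab <- matrix(NA_integer_, M, T)
    lab[cbind(labels$center, labels$frame)] <- as.integer(labels$state)
  } else {
    if (is.null(M) || is.null(T)) {
      rlang::abort("M and T are required for flat label input.",
                   class = "defectometer_index_error")
    }
    if (length(labels) != M * T) {
      rlang::abort(sprintf("expected %d labels (M*T), got %d.",
                           M * T, length(labels)),
                   class = "defectometer_index_error")
    }
    # flat order: frame-major blocks of M centers (matches soap_trajectory)
    lab <- matrix(as.integer(labels), M, T)
  }
  structure(list(labels = lab, sampling_interval = sampling_interval),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory> %d monomers x %d frames, %d state(s)\n",
              nrow(x$labels), ncol(x$labels),
              length(unique(as.vector(x$labels)))))
  invisible(x)
}

#' Equilibrium state populations
#'
#' Fraction of all `M * T` (monomer, frame) observations found in each
#' state.
#'
#' @param st a [state_trajectories()] object (or a label matrix).
#' @param K number of states; defaults to the largest observed label.
#' @return Tibble with columns `state` and `population` (sums to 1).
#' @export
state_populations <- function(st, K = NULL) {
  lab <- if (inherits(st, "state_trajectory")) st$labels else st
  K <- K %||% max(lab)
  counts <- tabulate(as.vector(lab), nbins = K)
  tibble::tibble(state = seq_len(K), population = counts / sum(counts))
}

#' Transition probability matrix from state sequences
#'
#' Counts transitions `state(t) -> state(t + lag)` over all monomers and
#' admissible frame pairs and row-normalizes to a stochastic matrix
#' (self-transitions kept on the diagonal). States never observed as a
#' source get an undefined (all-`NA`) row, excluded from the
#' row-stochasticity contract.
#'
#' @param st a [state_trajectories()] object (or a label matrix).
#' @param lag transition lag in frames (default 1, i.e. one sampling
#'   interval).
#' @param K number of states; defaults to the largest observed label.
#' @return A `transition_model`: `populations` tibble, `P` (`K x K`
#'   row-stochastic, `NA` rows undefined), `counts`, `lag`, `lag_ns`.
#' @export
transition_matrix <- function(st, lag = 1, K = NULL) {
  lab <- if (inherits(st, "state_trajectory")) st$labels else st
  dt <- if (inherits(st, "state_trajectory")) st$sampling_interval else 1
  Tn <- ncol(lab)
  if (Tn <= lag) {
    rlang::abort("need more frames than the lag.",
                 class = "defectometer_shape_error")
  }
  K <- K %||% max(lab)
  from <- as.vector(lab[, seq_len(Tn - lag), drop = FALSE])
  to <- as.vector(lab[, (1 + lag):Tn, drop = FALSE])
  counts <- matrix(0L, K, K)
  tab <- table(factor(from, levels = seq_len(K)),
               factor(to, levels = seq_len(K)))
  counts[] <- as.integer(tab)
  P <- matrix(NA_real_, K, K)
  rs <- rowSums(counts)
  ok <- rs > 0
  P[ok, ] <- counts[ok, , drop = FALSE] / rs[ok]
  structure(list(populations = state_populations(lab, K = K),
                 P = P, counts = counts, lag = lag, lag_ns = lag * dt),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %d states, lag = %d frame(s) (%g ns)\n",
              nrow(x$P), x$lag, x$lag_ns))
  print(round(x$P, 3))
  invisible(x)
}

#' Off-diagonal interconversion matrix
#'
#' Row-renormalized transition probabilities excluding self-transitions:
#' the relative probability that a monomer leaving state a lands in state
#' b. Rows with no outgoing transitions are `NA`.
#'
#' @param tm a `transition_model`.
#' @return `K x K` matrix with zero diagonal.
#' @export
interconversion_matrix <- function(tm) {
  cnt <- tm$counts
  diag(cnt) <- 0L
  out <- matrix(NA_real_, nrow(cnt), ncol(cnt))
  rs <- rowSums(cnt)
  ok <- rs > 0
  out[ok, ] <- cnt[ok, , drop = FALSE] / rs[ok]
  out[!ok, ] <- NA_real_
  if (any(!ok)) out[!ok, ] <- NA_real_
  out
}

#' @rdname transition_matrix
#' @param x a `transition_model`.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.transition_model <- function(x, ...) {
  K <- nrow(x$P)
  tibble::tibble(from = rep(seq_len(K), times = K),
                 to = rep(seq_len(K), each = K),
                 count = as.vector(x$counts),
                 probability = as.vector(x$P))
}

#' @rdname transition_matrix
#' @exportS3Method generics::glance
#' @export
glance.transition_model <- function(x, ...) {
  tibble::tibble(n_states = nrow(x$P),
                 n_transitions = sum(x$counts),
                 lag_frames = x$lag, lag_ns = x$lag_ns,
                 diag_mass = sum(diag(x$counts)) / max(1, sum(x$counts)))
}

#' Export a transition model as a JSON report
#'
#' @param tm a `transition_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transitions_json <- function(tm, path) {
  jsonlite::write_json(
    list(populations = tm$populations$population,
         P = tm$P, counts = tm$counts, lag_ns = tm$lag_ns),
    path, auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Export the interconversion diagram as a DOT graph
#'
#' Nodes are macrostates annotated with their populations; directed edges
#' carry the off-diagonal, row-renormalized transition probabilities.
#'
#' @param tm a `transition_model`.
#' @param path output `.dot` path.
#' @param min_probability drop edges below this weight.
#' @return `path`, invisibly.
#' @export
write_interconversion_dot <- function(tm, path, min_probability = 0) {
  inter <- interconversion_matrix(tm)
  K <- nrow(inter)
  pops <- tm$populations$population
  lines <- c("digraph interconversion {",
             sprintf('  s%d [label="state %d\\n%.1f%%"];',
                     seq_len(K), seq_len(K), 100 * pops))
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      if (a != b && !is.na(inter[a, b]) && inter[a, b] > min_probability) {
        lines <- c(lines, sprintf('  s%d -> s%d [label="%.3f"];',
                                  a, b, inter[a, b]))
      }
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Simulate state sequences from a planted Markov chain
#'
#' Utility for generators and tests: evolves `M` independent monomers for
#' `T` frames under a row-stochastic transition matrix `P`, starting from
#' given initial states.
#'
#' @param P `K x K` row-stochastic matrix.
#' @param init integer vector of `M` initial states.
#' @param T number of frames.
#' @param seed integer seed.
#' @return `M x T` integer label matrix (first column = `init`).
#' @export
simulate_markov_states <- function(P, init, T, seed = 0) {
  K <- nrow(P)
  if (any(abs(rowSums(P) - 1) > 1e-8) || any(P < 0)) {
    rlang::abort("P must be row-stochastic.",
                 class = "defectometer_params_error")
  }
  M <- length(init)
  lab <- matrix(NA_integer_, M, T)
  lab[, 1] <- as.integer(init)
  if (T > 1) {
    local_seed(seed, {
      cum <- t(apply(P, 1, cumsum))
      for (t in 2:T) {
        u <- stats::runif(M)
        prev <- lab[, t - 1]
        nxt <- integer(M)
        for (s in seq_len(K)) {
          sel <- prev == s
          if (any(sel)) {
            nxt[sel] <- findInterval(u[sel], cum[s, ]) + 1L
          }
        }
        lab[, t] <- pmin(nxt, K)
      }
    })
  }
  lab
}
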