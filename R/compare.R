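#' Single-linkage hierarchical classification of systems
#'
#' Agglomerative single-linkage clustering of the pairwise SOAP distance
#' matrix: at each step the two clusters with the smallest minimum
#' inter-cluster distance are merged. Tie-breaking is deterministic: among
#' equal-distance pairs the one whose smallest leaf index is lowest wins
#' (then the second cluster's smallest leaf). Merge heights are
#' non-decreasing, so the tree is a valid dendrogram.
#'
#' @param dm a [soap_distance_matrix()] result (or any symmetric matrix
#'   with zero diagonal and dimnames).
#' @return A `linkage_tree` object with `merge`, `height`, `order`,
#'   `labels` (the `hclust` fields, plus `method = "single"`); convert
#'   with [as.hclust()] or export with [write_system_newick()].
#' @export
single_linkage <- function(dm) {
  d <- unclass(dm)
  S <- nrow(d)
  if (is.null(S) || S < 2) {
    rlang::abort("need at least two systems.",
                 class = "defectometer_shape_error")
  }
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0)) {
    rlang::abort("distance matrix must be symmetric with zero diagonal.",
                 class = "defectometer_shape_error")
  }
  labels <- rownames(d) %||% paste0("system", seq_len(S))
  merge <- matrix(0L, S - 1, 2)
  height <- numeric(S - 1)
  # distances between active clusters, indexed by slot (leaves 1..S, then
  # one new slot per merge)
  DM <- matrix(Inf, 2 * S - 1, 2 * S - 1)
  DM[seq_len(S), seq_len(S)] <- d
  diag(DM) <- Inf
  alive <- c(rep(TRUE, S), rep(FALSE, S - 1))
  minleaf <- c(seq_len(S), rep(NA_integer_, S - 1))
  for (step in seq_len(S - 1)) {
    idx <- which(alive)
    sub <- DM[idx, idx, drop = FALSE]
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on smallest leaf indices
    a_leaf <- pmin(minleaf[idx[cand[, 1]]], minleaf[idx[cand[, 2]]])
    b_leaf <- pmax(minleaf[idx[cand[, 1]]], minleaf[idx[cand[, 2]]])
    pick <- order(a_leaf, b_leaf)[1]
    ci <- idx[cand[pick, 1]]; cj <- idx[cand[pick, 2]]
    if (minleaf[ci] > minleaf[cj]) { tmp <- ci; ci <- cj; cj <- tmp }
    new <- S + step
    pair <- c(node_id_of(ci, S), node_id_of(cj, S))
    # hclust convention: leaves (negative) first, ascending by leaf index
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    height[step] <- h
    minleaf[new] <- min(minleaf[ci], minleaf[cj])
    alive[c(ci, cj)] <- FALSE
    # single linkage: distance to every other active cluster = min
    oth <- which(alive)
    if (length(oth)) {
      DM[new, oth] <- DM[oth, new] <- pmin(DM[ci, oth], DM[cj, oth])
    }
    alive[new] <- TRUE
  }
  ord <- tree_leaf_order(merge, minleaf, S)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "single",
                 call = match.call(), dist.method = "d_soap"),
            class = c("linkage_tree", "hclust"))
}

# hclust node coding: leaves are -i, internal nodes are +step
node_id_of <- function(slot, S) {
  if (slot <= S) -as.integer(slot) else as.integer(slot - S)
}

# left-to-right leaf order; the subtree holding the smaller minimum leaf
# index goes left
tree_leaf_order <- function(merge, minleaf, S) {
  leaves_of <- function(node) {
    if (node < 0) return(-node)
    l <- merge[node, 1]; r <- merge[node, 2]
    ml <- if (l < 0) -l else minleaf[S + l]
    mr <- if (r < 0) -r else minleaf[S + r]
    if (ml <= mr) c(leaves_of(l), leaves_of(r)) else c(leaves_of(r), leaves_of(l))
  }
  leaves_of(nrow(merge))
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> single linkage over %d systems\n",
              length(x$labels)))
  for (i in seq_along(x$height)) {
    cat(sprintf("  merge %d at d = %.4f\n", i, x$height[i]))
  }
  invisible(x)
}

#' @export
as.hclust.linkage_tree <- function(x, ...) {
  structure(unclass(x), class = "hclust")
}

#' Leaf order of the system dendrogram
#'
#' The left-to-right leaf order of the tree; applying it to the distance
#' matrix rows and columns places merged groups in contiguous blocks.
#'
#' @param tree a `linkage_tree`.
#' @return Character vector: the system labels in dendrogram order.
#' @export
dendrogram_order <- function(tree) {
  tree$labels[tree$order]
}

#' Reorder a distance matrix by dendrogram leaf order
#'
#' @param dm distance matrix with dimnames.
#' @param tree a `linkage_tree` built from it.
#' @return The reordered matrix.
#' @export
reorder_by_tree <- function(dm, tree) {
  ord <- dendrogram_order(tree)
  unclass(dm)[ord, ord]
}

#' Cophenetic distances of a linkage tree
#'
#' @param tree a `linkage_tree`.
#' @return A `dist` object of cophenetic (merge-height) distances.
#' @export
cophenetic_distances <- function(tree) {
  stats::cophenetic(as.hclust.linkage_tree(tree))
}

#' Rank systems by distance to a reference
#'
#' @param dm a distance matrix with dimnames.
#' @param reference label of the reference system (excluded from its own
#'   ranking).
#' @return Tibble with columns `system` and `d_soap`, ascending in
#'   distance; ties in label order.
#' @export
rank_by_distance <- function(dm, reference) {
  d <- unclass(dm)
  labels <- rownames(d)
  if (!reference %in% labels) {
    rlang::abort(sprintf("unknown reference system '%s'.", reference),
                 class = "defectometer_index_error")
  }
  others <- setdiff(labels, reference)
  dd <- d[reference, others]
  ord <- order(dd, others)
  tibble::tibble(system = others[ord], d_soap = unname(dd[ord]))
}

#' Export the system dendrogram as Newick
#'
#' Branch lengths are merge-height increments, so root-to-leaf path
#' lengths reproduce the merge heights.
#'
#' @param tree a `linkage_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_system_newick <- function(tree, path) {
  phy <- ape::as.phylo(as.hclust.linkage_tree(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Heatmap of a (reordered) SOAP distance matrix
#'
#' @param dm a `soap_dist` matrix.
#' @param tree optional `linkage_tree` used to reorder rows/columns.
#' @return A ggplot.
#' @export
plot_distance_matrix <- function(dm, tree = NULL) {
  m <- if (is.null(tree)) unclass(dm) else reorder_by_tree(dm, tree)
  lab <- rownames(m)
  df <- tidyr::expand_grid(from = lab, to = lab)
  df$d_soap <- m[cbind(match(df$from, lab), match(df$to, lab))]
  df$from <- factor(df$from, levels = lab)
  df$to <- factor(df$to, levels = rev(lab))
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to,
                                   fill = .data$d_soap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "d_SOAP") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
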