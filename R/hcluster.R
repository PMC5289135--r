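#' Agglomerative clustering under the RMS linkage
#'
#' Starts from singletons and repeatedly merges the pair of clusters with
#' the smallest linkage distance
#' `Delta(X, Y) = sqrt(mean of D^2 over all cross pairs)`.
#' Squared linkages obey the exact update
#' `Delta^2(X u Y, Z) = (N_X Delta^2(X,Z) + N_Y Delta^2(Y,Z)) / (N_X + N_Y)`,
#' which the implementation uses; equal linkages are broken by the smallest
#' (left node, right node) index pair, so the merge sequence is
#' deterministic across platforms.  RMS linkage is not guaranteed monotone;
#' the number of height inversions is recorded and reported.
#'
#' Node coding follows [stats::hclust()]: negative integers are leaves
#' (dataset positions), positive integers refer to earlier merge rows.
#'
#' @param D Symmetric non-negative distance matrix (N >= 2); dimnames
#'   supply structure ids.
#' @return An object of class `"cluster_tree"`: list with `merges` (tibble
#'   `node_a, node_b, delta, size` in merge order), `labels`, `n_inversions`.
#' @export
rms_linkage <- function(D) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (n < 2) abort("need at least 2 structures.")
  labels <- matrix_ids(D)
  # active cluster bookkeeping; creation index: leaves 1..n, merges n+k
  S <- D^2                      # squared linkage between active clusters
  diag(S) <- Inf
  sizes <- rep(1L, n)
  node_of <- seq_len(n)         # creation index of each active cluster
  merge_code <- -seq_len(n)     # hclust coding of each active cluster
  active <- rep(TRUE, n)
  merges <- matrix(0, n - 1, 2)
  deltas <- numeric(n - 1)
  msize <- integer(n - 1)
  pos <- seq_len(n)             # column positions in S of active clusters
  for (step in seq_len(n - 1)) {
    act <- which(active)
    Ssub <- S[act, act, drop = FALSE]
    Ssub[lower.tri(Ssub, diag = TRUE)] <- Inf
    mval <- min(Ssub)
    hit <- which(Ssub == mval, arr.ind = TRUE)
    # positions are kept in creation order, so lexicographic (row, col) of
    # the upper triangle is the smallest (left, right) node-index pair
    hit <- hit[order(hit[, 1], hit[, 2])[1], ]
    i <- act[hit[1]]
    j <- act[hit[2]]
    deltas[step] <- sqrt(mval)
    merges[step, ] <- c(merge_code[i], merge_code[j])
    msize[step] <- sizes[i] + sizes[j]
    # exact update of squared RMS linkage to every other active cluster
    others <- setdiff(act, c(i, j))
    if (length(others)) {
      newS <- (sizes[i] * S[i, others] + sizes[j] * S[j, others]) /
        (sizes[i] + sizes[j])
      S[i, others] <- newS
      S[others, i] <- newS
    }
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    merge_code[i] <- step
    node_of[i] <- n + step
  }
  n_inv <- sum(diff(deltas) < -1e-12)
  if (n_inv > 0) {
    inform(sprintf("RMS linkage produced %d height inversion(s).", n_inv))
  }
  structure(
    list(merges = tibble(node_a = merges[, 1], node_b = merges[, 2],
                         delta = deltas, size = msize),
         labels = labels, n_inversions = n_inv),
    class = "cluster_tree"
  )
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, %d merges, root delta %.4g%s\n",
              length(x$labels), nrow(x$merges),
              x$merges$delta[nrow(x$merges)],
              if (x$n_inversions) sprintf(" (%d inversions)", x$n_inversions) else ""))
  invisible(x)
}

# Leaf membership (dataset positions) of every merge node.
tree_members <- function(tree) {
  m <- nrow(tree$merges)
  members <- vector("list", m)
  for (k in seq_len(m)) {
    a <- tree$merges$node_a[k]
    b <- tree$merges$node_b[k]
    members[[k]] <- c(if (a < 0) -a else members[[a]],
                      if (b < 0) -b else members[[b]])
  }
  members
}

#' Convert a cluster tree to an hclust object
#'
#' @param x A `"cluster_tree"`.
#' @param ... Unused.
#' @return A [stats::hclust] object (heights may be non-monotone; plotting
#'   functions will warn on inversions).
#' @export
as.hclust.cluster_tree <- function(x, ...) {
  m <- as.matrix(x$merges[, c("node_a", "node_b")])
  dimnames(m) <- NULL
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(m[node, 1]), walk(m[node, 2]))
  }
  ord <- walk(nrow(m))
  structure(
    list(merge = m, height = x$merges$delta, order = ord,
         labels = x$labels, method = "rms", call = match.call(),
         dist.method = "kernel"),
    class = "hclust"
  )
}

#' Cut a cluster tree at a linkage height
#'
#' Clusters are the maximal subtrees whose internal merges all have linkage
#' `delta <= height`; every leaf belongs to exactly one cluster.  With
#' possible height inversions this subtree criterion (rather than a plain
#' height threshold) keeps the result well-defined.
#'
#' @param tree A `"cluster_tree"`.
#' @param height Linkage threshold (>= 0).
#' @return A tibble `id, cluster` in leaf order; cluster numbers are
#'   assigned by first appearance.
#' @export
cut_clusters <- function(tree, height) {
  if (height < 0) abort("`height` must be >= 0.")
  n <- length(tree$labels)
  m <- nrow(tree$merges)
  ok <- logical(m)              # subtree fully below the threshold?
  for (k in seq_len(m)) {
    a <- tree$merges$node_a[k]
    b <- tree$merges$node_b[k]
    ok[k] <- tree$merges$delta[k] <= height &&
      (a < 0 || ok[a]) && (b < 0 || ok[b])
  }
  members <- tree_members(tree)
  assignment <- integer(n)
  cl <- 0L
  # maximal qualifying nodes: qualifying merges whose parent does not
  # qualify, plus leaves whose parent merge does not qualify
  parent_ok <- logical(n + m)   # index: leaf i -> i, merge k -> n + k
  for (k in seq_len(m)) {
    for (child in c(tree$merges$node_a[k], tree$merges$node_b[k])) {
      idx <- if (child < 0) -child else n + child
      parent_ok[idx] <- ok[k]
    }
  }
  for (k in seq_len(m)) {
    if (ok[k] && !parent_ok[n + k]) {
      cl <- cl + 1L
      assignment[members[[k]]] <- cl
    }
  }
  for (i in seq_len(n)) {
    if (assignment[i] == 0L) {
      cl <- cl + 1L
      assignment[i] <- cl
    }
  }
  # renumber by first appearance in leaf order
  relabel <- match(assignment, unique(assignment))
  tibble(id = tree$labels, cluster = relabel)
}

#' Suggest a cut height from the merge-height gap
#'
#' Returns the midpoint of the largest gap between consecutive sorted
#' linkage heights — a simple automatic choice that separates the
#' small-scale (within-cluster) merges from the large-scale ones.
#'
#' @param tree A `"cluster_tree"`.
#' @return A cut height.
#' @export
suggest_cut <- function(tree) {
  h <- sort(tree$merges$delta)
  if (length(h) == 1) return(h / 2)
  gaps <- diff(h)
  k <- which.max(gaps)
  (h[k] + h[k + 1]) / 2
}

#' Representative structure of a cluster
#'
#' The member minimizing the mean squared distance to all members; ties go
#' to the member appearing first in the distance matrix.
#'
#' @param members Vector of structure ids (or indices) in the cluster.
#' @param D Distance matrix with ids as dimnames.
#' @return The representative's id (character if `D` has dimnames).
#' @export
representative_structure <- function(members, D) {
  idx <- resolve_indices(members, D)
  sub <- D[idx, idx, drop = FALSE]^2
  best <- idx[which.min(rowMeans(sub))]
  matrix_ids(D)[best]
}

#' Cluster spread about the representative
#'
#' `sigma_D = sqrt(mean over members of D^2(member, representative))`; zero
#' for singletons.
#'
#' @param members Vector of structure ids (or indices).
#' @param rep_id The representative (must be a member).
#' @param D Distance matrix.
#' @return The spread (same units as `D`).
#' @export
cluster_spread <- function(members, rep_id, D) {
  idx <- resolve_indices(members, D)
  r <- resolve_indices(rep_id, D)
  if (!(r %in% idx)) abort("representative must belong to the cluster.")
  sqrt(mean(D[idx, r]^2))
}

#' Per-cluster summary at a cut height
#'
#' @param tree A `"cluster_tree"`.
#' @param D Distance matrix used to build the tree.
#' @param height Cut height.
#' @param values Optional named vector of a scalar property (ids as names)
#'   for a `sigma_E` column (population SD within each cluster).
#' @return A tibble `cluster, size, representative_id, sigma_D` (and
#'   `sigma_E` when `values` is given), one row per cluster.
#' @export
cluster_summary <- function(tree, D, height, values = NULL) {
  assign <- cut_clusters(tree, height)
  split_ids <- split(assign$id, assign$cluster)
  rows <- lapply(names(split_ids), function(cl) {
    ids <- split_ids[[cl]]
    rep_id <- representative_structure(ids, D)
    out <- tibble(cluster = as.integer(cl), size = length(ids),
                  representative_id = rep_id,
                  sigma_D = cluster_spread(ids, rep_id, D))
    if (!is.null(values)) out$sigma_E <- property_spread(ids, values)
    out
  })
  dplyr::bind_rows(rows)
}

#' Linkage table export
#'
#' Writes the merge records as TSV (`node_a, node_b, delta, size`), the
#' standard interchange form for dendrogram tooling.
#'
#' @param tree A `"cluster_tree"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage_tsv <- function(tree, path) {
  write.table(tree$merges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Newick export of the cluster tree
#'
#' Requires \pkg{ape}; linkage heights become node heights.  With height
#' inversions the edge lengths are clamped at zero.
#'
#' @param tree A `"cluster_tree"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the 'ape' package.")
  }
  hc <- as.hclust(tree)
  if (tree$n_inversions > 0) {
    hc$height <- cummax(hc$height)
  }
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @export
tidy.cluster_tree <- function(x, ...) {
  dplyr::mutate(x$merges, step = dplyr::row_number(), .before = 1)
}

#' @export
glance.cluster_tree <- function(x, ...) {
  tibble(n_leaves = length(x$labels),
         n_merges = nrow(x$merges),
         root_delta = x$merges$delta[nrow(x$merges)],
         n_inversions = x$n_inversions)
}
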