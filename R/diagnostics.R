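#' Property spread within a cluster
#'
#' Population standard deviation of a scalar property (e.g. energy) over
#' the cluster members.  An alternative definition — RMS deviation about
#' the representative's value — is available via `about`.
#'
#' @param members Vector of structure ids.
#' @param values Named numeric vector of property values (ids as names).
#' @param about `"mean"` (default, population SD) or a single member id:
#'   RMS deviation about that member's value.
#' @return `sigma_E >= 0`.
#' @export
property_spread <- function(members, values, about = "mean") {
  members <- as.character(members)
  missing <- members[!(members %in% names(values))]
  if (length(missing)) {
    abort(sprintf("missing property value for id(s): %s",
                  paste(missing, collapse = ", ")))
  }
  v <- as.numeric(values[members])
  if (anyNA(v)) {
    abort(sprintf("missing property value for id(s): %s",
                  paste(members[is.na(v)], collapse = ", ")))
  }
  center <- if (identical(about, "mean")) mean(v) else {
    if (!(about %in% members)) abort("`about` must be 'mean' or a member id.")
    as.numeric(values[[about]])
  }
  sqrt(mean((v - center)^2))
}

#' Structure/property consistency screen
#'
#' Cuts the tree at `cut_height` and, for every cluster with at least two
#' members, compares the structural spread `sigma_D` with the property
#' spread `sigma_E`.  A cluster that is structurally tight but energetically
#' wild — `sigma_D < sigma_D_max` and `sigma_E > sigma_E_min` — is flagged
#' `inconsistent`: the metric cannot see whatever drives the property, the
#' signature of mixed-provenance or corrupted data.  The full
#' `(sigma_D, sigma_E)` table is returned for plotting regardless of flags.
#'
#' @param tree A `"cluster_tree"`.
#' @param D Distance matrix the tree was built from.
#' @param values Named numeric vector of the property (ids as names).
#' @param cut_height Linkage height for the flat clustering (default 0.1,
#'   the conventional truncation height for normalized kernel distances).
#' @param sigma_D_max Structural-tightness threshold (> 0).
#' @param sigma_E_min Property-wildness threshold (> 0).
#' @param spread_about Passed to [property_spread()]: `"mean"` or
#'   `"representative"`.
#' @return A tibble `cluster, size, representative_id, sigma_D, sigma_E,
#'   flagged, reason` with one row per cluster (singletons have `NA`
#'   spreads and are never flagged).
#' @export
consistency_screen <- function(tree, D, values, cut_height = 0.1,
                               sigma_D_max, sigma_E_min,
                               spread_about = c("mean", "representative")) {
  spread_about <- match.arg(spread_about)
  if (sigma_D_max <= 0 || sigma_E_min <= 0) abort("thresholds must be > 0.")
  assign <- cut_clusters(tree, cut_height)
  split_ids <- split(assign$id, assign$cluster)
  rows <- lapply(names(split_ids), function(cl) {
    ids <- split_ids[[cl]]
    rep_id <- representative_structure(ids, D)
    if (length(ids) >= 2) {
      sD <- cluster_spread(ids, rep_id, D)
      sE <- property_spread(ids, values,
                            about = if (spread_about == "mean") "mean" else rep_id)
      flag <- sD < sigma_D_max && sE > sigma_E_min
    } else {
      sD <- NA_real_; sE <- NA_real_; flag <- FALSE
    }
    tibble(cluster = as.integer(cl), size = length(ids),
           representative_id = rep_id, sigma_D = sD, sigma_E = sE,
           flagged = flag,
           reason = if (flag) "inconsistent" else "none")
  })
  dplyr::bind_rows(rows)
}

#' Scan a cluster tree for outlier branches
#'
#' Scanning from the root, returns the maximal branches containing at most
#' `max_size` leaves that attach to the rest of the tree at a linkage
#' height of at least `min_height` — small groups (often singletons) that
#' only merge with everything else near the top of the dendrogram.
#'
#' @param tree A `"cluster_tree"`.
#' @param max_size Maximum branch size to call an outlier group (>= 1).
#' @param min_height Minimum linkage height of the merge that attaches the
#'   branch to the rest.
#' @param D Optional distance matrix; adds `representative_id` and
#'   `sigma_D` columns.
#' @return A tibble `outlier_group, size, attach_height, ids` (list-column),
#'   plus representative/spread columns when `D` is supplied; zero rows if
#'   no branch qualifies.
#' @export
outlier_scan <- function(tree, max_size = 2L, min_height, D = NULL) {
  if (max_size < 1) abort("`max_size` must be >= 1.")
  n <- length(tree$labels)
  m <- nrow(tree$merges)
  members <- tree_members(tree)
  node_size <- function(node) if (node < 0) 1L else tree$merges$size[node]
  node_ids <- function(node) {
    if (node < 0) tree$labels[-node] else tree$labels[members[[node]]]
  }
  found <- list()
  claimed <- rep(FALSE, n + m)    # leaf i -> i, merge k -> n + k
  mark <- function(node) {
    idx <- if (node < 0) -node else n + node
    claimed[idx] <<- TRUE
  }
  is_claimed <- function(node) {
    idx <- if (node < 0) -node else n + node
    claimed[idx]
  }
  # walk merges from the root down; a child qualifies if it is small and
  # its attaching merge (the current one) is high
  for (k in rev(seq_len(m))) {
    for (child in c(tree$merges$node_a[k], tree$merges$node_b[k])) {
      if (is_claimed(child)) next
      if (node_size(child) <= max_size && tree$merges$delta[k] >= min_height) {
        found[[length(found) + 1]] <- list(ids = node_ids(child),
                                           attach_height = tree$merges$delta[k])
        # claim the whole subtree so nested branches are not re-reported
        stack <- child
        while (length(stack)) {
          nd <- stack[[1]]; stack <- stack[-1]
          mark(nd)
          if (nd > 0) stack <- c(stack, tree$merges$node_a[nd], tree$merges$node_b[nd])
        }
      }
    }
  }
  if (!length(found)) {
    out <- tibble(outlier_group = integer(), size = integer(),
                  attach_height = numeric(), ids = list())
  } else {
    out <- tibble(
      outlier_group = seq_along(found),
      size = vapply(found, function(f) length(f$ids), integer(1)),
      attach_height = vapply(found, function(f) f$attach_height, numeric(1)),
      ids = lapply(found, function(f) f$ids)
    )
  }
  if (!is.null(D) && nrow(out)) {
    out$representative_id <- vapply(out$ids, representative_structure,
                                    character(1), D = D)
    out$sigma_D <- mapply(cluster_spread, out$ids, out$representative_id,
                          MoreArgs = list(D = D))
  }
  out
}

#' Write the consistency/outlier report as TSV
#'
#' @param screen Output of [consistency_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
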