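# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run an expression with a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Symmetric-matrix sanity check used by every distance consumer.
check_distance_matrix <- function(D, arg = "D") {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    abort(sprintf("`%s` must be a square matrix.", arg))
  }
  if (any(!is.finite(D))) {
    abort(sprintf("`%s` contains non-finite entries.", arg))
  }
  if (any(D < 0)) {
    abort(sprintf("`%s` has negative entries; distances must be >= 0.", arg))
  }
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    abort(sprintf("`%s` is not symmetric.", arg))
  }
  invisible(D)
}

matrix_ids <- function(D) {
  rownames(D) %||% as.character(seq_len(nrow(D)))
}

# Resolve a vector of member ids to row indices of a distance matrix.
resolve_indices <- function(members, D) {
  ids <- matrix_ids(D)
  if (is.numeric(members)) {
    idx <- as.integer(members)
    if (any(idx < 1L) || any(idx > nrow(D))) {
      abort("member index out of range of the distance matrix.")
    }
    return(idx)
  }
  idx <- match(as.character(members), ids)
  if (anyNA(idx)) {
    abort(sprintf(
      "id(s) not present in the distance matrix: %s",
      paste(members[is.na(idx)], collapse = ", ")
    ))
  }
  idx
}
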