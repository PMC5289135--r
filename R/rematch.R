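#' Environment similarity matrix between two structures
#'
#' The matrix `C` whose entry `C[i, j]` is the environment kernel between
#' atom `i` of `A` and atom `j` of `B` (masked atoms excluded).
#'
#' @param A,B [conformer()] objects.
#' @param p A [soap_params()].
#' @param species_alphabet Optional common species alphabet; defaults to the
#'   union of the two structures' (non-masked) species.
#' @return Numeric matrix with entries in `[0, 1]`.
#' @export
env_similarity <- function(A, B, p, species_alphabet = NULL) {
  alphabet <- species_alphabet %||% sort(setdiff(unique(c(A$species, B$species)),
                                                 p$species_mask))
  da <- compute_descriptors(A, p, species_alphabet = alphabet)
  db <- compute_descriptors(B, p, species_alphabet = alphabet)
  env_similarity_from_descriptors(da, db, p$zeta)
}

env_similarity_from_descriptors <- function(da, db, zeta) {
  C <- da$vectors %*% t(db$vectors)
  C[C < 0] <- 0
  C[C > 1] <- 1
  C^zeta
}

#' Entropy-regularized optimal matching (Sinkhorn)
#'
#' Finds the coupling `P` minimizing `sum_ij P_ij (1 - C_ij + gamma log P_ij)`
#' over non-negative matrices whose rows sum to `1/N_A` and columns to
#' `1/N_B`, by alternating row/column rescaling of `exp(C/gamma)`.  Scaling
#' runs in the log domain whenever `max(C)/gamma` is large enough that the
#' element-wise exponential could overflow, so arbitrarily small `gamma` is
#' safe.
#'
#' @param C Environment similarity matrix (entries in `[0, 1]`).
#' @param gamma Regularization strength (> 0).  Large `gamma` drives `P` to
#'   the uniform coupling (average kernel); small `gamma` recovers the
#'   optimal-assignment (best-match) limit.
#' @param tol Convergence tolerance on the worst row/column marginal
#'   violation.
#' @param max_iter Maximum number of Sinkhorn sweeps.
#' @return An object of class `"match_plan"`: list with `plan` (the
#'   converged coupling), `gamma`, `iterations`, `residual`.
#' @export
sinkhorn <- function(C, gamma, tol = 1e-6, max_iter = 500000L) {
  C <- as.matrix(C)
  if (gamma <= 0) abort("`gamma` must be > 0.")
  if (tol <= 0) abort("`tol` must be > 0.")
  na <- nrow(C)
  nb <- ncol(C)
  rtar <- 1 / na
  ctar <- 1 / nb
  M <- C / gamma
  log_domain <- max(M) - min(M) > 500
  if (!log_domain) {
    K <- exp(M - max(M))          # constant shift cancels in the scaling
    u <- rep(rtar / mean(K), na)
    v <- rep(1, nb)
    for (it in seq_len(max_iter)) {
      u <- rtar / as.vector(K %*% v)
      v <- ctar / as.vector(crossprod(K, u))
      P <- (u * K) * rep(v, each = na)
      res <- max(abs(rowSums(P) - rtar), abs(colSums(P) - ctar))
      if (res < tol) {
        return(structure(list(plan = P, gamma = gamma, iterations = it,
                              residual = res), class = "match_plan"))
      }
    }
  } else {
    alpha <- rep(0, na)
    beta <- rep(0, nb)
    for (it in seq_len(max_iter)) {
      A1 <- M + rep(beta, each = na)
      alpha <- log(rtar) - apply(A1, 1, logsumexp)
      A2 <- M + alpha
      beta <- log(ctar) - apply(A2, 2, logsumexp)
      P <- exp(M + alpha + rep(beta, each = na))
      res <- max(abs(rowSums(P) - rtar), abs(colSums(P) - ctar))
      if (res < tol) {
        return(structure(list(plan = P, gamma = gamma, iterations = it,
                              residual = res), class = "match_plan"))
      }
    }
  }
  abort(sprintf("Sinkhorn did not converge in %d sweeps (residual %.3g).",
                max_iter, res))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Sinkhorn on a stack of equal-size square problems, run in lockstep with
# vectorized row/column scaling; returns the REMatch value sum(P * C) per
# problem.  Plain-domain only (caller guarantees C/gamma cannot overflow).
sinkhorn_batch <- function(C_arr, gamma, tol = 1e-6, max_iter = 500000L) {
  P <- dim(C_arr)[1]
  m <- dim(C_arr)[2]
  tar <- 1 / m
  K3 <- exp(C_arr / gamma)
  u <- matrix(tar, P, m)
  v <- matrix(1, P, m)
  Kv <- matrix(0, P, m)
  Ku <- matrix(0, P, m)
  for (it in seq_len(max_iter)) {
    Kv[] <- 0
    for (j in seq_len(m)) Kv <- Kv + K3[, , j] * v[, j]
    u <- tar / Kv
    Ku[] <- 0
    for (i in seq_len(m)) Ku <- Ku + K3[, i, ] * u[, i]
    v <- tar / Ku
    if (it %% 8L == 0L || it == max_iter) {
      # row sums are exact after the column update only via u * Kv(new)
      Kv[] <- 0
      for (j in seq_len(m)) Kv <- Kv + K3[, , j] * v[, j]
      res_r <- abs(u * Kv - tar)
      res <- max(apply(res_r, 1, max))
      if (res < tol) break
      if (it == max_iter) {
        abort(sprintf("Sinkhorn (batch) did not converge in %d sweeps (residual %.3g).",
                      max_iter, res))
      }
    }
  }
  vals <- numeric(P)
  KC <- K3 * C_arr
  acc <- matrix(0, P, m)
  for (j in seq_len(m)) acc[, j] <- rowSums(KC[, , j] * u) * v[, j]
  rowSums(acc)
}

# Regularized matching objective; non-increasing across Sinkhorn sweeps.
match_objective <- function(P, C, gamma) {
  sum(P * (1 - C)) + gamma * sum(P * log(pmax(P, .Machine$double.xmin)))
}

#' @export
print.match_plan <- function(x, ...) {
  cat(sprintf("<match_plan> %d x %d, gamma=%g, %d sweeps, residual %.2g\n",
              nrow(x$plan), ncol(x$plan), x$gamma, x$iterations, x$residual))
  invisible(x)
}

#' REMatch kernel between two structures
#'
#' The trace product of the converged entropy-regularized match plan with
#' the environment similarity matrix, `sum_ij P_ij C_ij` — a weighted
#' average of environment similarities lying in `[0, 1]`.
#'
#' @inheritParams env_similarity
#' @param gamma Regularization strength (> 0).
#' @param tol,max_iter Passed to [sinkhorn()].
#' @return Kernel value in `[0, 1]`.
#' @export
rematch_kernel <- function(A, B, p, gamma = 0.1, tol = 1e-6, max_iter = 500000L,
                           species_alphabet = NULL) {
  C <- env_similarity(A, B, p, species_alphabet = species_alphabet)
  rematch_from_C(C, gamma, tol, max_iter)
}

rematch_from_C <- function(C, gamma, tol = 1e-6, max_iter = 500000L) {
  sum(sinkhorn(C, gamma, tol, max_iter)$plan * C)
}

#' REMatch kernel matrix over a dataset
#'
#' Computes descriptors once over a common species alphabet, then the
#' REMatch kernel for all pairs.  With `normalize = TRUE` (the default) the
#' kernel is cosine-normalized, `K(A,B) / sqrt(K(A,A) K(B,B))`, so the
#' induced distance measures shape rather than molecule size.
#'
#' @param dataset A [conformer_set()].
#' @param p A [soap_params()].
#' @param gamma Regularization strength.
#' @param normalize Normalize to unit self-kernels?
#' @param tol,max_iter Passed to [sinkhorn()].
#' @return An object of class `"kernel_matrix"`: list with `values`
#'   (symmetric matrix with structure ids as dimnames), `ids`, `gamma`,
#'   `normalized`, `params`.
#' @export
kernel_matrix <- function(dataset, p, gamma = 0.1, normalize = TRUE,
                          tol = 1e-6, max_iter = 500000L) {
  descs <- dataset_descriptors(dataset, p)
  ids <- dataset_ids(dataset)
  n <- length(descs)
  sizes <- vapply(descs, function(d) nrow(d$vectors), integer(1))
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  equal_sized <- length(unique(sizes)) == 1L && max(1 / gamma) < 500
  if (equal_sized) {
    # one big descriptor gram, then all Sinkhorn problems in lockstep
    m <- sizes[1]
    X <- do.call(rbind, lapply(descs, function(d) d$vectors))
    G <- tcrossprod(X)
    G[G < 0] <- 0
    G[G > 1] <- 1
    G <- G^p$zeta
    P <- nrow(pairs)
    C_arr <- array(0, c(P, m, m))
    for (q in seq_len(P)) {
      ri <- (pairs[q, 1] - 1L) * m + seq_len(m)
      rj <- (pairs[q, 2] - 1L) * m + seq_len(m)
      C_arr[q, , ] <- G[ri, rj]
    }
    vals <- sinkhorn_batch(C_arr, gamma, tol, max_iter)
    K[pairs] <- vals
    K[pairs[, 2:1, drop = FALSE]] <- vals
  } else {
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      C <- env_similarity_from_descriptors(descs[[i]], descs[[j]], p$zeta)
      val <- rematch_from_C(C, gamma, tol, max_iter)
      K[i, j] <- val
      K[j, i] <- val
    }
  }
  if (any(!is.finite(K))) {
    bad <- which(!is.finite(K), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite kernel entry for pair (%s, %s).",
                  ids[bad[1]], ids[bad[2]]))
  }
  if (normalize) {
    d <- sqrt(diag(K))
    K <- K / (d %o% d)
    diag(K) <- 1
  }
  structure(list(values = K, ids = ids, gamma = gamma, normalized = normalize,
                 params = p),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %d structures, gamma=%g, normalized=%s\n",
              length(x$ids), x$gamma, x$normalized))
  invisible(x)
}

#' Kernel-induced distance matrix
#'
#' `D(A,B) = sqrt(K(A,A) + K(B,B) - 2 K(A,B))`.  The REMatch kernel is not
#' guaranteed positive semidefinite, so slightly negative radicands can
#' occur; they are clamped to zero and their count reported via a warning
#' and the `"n_clamped"` attribute (raise `gamma` if frequent).
#'
#' @param K A [kernel_matrix()] object or plain symmetric matrix.
#' @return Symmetric numeric matrix with zero diagonal and structure ids as
#'   dimnames.
#' @export
kernel_to_distance <- function(K) {
  V <- if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
  if (max(abs(V - t(V))) > 1e-8) abort("kernel matrix must be symmetric.")
  d <- diag(V)
  rad <- outer(d, d, "+") - 2 * V
  n_clamped <- sum(rad < 0 & upper.tri(rad))
  rad[rad < 0] <- 0
  D <- sqrt(rad)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (n_clamped > 0) {
    warn(sprintf("clamped %d negative radicand(s) in kernel distance.", n_clamped))
  }
  attr(D, "n_clamped") <- n_clamped
  D
}

# ---------------------------------------------------------------------------
# Plain-text persistence for kernel/distance matrices.

#' Write or read a square matrix as TSV with ids
#'
#' Plain-TSV container for kernel and distance matrices: first column `id`,
#' one column per structure.  Metadata (gamma, normalization, SOAP
#' parameters) travels in a JSON sidecar written by [cmd_kernel()].
#'
#' @param M Square matrix with ids as dimnames (or a [kernel_matrix()]).
#' @param path Output path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(M, path) {
  V <- if (inherits(M, "kernel_matrix")) M$values else as.matrix(M)
  df <- data.frame(id = rownames(V) %||% as.character(seq_len(nrow(V))),
                   V, check.names = FALSE)
  colnames(df) <- c("id", rownames(V) %||% as.character(seq_len(nrow(V))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  ids <- as.character(df$id)
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(ids, ids)
  M
}
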