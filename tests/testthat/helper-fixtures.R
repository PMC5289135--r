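# Shared fixtures and independent oracles for the test suite.

random_structure <- function(n_atoms = 5, species = c("C", "H", "O", "N"),
                             id = "s", spread = 1.5) {
  conformer(id,
            sample(species, n_atoms, replace = TRUE),
            matrix(rnorm(3 * n_atoms, sd = spread), n_atoms, 3))
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

# A proper rotation (determinant +1).
proper_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_distance_matrix <- function(n, dim = 5) {
  X <- matrix(rnorm(n * dim), n, dim)
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  D
}

# Exhaustive-permutation best-match score of a square similarity matrix,
# normalized by N (the gamma -> 0 limit of the REMatch kernel).
brute_force_best_match <- function(C) {
  n <- nrow(C)
  perms <- pracma::perms(seq_len(n))
  max(apply(perms, 1, function(pp) sum(C[cbind(seq_len(n), pp)]))) / n
}

# O(N^3) from-scratch RMS-linkage: re-evaluates the cross-pair RMS at every
# step directly from the distance matrix (no update formula), with the same
# smallest-(left, right)-node tie-break.
brute_force_rms_linkage <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)    # leaf index sets
  codes <- -seq_len(n)                        # hclust node coding
  nodes <- seq_len(n)                         # creation index, for tie-break
  merges <- matrix(0, n - 1, 2)
  deltas <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL
    m <- length(clusters)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        d2 <- mean(D[clusters[[i]], clusters[[j]]]^2)
        take <- is.null(best) || d2 < best$d2 ||
          (d2 == best$d2 && (nodes[i] < best$ni ||
                             (nodes[i] == best$ni && nodes[j] < best$nj)))
        if (take) best <- list(i = i, j = j, d2 = d2, ni = nodes[i], nj = nodes[j])
      }
    }
    merges[step, ] <- c(codes[best$i], codes[best$j])
    deltas[step] <- sqrt(best$d2)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    codes[best$i] <- step
    nodes[best$i] <- n + step
    clusters[[best$j]] <- NULL
    codes <- codes[-best$j]
    nodes <- nodes[-best$j]
  }
  list(merges = merges, deltas = deltas)
}

# Tiny two-basin generator spec for fast end-to-end tests.
small_gen_spec <- function(n = 40, ...) {
  generator_spec(n_structures = n, seed = 11, ...)
}

# Adjusted Rand index between two labelings (independent oracle: mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Descriptor length for a given alphabet size (mirrors the documented
# flattening: S diagonal species blocks of n(n+1)/2 radial pairs and
# S(S-1)/2 off-diagonal blocks of n^2, each times (l_max + 1)).
soap_dim_for_test <- function(S, n_max, l_max) {
  (S * n_max * (n_max + 1) / 2 + S * (S - 1) / 2 * n_max^2) * (l_max + 1)
}

rematch_from_C_test <- function(C, gamma, ...) {
  conformap:::rematch_from_C(C, gamma, ...)
}
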