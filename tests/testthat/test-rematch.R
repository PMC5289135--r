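p_fast <- soap_params(n_max = 4, l_max = 3)

test_that("env_similarity has unit self-diagonal and matches per-pair kernels", {
  set.seed(31)
  A <- random_structure(5, id = "A")
  B <- random_structure(4, id = "B")
  CAA <- env_similarity(A, A, p_fast)
  expect_equal(diag(CAA), rep(1, 5), tolerance = 1e-10)
  # duplicated environments give an all-ones block
  twin <- conformer("tw", c("C", "C"), rbind(c(0, 0, 0), c(40, 0, 0)))
  expect_equal(env_similarity(twin, twin, p_fast),
               matrix(1, 2, 2), tolerance = 1e-8)
  # entry-wise equal to looping over environment_kernel
  al <- sort(unique(c(A$species, B$species)))
  da <- compute_descriptors(A, p_fast, al)
  db <- compute_descriptors(B, p_fast, al)
  C <- env_similarity(A, B, p_fast)
  for (i in 1:5) for (j in 1:4) {
    expect_equal(C[i, j],
                 environment_kernel(da$vectors[i, ], db$vectors[j, ], p_fast$zeta),
                 tolerance = 1e-12)
  }
})

test_that("sinkhorn satisfies marginals, symmetry limits and objective descent", {
  set.seed(32)
  # constant C: exactly uniform plan
  pl <- sinkhorn(matrix(0.7, 3, 5), gamma = 0.1)
  expect_equal(pl$plan, matrix(1 / 15, 3, 5), tolerance = 1e-9)
  # marginals within tol on random rectangular problems
  for (rep in 1:10) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    C <- matrix(runif(na * nb), na, nb)
    pl <- sinkhorn(C, gamma = 0.05, tol = 1e-6)
    expect_lt(max(abs(rowSums(pl$plan) - 1 / na)), 1e-6)
    expect_lt(max(abs(colSums(pl$plan) - 1 / nb)), 1e-6)
  }
  # large gamma: near-uniform plan
  C <- matrix(runif(20), 4, 5)
  pl <- sinkhorn(C, gamma = 100)
  expect_lt(max(abs(pl$plan - 1 / 20)), 1e-3)
  # small gamma on identity: optimal assignment
  pl <- sinkhorn(diag(2), gamma = 0.01)
  expect_lt(max(abs(pl$plan - diag(0.5, 2))), 1e-6)
  # tiny gamma runs in the log domain without overflow
  pl <- sinkhorn(matrix(runif(16), 4, 4), gamma = 1e-4)
  expect_true(all(is.finite(pl$plan)))
  # objective is non-increasing across sweeps
  C <- matrix(runif(25), 5, 5)
  K <- exp(C / 0.1)
  u <- rep(1, 5); v <- rep(1, 5)
  objs <- numeric(20)
  for (it in 1:20) {
    u <- (1 / 5) / as.vector(K %*% v)
    v <- (1 / 5) / as.vector(crossprod(K, u))
    P <- (u * K) * rep(v, each = 5)
    objs[it] <- conformap:::match_objective(P, C, 0.1)
  }
  expect_true(all(diff(objs) < 1e-10))
})

test_that("rematch kernel interpolates between average and best-match limits", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    C <- matrix(runif(n * n), n, n)
    k_avg <- rematch_from_C_test(C, 100)
    k_best <- brute_force_best_match(C)
    expect_lt(abs(k_avg - mean(C)), 1e-3)
    for (g in c(0.1, 0.3, 1)) {
      k_mid <- rematch_from_C_test(C, g)
      expect_gte(k_mid, mean(C) - 1e-6)
      expect_lte(k_mid, k_best + 1e-6)
    }
  }
  # the gamma -> 0 limit approaches the assignment value (1e-3 by gamma = 0.002)
  C <- matrix(runif(25), 5, 5)
  expect_equal(rematch_from_C_test(C, 0.002), brute_force_best_match(C),
               tolerance = 1e-3)
})

test_that("rematch kernel is symmetric and atom-order invariant", {
  set.seed(34)
  A <- random_structure(5, id = "A")
  B <- random_structure(5, id = "B")
  al <- sort(unique(c(A$species, B$species)))
  # tight Sinkhorn tolerance so the fixed-point symmetry shows at 1e-10
  kab <- rematch_kernel(A, B, p_fast, gamma = 0.1, tol = 1e-12,
                        species_alphabet = al)
  kba <- rematch_kernel(B, A, p_fast, gamma = 0.1, tol = 1e-12,
                        species_alphabet = al)
  expect_equal(kab, kba, tolerance = 1e-10)
  perm <- sample(5)
  A2 <- conformer("A2", A$species[perm], A$coords[perm, ])
  expect_equal(rematch_kernel(A2, B, p_fast, gamma = 0.1, tol = 1e-12,
                              species_alphabet = al),
               kab, tolerance = 1e-10)
  # all-identical environments give unit self-kernel
  twin <- conformer("tw", c("C", "C"), rbind(c(0, 0, 0), c(40, 0, 0)))
  expect_equal(rematch_kernel(twin, twin, p_fast, gamma = 0.1), 1,
               tolerance = 1e-8)
})

test_that("kernel_matrix matches per-pair calls and normalizes duplicates to 1", {
  set.seed(35)
  structures <- lapply(1:5, function(i) random_structure(4, id = sprintf("s%d", i)))
  structures[[5]] <- conformer("s5", structures[[1]]$species,
                               structures[[1]]$coords)   # duplicate of s1
  ds <- conformer_set(structures)
  K <- kernel_matrix(ds, p_fast, gamma = 0.1, normalize = TRUE)
  expect_equal(K$values, t(K$values), tolerance = 1e-10)
  expect_equal(unname(diag(K$values)), rep(1, 5))
  expect_equal(unname(K$values[1, 5]), 1, tolerance = 1e-8)
  # element-wise agreement with rematch_kernel on the raw kernel
  Kraw <- kernel_matrix(ds, p_fast, gamma = 0.1, normalize = FALSE)
  al <- attr(dataset_descriptors(ds, p_fast), "alphabet")
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(unname(Kraw$values[i, j]),
                 rematch_kernel(structures[[i]], structures[[j]], p_fast,
                                gamma = 0.1, species_alphabet = al),
                 tolerance = 1e-5)
  }
  # mixed atom counts exercise the general path; invariants still hold
  mixed <- conformer_set(list(structures[[1]],
                              random_structure(6, id = "big"),
                              random_structure(3, id = "small")))
  Km <- kernel_matrix(mixed, p_fast, gamma = 0.1)
  expect_equal(Km$values, t(Km$values), tolerance = 1e-10)
  expect_equal(unname(diag(Km$values)), rep(1, 3))
  expect_true(all(Km$values >= -1e-10 & Km$values <= 1 + 1e-10))
})

test_that("kernel_to_distance implements the induced metric with clamping", {
  K <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(kernel_to_distance(K), matrix(0, 2, 2), ignore_attr = TRUE)
  K <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(kernel_to_distance(K)[1, 2], sqrt(2), tolerance = 1e-12)
  K <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(kernel_to_distance(K)[1, 2], 1.0, tolerance = 1e-12)
  # negative radicand: clamped to zero with a warning
  K <- matrix(c(1, 1.1, 1.1, 1), 2, 2)
  expect_warning(D <- kernel_to_distance(K), "clamped")
  expect_equal(D[1, 2], 0)
  expect_equal(attr(D, "n_clamped"), 1L)
})

test_that("matrix TSV round-trips with ids", {
  set.seed(36)
  D <- random_distance_matrix(6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(D, path)
  back <- read_matrix_tsv(path)
  expect_equal(back, D, tolerance = 1e-12)
})
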