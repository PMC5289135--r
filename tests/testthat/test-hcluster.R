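three_point_D <- function() {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 1
  D[1, 3] <- D[3, 1] <- 2
  D[2, 3] <- D[3, 2] <- 2
  dimnames(D) <- list(c("1", "2", "3"), c("1", "2", "3"))
  D
}

test_that("RMS linkage reproduces the worked three-point tree", {
  tr <- rms_linkage(three_point_D())
  expect_equal(tr$merges$delta[1], 1)
  expect_equal(tr$merges$node_a[1], -1)
  expect_equal(tr$merges$node_b[1], -2)
  # Delta({1,2},{3}) = sqrt((4 + 4)/2) = 2, exactly
  expect_identical(tr$merges$delta[2], 2)
  expect_equal(tr$merges$size, c(2L, 3L))
})

test_that("two tight far-apart pairs merge within-pair first", {
  X <- c(0, 0.01, 10, 10.01)
  D <- as.matrix(stats::dist(X))
  tr <- rms_linkage(D)
  first_two <- list(sort(unname(-unlist(tr$merges[1, c("node_a", "node_b")]))),
                    sort(unname(-unlist(tr$merges[2, c("node_a", "node_b")]))))
  expect_true(any(vapply(first_two, function(x) all(x == c(1, 2)), logical(1))))
  expect_true(any(vapply(first_two, function(x) all(x == c(3, 4)), logical(1))))
})

test_that("the linkage update equals the from-scratch brute force exactly", {
  set.seed(51)
  for (rep in 1:8) {
    D <- random_distance_matrix(8)
    tr <- rms_linkage(D)
    bf <- brute_force_rms_linkage(D)
    expect_equal(as.matrix(tr$merges[, c("node_a", "node_b")]), bf$merges,
                 ignore_attr = TRUE)
    expect_equal(tr$merges$delta, bf$deltas, tolerance = 1e-10)
  }
})

test_that("RMS linkage agrees with UPGMA on squared distances", {
  # independent cross-check: Delta^2 is average linkage of D^2
  set.seed(52)
  D <- random_distance_matrix(12)
  tr <- rms_linkage(D)
  hc <- stats::hclust(as.dist(D^2), method = "average")
  expect_equal(sort(tr$merges$delta), sort(sqrt(hc$height)), tolerance = 1e-10)
})

test_that("linkage is relabeling-invariant up to the documented tie-break", {
  set.seed(53)
  D <- random_distance_matrix(7)
  perm <- sample(7)
  Dp <- D[perm, perm]
  tr <- rms_linkage(D)
  trp <- rms_linkage(Dp)
  expect_equal(sort(tr$merges$delta), sort(trp$merges$delta), tolerance = 1e-10)
})

test_that("cut produces a partition, refinement, and the worked flat clustering", {
  tr <- rms_linkage(three_point_D())
  cl <- cut_clusters(tr, 1.5)
  expect_equal(cl$cluster[cl$id %in% c("1", "2")], c(1L, 1L))
  expect_equal(cl$cluster[cl$id == "3"], 2L)
  # extremes
  expect_equal(unique(cut_clusters(tr, 10)$cluster), 1L)
  expect_equal(sort(cut_clusters(tr, 0.5)$cluster), 1:3)
  # refinement on a random tree
  set.seed(54)
  D <- random_distance_matrix(15)
  tr <- rms_linkage(D)
  h1 <- stats::quantile(tr$merges$delta, 0.3)
  h2 <- stats::quantile(tr$merges$delta, 0.8)
  c1 <- cut_clusters(tr, h1)
  c2 <- cut_clusters(tr, h2)
  expect_equal(nrow(c1), 15)
  joint <- table(c1$cluster, c2$cluster)
  expect_true(all(rowSums(joint > 0) == 1))   # every fine cluster nests
})

test_that("representative and spread equal exhaustive evaluation", {
  # worked chain: member 2 wins (mean-square 2/3 vs 5/3)
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 1
  D[2, 3] <- D[3, 2] <- 1
  D[1, 3] <- D[3, 1] <- 2
  expect_equal(representative_structure(1:3, D), "2")
  # singleton
  expect_equal(representative_structure(2, D), "2")
  expect_equal(cluster_spread(2, 2, D), 0)
  # pair at distance d: spread d/sqrt(2)
  d <- 1.7
  Dp <- matrix(c(0, d, d, 0), 2, 2)
  rep_id <- representative_structure(1:2, Dp)
  expect_equal(rep_id, "1")   # tie broken by matrix order
  expect_equal(cluster_spread(1:2, rep_id, Dp), d / sqrt(2), tolerance = 1e-12)
  # random clusters vs brute force
  set.seed(55)
  for (rep in 1:10) {
    D <- random_distance_matrix(10)
    members <- sample(10, sample(3:10, 1))
    ms <- vapply(members, function(i) mean(D[i, members]^2), numeric(1))
    best <- members[which.min(ms)]
    got <- representative_structure(members, D)
    expect_equal(got, as.character(best))
    expect_equal(cluster_spread(members, got, D),
                 sqrt(mean(D[members, best]^2)), tolerance = 1e-12)
  }
  expect_error(representative_structure(c("1", "zz"), D), "not present")
  expect_error(cluster_spread(1:3, 5, random_distance_matrix(10)), "belong")
})

test_that("pair clusters reduce the linkage to the plain distance", {
  set.seed(56)
  D <- random_distance_matrix(2)
  tr <- rms_linkage(D)
  expect_equal(tr$merges$delta, D[1, 2], tolerance = 1e-12)
})

test_that("linkage exports, hclust conversion and tidiers work", {
  set.seed(57)
  D <- random_distance_matrix(10)
  tr <- rms_linkage(D)
  hc <- as.hclust(tr)
  expect_s3_class(hc, "hclust")
  expect_setequal(hc$order, 1:10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_linkage_tsv(tr, path)
  back <- read.delim(path)
  expect_equal(back$delta, tr$merges$delta, tolerance = 1e-12)
  nw <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, nw)
  phy <- ape::read.tree(nw)
  expect_equal(ape::Ntip(phy), 10)
  expect_equal(nrow(tidy(tr)), 9)
  expect_equal(glance(tr)$n_leaves, 10)
  # dendrogram autoplot builds without error
  expect_s3_class(autoplot(tr, cut_height = 0.5), "ggplot")
})
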