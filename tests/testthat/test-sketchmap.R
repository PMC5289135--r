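test_that("sigmoid hits its anchor points and is monotone", {
  set.seed(41)
  for (rep in 1:20) {
    p <- sigmoid_params(sigma = runif(1, 0.5, 5),
                        A_hd = runif(1, 0.5, 3), B_hd = runif(1, 1, 6),
                        a_ld = runif(1, 0.5, 3), b_ld = runif(1, 1, 6))
    expect_identical(sm_sigmoid(0, p, "high"), 0)
    expect_equal(sm_sigmoid(p$sigma, p, "high"), 0.5, tolerance = 1e-14)
    expect_equal(sm_sigmoid(p$sigma, p, "low"), 0.5, tolerance = 1e-14)
    r <- seq(0, 5 * p$sigma, length.out = 50)
    expect_true(all(diff(sm_sigmoid(r, p, "high")) > 0))
  }
  p14 <- sigmoid_params(sigma = 1)   # default exponents 1 and 4
  expect_equal(c(p14$A_hd, p14$B_hd, p14$a_ld, p14$b_ld), c(1, 4, 1, 4))
  expect_gt(sm_sigmoid(100 * p14$sigma, p14, "high"), 0.99)
  expect_error(sm_sigmoid(-0.1, p14, "high"), ">= 0")
})

test_that("auto_sigma returns 0.8 x histogram mode", {
  # single occupied bin: exact
  D <- matrix(2.5, 4, 4); diag(D) <- 0
  expect_equal(auto_sigma(D), 0.8 * 2.5, tolerance = 1e-12)
  # constructed bimodal sample with a known dominant mode near 2.5
  set.seed(42)
  n <- 35
  X <- c(rnorm(500, 2.5, 0.02), rnorm(95, 5, 0.4))
  d <- X[seq_len(n * (n - 1) / 2)]
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- d
  D <- D + t(D)
  sig <- auto_sigma(D, n_bins = 100)
  # histogram oracle on the same sample
  rng <- range(d)
  breaks <- seq(rng[1], rng[2], length.out = 101)
  counts <- tabulate(pmin(findInterval(d, breaks, rightmost.closed = TRUE), 100),
                     nbins = 100)
  mode_center <- (breaks[which.max(counts)] + breaks[which.max(counts) + 1]) / 2
  expect_equal(sig, 0.8 * mode_center, tolerance = 1e-12)
  expect_lt(abs(mode_center - 2.5), 0.1)
  expect_error(auto_sigma(matrix(0, 3, 3)), "zero")
})

test_that("stress matches the explicit double loop and rigid-motion invariance", {
  set.seed(43)
  n <- 8
  D <- random_distance_matrix(n)
  xy <- matrix(rnorm(2 * n), n, 2)
  p <- sigmoid_params(sigma = 1.5)
  brute <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    brute <- brute + (sm_sigmoid(D[i, j], p, "high") -
                        sm_sigmoid(sqrt(sum((xy[i, ] - xy[j, ])^2)), p, "low"))^2
  }
  expect_equal(sm_stress(D, xy, p), brute, tolerance = 1e-12)
  # single pair worked example: (0.9 - 0.4)^2
  p2 <- sigmoid_params(sigma = 1)
  # analytic inverse of the sigmoid: r(v) = (((1-v)^(-a/b) - 1)/c)^(1/a)
  Finv <- function(v, a, b) ((((1 - v)^(-a / b)) - 1) / (2^(a / b) - 1))^(1 / a)
  rD <- Finv(0.9, 1, 4)
  rd <- Finv(0.4, 1, 4)
  D2 <- matrix(c(0, rD, rD, 0), 2, 2)
  xy2 <- rbind(c(0, 0), c(rd, 0))
  expect_equal(sm_stress(D2, xy2, p2), 0.25, tolerance = 1e-10)
  # rigid motion of the layout leaves stress unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(sm_stress(D, xy %*% R + 3, p), sm_stress(D, xy, p),
               tolerance = 1e-10)
  expect_equal(sm_stress(D, xy %*% diag(c(-1, 1)), p), sm_stress(D, xy, p),
               tolerance = 1e-10)
})

test_that("fit recovers planar data and never worsens the MDS start", {
  set.seed(44)
  X <- matrix(rnorm(60), 30, 2)
  D <- as.matrix(stats::dist(X))
  p <- sigmoid_params(sigma = auto_sigma(D))
  m <- sketchmap_fit(D, p, seed = 1, n_starts = 3)
  expect_lt(m$final_stress, 1e-6)
  # recovered distances match D (rigid-motion invariant comparison)
  expect_gt(stats::cor(as.vector(stats::dist(m$landmark_xy)), D[lower.tri(D)]),
            0.999)
  # optimizer contract: no worse than the metric-scaling initialization
  init <- stats::cmdscale(as.dist(D), k = 2)
  expect_lte(m$final_stress, sm_stress(D, init, p) + 1e-12)
  # near-linear regime: correlation with D stays essentially perfect
  p_lin <- sigmoid_params(sigma = 50 * max(D))
  m_lin <- sketchmap_fit(D, p_lin, seed = 1, n_starts = 2)
  expect_gt(stats::cor(as.vector(stats::dist(m_lin$landmark_xy)),
                       D[lower.tri(D)]), 0.99)
})

test_that("three equidistant points embed as an equilateral triangle", {
  D <- matrix(2, 3, 3); diag(D) <- 0
  p <- sigmoid_params(sigma = 1.6)
  m <- sketchmap_fit(D, p, seed = 2, n_starts = 5)
  d12 <- sm_sigmoid(sqrt(sum((m$landmark_xy[1, ] - m$landmark_xy[2, ])^2)), p, "low")
  d13 <- sm_sigmoid(sqrt(sum((m$landmark_xy[1, ] - m$landmark_xy[3, ])^2)), p, "low")
  d23 <- sm_sigmoid(sqrt(sum((m$landmark_xy[2, ] - m$landmark_xy[3, ])^2)), p, "low")
  expect_lt(max(abs(c(d12 - d13, d12 - d23, d13 - d23))), 1e-6)
})

test_that("farthest point sampling equals the greedy brute force", {
  # collinear worked example: 0, 1, 10 with seed 0 picks the far point next
  D <- as.matrix(stats::dist(c(0, 1, 10)))
  expect_equal(farthest_point_sample(D, 3, seed_index = 1)[2], 3L)
  set.seed(45)
  D <- random_distance_matrix(9)
  got <- farthest_point_sample(D, 4, seed_index = 2)
  # exhaustive greedy recomputation
  chosen <- 2L
  for (k in 2:4) {
    cand <- setdiff(seq_len(9), chosen)
    score <- vapply(cand, function(i) min(D[i, chosen]), numeric(1))
    chosen <- c(chosen, cand[which.max(score)])
  }
  expect_identical(got, chosen)
  expect_length(farthest_point_sample(D, 9), 9L)
  expect_error(farthest_point_sample(D, 10), "between")
})

test_that("out-of-sample projection is self-consistent and grid-optimal", {
  set.seed(46)
  X <- matrix(rnorm(40), 20, 2)
  D <- as.matrix(stats::dist(X))
  p <- sigmoid_params(sigma = auto_sigma(D))
  m <- sketchmap_fit(D, p, seed = 3, n_starts = 2)
  # projecting a landmark's own distance row returns its coordinates
  scale <- max(stats::dist(m$landmark_xy))
  for (k in c(1, 7, 20)) {
    xy <- sm_project(m, m$landmark_D[k, ])
    expect_lt(sqrt(sum((xy - m$landmark_xy[k, ])^2)), 1e-3 * scale)
  }
  # single landmark: the optimal radius satisfies f(r*) = F(d)
  m1 <- m
  m1$landmark_ids <- m$landmark_ids[1]
  m1$landmark_D <- m$landmark_D[1, 1, drop = FALSE]
  m1$landmark_xy <- m$landmark_xy[1, , drop = FALSE]
  d0 <- 0.6 * p$sigma
  xy1 <- sm_project(m1, d0)
  r_star <- sqrt(sum((xy1 - m1$landmark_xy[1, ])^2))
  expect_equal(sm_sigmoid(r_star, p, "low"), sm_sigmoid(d0, p, "high"),
               tolerance = 1e-6)
  # returned point beats every node of the coarse grid
  dnew <- D[5, ] * 0.9
  xy <- sm_project(m, dnew, grid_n = 32)
  obj <- function(pt) {
    dd <- sqrt(colSums((t(m$landmark_xy) - pt)^2))
    sum((sm_sigmoid(dnew, p, "high") - sm_sigmoid(dd, p, "low"))^2)
  }
  rx <- range(m$landmark_xy[, 1]); ry <- range(m$landmark_xy[, 2])
  gx <- seq(rx[1] - 0.25 * diff(rx), rx[2] + 0.25 * diff(rx), length.out = 32)
  gy <- seq(ry[1] - 0.25 * diff(ry), ry[2] + 0.25 * diff(ry), length.out = 32)
  grid_best <- min(apply(expand.grid(gx, gy), 1, function(g) obj(as.numeric(g))))
  expect_lte(obj(as.numeric(xy)), grid_best + 1e-10)
})

test_that("sketchmap driver embeds non-landmarks and round-trips to JSON", {
  set.seed(47)
  X <- matrix(rnorm(50), 25, 2)
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- list(sprintf("s%02d", 1:25), sprintf("s%02d", 1:25))
  res <- sketchmap(D, n_landmarks = 10, seed = 5, n_starts = 2)
  expect_equal(sum(res$embedding$landmark), 10)
  expect_true(all(is.finite(res$embedding$x)))
  path <- withr::local_tempfile(fileext = ".json")
  write_sketchmap(res$model, path, kernel_settings = list(gamma = 0.1))
  back <- read_sketchmap(path)
  expect_equal(back$landmark_xy, res$model$landmark_xy, tolerance = 1e-10)
  expect_equal(back$final_stress, res$model$final_stress, tolerance = 1e-10)
  expect_equal(back$label, res$model$label)
  expect_equal(attr(back, "kernel_settings")$gamma, 0.1)
  # tidiers
  expect_named(glance(res$model),
               c("label", "sigma", "n_landmarks", "final_stress"))
  expect_equal(nrow(tidy(res$model)), 10)
})
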