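#' Sketch-map sigmoid parameters
#'
#' Parameters of the non-linear transforms applied to high-dimensional
#' distances (`F`, exponents `A_hd`, `B_hd`) and low-dimensional map
#' distances (`f`, exponents `a_ld`, `b_ld`):
#' `F(r) = 1 - (1 + (2^(a/b) - 1) (r/sigma)^a)^(-b/a)`.
#' `sigma` is the switching threshold separating the distances the map
#' tries to reproduce faithfully from those it merely keeps "far".  The
#' conventional short label is `sigma-A_B-a_b`.
#'
#' Defaults `A_hd = a_ld = 1`, `B_hd = b_ld = 4`: short-range distances are
#' represented near-faithfully while long-range ones saturate quickly,
#' appropriate for databases of locally-minimized conformers with no
#' thermal noise to filter out.
#'
#' @param sigma Switching threshold (> 0), same units as the distances.
#' @param A_hd,B_hd High-dimensional sigmoid exponents (> 0).
#' @param a_ld,b_ld Low-dimensional sigmoid exponents (> 0).
#' @return An object of class `"sigmoid_params"`.
#' @export
sigmoid_params <- function(sigma, A_hd = 1, B_hd = 4, a_ld = 1, b_ld = 4) {
  if (sigma <= 0) abort("`sigma` must be > 0.")
  if (any(c(A_hd, B_hd, a_ld, b_ld) <= 0)) abort("sigmoid exponents must be > 0.")
  structure(list(sigma = sigma, A_hd = A_hd, B_hd = B_hd,
                 a_ld = a_ld, b_ld = b_ld),
            class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("<sigmoid_params> %s\n", sigmoid_label(x)))
  invisible(x)
}

#' @rdname sigmoid_params
#' @param p A `sigmoid_params` object.
#' @export
sigmoid_label <- function(p) {
  sprintf("%g-%g_%g-%g_%g", p$sigma, p$A_hd, p$B_hd, p$a_ld, p$b_ld)
}

#' Sketch-map sigmoid transform
#'
#' @param r Non-negative distance(s).
#' @param p A [sigmoid_params()].
#' @param which `"high"` for the transform of input-space distances,
#'   `"low"` for map distances.
#' @return Values in `[0, 1)`, strictly increasing in `r`, with
#'   `F(0) = 0` and `F(sigma) = 0.5` for any exponent pair.
#' @export
sm_sigmoid <- function(r, p, which = c("high", "low")) {
  which <- match.arg(which)
  if (any(r < 0)) abort("distances must be >= 0.")
  if (which == "high") sigmoid_eval(r, p$sigma, p$A_hd, p$B_hd)
  else sigmoid_eval(r, p$sigma, p$a_ld, p$b_ld)
}

sigmoid_eval <- function(r, sigma, a, b) {
  1 - (1 + (2^(a / b) - 1) * (r / sigma)^a)^(-b / a)
}

# d/dr of sigmoid_eval.
sigmoid_deriv <- function(r, sigma, a, b) {
  cc <- 2^(a / b) - 1
  u <- 1 + cc * (r / sigma)^a
  (b / a) * u^(-b / a - 1) * cc * a * r^(a - 1) / sigma^a
}

#' Automatic switching threshold from the distance histogram
#'
#' Histograms the off-diagonal distances into `n_bins` equal-width bins,
#' takes the center of the most populated bin (leftmost on ties) as the
#' dominant distance scale `D_max`, and returns `0.8 * D_max`.
#'
#' @param D Symmetric distance matrix (N >= 3).
#' @param n_bins Number of equal-width histogram bins.
#' @return The threshold `sigma`.
#' @export
auto_sigma <- function(D, n_bins = 100L) {
  check_distance_matrix(D)
  if (nrow(D) < 3) abort("need at least 3 structures.")
  d <- D[upper.tri(D)]
  if (all(d == 0)) abort("all distances are zero; sigma undefined.")
  rng <- range(d)
  if (rng[1] == rng[2]) return(0.8 * rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(d, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mode_bin <- which.max(counts)      # which.max returns the leftmost tie
  d_max <- (breaks[mode_bin] + breaks[mode_bin + 1]) / 2
  0.8 * d_max
}

#' Sketch-map stress
#'
#' `S^2 = sum_{i<j} w_ij (F(D_ij) - f(d_ij))^2` where `d` is the Euclidean
#' distance between the 2-D projections.
#'
#' @param D Symmetric high-dimensional distance matrix.
#' @param xy N x 2 matrix of map coordinates.
#' @param p A [sigmoid_params()].
#' @param weights Optional symmetric matrix of per-pair weights (default 1).
#' @return The stress value (>= 0).
#' @export
sm_stress <- function(D, xy, p, weights = NULL) {
  xy <- as.matrix(xy)
  if (nrow(xy) != nrow(D) || ncol(xy) != 2) {
    abort("`xy` must be an N x 2 matrix matching D.")
  }
  FD <- sm_sigmoid(D[upper.tri(D)], p, "high")
  d <- as.matrix(stats::dist(xy))
  fd <- sm_sigmoid(d[upper.tri(d)], p, "low")
  w <- if (is.null(weights)) 1 else weights[upper.tri(weights)]
  sum(w * (FD - fd)^2)
}

# Stress and analytic gradient for the optimizer; par = as.vector(xy).
stress_fg <- function(D, p, weights = NULL) {
  n <- nrow(D)
  FD <- sm_sigmoid(D, p, "high")
  diag(FD) <- 0
  W <- if (is.null(weights)) matrix(1, n, n) else weights
  diag(W) <- 0
  list(
    fn = function(par) {
      xy <- matrix(par, n, 2)
      d <- as.matrix(stats::dist(xy))
      fd <- sigmoid_eval(d, p$sigma, p$a_ld, p$b_ld)
      diag(fd) <- 0
      sum(W * (FD - fd)^2) / 2
    },
    gr = function(par) {
      xy <- matrix(par, n, 2)
      d <- as.matrix(stats::dist(xy))
      dsafe <- pmax(d, 1e-12)
      fd <- sigmoid_eval(d, p$sigma, p$a_ld, p$b_ld)
      fp <- sigmoid_deriv(dsafe, p$sigma, p$a_ld, p$b_ld)
      diag(fd) <- 0
      # coefficient on (x_i - x_j) in dS2/dx_i (full sum over ordered pairs)
      A <- 2 * W * (fd - FD) * fp / dsafe
      diag(A) <- 0
      rs <- rowSums(A)
      gx <- rs * xy[, 1] - A %*% xy[, 1]
      gy <- rs * xy[, 2] - A %*% xy[, 2]
      c(gx, gy)
    }
  )
}

#' Fit a sketch-map embedding
#'
#' Minimizes the sketch-map stress by quasi-Newton local optimization from a
#' classical metric-scaling initialization, plus seeded randomly-perturbed
#' restarts; the best-of-restarts layout is returned.
#'
#' @param D Symmetric distance matrix (N >= 3); dimnames supply ids.
#' @param p A [sigmoid_params()]; use [auto_sigma()] to pick `sigma`.
#' @param seed Integer seed for the restart perturbations.
#' @param n_starts Number of starts (1 = metric-scaling start only).
#' @param weights Optional per-pair weight matrix.
#' @param max_iter Maximum optimizer iterations per start.
#' @return An object of class `"sketch_map"`: list with `params`,
#'   `landmark_ids`, `landmark_D`, `landmark_xy`, `final_stress`, `label`.
#' @export
sketchmap_fit <- function(D, p, seed = 42L, n_starts = 5L, weights = NULL,
                          max_iter = 1000L) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (n < 3) abort("need at least 3 structures.")
  ids <- matrix_ids(D)
  mds <- stats::cmdscale(as.dist(D), k = 2)
  if (ncol(mds) < 2) mds <- cbind(mds, matrix(0, n, 2 - ncol(mds)))
  fg <- stress_fg(D, p, weights)
  scale0 <- max(stats::sd(mds), 1e-3)
  best <- NULL
  with_local_seed(seed, {
    for (s in seq_len(n_starts)) {
      start <- if (s == 1) mds else mds + matrix(rnorm(2 * n, sd = 0.1 * scale0), n, 2)
      fit <- tryCatch(
        optim(as.vector(start), fg$fn, fg$gr, method = "L-BFGS-B",
              control = list(maxit = max_iter, factr = 1e4)),
        error = function(e) NULL
      )
      if (is.null(fit) || !is.finite(fit$value)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best)) abort("all optimizer restarts failed.")
  xy <- matrix(best$par, n, 2, dimnames = list(ids, c("x", "y")))
  structure(
    list(params = p, landmark_ids = ids, landmark_D = D, landmark_xy = xy,
         final_stress = sm_stress(D, xy, p, weights),
         label = sigmoid_label(p)),
    class = "sketch_map"
  )
}

#' @export
print.sketch_map <- function(x, ...) {
  cat(sprintf("<sketch_map> %s: %d landmarks, stress %.4g\n",
              x$label, length(x$landmark_ids), x$final_stress))
  invisible(x)
}

#' Farthest-point-sampling landmark selection
#'
#' Greedy max-min selection: starting from `seed_index`, repeatedly add the
#' point whose minimum distance to the chosen set is largest (ties broken by
#' lowest index).
#'
#' @param D Symmetric distance matrix.
#' @param m Number of landmarks (1 <= m <= N).
#' @param seed_index 1-based index of the first landmark.
#' @return Integer vector of `m` indices in selection order.
#' @export
farthest_point_sample <- function(D, m, seed_index = 1L) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (m < 1 || m > n) abort("`m` must be between 1 and N.")
  if (seed_index < 1 || seed_index > n) abort("`seed_index` out of range.")
  chosen <- integer(m)
  chosen[1] <- as.integer(seed_index)
  mind <- D[, seed_index]
  mind[chosen[1]] <- -Inf
  if (m > 1) {
    for (k in 2:m) {
      nxt <- which.max(mind)        # leftmost maximum: lowest-index tie-break
      chosen[k] <- nxt
      mind <- pmin(mind, D[, nxt])
      mind[chosen[1:k]] <- -Inf
    }
  }
  chosen
}

#' Out-of-sample sketch-map projection
#'
#' Places one new structure on an existing map by minimizing its stress
#' against the fixed landmarks: a coarse grid search over the (padded)
#' landmark bounding box followed by gradient-based refinement from the best
#' grid cell.
#'
#' @param model A [sketchmap_fit()] result.
#' @param d_to_landmarks Vector of high-dimensional distances from the new
#'   structure to each landmark, in landmark order.
#' @param grid_n Grid resolution per axis.
#' @param pad Bounding-box padding fraction per side.
#' @return Named numeric of length 2 (`x`, `y`).
#' @export
sm_project <- function(model, d_to_landmarks, grid_n = 64L, pad = 0.25) {
  if (!inherits(model, "sketch_map") || !length(model$landmark_ids)) {
    abort("`model` must be a fitted sketch_map.")
  }
  m <- nrow(model$landmark_xy)
  if (length(d_to_landmarks) != m) {
    abort("`d_to_landmarks` length must equal the landmark count.")
  }
  p <- model$params
  Ft <- sm_sigmoid(as.numeric(d_to_landmarks), p, "high")
  L <- model$landmark_xy
  obj_at <- function(pts) {
    # pts: k x 2; returns k objective values
    dx <- outer(pts[, 1], L[, 1], "-")
    dy <- outer(pts[, 2], L[, 2], "-")
    dd <- sqrt(dx^2 + dy^2)
    fd <- sigmoid_eval(dd, p$sigma, p$a_ld, p$b_ld)
    rowSums(sweep(fd, 2, Ft)^2)
  }
  rx <- range(L[, 1]); ry <- range(L[, 2])
  ex <- max(diff(rx), 1e-6) * pad; ey <- max(diff(ry), 1e-6) * pad
  gx <- seq(rx[1] - ex, rx[2] + ex, length.out = grid_n)
  gy <- seq(ry[1] - ey, ry[2] + ey, length.out = grid_n)
  grid <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  vals <- obj_at(grid)
  x0 <- grid[which.min(vals), ]
  fn <- function(par) obj_at(matrix(par, 1, 2))
  gr <- function(par) {
    dx <- par[1] - L[, 1]; dy <- par[2] - L[, 2]
    dd <- pmax(sqrt(dx^2 + dy^2), 1e-12)
    fd <- sigmoid_eval(dd, p$sigma, p$a_ld, p$b_ld)
    fp <- sigmoid_deriv(dd, p$sigma, p$a_ld, p$b_ld)
    coef <- 2 * (fd - Ft) * fp / dd
    c(sum(coef * dx), sum(coef * dy))
  }
  fit <- optim(x0, fn, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  stats::setNames(fit$par, c("x", "y"))
}

#' Build a sketch-map of a dataset distance matrix
#'
#' High-level driver: selects `n_landmarks` by farthest point sampling, fits
#' the landmark map, and places the remaining structures by out-of-sample
#' projection.
#'
#' @param D Symmetric distance matrix with ids as dimnames.
#' @param p A [sigmoid_params()], or `NULL` to use defaults with
#'   [auto_sigma()].
#' @param n_landmarks Number of landmarks (capped at N).
#' @param seed Seed for the fit restarts.
#' @param n_starts,grid_n Passed to [sketchmap_fit()] / [sm_project()].
#' @return List with `model` (a `"sketch_map"`) and `embedding`, a tibble
#'   `id, x, y, landmark, stress_contribution`.
#' @export
sketchmap <- function(D, p = NULL, n_landmarks = min(nrow(D), 500L),
                      seed = 42L, n_starts = 5L, grid_n = 64L) {
  check_distance_matrix(D)
  ids <- matrix_ids(D)
  if (is.null(p)) p <- sigmoid_params(sigma = auto_sigma(D))
  n <- nrow(D)
  m <- min(n_landmarks, n)
  lm_idx <- farthest_point_sample(D, m)
  Dl <- D[lm_idx, lm_idx, drop = FALSE]
  dimnames(Dl) <- list(ids[lm_idx], ids[lm_idx])
  model <- sketchmap_fit(Dl, p, seed = seed, n_starts = n_starts)
  xy <- matrix(NA_real_, n, 2, dimnames = list(ids, c("x", "y")))
  xy[lm_idx, ] <- model$landmark_xy
  rest <- setdiff(seq_len(n), lm_idx)
  for (i in rest) {
    xy[i, ] <- sm_project(model, D[i, lm_idx], grid_n = grid_n)
  }
  # per-structure stress contribution against the landmarks
  FT <- sm_sigmoid(D[, lm_idx, drop = FALSE], p, "high")
  dmap <- sqrt(outer(xy[, 1], xy[lm_idx, 1], "-")^2 +
                 outer(xy[, 2], xy[lm_idx, 2], "-")^2)
  fmap <- sm_sigmoid(dmap, p, "low")
  contrib <- rowSums((FT - fmap)^2)
  contrib[lm_idx] <- contrib[lm_idx] - 0   # landmark self-term is zero already
  emb <- tibble(id = ids, x = xy[, 1], y = xy[, 2],
                landmark = seq_len(n) %in% lm_idx,
                stress_contribution = contrib)
  list(model = model, embedding = emb)
}

# ---------------------------------------------------------------------------
# Model persistence (plain-text JSON).

#' Save or load a sketch-map model
#'
#' JSON container holding the sigmoid parameters (with the `sigma-A_B-a_b`
#' label), landmark ids, landmark distance matrix and 2-D coordinates, plus
#' an optional kernel-settings block so out-of-sample projection can
#' recompute distances consistently.
#'
#' @param model A `"sketch_map"` object.
#' @param path Output path (`.json`).
#' @param kernel_settings Optional list (SOAP parameters, gamma, normalize)
#'   stored alongside the model.
#' @return `path` (write) / a `"sketch_map"` (read).
#' @export
write_sketchmap <- function(model, path, kernel_settings = NULL) {
  payload <- list(
    label = model$label,
    params = unclass(model$params),
    landmark_ids = model$landmark_ids,
    landmark_D = model$landmark_D,
    landmark_xy = model$landmark_xy,
    final_stress = model$final_stress,
    kernel_settings = kernel_settings
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sketchmap
#' @export
read_sketchmap <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- do.call(sigmoid_params, x$params)
  D <- as.matrix(x$landmark_D)
  xy <- as.matrix(x$landmark_xy)
  ids <- as.character(x$landmark_ids)
  dimnames(D) <- list(ids, ids)
  dimnames(xy) <- list(ids, c("x", "y"))
  model <- structure(
    list(params = p, landmark_ids = ids, landmark_D = D, landmark_xy = xy,
         final_stress = as.numeric(x$final_stress), label = x$label),
    class = "sketch_map"
  )
  attr(model, "kernel_settings") <- x$kernel_settings
  model
}
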